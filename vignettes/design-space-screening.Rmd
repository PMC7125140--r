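---
title: "Screening power-law kinetic models for autonomous oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening power-law kinetic models for autonomous oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscidesign)
```

## The problem

Finding parameter sets at which a nonlinear kinetic model exhibits an
autonomous limit cycle is hard: the oscillatory region is usually a thin,
curved sliver of a high-dimensional parameter space, and blind random
sampling almost never hits it. `oscidesign` implements a screening strategy
built on the design-space (S-system dominance) decomposition of Generalized
Mass Action (GMA) models:

1. **Partition** the parameter space into *phenotypes*: for each differential
   equation exactly one production and one consumption term is assumed to
   dominate numerically; every such choice defines a candidate subsystem
   (an S-system) plus the inequalities under which the choice is
   self-consistent.
2. **Validate** each phenotype by linear programming: the dominance
   inequalities are linear in the logarithms of parameters and states, and
   the steady state of an S-system is the solution of a *linear* system in
   log space, so the states can be eliminated and feasibility of the
   phenotype region inside the global parameter bounds is an LP.
3. **Sample** each valid phenotype log-uniformly inside its own boundaries.
4. **Screen** every sampled steady state for a complex-conjugate eigenvalue
   pair with non-negative real part — the necessary condition for a
   Hopf-born limit cycle.
5. **Verify** only the qualifying samples by integrating the full model and
   applying explicit limit-cycle acceptance rules (peak counts, amplitudes,
   cross-species ratio, peak order).

The expensive step (numerical integration) is run only on the small fraction
of samples that pass the cheap algebraic filter.

## GMA models and the S-system reduction

A GMA model writes each rate as a signed sum of power-law terms
$c\,\prod_k x_k^{g_k}$, one line per species:

```{r}
m <- parse_gma_model(c(
  "x' = a1 + a2*y - b1*x - b2*x*y",
  "y' = c1*x  - d1*y - d2*y^2"))
m
count_signatures(m)
```

For a phenotype signature (one dominant term per side per equation), the
steady-state condition `log(production) = log(consumption)` is linear in
`log10` of states and parameters:

```{r}
ss <- build_ssystem(m, 1)
v <- phenotype_validity(ss)
v$feasible
ssystem_steady_state(ss, v$witness)
```

Saturable (rational) regulation is represented with *denominator
auxiliaries*: an inhibited synthesis $v_x K/(K + z)$ becomes the power-law
term `v_x*K*D^-1` with the algebraic relation `D = K + z`. The auxiliary's
terms take part in dominance enumeration exactly like production terms, so
the two regimes of the inhibition (`K` dominant: no inhibition; `z`
dominant: full repression) appear as distinct phenotypes. Pure power-law
auxiliaries (such as quasi-steady-state complexes `c_x = K_A*x*s`) are
flattened away by `substitute_auxiliaries()` before any design-space work.

### Numerical choices

* All log-linear algebra uses `log10`; parameter bounds default to
  $[10^{-9}, 10^3]$, the screening range of the study this package
  re-implements.
* A phenotype whose log-linear system is singular (reciprocal condition
  number below $10^{-12}$) is recorded as *degenerate* and excluded from
  sampling; its region may be non-empty but its S-system has no unique
  steady state to screen. Degenerate counts are reported, never silently
  dropped.
* Phenotype feasibility is decided by a max-margin (Chebyshev-style) LP
  solved with `boot::simplex()`: we maximise the common slack of all
  dominance inequalities and bound constraints. The optimum is an interior
  point whenever the region is full-dimensional, which we use directly as
  the witness — at the witness's steady state the chosen terms strictly
  dominate. (A vertex witness would sit exactly on dominance ties and need
  an ad hoc inward shift.) The margin is capped at 6 decades to keep the LP
  bounded.
* Dominance boundaries are non-strict; ties therefore belong to both
  adjacent phenotypes.

## Sampling inside a phenotype

Parameter sets are drawn by the study's sequential-tolerance procedure:
start from the LP witness, shuffle the parameter order (a fresh shuffle per
point, so no parameter systematically constrains the later ones), then for
each parameter compute its *phenotypic tolerance* — the exact 1D interval
within which all boundaries stay satisfiable given the values fixed so far —
and draw log-uniformly inside it. Every returned point provably satisfies
all boundaries; unconstrained parameters get exact log-uniform marginals
over the full 12 decades. "Log-uniform" means uniform in `log10`: in models
whose parameters act multiplicatively, equal relative changes are equally
probable.

Seeding: each pipeline run takes one integer seed; per-phenotype substreams
are derived arithmetically from `(seed, case_id)`, so results are
reproducible and independent of scheduling order.

## Limit-cycle verification

`integrate_full_model()` integrates the *full* GMA model (all terms) in
500-minute windows at 0.1-minute output resolution, up to a 10,000-minute
horizon, with a fallback chain of integrators per window: `lsoda`
(stiff-switching), `bdf` (implicit multistep), then a Dormand–Prince
explicit Runge–Kutta pair. The explicit fallback gets a bounded step budget:
it exists to rescue non-stiff failures and must not crawl through stiff
problems. Any window that no integrator completes with finite values yields
the verdict `integration_failure` (never an exception).

After each window the classifier inspects the last window only:

* **Limit cycle** — every observable species shows at least five
  *qualifying maxima* (local maxima within 5% of the window's global
  maximum) in a repeating circular order matching the expected peak order
  (Sic1 → Clb5 → Clb3 → Clb2 for the cell-cycle designs); each species'
  amplitude is at least 10% of its window maximum; the spread between
  species maxima is below 100-fold; and qualifying maxima are not confined
  to the first half of the window (that would indicate damping). The
  "not only in the beginning" rule is operationalised as: at least one
  qualifying maximum per species in the second half of the window.
* **Steady state** — no concentration moved more than 1% of its global
  maximum within the last window.
* Otherwise integration continues; at the horizon the verdict is
  `undetermined`.

The period is measured as the mean spacing of qualifying maxima of the last
species in the expected order (Clb2), configurable; for a periodic orbit any
single species suffices. Integration starts at the phenotype's S-system
steady state with a 1% perturbation on the first species — starting exactly
on an unstable equilibrium can stall the escape indefinitely.

Window length is a package choice (the source protocol fixes only the
horizon): 500 minutes comfortably holds the required five peaks at the
tens-of-minutes periods these models produce.

## The built-in cell-cycle designs

Eleven minimal budding-yeast Clb/Cdk1 network designs ship as plain-text
model files (`inst/extdata/designs/`). The family describes three
cyclin/Cdk1 complexes — Clb5 (`x`, S phase), Clb3 (`y`, G2), Clb2 (`z`, M) —
and their stoichiometric inhibitor Sic1 (`s`, G1), with basal synthesis
(`v_*`) and degradation (`beta_*`), cascade activations (`alpha_xy`,
`alpha_yz`, `alpha_xz`), positive feedback loops (`alpha_yy`, `alpha_zz`),
APC-mediated inhibitions (`gamma_*`), and degradation of Sic1 (`delta`) or
of the Clb moiety (`epsilon`) out of the ternary Clb/Cdk1/Sic1 complexes.

Designs `1A`–`2` carry the ternary complexes as explicit mass-action species
(`k_on`, `k_off`; 7 dynamic variables). Designs `3`–`9` use the
quasi-steady-state approximation `c_i = K_A * i * s` (4 dynamic variables);
designs `4`–`9` each add one saturable inhibition to Design 3 (e.g. Design 4:
Clb2/Cdk1 represses Clb5 synthesis through `K_zx`).

**Provenance.** The packaged files are a *synthetic reference
reconstruction*: they encode the published description of the interaction
network (which species activates, inhibits or sequesters which, and through
what mechanism) rather than a verbatim transcription of the original model
equations, and they are marked as such in each file. Where the intermediate designs `1B`, `1C`, `2` are
described only qualitatively, we chose a progressive series — `1A`: basal
core plus the two feed-forward activations; `1B`: plus the Clb3 → Clb2
cascade step; `1C`: plus the two PFLs; `2`: plus the APC-type inhibitions;
`3` = QSSA of `2` — so that the QSSA family extends the mass-action family
coherently. Counts derived from these files (phenotype totals in
particular) depend on this reconstruction and on the fact that this
package's dominance enumeration is a plain product over equation sides; they
are not expected to match numbering or totals of other design-space
implementations.

Under the reconstruction, Design 3 has 21 parameters and designs 4–9 have
22 (the extra inhibition constant `K`); the mass-action designs replace
`K_A` by `k_on`/`k_off`.

### What the QSSA does and does not preserve

With association equilibrium `c_i = K_A i s`, degrading Sic1 out of a
complex (`delta`) consumes `s`, and degrading the Clb moiety (`epsilon`)
consumes `i` — this is exactly the limit of the mass-action designs when
complexes equilibrate fast. Two caveats, verified numerically in the test
suite: convergence of Design 2 trajectories to Design 3 requires (i) fast
equilibration (`k_off` large against the other rates) **and** (ii) weak
sequestration (`K_A`·concentrations small). The simple QSSA form neglects
the mass buffered in the complexes, so at strong sequestration a residual
discrepancy of order `K_A * i * s` persists no matter how fast the
equilibrium — the correct limiting statement, and the form the test
asserts.

## The screening pipeline

```{r, eval = FALSE}
ds <- prepare_design_space(get_design("3")$model)  # seed-independent part
res <- run_design_screen("3", samples_per_phenotype = 25, seed = 1,
                         design_space = ds)
summarize_counts(res)
count_dominant_parameters(res)
```

A phenotype counts toward "potential for oscillations" when at least one of
its samples passes the eigenvalue screen (the count is per phenotype, not
per sample — the header of the corresponding summary table is phrased per
phenotype). The eigenvalue screen is a necessary-condition filter computed
on the *dominant subsystem*; the full model's stability can differ in both
directions, which is why verified limit cycles are established by
integration and why some oscillations may be missed (a limitation the
screening methodology accepts by construction).

Problem sizes: the study protocol samples each valid phenotype 250 times
(`samples_per_phenotype` default). The package's own desk-scale protocol —
used in the test suite and the acceptance script — runs Design 3 at 25
samples per phenotype, which keeps a full screen in the minutes range while
preserving the pipeline end to end; `scripts/full_scale.R` runs Designs 3
and 7 at the full 250. Under the reconstruction, Design 3 has 2304
phenotypes, of which about 1400 are valid and about 900 degenerate; roughly
1–2% of sampled parameter sets pass the eigenvalue screen. Verified limit
cycles are *rare* — most sustained oscillations with the correct peak order
fail the 100-fold cross-species ratio rule — which mirrors the rarity
reported by the original study (a handful of cycles out of ~7·10⁵ samples).
At 25 samples per phenotype a single seed may well retrieve none; the
acceptance layer therefore tries several seeds.

## Downstream analyses

All analyses are pure functions of the screen result and return tibbles
(with `tidy()`/`glance()`/`autoplot()` methods):

* `count_dominant_parameters()` — in how many limit-cycle phenotypes each
  parameter's coefficient is dominant (per phenotype, not per cycle);
  parameters structurally present in every phenotype (sole synthesis terms)
  are flagged.
* `parameter_correlations()` / `pca_projection()` — Pearson correlations and
  PCA of the limit-cycle parameter sets, computed on `log10` values
  (standardised to mean 0, variance 1 for PCA) because the sampled
  parameters span orders of magnitude. `pool_design_records()` renames each
  design's specific inhibition constant to a common `K` for cross-design
  pooling.
* `period_parameter_sensitivity()` — scaled sensitivities ∂lnT/∂ln p by
  central differences with re-integration. Dimensional analysis fixes a
  summation theorem: scaling all rate coefficients by λ rescales time by
  1/λ, so the sensitivities of all rate coefficients sum to −1; the test
  suite verifies this within 5% on the fixture oscillator, and by a direct
  λ = 2 rescale.
* `bifurcation_scan_1d()` — full-model oscillation envelope along one
  parameter (integrations continue from the neighbouring scan value's final
  state, sweeping outward from the limit cycle), plus the steady-state
  branches and positive-eigenvalue counts of every phenotype valid at each
  scan value (multi-stability appears as multiple branches).
* `robustness_scan_2d()` — random log-uniform 2D scan around a cycle with
  the amplitude of a chosen species (Clb5 by default, configurable); a
  thin-plate spline interpolation onto a regular grid is attached for
  rendering, with a nearest-neighbour fallback for degenerate sample sets —
  the raw samples remain the data of record.
* `phenotype_phase_plane()` — which phenotypes are valid at each point of a
  2D log-grid, with their positive-eigenvalue counts; overlapping regions
  indicate multi-stability.

## Fixture models and what passing tests show

Three small fixtures with known dynamics anchor the test suite:

* `negative_feedback_3node` — a Goodwin-type power-law loop whose fixed
  point loses stability exactly at feedback exponent 8 (secant condition);
  the default exponent 12 oscillates over a sizeable region. Its parameter
  bounds are deliberately `[0.1, 10]` so that random screening hits the
  oscillatory region at useful frequency. It provides the end-to-end screen
  check and the sensitivity summation check.
* `lotka_volterra` — a conservative centre with eigenvalues ±i√(ad): the
  canonical "oscillatory pair with zero real part" edge case.
* `linear_chain` — no feedback, all eigenvalues real negative: the screen
  must find nothing.

The synthetic-data side of the tests (constructed phase-shifted sinusoids,
damped and order-violating variants) exercises every acceptance rule of the
classifier with known ground truth. What passing these tests does *not*
show: that the reconstruction reproduces the original study's exact counts —
the equations are a reconstruction, and the dominance enumeration is
implementation-relative — nor that the classifier's thresholds are
biologically optimal; they are the published acceptance rules, implemented
as stated.

## Known limitations

* Dominance enumeration is the plain per-equation product; hierarchical
  cases, co-dominance and cycle-based case analyses of richer design-space
  toolboxes are out of scope, so "total phenotypes" counts are
  implementation-relative.
* The eigenvalue filter can miss oscillations whose dominant subsystem is
  stable while the full model is not.
* Degenerate phenotypes are excluded from sampling rather than analysed.
* Periods are measured from discrete qualifying maxima on a 0.1-minute
  grid; sub-grid precision is not attempted.
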