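# End-to-end screening pipeline for one design: enumerate phenotypes, decide
# validity by LP, sample valid phenotypes log-uniformly, screen sampled
# steady states for a Hopf-type eigenvalue pair, and verify limit cycles by
# full-model integration.

#' Precompute a model's design space for repeated screening
#'
#' Enumerates all phenotype signatures, builds their S-systems and decides LP
#' validity once, so that repeated screens (e.g. over several seeds) do not
#' redo the seed-independent work.
#'
#' @param model A `gma_model` (flattened internally).
#' @param bounds Optional global bounds override (length-2 numeric).
#' @return List of class `design_space` with the per-phenotype S-systems,
#'   validity flags and LP witnesses.
#' @export
prepare_design_space <- function(model, bounds = NULL) {
  if (!is.null(bounds)) model <- set_parameter_bounds(model, bounds[1], bounds[2])
  flat <- substitute_auxiliaries(model)
  total <- count_signatures(flat)
  entries <- vector("list", total)
  it <- enumerate_signatures(flat)
  repeat {
    nxt <- it()
    if (is.null(nxt)) break
    ss <- build_ssystem(flat, nxt$signature)
    entry <- list(case_id = nxt$case_id, ssystem = ss,
                  degenerate = ss$degenerate, feasible = FALSE, error = FALSE,
                  witness = NULL)
    if (!ss$degenerate) {
      val <- tryCatch(phenotype_validity(ss), error = function(e) NULL)
      if (is.null(val)) entry$error <- TRUE
      else {
        entry$feasible <- val$feasible
        entry$witness <- val$witness
      }
    }
    entries[[nxt$case_id]] <- entry
  }
  structure(list(model = flat, total = total, entries = entries,
                 bounds = bounds), class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space> ", x$model$name, ": ", x$total, " phenotypes, ",
      sum(vapply(x$entries, `[[`, TRUE, "feasible")), " valid, ",
      sum(vapply(x$entries, `[[`, TRUE, "degenerate")), " degenerate\n", sep = "")
  invisible(x)
}


#' Screen one design for autonomous limit cycles
#'
#' For every valid phenotype, `samples_per_phenotype` log-uniform parameter
#' sets are drawn inside its boundaries; each sample's S-system steady state
#' is screened for a complex-conjugate eigenvalue pair with non-negative real
#' part (the necessary, Hopf-type condition); only qualifying samples are
#' integrated in the full model, starting at the phenotype steady state with
#' a 1% perturbation on the first species, and classified. A phenotype counts
#' as having "potential for oscillations" when at least one of its samples
#' passes the eigenvalue screen.
#'
#' @param design A `cellcycle_design`, a `gma_model`, or a design id.
#' @param samples_per_phenotype Samples drawn per valid phenotype
#'   (study default 250).
#' @param seed Integer seed; per-phenotype substreams are derived from it so
#'   results are reproducible and schedule-independent.
#' @param bounds Optional global bounds override (length-2 numeric).
#' @param horizon,window_length,dt Integration controls (minutes); see
#'   [integrate_full_model()].
#' @param perturbation Relative perturbation applied to the first dynamic
#'   variable of the initial steady state.
#' @param progress Print per-phenotype progress.
#' @param design_space Optional precomputed [prepare_design_space()] result
#'   (overrides `bounds`); the seed-independent enumeration/validity work is
#'   then reused across seeds.
#' @return Object of class `screen_result`: `design`, `config`, `counts`
#'   (named list mirroring the summary-table columns), `phenotypes` (tibble:
#'   case_id, valid, degenerate, n_sampled, n_potential, n_limit_cycles),
#'   `samples` (tibble of all retained samples with stability flags and
#'   verdicts) and `records` (tibble of verified limit cycles with period,
#'   per-species amplitude statistics, peak order and the full parameter
#'   set).
#' @export
run_design_screen <- function(design, samples_per_phenotype = 250, seed = 1L,
                              bounds = NULL, horizon = 10000,
                              window_length = 500, dt = 0.1,
                              perturbation = 0.01, progress = FALSE,
                              design_space = NULL) {
  if (inherits(design, "cellcycle_design")) {
    model <- design$model; design_id <- design$id
  } else if (inherits(design, "gma_model")) {
    model <- design; design_id <- design$name
  } else {
    d <- get_design(design); model <- d$model; design_id <- d$id
  }
  if (is.null(design_space)) design_space <- prepare_design_space(model, bounds)
  flat <- design_space$model
  total <- design_space$total
  pn <- flat$parameters$name

  phen_rows <- list(); sample_rows <- list(); record_rows <- list()
  failures <- 0L
  for (entry in design_space$entries) {
    cid <- entry$case_id
    if (entry$error) { failures <- failures + 1L; next }
    if (entry$degenerate || !entry$feasible) {
      phen_rows[[length(phen_rows) + 1L]] <- tibble::tibble(
        case_id = cid, valid = FALSE, degenerate = entry$degenerate,
        n_sampled = 0L, n_potential = 0L, n_limit_cycles = 0L)
      next
    }
    ss <- entry$ssystem
    sub_seed <- phenotype_seed(seed, cid)
    pts <- tryCatch(
      sample_valid_phenotype(ss, samples_per_phenotype, seed = sub_seed,
                             witness = entry$witness),
      error = function(e) NULL)
    if (is.null(pts)) { failures <- failures + 1L; next }
    n_pot <- 0L; n_lc <- 0L
    pmat <- as.matrix(pts[, pn, drop = FALSE])
    nr <- nrow(pmat)
    col_nn <- integer(nr); col_osc <- logical(nr)
    col_verdict <- rep(NA_character_, nr); col_period <- rep(NA_real_, nr)
    keep_row <- logical(nr)
    for (r in seq_len(nr)) {
      p <- stats::setNames(pmat[r, ], pn)
      rep_ <- tryCatch(stability_report(ss, p), error = function(e) NULL)
      if (is.null(rep_)) next
      keep_row[r] <- TRUE
      col_nn[r] <- rep_$n_nonnegative_real
      col_osc[r] <- rep_$has_oscillatory_pair
      if (rep_$has_oscillatory_pair) {
        n_pot <- n_pot + 1L
        init <- rep_$steady_state
        init[1] <- init[1] * (1 + perturbation)
        lc <- detect_limit_cycle(flat, p, init, horizon = horizon,
                                 window_length = window_length, dt = dt)
        col_verdict[r] <- lc$verdict
        if (lc$verdict == "limit_cycle") {
          n_lc <- n_lc + 1L
          col_period[r] <- lc$period
          stats_wide <- stats::setNames(
            as.list(c(lc$species$max, lc$species$min, lc$species$amp_frac)),
            c(paste0("max_", lc$species$species),
              paste0("min_", lc$species$species),
              paste0("amp_frac_", lc$species$species)))
          record_rows[[length(record_rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(design = design_id, case_id = cid, sample = r,
                           seed = sub_seed, period = lc$period,
                           min_amp_frac = min(lc$species$amp_frac),
                           peak_order = lc$peak_order),
            tibble::as_tibble(stats_wide),
            tibble::as_tibble(as.list(p)))
        }
      }
    }
    if (any(keep_row)) {
      sample_rows[[length(sample_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(case_id = cid, sample = which(keep_row),
                       n_nonnegative = col_nn[keep_row],
                       oscillatory_pair = col_osc[keep_row],
                       verdict = col_verdict[keep_row],
                       period = col_period[keep_row]),
        tibble::as_tibble(pmat[keep_row, , drop = FALSE]))
    }
    phen_rows[[length(phen_rows) + 1L]] <- tibble::tibble(
      case_id = cid, valid = TRUE, degenerate = FALSE,
      n_sampled = nrow(pts), n_potential = n_pot, n_limit_cycles = n_lc)
    if (progress) {
      message(sprintf("phenotype %d: potential %d, limit cycles %d",
                      cid, n_pot, n_lc))
    }
  }

  phenotypes <- dplyr::bind_rows(phen_rows)
  samples <- if (length(sample_rows)) dplyr::bind_rows(sample_rows) else tibble::tibble()
  records <- if (length(record_rows)) dplyr::bind_rows(record_rows) else tibble::tibble()
  counts <- list(
    total_phenotypes = total,
    valid_phenotypes = sum(phenotypes$valid),
    degenerate_phenotypes = sum(phenotypes$degenerate),
    potential_phenotypes = sum(phenotypes$n_potential > 0),
    lc_phenotypes = sum(phenotypes$n_limit_cycles > 0),
    limit_cycles = sum(phenotypes$n_limit_cycles),
    failed_phenotypes = failures
  )
  structure(list(
    design = design_id,
    config = list(samples_per_phenotype = samples_per_phenotype, seed = seed,
                  bounds = bounds, horizon = horizon,
                  window_length = window_length, dt = dt,
                  perturbation = perturbation,
                  package_version = as.character(utils::packageVersion("oscidesign")),
                  model_md5 = model_digest(flat)),
    counts = counts, phenotypes = phenotypes, samples = samples,
    records = records
  ), class = "screen_result")
}

phenotype_seed <- function(seed, case_id) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(case_id) * 7919) %% 2147483647)
}

# md5 of the model's canonical text, so any result traces back to the exact
# equations that produced it
model_digest <- function(model) {
  tf <- tempfile(fileext = ".gma")
  on.exit(unlink(tf))
  writeLines(write_gma_model(model), tf)
  unname(tools::md5sum(tf))
}

#' Phenotype table of a design space
#'
#' @param design_space A [prepare_design_space()] result.
#' @return Tibble: case_id, signature (text form `prod/cons` per equation),
#'   valid, degenerate.
#' @export
phenotype_table <- function(design_space) {
  stopifnot(inherits(design_space, "design_space"))
  rows <- lapply(design_space$entries, function(e) {
    sig <- e$ssystem$signature
    tibble::tibble(
      case_id = e$case_id,
      signature = paste(paste0(sig["production", ], "/", sig["consumption", ]),
                        collapse = "|"),
      valid = e$feasible, degenerate = e$degenerate)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> design ", x$design, " (",
      x$config$samples_per_phenotype, " samples/phenotype, seed ",
      x$config$seed, ")\n", sep = "")
  print(summarize_counts(x))
  invisible(x)
}

#' One-row summary of a screen, mirroring the headline count table
#'
#' @param result A `screen_result`.
#' @return A one-row tibble: design, total/valid/degenerate phenotypes,
#'   phenotypes with oscillatory potential, phenotypes with limit cycles,
#'   limit cycles retrieved.
#' @export
summarize_counts <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  tibble::tibble(
    design = result$design,
    total_phenotypes = result$counts$total_phenotypes,
    valid_phenotypes = result$counts$valid_phenotypes,
    degenerate_phenotypes = result$counts$degenerate_phenotypes,
    potential_phenotypes = result$counts$potential_phenotypes,
    lc_phenotypes = result$counts$lc_phenotypes,
    limit_cycles = result$counts$limit_cycles
  )
}

#' Count parameters appearing in dominant terms of limit-cycle phenotypes
#'
#' For each parameter, the number of distinct phenotypes-with-limit-cycles in
#' whose dominant (S-system) terms the parameter's coefficient appears —
#' counted per phenotype, not per limit cycle. Parameters that appear in the
#' dominant terms of every phenotype by construction are flagged.
#'
#' @param result A `screen_result`.
#' @param model Optional model (defaults to the built-in design named by the
#'   result).
#' @return Tibble: parameter, count, always_present.
#' @export
count_dominant_parameters <- function(result, model = NULL) {
  stopifnot(inherits(result, "screen_result"))
  if (is.null(model)) model <- get_design(result$design)$model
  flat <- substitute_auxiliaries(model)
  pn <- flat$parameters$name
  lc_cases <- if (nrow(result$records)) unique(result$records$case_id) else numeric(0)
  in_dominant <- function(cid) {
    ss <- build_ssystem(flat, cid)
    dom <- ssystem_dominant_terms(ss)
    used <- logical(length(pn))
    for (d in dom) {
      used <- used | d$production$ce != 0 | d$consumption$ce != 0
    }
    used
  }
  counts <- rep(0L, length(pn))
  for (cid in lc_cases) counts <- counts + in_dominant(cid)
  # structurally always present: the parameter occurs in every term of some
  # equation side, so every signature's dominant terms include it (e.g. the
  # sole synthesis terms v_x, v_s of the cell-cycle designs)
  eqs <- ds_equations(flat)
  always <- rep(FALSE, length(pn))
  for (e in eqs) {
    for (side in c("production", "consumption")) {
      ce_all <- do.call(rbind, lapply(e[[side]], `[[`, "ce"))
      always <- always | apply(ce_all != 0, 2, all)
    }
  }
  tibble::tibble(parameter = pn, count = as.integer(counts),
                 always_present = always)
}
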