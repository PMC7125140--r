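fake_records <- function(n = 1000, seed = 1, p = 5) {
  withr::with_seed(seed, {
    X <- 10^matrix(stats::runif(n * p, -3, 3), n, p)
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- paste0("p", seq_len(p))
    dplyr::bind_cols(tibble::tibble(design = "toy", case_id = 1,
                                    sample = seq_len(n),
                                    period = stats::runif(n, 10, 50)), df)
  })
}

test_that("correlations: duplicates correlate perfectly, independents do not", {
  rec <- fake_records(1000, seed = 2)
  rec$p_dup <- rec$p1
  R <- parameter_correlations(rec)
  expect_equal(R["p1", "p_dup"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_equal(unname(diag(R)), rep(1, ncol(R)))
  off <- R[c("p2", "p3", "p4", "p5"), c("p2", "p3", "p4", "p5")]
  expect_lt(max(abs(off[upper.tri(off)])), 0.1)

  rec$flat <- 2  # zero variance -> undefined, reported missing
  rec$flat <- rec$flat + 0 # keep positive numeric
  R2 <- parameter_correlations(rec)
  expect_true(all(is.na(R2["flat", setdiff(colnames(R2), "flat")])))
})

test_that("PCA standardizes, ranks variance and preserves subspace geometry", {
  # all variance along one parameter (others constant): PC1 explains 100%
  rec <- fake_records(200, seed = 3, p = 1)
  rec$p2 <- 2; rec$p3 <- 5
  pc <- pca_projection(rec)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  # isotropic standardized 2D cloud: PC1 ~ 50%
  rec2 <- fake_records(10000, seed = 4, p = 2)
  pc2 <- pca_projection(rec2)
  expect_equal(pc2$explained[1], 0.5, tolerance = 0.02)
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_equal(sum(pc2$explained), 1, tolerance = 1e-9)

  # scores reproduce pairwise distances of the standardized data (p = 2)
  X <- scale(log10(as.matrix(rec2[, c("p1", "p2")])))
  d_orig <- stats::dist(X[1:50, ])
  d_pc <- stats::dist(pc2$all_scores[1:50, 1:2])
  expect_equal(as.numeric(d_pc), as.numeric(d_orig), tolerance = 1e-9)

  # permutation invariance of explained variance
  perm <- withr::with_seed(9, sample(nrow(rec2)))
  pc3 <- pca_projection(rec2[perm, ])
  expect_equal(pc3$explained, pc2$explained, tolerance = 1e-9)
})

test_that("pooling renames design-specific inhibition constants to K", {
  rec <- fake_records(5, seed = 5, p = 2)
  names(rec)[names(rec) == "p2"] <- "K_zx"
  res <- structure(list(design = "4", records = rec), class = "screen_result")
  pooled <- pool_design_records(list(res))
  expect_true("K" %in% names(pooled))
  expect_false("K_zx" %in% names(pooled))
})

test_that("period sensitivities satisfy the time-rescaling summation theorem", {
  nf <- make_fixture_oscillator("negative_feedback_3node")
  p <- nf3_base_params(nf)
  st <- ssystem_steady_state(build_ssystem(nf, 1), p)
  init <- st; init[1] <- init[1] * 1.01

  sens <- period_parameter_sensitivity(nf, p, init)
  expect_false(any(sens$cycle_lost))
  expect_equal(sum(sens$sensitivity), -1, tolerance = 0.05)

  # direct verification of the scaling law at lambda = 2
  base <- detect_limit_cycle(nf, p, init)
  doubled <- detect_limit_cycle(nf, p * 2, st * c(1.01, 1, 1))
  expect_equal(doubled$period, base$period / 2, tolerance = 0.02)
})

test_that("a coefficient multiplying every term has sensitivity -1", {
  nf <- parse_gma_model(c(
    "x1' = k*a1*x3^-12 - k*b1*x1",
    "x2' = k*a2*x1 - k*b2*x2",
    "x3' = k*a3*x2 - k*b3*x3"), bounds = c(0.1, 10))
  p <- stats::setNames(rep(1, 7), nf$parameters$name)
  st <- ssystem_steady_state(build_ssystem(nf, 1), p)
  sens <- period_parameter_sensitivity(nf, p, st * c(1.01, 1, 1))
  sk <- sens$sensitivity[sens$parameter == "k"]
  expect_equal(sk, -1, tolerance = 0.02)
})

test_that("1D bifurcation scans track the Hopf boundary and steady branches", {
  lin <- make_fixture_oscillator("linear_chain")
  p <- stats::setNames(rep(1, 6), lin$parameters$name)
  st <- ssystem_steady_state(build_ssystem(lin, 1), p)
  scan <- bifurcation_scan_1d(lin, p, "b1", log_range = c(-0.5, 0.5), n = 7,
                              species = names(lin$observables)[3],
                              initial_state = st, horizon = 1500)
  expect_true(all(scan$envelope$verdict == "steady_state"))
  expect_equal(scan$envelope$env_min, scan$envelope$env_max, tolerance = 1e-9)
  br <- scan$branches
  expect_true(all(br$n_positive == 0))
  # envelope equals the (unique) steady-state branch
  m <- merge(scan$envelope, br, by = "value")
  expect_equal(m$env_max, m$x3, tolerance = 1e-3)

  # Goodwin loop: the oscillatory range boundary along b1 agrees with the
  # eigenvalue sign change within one grid step
  nf <- make_fixture_oscillator("negative_feedback_3node")
  pnf <- nf3_base_params(nf)
  ssnf <- build_ssystem(nf, 1)
  stnf <- ssystem_steady_state(ssnf, pnf)
  lg <- seq(0, 1.1, length.out = 12)
  scan2 <- bifurcation_scan_1d(nf, pnf, "b1", log_range = range(lg), n = 12,
                               species = "x1",
                               initial_state = stnf * c(1.01, 1, 1),
                               horizon = 3000)
  osc <- scan2$envelope$verdict == "limit_cycle"
  eig_osc <- vapply(scan2$envelope$value, function(v) {
    p2 <- pnf; p2["b1"] <- v
    rep_ <- stability_report(ssnf, p2)
    any(Re(rep_$eigenvalues) > 0 & Im(rep_$eigenvalues) != 0)
  }, TRUE)
  # agreement up to one grid step around the threshold
  expect_lte(sum(osc != eig_osc), 1)
  expect_true(any(osc) && !all(osc))
})

test_that("2D robustness scans are reproducible with a non-negative amplitude", {
  nf <- make_fixture_oscillator("negative_feedback_3node")
  p <- nf3_base_params(nf)
  st <- ssystem_steady_state(build_ssystem(nf, 1), p)
  sc1 <- robustness_scan_2d(nf, p, c("b1", "b2"), n = 40, seed = 21,
                            species = "x1", initial_state = st * c(1.01, 1, 1),
                            horizon = 1500, grid_n = 12)
  expect_equal(nrow(sc1$samples), 40)
  expect_true(all(sc1$samples$amplitude >= 0))
  sc2 <- robustness_scan_2d(nf, p, c("b1", "b2"), n = 40, seed = 21,
                            species = "x1", initial_state = st * c(1.01, 1, 1),
                            horizon = 1500, grid_n = 12)
  expect_identical(sc1$samples, sc2$samples)

  # oscillating samples concentrate where both degradation rates are close,
  # consistent with the 1D Hopf geometry along each axis
  s <- sc1$samples
  ratio <- abs(log10(s$b1) - log10(s$b2))
  if (any(s$verdict == "limit_cycle") && any(s$verdict != "limit_cycle")) {
    expect_lt(median(ratio[s$verdict == "limit_cycle"]),
              median(ratio[s$verdict != "limit_cycle"]))
  }
})

test_that("phase planes agree with direct dominance evaluation", {
  m <- toy_sum()
  p0 <- c(a1 = 1, a2 = 1, b = 1)
  pp <- phenotype_phase_plane(m, p0, c("a1", "a2"),
                              log_ranges = rbind(c(-2, 2), c(-2, 2)), n = 9)
  expect_true(all(pp$case_id %in% seq_len(count_signatures(m))))
  # the boundary is the diagonal log a1 = log a2
  for (r in seq_len(nrow(pp))) {
    la1 <- pp[[1]][r]; la2 <- pp[[2]][r]
    sig <- build_ssystem(m, pp$case_id[r])$signature["production", 1]
    if (la1 > la2) expect_equal(unname(sig), 1L)
    if (la2 > la1) expect_equal(unname(sig), 2L)
  }
  # single-phenotype model covers the plane
  lin <- make_fixture_oscillator("linear_chain")
  pl <- phenotype_phase_plane(lin, stats::setNames(rep(1, 6), lin$parameters$name),
                              c("a1", "b1"), rbind(c(-1, 1), c(-1, 1)), n = 4)
  expect_equal(nrow(pl), 16)
  expect_equal(unique(pl$case_id), 1)
})

test_that("oscillation summaries are a pure function of the screen result", {
  nf <- make_fixture_oscillator("negative_feedback_3node")
  res <- run_design_screen(nf, samples_per_phenotype = 40, seed = 2)
  s1 <- oscillation_summaries(res)
  s2 <- oscillation_summaries(res)
  expect_identical(s1, s2)
  expect_true("period_min" %in% s1$quantity)
  per <- s1[s1$quantity == "period_min", ]
  expect_true(per$min <= per$median && per$median <= per$max)
})
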