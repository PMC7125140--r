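# Post-screen analyses: parameter correlations, PCA projections, period
# sensitivity, 1D bifurcation scans, 2D robustness heatmaps and phenotype
# phase planes.

records_param_matrix <- function(records, param_names) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(param_names, colnames(records))
  if (length(miss)) stop("records lack parameter column(s): ", paste(miss, collapse = ", "))
  as.matrix(records[, param_names, drop = FALSE])
}

#' Pairwise Pearson correlations of limit-cycle parameter sets
#'
#' Correlations are computed on log10 parameter values, since the sampled
#' parameters span orders of magnitude. Zero-variance parameters yield `NA`
#' for their pairs.
#'
#' @param records Data frame of limit-cycle parameter sets (e.g.
#'   `screen_result$records`).
#' @param param_names Parameter columns; defaults to every column after the
#'   bookkeeping columns that is fully positive numeric.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(records, param_names = NULL) {
  param_names <- param_names %||% guess_param_cols(records)
  if (nrow(records) < 3) stop("need at least 3 records")
  X <- log10(records_param_matrix(records, param_names))
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(stats::cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}

guess_param_cols <- function(records) {
  book <- c("design", "case_id", "sample", "seed", "period", "min_amp_frac",
            "peak_order", "n_nonnegative", "oscillatory_pair", "verdict")
  cand <- setdiff(colnames(records), book)
  cand <- cand[!grepl("^(max|min|amp_frac)_", cand)]
  cand[vapply(cand, function(cc) is.numeric(records[[cc]]) &&
                all(records[[cc]] > 0), TRUE)]
}

#' Principal component projection of limit-cycle parameter sets
#'
#' Log10 parameter values are standardized (mean 0, variance 1 per
#' parameter), then projected onto principal components. For pooling across
#' designs, rename each design's specific inhibition constant to a common
#' name before calling (see `pool_design_records()`).
#'
#' @param records Data frame of limit-cycle parameter sets.
#' @param param_names Parameter columns (default guessed as in
#'   [parameter_correlations()]).
#' @return Object of class `pca_projection`: `scores` tibble (2D scores plus
#'   bookkeeping columns), `loadings`, `explained` (variance fractions) and
#'   the standardized matrix dimensions.
#' @export
pca_projection <- function(records, param_names = NULL) {
  param_names <- param_names %||% guess_param_cols(records)
  if (nrow(records) < 3) stop("need at least 3 records")
  X <- log10(records_param_matrix(records, param_names))
  keep <- apply(X, 2, stats::sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  book <- intersect(c("design", "case_id", "sample", "period"), colnames(records))
  scores <- dplyr::bind_cols(
    tibble::as_tibble(records[, book, drop = FALSE]),
    tibble::tibble(PC1 = pc$x[, 1],
                   PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  )
  structure(list(scores = scores, loadings = pc$rotation,
                 explained = explained, n = nrow(Xs), p = ncol(Xs),
                 all_scores = pc$x),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("<pca_projection> ", x$n, " points, ", x$p, " parameters\n", sep = "")
  cat("  explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(x$explained))),
                    100 * x$explained[seq_len(min(4, length(x$explained)))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pool limit-cycle records across designs for joint PCA
#'
#' Renames each design's specific inhibition constant column (e.g. `K_zx`,
#' `K_zs`) to the common name `K`, so the pooled sets live in one shared
#' parameter space.
#'
#' @param results List of `screen_result`s.
#' @return Tibble of pooled records.
#' @export
pool_design_records <- function(results) {
  dplyr::bind_rows(lapply(results, function(res) {
    rec <- res$records
    if (!nrow(rec)) return(NULL)
    d <- tryCatch(get_design(res$design), error = function(e) NULL)
    if (!is.null(d) && !is.na(d$k_param) && d$k_param %in% colnames(rec)) {
      names(rec)[names(rec) == d$k_param] <- "K"
    }
    rec
  }))
}

#' Scaled sensitivity of the oscillation period to each parameter
#'
#' Central finite difference of log-period under a +/- `rel_step`
#' perturbation of each parameter's natural log, re-integrating the full
#' model and re-measuring the period each time. Scaling every rate
#' coefficient by a common factor rescales time by its inverse, so the
#' sensitivities of all rate coefficients sum to -1 (a summation theorem used
#' as a consistency check).
#'
#' @param model A `gma_model`.
#' @param lc_point Named parameter vector at which a limit cycle was
#'   verified.
#' @param initial_state Initial state for the re-integrations (e.g. the
#'   phenotype steady state, perturbed).
#' @param rel_step Log-perturbation step (natural log units).
#' @param horizon,window_length,dt Integration controls.
#' @return Tibble: parameter, sensitivity (`d ln T / d ln p`), `cycle_lost`
#'   flag for perturbations that break the limit cycle.
#' @export
period_parameter_sensitivity <- function(model, lc_point, initial_state,
                                         rel_step = 0.01, horizon = 10000,
                                         window_length = 500, dt = 0.1) {
  flat <- substitute_auxiliaries(model)
  base <- detect_limit_cycle(flat, lc_point, initial_state, horizon = horizon,
                             window_length = window_length, dt = dt)
  if (base$verdict != "limit_cycle") {
    stop("precondition error: baseline point is not a verified limit cycle")
  }
  pn <- flat$parameters$name
  period_at <- function(p) {
    lc <- detect_limit_cycle(flat, p, initial_state, horizon = horizon,
                             window_length = window_length, dt = dt)
    if (lc$verdict != "limit_cycle") NA_real_ else lc$period
  }
  rows <- lapply(pn, function(nm) {
    up <- lc_point; up[nm] <- up[nm] * exp(rel_step)
    dn <- lc_point; dn[nm] <- dn[nm] * exp(-rel_step)
    Tu <- period_at(up); Td <- period_at(dn)
    lost <- is.na(Tu) || is.na(Td)
    tibble::tibble(parameter = nm,
                   sensitivity = if (lost) NA_real_ else
                     (log(Tu) - log(Td)) / (2 * rel_step),
                   cycle_lost = lost)
  })
  dplyr::bind_rows(rows)
}

#' 1D bifurcation scan of the full model and its phenotype branches
#'
#' Sweeps one parameter over a log10 range. The full model is integrated at
#' every scan value, continuing from the previous value's final state
#' (outward from the limit-cycle point in both directions), giving the
#' oscillation envelope (min/max of the chosen species in the last window;
#' equal where the verdict is a steady state). Alongside, every
#' non-degenerate phenotype valid at each scan value contributes a
#' steady-state branch with its positive-eigenvalue count, reproducing
#' stable/unstable branch bookkeeping and multi-stability.
#'
#' @param model A `gma_model`.
#' @param lc_point Named parameter vector of a verified limit cycle.
#' @param param Parameter to scan.
#' @param log_range Length-2 numeric, log10 limits of the scan.
#' @param n Number of scan points.
#' @param species Observable label whose amplitude is reported (default the
#'   second peak-order species, Clb5 for the cell-cycle designs).
#' @param initial_state State at the limit-cycle point used to seed the
#'   sweep.
#' @param horizon,window_length,dt Integration controls.
#' @return List of class `bifurcation_scan`: `envelope` tibble (value,
#'   verdict, env_min, env_max) and `branches` tibble (value, case_id,
#'   steady_state, n_positive).
#' @export
bifurcation_scan_1d <- function(model, lc_point, param, log_range, n = 25,
                                species = model$peak_order[min(2, length(model$peak_order))],
                                initial_state, horizon = 4000,
                                window_length = 500, dt = 0.1) {
  flat <- substitute_auxiliaries(model)
  col <- flat$observables[[species]]
  values <- 10^seq(log_range[1], log_range[2], length.out = n)
  base_val <- lc_point[[param]]

  scan_one_direction <- function(vals, y0) {
    rows <- list()
    for (v in vals) {
      p <- lc_point; p[param] <- v
      traj <- integrate_full_model(flat, p, y0, horizon = horizon,
                                   window_length = window_length, dt = dt)
      verdict <- attr(traj, "verdict")
      if (verdict == "integration_failure" || !length(traj$time)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          value = v, verdict = "integration_failure",
          env_min = NA_real_, env_max = NA_real_)
        next
      }
      idx <- last_window_idx(traj)
      tr <- traj$states[idx, col]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        value = v, verdict = verdict,
        env_min = if (verdict == "steady_state") tr[length(tr)] else min(tr),
        env_max = if (verdict == "steady_state") tr[length(tr)] else max(tr))
      y0 <- stats::setNames(pmax(traj$states[nrow(traj$states), ], 1e-12),
                            flat$dynamic)
    }
    dplyr::bind_rows(rows)
  }
  lower <- rev(values[values <= base_val])
  upper <- values[values > base_val]
  env <- dplyr::arrange(dplyr::bind_rows(
    scan_one_direction(lower, initial_state),
    scan_one_direction(upper, initial_state)), .data$value)

  branches <- phenotype_branches(flat, lc_point, param, values)
  structure(list(envelope = env, branches = branches, param = param,
                 species = species, lc_value = base_val),
            class = "bifurcation_scan")
}

# steady-state branches of every phenotype valid along the scan line
phenotype_branches <- function(flat, base_params, param, values,
                               species_col = NULL) {
  cache <- ssystem_cache(flat)
  pn <- flat$parameters$name
  j <- match(param, pn)
  rows <- list()
  for (v in values) {
    p <- base_params[pn]; p[j] <- v
    logp <- log10(as.numeric(p))
    for (ss in cache) {
      if (nrow(ss$C) && min(ss$C %*% logp) < -1e-9) next
      x <- tryCatch(ssystem_steady_state(ss, stats::setNames(as.numeric(p), pn)),
                    error = function(e) NULL)
      if (is.null(x)) next
      rep_ <- stability_report(ss, stats::setNames(as.numeric(p), pn))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(value = v, case_id = ss$case_id,
                       n_positive = sum(Re(rep_$eigenvalues) > 1e-9)),
        tibble::as_tibble(as.list(x)))
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(value = numeric(), case_id = numeric(), n_positive = integer())
}

ssystem_cache <- function(flat) {
  n <- count_signatures(flat)
  out <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ss <- build_ssystem(flat, i)
    if (!ss$degenerate) { out[[i]] <- ss; keep[i] <- TRUE }
  }
  out[keep]
}

#' 2D robustness scan around a limit cycle
#'
#' Draws `n` random log-uniform samples of two parameters (all others fixed
#' at the limit-cycle point), integrates the full model at each sample and
#' records the oscillation amplitude of the chosen species (`max - min` in
#' the last window; 0 for a steady state). A thin-plate spline interpolation
#' onto a regular grid is provided for rendering; the raw samples remain the
#' data of record.
#'
#' @inheritParams bifurcation_scan_1d
#' @param params Character vector of the two parameters to vary.
#' @param n Number of random samples.
#' @param seed Integer seed.
#' @param log_bounds 2x2 matrix (rows = parameters) of log10 bounds, default
#'   +/- 1.5 decades around the limit-cycle values.
#' @param grid_n Interpolation grid resolution per axis.
#' @return List of class `robustness_scan`: `samples` tibble (two parameter
#'   columns, verdict, amplitude) and `grid` tibble (interpolated amplitude).
#' @export
robustness_scan_2d <- function(model, lc_point, params, n = 1000, seed = 1L,
                               log_bounds = NULL,
                               species = model$peak_order[min(2, length(model$peak_order))],
                               initial_state, horizon = 4000,
                               window_length = 500, dt = 0.1, grid_n = 40) {
  stopifnot(length(params) == 2)
  flat <- substitute_auxiliaries(model)
  col <- flat$observables[[species]]
  if (is.null(log_bounds)) {
    ctr <- log10(as.numeric(lc_point[params]))
    log_bounds <- cbind(ctr - 1.5, ctr + 1.5)
  }
  U <- withr::with_seed(seed, matrix(stats::runif(2 * n), n, 2))
  P <- sweep(sweep(U, 2, log_bounds[, 2] - log_bounds[, 1], `*`),
             2, log_bounds[, 1], `+`)
  rows <- lapply(seq_len(n), function(i) {
    p <- lc_point
    p[params] <- 10^P[i, ]
    traj <- integrate_full_model(flat, p, initial_state, horizon = horizon,
                                 window_length = window_length, dt = dt)
    verdict <- attr(traj, "verdict")
    amp <- 0
    if (verdict == "limit_cycle") {
      idx <- last_window_idx(traj)
      tr <- traj$states[idx, col]
      amp <- max(tr) - min(tr)
    }
    tibble::tibble(!!params[1] := 10^P[i, 1], !!params[2] := 10^P[i, 2],
                   verdict = verdict, amplitude = amp)
  })
  samples <- dplyr::bind_rows(rows)
  grid <- tps_grid(P, samples$amplitude, log_bounds, grid_n)
  names(grid)[1:2] <- paste0("log10_", params)
  structure(list(samples = samples, grid = grid, params = params,
                 species = species),
            class = "robustness_scan")
}

# thin-plate spline interpolation of scattered 2D data onto a regular grid;
# falls back to nearest neighbour if the spline system is degenerate
tps_grid <- function(X, y, log_bounds, grid_n) {
  gx <- seq(log_bounds[1, 1], log_bounds[1, 2], length.out = grid_n)
  gy <- seq(log_bounds[2, 1], log_bounds[2, 2], length.out = grid_n)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  D <- as.matrix(stats::dist(X))
  K <- phi(D)
  P <- cbind(1, X)
  Asys <- rbind(cbind(K + diag(1e-8, nrow(X)), P),
                cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(y, numeric(3))
  coefs <- tryCatch(solve(Asys, rhs), error = function(e) NULL)
  z <- if (is.null(coefs)) {
    # nearest neighbour fallback
    idx <- apply(G, 1, function(g) which.min((X[, 1] - g[1])^2 + (X[, 2] - g[2])^2))
    y[idx]
  } else {
    DG <- sqrt(outer(G[, 1], X[, 1], `-`)^2 + outer(G[, 2], X[, 2], `-`)^2)
    as.numeric(phi(DG) %*% coefs[seq_len(nrow(X))] +
                 cbind(1, G) %*% coefs[nrow(X) + 1:3])
  }
  tibble::tibble(x = G[, 1], y = G[, 2], amplitude = z)
}

#' Phenotype phase plane over two parameters
#'
#' For every point of a regular log10 grid over two parameters (all others
#' fixed), lists the set of phenotypes whose dominance boundaries are
#' satisfied there (overlaps mark multi-stability) together with each
#' phenotype's positive-eigenvalue count at its steady state.
#'
#' @param model A `gma_model`.
#' @param base_params Named parameter vector fixing the remaining
#'   parameters.
#' @param params Character vector of the two parameters to span.
#' @param log_ranges 2x2 matrix (rows = parameters) of log10 limits.
#' @param n Grid resolution per axis.
#' @return Tibble of class `phase_plane`: one row per (grid point, valid
#'   phenotype): the two log10 coordinates, `case_id`, `n_positive`.
#' @export
phenotype_phase_plane <- function(model, base_params, params, log_ranges, n = 30) {
  stopifnot(length(params) == 2)
  flat <- substitute_auxiliaries(model)
  pn <- flat$parameters$name
  cache <- ssystem_cache(flat)
  g1 <- seq(log_ranges[1, 1], log_ranges[1, 2], length.out = n)
  g2 <- seq(log_ranges[2, 1], log_ranges[2, 2], length.out = n)
  j1 <- match(params[1], pn); j2 <- match(params[2], pn)
  p0 <- check_params(flat, base_params)
  rows <- list()
  for (a in g1) for (b in g2) {
    p <- p0; p[j1] <- 10^a; p[j2] <- 10^b
    logp <- log10(p)
    for (ss in cache) {
      if (nrow(ss$C) && min(ss$C %*% logp) < -1e-9) next
      rep_ <- tryCatch(stability_report(ss, p), error = function(e) NULL)
      if (is.null(rep_)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        !!paste0("log10_", params[1]) := a,
        !!paste0("log10_", params[2]) := b,
        case_id = ss$case_id,
        n_positive = sum(Re(rep_$eigenvalues) > 1e-9))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(case_id = numeric(), n_positive = integer())
  class(out) <- c("phase_plane", class(out))
  out
}

#' Boxplot-style summaries of period, amplitude and parameter spread
#'
#' Pure function of a screen result: five-number summaries of the oscillation
#' period, the minimal amplitude fraction, and each parameter's log10 range
#' over the retrieved limit cycles.
#'
#' @param result A `screen_result`.
#' @return Tibble: quantity, n, min, q1, median, q3, max.
#' @export
oscillation_summaries <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  rec <- result$records
  if (!nrow(rec)) {
    return(tibble::tibble(quantity = character(), n = integer(),
                          min = numeric(), q1 = numeric(), median = numeric(),
                          q3 = numeric(), max = numeric()))
  }
  five <- function(nm, v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE, na.rm = TRUE)
    tibble::tibble(quantity = nm, n = sum(is.finite(v)), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  }
  pcols <- guess_param_cols(rec)
  dplyr::bind_rows(
    five("period_min", rec$period),
    five("min_amp_frac", rec$min_amp_frac),
    dplyr::bind_rows(lapply(pcols, function(cc) five(paste0("log10_", cc),
                                                     log10(rec[[cc]]))))
  )
}
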