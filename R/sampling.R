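# Log-uniform sampling inside a phenotype's dominance region.

#' Sample valid, log-uniform parameter sets within a phenotype
#'
#' Each point starts from the LP witness. The parameters are shuffled into a
#' random order (so no parameter systematically constrains the later ones);
#' then, parameter by parameter, the 1D phenotypic tolerance given the
#' already-fixed values is computed and a value drawn log-uniformly (uniform
#' in log10) within tolerance intersected with the global bounds. Every
#' returned point satisfies all boundary inequalities. A numerically
#' collapsed interval triggers a fresh shuffle (up to 10 retries) before the
#' point is skipped.
#'
#' @param ssystem A feasible `ssystem`.
#' @param n Number of points.
#' @param seed Integer seed; the same seed reproduces the same points.
#' @param bounds Optional bounds as in [phenotype_validity()].
#' @param witness Optional precomputed interior witness (as returned by
#'   [phenotype_validity()]), to avoid re-solving the LP.
#' @return A tibble with columns `case_id`, `sample`, `seed`, then one column
#'   per parameter.
#' @export
sample_valid_phenotype <- function(ssystem, n, seed = 1L, bounds = NULL,
                                   witness = NULL) {
  if (is.null(witness)) {
    val <- phenotype_validity(ssystem, bounds)
    if (!val$feasible) stop("precondition error: phenotype is infeasible")
    witness <- val$witness
  }
  bl <- param_log_bounds(ssystem$model, bounds)
  mat <- withr::with_seed(seed, sample_points_log(ssystem, n, log10(witness), bl))
  pn <- ssystem$model$parameters$name
  out <- tibble::as_tibble(stats::setNames(as.data.frame(10^mat), pn))
  dplyr::bind_cols(
    tibble::tibble(case_id = rep(ssystem$case_id, nrow(out)),
                   sample = seq_len(nrow(out)), seed = seed),
    out
  )
}

# matrix of log10 points (rows = points); assumes RNG already seeded
sample_points_log <- function(ssystem, n, witness_log, bl) {
  np <- length(witness_log)
  C <- ssystem$C
  pts <- matrix(NA_real_, 0, np)
  for (i in seq_len(n)) {
    for (attempt in seq_len(10L)) {
      logp <- witness_log
      resid <- if (nrow(C)) as.numeric(C %*% logp) else numeric(0)
      ok <- TRUE
      for (j in sample.int(np)) {
        iv <- tolerance_interval(C, resid, logp, j, bl$lower[j], bl$upper[j])
        if (iv[2] < iv[1] - 1e-9) { ok <- FALSE; break }
        if (iv[2] < iv[1]) iv <- rep(mean(iv), 2)
        newv <- stats::runif(1, iv[1], iv[2])
        if (nrow(C)) resid <- resid + C[, j] * (newv - logp[j])
        logp[j] <- newv
      }
      if (ok && (!length(resid) || min(resid) >= -1e-7)) {
        pts <- rbind(pts, logp)
        break
      }
    }
  }
  unname(pts)
}
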