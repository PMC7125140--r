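# Design-space decomposition: dominance phenotypes, S-systems, log-linear
# steady states, LP validity, 1D tolerances and stability classification.
#
# Throughout, "log" means log10: parameter bounds span decades and the
# phenotype boundaries are linear in log10 of parameters and states.

ds_equations <- function(model) {
  # per-equation term tables over the log-linear variables (dyn + retained aux)
  vars <- model$variables
  pnames <- model$parameters$name
  as_row <- function(t) {
    ce <- numeric(length(pnames)); g <- numeric(length(vars))
    ce[match(names(t$coefs), pnames)] <- t$coefs
    g[match(names(t$exps), vars)] <- t$exps
    list(ce = ce, g = g)
  }
  lapply(model$equations, function(eq) {
    prod <- lapply(eq$production, as_row)
    cons <- if (eq$is_algebraic) {
      # algebraic auxiliary: the "consumption" side is the variable itself
      g <- numeric(length(vars)); g[match(eq$variable, vars)] <- 1
      list(list(ce = numeric(length(pnames)), g = g))
    } else {
      lapply(eq$consumption, as_row)
    }
    if (eq$is_algebraic) {
      refs <- unlist(lapply(eq$production, function(t) names(t$exps)))
      if (length(intersect(refs, model$auxiliary))) {
        stop("model error: retained auxiliaries must reference dynamic variables only")
      }
    }
    list(variable = eq$variable, is_algebraic = eq$is_algebraic,
         production = prod, consumption = cons,
         np = length(prod), nc = length(cons))
  })
}

#' Number of dominance phenotypes of a model
#'
#' The product over all equations (including retained algebraic denominator
#' auxiliaries) of the number of production choices times the number of
#' consumption choices.
#'
#' @param model A `gma_model` (flattened with [substitute_auxiliaries()]).
#' @return Integer count.
#' @export
count_signatures <- function(model) {
  model <- substitute_auxiliaries(model)
  eqs <- ds_equations(model)
  radii <- vapply(eqs, function(e) {
    if (e$np == 0L || e$nc == 0L) {
      stop("model error: equation for '", e$variable, "' has an empty term side")
    }
    e$np * e$nc
  }, 1)
  prod(radii)
}

signature_radices <- function(eqs) {
  vapply(eqs, function(e) c(np = e$np, nc = e$nc), c(np = 1, nc = 1))
}

#' Convert between case ids and phenotype signatures
#'
#' Case ids are a 1-based mixed-radix encoding: equations in model order, the
#' production index being the major digit within each equation, and the first
#' equation the most significant position. The encoding is a bijection onto
#' `1:count_signatures(model)`. It is specific to this package and does not
#' reproduce any external toolbox numbering.
#'
#' @param model A flattened `gma_model`.
#' @param case_id Integer (possibly > 2^31, passed as double).
#' @return `case_id_to_signature()`: integer matrix with rows `production`,
#'   `consumption` and one column per equation. `signature_to_case_id()`: the
#'   case id as a double.
#' @export
case_id_to_signature <- function(model, case_id) {
  model <- substitute_auxiliaries(model)
  eqs <- ds_equations(model)
  r <- signature_radices(eqs)
  radii <- r["np", ] * r["nc", ]
  if (case_id < 1 || case_id > prod(radii)) stop("case_id out of range")
  rem <- case_id - 1
  neq <- length(radii)
  sig <- matrix(0L, 2, neq, dimnames = list(c("production", "consumption"),
                                            colnames(r)))
  for (i in seq_len(neq)) {
    place <- prod(radii[seq_len(neq) > i])
    digit <- floor(rem / place)
    rem <- rem - digit * place
    sig["production", i] <- as.integer(digit %/% r["nc", i]) + 1L
    sig["consumption", i] <- as.integer(digit %% r["nc", i]) + 1L
  }
  sig
}

#' @rdname case_id_to_signature
#' @param signature Integer matrix as returned by `case_id_to_signature()`.
#' @export
signature_to_case_id <- function(model, signature) {
  model <- substitute_auxiliaries(model)
  eqs <- ds_equations(model)
  r <- signature_radices(eqs)
  radii <- r["np", ] * r["nc", ]
  neq <- length(radii)
  id <- 1
  for (i in seq_len(neq)) {
    if (signature["production", i] > r["np", i] || signature["consumption", i] > r["nc", i] ||
        any(signature[, i] < 1L)) {
      stop("signature index out of range for equation ", i)
    }
    digit <- (signature["production", i] - 1) * r["nc", i] + (signature["consumption", i] - 1)
    id <- id + digit * prod(radii[seq_len(neq) > i])
  }
  id
}

#' Enumerate all phenotype signatures of a model
#'
#' Returns an iterator function producing one signature per call (`NULL` when
#' exhausted), in ascending case-id order, so that large design spaces are
#' never materialized at once.
#'
#' @param model A `gma_model`.
#' @return A function; each call yields `list(case_id, signature)` or `NULL`.
#' @export
enumerate_signatures <- function(model) {
  model <- substitute_auxiliaries(model)
  n <- count_signatures(model)
  i <- 0
  function() {
    if (i >= n) return(NULL)
    i <<- i + 1
    list(case_id = i, signature = case_id_to_signature(model, i))
  }
}

#' Build the S-system of a phenotype
#'
#' Keeps the signature's dominant production and consumption term in every
#' equation. The steady state condition `log(production) = log(consumption)`
#' is linear in log-states and log-parameters; the dominance conditions
#' `log(dominant) >= log(neglected)`, one inequality per neglected term,
#' bound the phenotype's region. Log-states are eliminated through the
#' steady-state relations, leaving boundary inequalities over log-parameters
#' only (`C %*% log10(p) >= 0`).
#'
#' @param model A `gma_model` (flattened internally).
#' @param signature Integer matrix (rows production/consumption) or a case id.
#' @return An object of class `ssystem`. Phenotypes whose log-linear system
#'   is singular are flagged `degenerate`.
#' @export
build_ssystem <- function(model, signature) {
  model <- substitute_auxiliaries(model)
  eqs <- ds_equations(model)
  if (length(signature) == 1L && is.numeric(signature)) {
    case_id <- as.numeric(signature)
    signature <- case_id_to_signature(model, case_id)
  } else {
    case_id <- signature_to_case_id(model, signature)
  }
  N <- length(model$variables)
  np <- nrow(model$parameters)
  A <- matrix(0, N, N, dimnames = list(model$variables, model$variables))
  B <- matrix(0, N, np, dimnames = list(model$variables, model$parameters$name))
  rowsC <- list(); binfo <- list()
  for (i in seq_len(N)) {
    e <- eqs[[i]]
    dp <- e$production[[signature["production", i]]]
    dc <- e$consumption[[signature["consumption", i]]]
    A[i, ] <- dp$g - dc$g
    B[i, ] <- dc$ce - dp$ce
    for (side in c("production", "consumption")) {
      terms <- e[[side]]
      dom <- if (side == "production") dp else dc
      for (j in seq_along(terms)) {
        if (j == signature[side, i]) next
        rowsC[[length(rowsC) + 1L]] <- list(
          g = dom$g - terms[[j]]$g, ce = dom$ce - terms[[j]]$ce)
        binfo[[length(binfo) + 1L]] <- tibble::tibble(
          equation = e$variable, side = side, neglected = j)
      }
    }
  }

  degenerate <- FALSE
  M <- NULL
  if (N > 0) {
    qa <- qr(A)
    if (qa$rank < N || rcond(A) < 1e-12) {
      degenerate <- TRUE
    } else {
      M <- solve(A, B)
    }
  }
  C <- NULL
  if (!degenerate && length(rowsC)) {
    C <- do.call(rbind, lapply(rowsC, function(r) r$ce + as.numeric(r$g %*% M)))
    colnames(C) <- model$parameters$name
  } else if (!degenerate) {
    C <- matrix(0, 0, np, dimnames = list(NULL, model$parameters$name))
  }

  obj <- structure(list(
    model = model, case_id = case_id, signature = signature,
    A = A, B = B, M = M, C = C,
    boundaries = if (length(binfo)) dplyr::bind_rows(binfo) else
      tibble::tibble(equation = character(), side = character(), neglected = integer()),
    degenerate = degenerate
  ), class = "ssystem")
  if (!degenerate) obj$dom <- ssystem_dominant_terms(obj)
  obj
}

#' @export
print.ssystem <- function(x, ...) {
  cat("<ssystem> case_id ", format(x$case_id, scientific = FALSE),
      " of ", x$model$name, "\n", sep = "")
  if (x$degenerate) cat("  degenerate (singular log-linear system)\n")
  cat("  boundaries: ", if (is.null(x$C)) NA_integer_ else nrow(x$C), "\n", sep = "")
  invisible(x)
}

#' Closed-form steady state of an S-system
#'
#' Solves the log-linear steady-state system and exponentiates. The solution
#' is unique whenever the system is nonsingular.
#'
#' @param ssystem An `ssystem`.
#' @param params Named positive parameter vector.
#' @return Named positive vector over the dynamic variables, with retained
#'   auxiliary values in attribute `"aux"`.
#' @export
ssystem_steady_state <- function(ssystem, params) {
  if (ssystem$degenerate) {
    stop("degenerate phenotype: singular log-linear steady-state system")
  }
  p <- check_params(ssystem$model, params)
  logx <- as.numeric(ssystem$M %*% log10(p))
  x <- stats::setNames(10^logx, ssystem$model$variables)
  nd <- length(ssystem$model$dynamic)
  out <- x[seq_len(nd)]
  if (length(x) > nd) attr(out, "aux") <- x[-seq_len(nd)]
  out
}

lp_feasible <- function(C, lower_log, upper_log, margin_cap = 6) {
  np <- length(lower_log)
  if (is.null(C) || nrow(C) == 0) {
    return(list(feasible = TRUE, witness_log = (lower_log + upper_log) / 2,
                margin = min((upper_log - lower_log) / 2)))
  }
  keep <- apply(abs(C), 1, max) > 1e-12
  Cv <- C[keep, , drop = FALSE]
  if (!nrow(Cv)) {
    return(list(feasible = TRUE, witness_log = (lower_log + upper_log) / 2,
                margin = min((upper_log - lower_log) / 2)))
  }
  r <- sqrt(rowSums(Cv^2))
  # variables: w = log10(p) - lower (>= 0), t = margin (>= 0); maximize t
  a <- c(numeric(np), 1)
  A2 <- cbind(Cv, -r)                       # C (w + l) - t r >= 0
  b2 <- as.numeric(-Cv %*% lower_log)
  A1 <- rbind(cbind(diag(np), 1),           # w + t <= u - l
              c(numeric(np), 1))            # t <= cap
  b1 <- c(upper_log - lower_log, margin_cap)
  res <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = TRUE, n.iter = 50 * (np + nrow(A1) + nrow(A2)))
  if (res$solved == -1) return(list(feasible = FALSE, witness_log = NULL, margin = NA_real_))
  if (res$solved != 1) stop("LP solver failure (iteration limit) for phenotype feasibility")
  w <- res$soln[seq_len(np)]
  list(feasible = TRUE, witness_log = unname(w + lower_log),
       margin = unname(res$soln[np + 1]))
}

#' Decide phenotype validity by linear programming
#'
#' A phenotype is valid when its dominance boundary inequalities admit a
#' solution within the global parameter bounds. Feasibility is decided on a
#' max-margin (Chebyshev-style) linear program, so the returned witness lies
#' strictly inside the region whenever it is full-dimensional, and the
#' signature's terms strictly dominate at the witness's steady state.
#'
#' @param ssystem An `ssystem`.
#' @param bounds Optional 2-column matrix/data frame of per-parameter bounds;
#'   defaults to the model registry.
#' @return List with `feasible` (flag), `witness` (named parameter vector or
#'   `NULL`), and `margin` (log10 slack at the witness).
#' @export
phenotype_validity <- function(ssystem, bounds = NULL) {
  if (ssystem$degenerate) {
    stop("degenerate phenotype: validity undefined (excluded from sampling)")
  }
  bl <- param_log_bounds(ssystem$model, bounds)
  res <- lp_feasible(ssystem$C, bl$lower, bl$upper)
  witness <- if (res$feasible) {
    stats::setNames(10^res$witness_log, ssystem$model$parameters$name)
  }
  list(feasible = res$feasible, witness = witness, margin = res$margin)
}

param_log_bounds <- function(model, bounds = NULL) {
  if (is.null(bounds)) {
    list(lower = log10(model$parameters$lower), upper = log10(model$parameters$upper))
  } else if (is.numeric(bounds) && length(bounds) == 2) {
    np <- nrow(model$parameters)
    list(lower = rep(log10(bounds[1]), np), upper = rep(log10(bounds[2]), np))
  } else {
    stopifnot(nrow(bounds) == nrow(model$parameters))
    list(lower = log10(bounds[[1]]), upper = log10(bounds[[2]]))
  }
}

#' Phenotypic tolerance of one parameter
#'
#' The maximal interval over which `name` can vary, all other parameters
#' fixed, while every dominance boundary remains satisfied, intersected with
#' the global bounds. Always contains the current value.
#'
#' @param ssystem An `ssystem`.
#' @param params Named parameter vector currently valid for the phenotype.
#' @param name Parameter name.
#' @param bounds Optional bounds as in [phenotype_validity()].
#' @return Numeric `c(lower, upper)` on the linear scale.
#' @export
parameter_tolerance <- function(ssystem, params, name, bounds = NULL) {
  p <- check_params(ssystem$model, params)
  j <- match(name, ssystem$model$parameters$name)
  if (is.na(j)) stop("unknown parameter: ", name)
  logp <- log10(p)
  C <- ssystem$C
  resid_all <- if (nrow(C)) as.numeric(C %*% logp) else numeric(0)
  if (length(resid_all) && min(resid_all) < -1e-7) {
    stop("precondition error: parameters are not valid for this phenotype")
  }
  bl <- param_log_bounds(ssystem$model, bounds)
  iv <- tolerance_interval(C, resid_all, logp, j, bl$lower[j], bl$upper[j])
  10^iv
}

# interval in log10 for parameter j given current residuals r = C %*% logp
tolerance_interval <- function(C, resid, logp, j, lo, hi) {
  if (nrow(C)) {
    cj <- C[, j]
    base <- resid - cj * logp[j]
    pos <- cj > 1e-12; neg <- cj < -1e-12
    if (any(pos)) lo <- max(lo, max(-base[pos] / cj[pos]))
    if (any(neg)) hi <- min(hi, min(-base[neg] / cj[neg]))
  }
  c(lo, hi)
}

#' Stability of a phenotype's steady state
#'
#' Eigenvalues of the S-system Jacobian (dominant terms only, exact power-law
#' derivatives, retained auxiliaries substituted by their dominant term) at
#' the phenotype's closed-form steady state. The oscillatory-potential flag
#' marks a complex-conjugate pair with non-negative real part, the necessary
#' condition for a Hopf-born limit cycle used by the screening pipeline.
#'
#' @param ssystem An `ssystem`.
#' @param params Named positive parameter vector.
#' @return List of class `stability_report`: `steady_state`, `eigenvalues`,
#'   `n_nonnegative_real`, `has_oscillatory_pair`.
#' @export
stability_report <- function(ssystem, params) {
  p <- check_params(ssystem$model, params)
  x <- ssystem_steady_state(ssystem, p)
  J <- ssystem_jacobian(ssystem, p, x)
  ev <- eigen(J, only.values = TRUE)$values
  tol <- 1e-9 * max(1, max(abs(ev)))
  res <- list(
    steady_state = x,
    eigenvalues = ev,
    n_nonnegative_real = sum(Re(ev) >= -tol),
    has_oscillatory_pair = any(abs(Im(ev)) > tol & Re(ev) >= -tol)
  )
  class(res) <- "stability_report"
  res
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n  eigenvalues:\n")
  print(x$eigenvalues)
  cat("  non-negative real parts: ", x$n_nonnegative_real,
      "; oscillatory pair: ", x$has_oscillatory_pair, "\n", sep = "")
  invisible(x)
}

# dominant-subsystem terms over dynamic variables (aux substituted), as
# (ce over params, g over dynamic vars) per side per equation
ssystem_dominant_terms <- function(ssystem) {
  model <- ssystem$model
  eqs <- ds_equations(model)
  nd <- length(model$dynamic)
  N <- length(model$variables)
  aux_idx <- if (N > nd) (nd + 1):N else integer(0)
  aux_dom <- lapply(aux_idx, function(k) {
    e <- eqs[[k]]
    e$production[[ssystem$signature["production", k]]]
  })
  subst <- function(term) {
    g <- term$g; ce <- term$ce
    for (ai in seq_along(aux_idx)) {
      k <- aux_idx[ai]
      e <- g[k]
      if (e != 0) {
        g[k] <- 0
        g <- g + e * aux_dom[[ai]]$g
        ce <- ce + e * aux_dom[[ai]]$ce
      }
    }
    list(ce = ce, g = g[seq_len(nd)])
  }
  lapply(seq_len(nd), function(i) {
    e <- eqs[[i]]
    list(production = subst(e$production[[ssystem$signature["production", i]]]),
         consumption = subst(e$consumption[[ssystem$signature["consumption", i]]]))
  })
}

ssystem_jacobian <- function(ssystem, params, state) {
  model <- ssystem$model
  nd <- length(model$dynamic)
  x <- as.numeric(state[seq_len(nd)])
  logp <- log(params[model$parameters$name])
  dom <- ssystem$dom %||% ssystem_dominant_terms(ssystem)
  J <- matrix(0, nd, nd, dimnames = list(model$dynamic, model$dynamic))
  for (i in seq_len(nd)) {
    for (side in c("production", "consumption")) {
      t <- dom[[i]][[side]]
      v <- exp(sum(t$ce * logp) + sum(t$g * log(x)))
      s <- if (side == "production") 1 else -1
      J[i, ] <- J[i, ] + s * v * t$g / x
    }
  }
  J
}
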