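# Compiled (matrix) view of a model, used by the evaluators and the ODE
# right-hand side. Terms are ordered: auxiliary-equation terms first, in
# topological order of the auxiliaries, then dynamic-equation terms.
#
# For every term t:  value_t = exp(Ce[t, ] %*% log(p)) * exp(G[t, ] %*% log(u))
# where u = (dynamic states, auxiliary values).
compile_gma <- function(model) {
  nd <- length(model$dynamic)
  na <- length(model$auxiliary)
  vars <- model$variables
  pnames <- model$parameters$name

  # topological order of auxiliaries (aux may reference earlier aux)
  aux_order <- integer(0)
  if (na) {
    deps <- lapply(model$auxiliary, function(a) {
      intersect(unlist(lapply(model$equations[[a]]$production,
                              function(t) names(t$exps))), model$auxiliary)
    })
    names(deps) <- model$auxiliary
    remaining <- model$auxiliary
    while (length(remaining)) {
      ready <- remaining[vapply(remaining, function(a) {
        !length(intersect(deps[[a]], remaining))
      }, TRUE)]
      if (!length(ready)) stop("model error: cyclic auxiliary definitions")
      aux_order <- c(aux_order, match(ready, model$auxiliary))
      remaining <- setdiff(remaining, ready)
    }
  }

  rows_ce <- list(); rows_g <- list(); sign <- integer(0); eq <- integer(0)
  add_term <- function(t, s, e) {
    ce <- numeric(length(pnames)); g <- numeric(length(vars))
    ce[match(names(t$coefs), pnames)] <- t$coefs
    gi <- match(names(t$exps), vars)
    if (anyNA(gi)) stop("model error: unknown variable in term")
    g[gi] <- t$exps
    rows_ce[[length(rows_ce) + 1L]] <<- ce
    rows_g[[length(rows_g) + 1L]] <<- g
    sign <<- c(sign, s); eq <<- c(eq, e)
  }
  for (k in aux_order) {
    a <- model$auxiliary[k]
    for (t in model$equations[[a]]$production) add_term(t, 1L, nd + k)
  }
  n_aux_terms <- length(sign)
  for (i in seq_len(nd)) {
    eqn <- model$equations[[model$dynamic[i]]]
    for (t in eqn$production) add_term(t, 1L, i)
    for (t in eqn$consumption) add_term(t, -1L, i)
  }
  list(
    nd = nd, na = na, vars = vars, pnames = pnames,
    aux_order = aux_order, n_aux_terms = n_aux_terms,
    Ce = do.call(rbind, rows_ce), G = do.call(rbind, rows_g),
    sign = sign, eq = eq
  )
}

term_coefs_values <- function(cmp, params) {
  p <- params[cmp$pnames]
  as.numeric(exp(cmp$Ce %*% log(p)))
}

# full state (dynamic + auxiliaries) from a dynamic state vector
full_state <- function(cmp, cf, state) {
  u <- c(state, rep(NA_real_, cmp$na))
  if (cmp$na) {
    for (t in seq_len(cmp$n_aux_terms)) {
      j <- cmp$eq[t]
      v <- cf[t] * prod(u[cmp$G[t, ] != 0]^cmp$G[t, cmp$G[t, ] != 0])
      u[j] <- if (is.na(u[j])) v else u[j] + v
    }
  }
  u
}

#' Evaluate the net rates of a GMA model
#'
#' Computes `du_i/dt = sum(production) - sum(consumption)` for every dynamic
#' variable, with each term `coef * prod(state^exponent)`. Algebraic
#' auxiliaries are evaluated first (in dependency order) and substituted.
#'
#' @param model A `gma_model`.
#' @param params Named numeric vector covering all model parameters
#'   (positive).
#' @param state Named or ordered numeric vector of the dynamic variables,
#'   strictly positive.
#' @return Numeric vector of time derivatives, one per dynamic variable.
#' @export
evaluate_rates <- function(model, params, state) {
  p <- check_params(model, params)
  x <- state_vector(model, state)
  cmp <- compile_gma(model)
  cf <- term_coefs_values(cmp, p)
  u <- full_state(cmp, cf, x)
  v <- cf * as.numeric(exp(cmp$G %*% log(u)))
  rates <- numeric(cmp$nd)
  dyn <- seq_len(length(v)) > cmp$n_aux_terms
  for (t in which(dyn)) rates[cmp$eq[t]] <- rates[cmp$eq[t]] + cmp$sign[t] * v[t]
  stats::setNames(rates, model$dynamic)
}

state_vector <- function(model, state) {
  nd <- length(model$dynamic)
  x <- if (!is.null(names(state))) {
    miss <- setdiff(model$dynamic, names(state))
    if (length(miss)) stop("missing state variable(s): ", paste(miss, collapse = ", "))
    as.numeric(state[model$dynamic])
  } else {
    if (length(state) != nd) stop("state must have length ", nd)
    as.numeric(state)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("domain error: state variables must be strictly positive")
  }
  stats::setNames(x, model$dynamic)
}

#' Analytic Jacobian of a flat GMA model
#'
#' Exact power-law derivative: entry (i, k) is
#' `sum_terms sign * coef * prod(state^g) * g_k / state_k`. The model must be
#' flat (no algebraic auxiliaries); use [substitute_auxiliaries()] first.
#'
#' @inheritParams evaluate_rates
#' @return Square matrix over the dynamic variables.
#' @export
analytic_jacobian <- function(model, params, state) {
  if (length(model$auxiliary)) {
    stop("analytic_jacobian requires a flat model; call substitute_auxiliaries() first")
  }
  p <- check_params(model, params)
  x <- state_vector(model, state)
  cmp <- compile_gma(model)
  cf <- term_coefs_values(cmp, p)
  v <- cmp$sign * cf * as.numeric(exp(cmp$G %*% log(x)))
  J <- matrix(0, cmp$nd, cmp$nd, dimnames = list(model$dynamic, model$dynamic))
  for (t in seq_along(v)) {
    J[cmp$eq[t], ] <- J[cmp$eq[t], ] + v[t] * cmp$G[t, ] / x
  }
  J
}

#' Flatten pure power-law auxiliaries into the referencing terms
#'
#' Auxiliaries defined by a single power-law term (for instance a
#' quasi-steady-state ternary complex `c_x = K_A*x*s`) are substituted into
#' every term that references them, which yields a model whose terms are pure
#' power laws over the remaining variables. Auxiliaries with two or more
#' terms (denominator relations such as `D = K_zx + z`, used for saturable
#' inhibition) are retained as algebraic equations; they contribute their own
#' dominance choices in the design space.
#'
#' @param model A `gma_model`.
#' @return A `gma_model` with single-term auxiliaries eliminated.
#' @export
substitute_auxiliaries <- function(model) {
  if (!length(model$auxiliary)) return(model)
  compile_gma(model) # raises on cyclic definitions
  pure <- model$auxiliary[vapply(model$auxiliary, function(a) {
    length(model$equations[[a]]$production) == 1L
  }, TRUE)]
  if (!length(pure)) return(model)

  # iterate substitution until no pure-aux reference remains
  defs <- lapply(model$equations[pure], function(eq) eq$production[[1]])
  names(defs) <- pure
  subst_term <- function(t) {
    repeat {
      hit <- intersect(names(t$exps), pure)
      if (!length(hit)) return(t)
      a <- hit[1]; e <- t$exps[[a]]
      t$exps <- t$exps[names(t$exps) != a]
      d <- defs[[a]]
      for (nm in names(d$coefs)) {
        t$coefs[nm] <- (if (nm %in% names(t$coefs)) t$coefs[[nm]] else 0) + e * d$coefs[[nm]]
      }
      for (nm in names(d$exps)) {
        t$exps[nm] <- (if (nm %in% names(t$exps)) t$exps[[nm]] else 0) + e * d$exps[[nm]]
      }
      t$coefs <- t$coefs[t$coefs != 0]
      t$exps <- t$exps[t$exps != 0]
    }
  }

  keep_vars <- setdiff(model$variables, pure)
  equations <- lapply(model$equations[keep_vars], function(eq) {
    eq$production <- lapply(eq$production, subst_term)
    eq$consumption <- lapply(eq$consumption, subst_term)
    eq
  })
  out <- model
  out$variables <- keep_vars
  out$auxiliary <- setdiff(model$auxiliary, pure)
  out$equations <- equations
  out
}
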