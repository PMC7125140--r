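`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent oracles used across the test files.

toy_1eq <- function() parse_gma_model("x' = a - b*x")

toy_2eq <- function() parse_gma_model(c(
  "x' = a - b*x*y",
  "y' = c*x - d*y"
))

toy_sum <- function() parse_gma_model("x' = a1 + a2 - b*x")

lv_model <- function() make_fixture_oscillator("lotka_volterra")

# random single-coefficient GMA model: <= nv variables, <= mt terms per side
random_gma_model <- function(nv = 3, mt = 3, seed = 1) {
  withr::with_seed(seed, {
    vars <- paste0("x", seq_len(nv))
    k <- 0
    lines <- vapply(seq_len(nv), function(i) {
      term <- function() {
        k <<- k + 1
        nref <- sample(0:min(2, nv), 1)
        refs <- if (nref) sample(vars, nref) else character(0)
        exps <- sample(c(0.5, 1, 2), length(refs), replace = TRUE)
        paste(c(paste0("p", k),
                paste0(refs, ifelse(exps == 1, "", paste0("^", exps)))),
              collapse = "*")
      }
      np <- sample(1:mt, 1); nc <- sample(1:mt, 1)
      prod <- vapply(seq_len(np), function(.) term(), "")
      # guarantee one self-degradation so steady states can exist
      cons <- c(paste0("p", (k <<- k + 1), "*", vars[i]),
                vapply(seq_len(nc - 1), function(.) term(), character(1)))
      paste0(vars[i], "' = ", paste(prod, collapse = " + "), " - ",
             paste(cons, collapse = " - "))
    }, "")
    parse_gma_model(lines, name = paste0("random", seed))
  })
}

random_params <- function(model, seed = 1, range = c(0.1, 10)) {
  withr::with_seed(seed, {
    p <- 10^stats::runif(nrow(model$parameters), log10(range[1]), log10(range[2]))
    stats::setNames(p, model$parameters$name)
  })
}

random_state <- function(model, seed = 1, range = c(0.2, 5)) {
  withr::with_seed(seed + 1000, {
    x <- 10^stats::runif(length(model$dynamic), log10(range[1]), log10(range[2]))
    stats::setNames(x, model$dynamic)
  })
}

# finite-difference Jacobian oracle (central, relative step)
fd_jacobian <- function(model, params, state, h = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    dp <- state; dm <- state
    step <- h * state[k]
    dp[k] <- dp[k] + step; dm[k] <- dm[k] - step
    J[, k] <- (evaluate_rates(model, params, dp) -
                 evaluate_rates(model, params, dm)) / (2 * step)
  }
  J
}

# symbolic-expression oracle: evaluate the model's equations as plain R
# arithmetic, independently of the package's matrix evaluator
symbolic_rates <- function(model_text, params, state) {
  lines <- grep("'", strsplit(model_text, "\n")[[1]], fixed = TRUE, value = TRUE)
  env <- as.list(c(params, state))
  vapply(lines, function(ln) {
    rhs <- sub("^[^=]*=", "", ln)
    eval(parse(text = gsub("\\^", "^", rhs)), envir = env)
  }, 0, USE.NAMES = FALSE)
}

# plain-R rate closure built term by term from the parsed equations:
# independent of the package's compiled evaluator
make_rate_fn <- function(model) {
  eqs <- model$equations[model$dynamic]
  function(params, x) {
    tv <- function(t) {
      prod(params[names(t$coefs)]^t$coefs) * prod(x[names(t$exps)]^t$exps)
    }
    vapply(eqs, function(eq) {
      sum(vapply(eq$production, tv, 0)) - sum(vapply(eq$consumption, tv, 0))
    }, 0)
  }
}

# Newton solver for a full-model steady state in log space, with a
# finite-difference Jacobian (oracle for the LP validity check; fully
# independent of the S-system path)
newton_steady_state <- function(model, params, x0, iter = 120, rate_fn = NULL) {
  f <- rate_fn %||% make_rate_fn(model)
  x <- x0
  n <- length(x)
  for (i in seq_len(iter)) {
    r <- f(params, x)
    if (any(!is.finite(r))) return(NULL)
    Jl <- matrix(0, n, n)  # d r / d log x
    for (k in seq_len(n)) {
      xp <- x; xm <- x
      xp[k] <- xp[k] * exp(1e-6); xm[k] <- xm[k] * exp(-1e-6)
      Jl[, k] <- (f(params, xp) - f(params, xm)) / 2e-6
    }
    dl <- tryCatch(solve(Jl, -r), error = function(e) NULL)
    if (is.null(dl)) return(NULL)
    dl <- pmin(pmax(dl, -2), 2)
    x <- x * exp(dl)
    if (any(x <= 0) || any(!is.finite(x))) return(NULL)
    if (max(abs(r)) < 1e-11 * max(1, max(abs(f(params, x))), 1)) break
  }
  if (max(abs(f(params, x))) < 1e-8) x else NULL
}

# dominance signature realized at a given (params, state): index of the
# numerically largest term on each side of each equation
realized_signature <- function(model, params, state) {
  eqs <- model$equations[model$dynamic]
  term_val <- function(t) {
    prod(params[names(t$coefs)]^t$coefs) * prod(state[names(t$exps)]^t$exps)
  }
  margin_of <- function(v) {
    if (length(v) < 2) Inf else max(v) / sort(v, decreasing = TRUE)[2]
  }
  sig <- vapply(eqs, function(eq) {
    pv <- vapply(eq$production, term_val, 0)
    cv <- vapply(eq$consumption, term_val, 0)
    c(production = which.max(pv), consumption = which.max(cv),
      margin = min(margin_of(pv), margin_of(cv)))
  }, c(production = 1, consumption = 1, margin = 1))
  sig
}

# constructed 4-species phase-shifted periodic signal on [0, 500]
make_phase_signal <- function(period = 20, phases_min = c(0, 5, 10, 15),
                              amp = 0.4, means = c(1, 1, 1, 1), dt = 0.1,
                              t_end = 500, damp = 0) {
  tt <- seq(0, t_end, by = dt)
  S <- sapply(seq_along(phases_min), function(k) {
    a <- amp * means[k] * exp(-damp * tt)
    means[k] + a * cos(2 * pi * (tt - phases_min[k]) / period)
  })
  colnames(S) <- c("s", "x", "y", "z")
  oscidesign:::new_trajectory(tt, S)
}

cc_observables <- c(Sic1 = "s", Clb5 = "x", Clb3 = "y", Clb2 = "z")
cc_order <- c("Sic1", "Clb5", "Clb3", "Clb2")

nf3_base_params <- function(model) {
  stats::setNames(rep(1, nrow(model$parameters)), model$parameters$name)
}
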