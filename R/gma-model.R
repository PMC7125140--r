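#' @useDynLib oscidesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# A power-law term is a product  prod_j p_j^ce_j * prod_k x_k^g_k :
#   coefs: named numeric, parameter name -> power (usually a single name, power 1)
#   exps:  named numeric, variable name  -> exponent
new_term <- function(coefs = numeric(), exps = numeric()) {
  list(coefs = coefs, exps = exps)
}

term_text <- function(term) {
  fmt <- function(nm, e) {
    ifelse(e == 1, nm, paste0(nm, "^", format(e, scientific = FALSE, trim = TRUE)))
  }
  parts <- c(
    if (length(term$coefs)) fmt(names(term$coefs), unname(term$coefs)),
    if (length(term$exps)) fmt(names(term$exps), unname(term$exps))
  )
  if (!length(parts)) "1" else paste(parts, collapse = "*")
}

#' Parse a kinetic model in Generalized Mass Action (GMA) form
#'
#' The text format has one line per equation. A differential equation is
#' written `x' = expr`, an algebraic auxiliary `x = expr`. The right-hand
#' side is a `+`/`-` separated list of power-law terms; each term is a
#' `*`-separated product of identifiers with optional `^exponent` (exponents
#' may be negative, e.g. `D^-1`). Identifiers defined on a left-hand side are
#' state variables; all other identifiers are parameters. Lines starting with
#' `#` (or trailing `#` fragments) are comments.
#'
#' @param text Character scalar or vector of lines with the model definition.
#' @param name Model label.
#' @param bounds Length-2 numeric, default global parameter bounds
#'   (positive, lower < upper). Defaults to `c(1e-9, 1e3)`.
#' @param observables Named character vector mapping species labels (e.g.
#'   `Clb5`) to variable names; defaults to the dynamic variables themselves.
#' @param peak_order Character vector of species labels giving the expected
#'   circular order of concentration peaks over one oscillation; defaults to
#'   the order of `observables`.
#' @return An object of class `gma_model`.
#' @export
parse_gma_model <- function(text, name = "model", bounds = c(1e-9, 1e3),
                            observables = NULL, peak_order = NULL) {
  stopifnot(is.character(text), length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  raw <- trimws(lines[keep])

  m <- regmatches(raw, regexec("^([A-Za-z][A-Za-z0-9_.]*)\\s*('?)\\s*=\\s*(.+)$", raw))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad)) {
    stop("parse error at line ", keep[bad[1]], ": not an equation: '", raw[bad[1]], "'")
  }
  lhs <- vapply(m, `[[`, "", 2L)
  prime <- vapply(m, `[[`, "", 3L) == "'"
  rhs <- vapply(m, `[[`, "", 4L)
  if (anyDuplicated(lhs)) {
    stop("model error: duplicate variable '", lhs[duplicated(lhs)][1], "'")
  }
  vars <- lhs

  parse_factor <- function(fct, lineno) {
    mm <- regmatches(fct, regexec(
      "^([A-Za-z][A-Za-z0-9_.]*)(\\^(-?[0-9]*\\.?[0-9]+([eE]-?[0-9]+)?))?$", fct))[[1]]
    if (!length(mm)) {
      stop("parse error at line ", lineno, ": malformed factor '", fct, "'")
    }
    list(base = mm[2], exp = if (nzchar(mm[3])) as.numeric(mm[4]) else 1)
  }

  parse_side <- function(expr, lineno) {
    expr <- gsub("[[:space:]]", "", expr)
    if (!nzchar(expr)) stop("parse error at line ", lineno, ": empty expression")
    if (grepl("[^A-Za-z0-9_.*^+-]", expr)) {
      stop("parse error at line ", lineno, ": unknown operator in '", expr, "'")
    }
    # split before each top-level +/- (exponent signs are glued to '^')
    expr2 <- gsub("\\^\\+", "^", expr)
    expr2 <- gsub("\\^-", "^\x01", expr2) # shield negative exponents
    pieces <- strsplit(expr2, "(?<=.)(?=[+-])", perl = TRUE)[[1]]
    pieces <- gsub("\x01", "-", pieces, fixed = TRUE)
    signs <- integer(0); bodies <- character(0)
    for (p in pieces) {
      if (substr(p, 1, 1) %in% c("+", "-")) {
        signs <- c(signs, if (substr(p, 1, 1) == "-") -1L else 1L)
        bodies <- c(bodies, substring(p, 2))
      } else {
        signs <- c(signs, 1L)
        bodies <- c(bodies, p)
      }
    }
    if (any(!nzchar(bodies))) stop("parse error at line ", lineno, ": empty term")
    terms <- lapply(bodies, function(b) {
      fcts <- lapply(strsplit(b, "*", fixed = TRUE)[[1]], parse_factor, lineno = lineno)
      coefs <- numeric(); exps <- numeric()
      for (f in fcts) {
        if (f$base %in% vars) {
          exps[f$base] <- (if (f$base %in% names(exps)) exps[[f$base]] else 0) + f$exp
        } else {
          coefs[f$base] <- (if (f$base %in% names(coefs)) coefs[[f$base]] else 0) + f$exp
        }
      }
      if (any(!is.finite(c(coefs, exps)))) {
        stop("parse error at line ", lineno, ": non-finite exponent")
      }
      new_term(coefs, exps)
    })
    list(signs = signs, terms = terms)
  }

  equations <- vector("list", length(vars))
  names(equations) <- vars
  for (i in seq_along(vars)) {
    side <- parse_side(rhs[i], keep[i])
    prod <- side$terms[side$signs > 0]
    cons <- side$terms[side$signs < 0]
    if (prime[i]) {
      if (!length(prod) || !length(cons)) {
        stop("model error: differential equation for '", vars[i],
             "' needs at least one production and one consumption term")
      }
    } else {
      if (length(cons)) {
        stop("model error: algebraic auxiliary '", vars[i],
             "' must be a sum of positive terms")
      }
    }
    equations[[i]] <- list(variable = vars[i], production = prod,
                           consumption = cons, is_algebraic = !prime[i])
  }

  dynamic <- vars[prime]
  auxiliary <- vars[!prime]
  # parameters in first-appearance order
  pnames <- character(0)
  for (eq in equations) {
    for (t in c(eq$production, eq$consumption)) {
      pnames <- c(pnames, setdiff(names(t$coefs), pnames))
    }
  }
  if (is.null(observables)) {
    observables <- stats::setNames(dynamic, dynamic)
  }
  if (!all(observables %in% dynamic)) {
    stop("model error: observables must map to dynamic variables")
  }
  if (anyDuplicated(observables)) stop("model error: observables map must be injective")
  if (is.null(peak_order)) peak_order <- names(observables)
  if (!setequal(peak_order, names(observables))) {
    stop("model error: peak_order must be a permutation of the observable labels")
  }

  structure(list(
    name = name,
    variables = c(dynamic, auxiliary),
    dynamic = dynamic,
    auxiliary = auxiliary,
    equations = equations[c(dynamic, auxiliary)],
    parameters = tibble::tibble(name = pnames, lower = bounds[1], upper = bounds[2]),
    observables = observables,
    peak_order = peak_order
  ), class = "gma_model")
}

#' Read a GMA model definition from a file
#'
#' @param path Path to a plain-text model definition.
#' @inheritParams parse_gma_model
#' @return A `gma_model`.
#' @export
read_gma_model <- function(path, name = sub("\\.[^.]*$", "", basename(path)), ...) {
  parse_gma_model(readLines(path, warn = FALSE), name = name, ...)
}

#' Serialize a GMA model to its text format
#'
#' Writing then re-parsing is the identity on models; for files written in
#' canonical form (coefficients before variables within each term, single
#' spaces around operators) the text itself round-trips byte-identically.
#'
#' @param model A `gma_model`.
#' @param path Optional file path; when `NULL` the text is returned invisibly.
#' @return The model text, invisibly when written to a file.
#' @export
write_gma_model <- function(model, path = NULL) {
  eq_text <- vapply(model$equations, function(eq) {
    lhs <- paste0(eq$variable, if (eq$is_algebraic) " = " else "' = ")
    rhs <- paste(vapply(eq$production, term_text, ""), collapse = " + ")
    if (length(eq$consumption)) {
      rhs <- paste(rhs, paste(vapply(eq$consumption, term_text, ""), collapse = " - "),
                   sep = " - ")
    }
    paste0(lhs, rhs)
  }, "")
  txt <- paste0(paste(eq_text, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.gma_model <- function(x, ...) {
  cat("<gma_model> ", x$name, "\n", sep = "")
  cat("  dynamic variables:  ", paste(x$dynamic, collapse = ", "), "\n", sep = "")
  if (length(x$auxiliary)) {
    cat("  algebraic auxiliaries: ", paste(x$auxiliary, collapse = ", "), "\n", sep = "")
  }
  cat("  parameters: ", nrow(x$parameters), "\n", sep = "")
  cat("  observables: ",
      paste(names(x$observables), x$observables, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Set global bounds for one or all parameters
#'
#' @param model A `gma_model`.
#' @param lower,upper Positive bounds, `lower < upper`.
#' @param name Parameter name, or `NULL` for all parameters.
#' @return The modified model.
#' @export
set_parameter_bounds <- function(model, lower, upper, name = NULL) {
  stopifnot(lower > 0, lower < upper)
  idx <- if (is.null(name)) seq_len(nrow(model$parameters)) else {
    i <- match(name, model$parameters$name)
    if (anyNA(i)) stop("unknown parameter: ", paste(name[is.na(i)], collapse = ", "))
    i
  }
  model$parameters$lower[idx] <- lower
  model$parameters$upper[idx] <- upper
  model
}

check_params <- function(model, params) {
  need <- model$parameters$name
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- as.numeric(params[need])
  if (any(!is.finite(p)) || any(p <= 0)) stop("parameters must be positive and finite")
  stats::setNames(p, need)
}
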