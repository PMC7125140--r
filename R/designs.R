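# Built-in cell-cycle network designs and small fixture oscillators.

designs_manifest <- function() {
  path <- system.file("extdata", "designs", "manifest.json", package = "oscidesign")
  jsonlite::read_json(path)
}

#' List the built-in cell-cycle design ids
#'
#' @return Character vector of design ids.
#' @export
list_designs <- function() names(designs_manifest()$designs)

#' Load a built-in Clb/Cdk1 cell-cycle network design
#'
#' Eleven minimal budding-yeast designs are packaged as plain-text GMA model
#' files. Designs `1A`, `1B`, `1C` and `2` carry the Clb/Cdk1/Sic1 ternary
#' complexes as explicit mass-action species (7 dynamic variables); designs
#' `3`-`9` use the quasi-steady-state approximation (complexes `c_i =
#' K_A*i*s`), and designs `4`-`9` each add one set of saturable inhibitory
#' regulations to Design 3. The equations are a documented reconstruction of
#' the published network family (see the methods vignette); they are marked
#' synthetic in the model files.
#'
#' @param id Design id, one of `list_designs()`.
#' @return An object of class `cellcycle_design`: list with `id`, `model`
#'   (a `gma_model` with observables Sic1, Clb5, Clb3, Clb2 and the expected
#'   peak order), `k_param` (the design-specific inhibition constant, `NA`
#'   when absent) and `glossary` (tibble of parameter roles).
#' @export
get_design <- function(id) {
  man <- designs_manifest()
  id <- as.character(id)
  if (!id %in% names(man$designs)) {
    stop("unknown design id '", id, "'; valid ids: ",
         paste(names(man$designs), collapse = ", "))
  }
  entry <- man$designs[[id]]
  path <- system.file("extdata", "designs", entry$file, package = "oscidesign")
  model <- read_gma_model(
    path, name = paste0("design", id),
    observables = unlist(man$observables),
    peak_order = unlist(man$peak_order)
  )
  structure(list(
    id = id, model = model,
    k_param = entry$k_param %||% NA_character_,
    family = entry$family,
    glossary = design_glossary(model)
  ), class = "cellcycle_design")
}

#' @export
print.cellcycle_design <- function(x, ...) {
  cat("<cellcycle_design> Design ", x$id, " (", x$family, ")\n", sep = "")
  print(x$model)
  invisible(x)
}

design_glossary <- function(model) {
  role <- function(p) {
    if (grepl("^v_", p)) "basal synthesis"
    else if (grepl("^beta_", p)) "basal degradation"
    else if (grepl("^alpha_", p)) "Clb/Cdk1-mediated synthesis activation"
    else if (grepl("^gamma_", p)) "APC-mediated degradation (negative feedback)"
    else if (p == "delta") "Sic1 degradation out of the ternary complex"
    else if (p == "epsilon") "Clb degradation out of the ternary complex"
    else if (p == "K_A") "ternary-complex association constant (QSSA)"
    else if (p == "k_on") "ternary-complex formation rate"
    else if (p == "k_off") "ternary-complex dissociation rate"
    else if (grepl("^K_", p)) "saturable inhibition constant"
    else "parameter"
  }
  tibble::tibble(parameter = model$parameters$name,
                 role = vapply(model$parameters$name, role, ""))
}

#' Small fixture models with known dynamical behaviour
#'
#' * `negative_feedback_3node`: a three-variable Goodwin-type power-law loop
#'   `x1' = a1*x3^-g - b1*x1; x2' = a2*x1 - b2*x2; x3' = a3*x2 - b3*x3`. With
#'   equal degradation rates its fixed point loses stability through a Hopf
#'   bifurcation exactly at feedback exponent `g = 8` (the secant condition),
#'   so the default `g = 12` oscillates over a sizeable parameter region.
#'   Parameter bounds are set to `[0.1, 10]` so that random screening hits
#'   the oscillatory region with useful frequency.
#' * `lotka_volterra`: `x' = a*x - b*x*y; y' = c*x*y - d*y`, whose fixed
#'   point `(d/c, a/b)` has purely imaginary eigenvalues (a conservative
#'   centre), flagged as oscillatory potential.
#' * `linear_chain`: a feedback-free synthesis cascade with a globally stable
#'   fixed point; screening finds no oscillatory potential.
#'
#' @param kind One of `"negative_feedback_3node"`, `"lotka_volterra"`,
#'   `"linear_chain"`.
#' @param feedback_exponent Exponent `g` of the repression in the
#'   negative-feedback fixture.
#' @return A `gma_model`.
#' @export
make_fixture_oscillator <- function(kind = c("negative_feedback_3node",
                                             "lotka_volterra", "linear_chain"),
                                    feedback_exponent = 12) {
  kind <- match.arg(kind)
  switch(kind,
    negative_feedback_3node = parse_gma_model(c(
      sprintf("x1' = a1*x3^-%s - b1*x1",
              format(feedback_exponent, scientific = FALSE)),
      "x2' = a2*x1 - b2*x2",
      "x3' = a3*x2 - b3*x3"
    ), name = "negative_feedback_3node", bounds = c(0.1, 10)),
    lotka_volterra = parse_gma_model(c(
      "x' = a*x - b*x*y",
      "y' = c*x*y - d*y"
    ), name = "lotka_volterra"),
    linear_chain = parse_gma_model(c(
      "x1' = a1 - b1*x1",
      "x2' = a2*x1 - b2*x2",
      "x3' = a3*x2 - b3*x3"
    ), name = "linear_chain")
  )
}
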