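# Result persistence: lossless JSON round trip plus CSV table exports.

RESULT_SCHEMA <- 1L

#' Write or read a screen result
#'
#' `write_results()` persists a `screen_result` losslessly as versioned JSON
#' and, alongside it, the summary tables as CSV (`table1.csv` headline
#' counts, `table2.csv` dominant-parameter counts, `limit_cycles.csv` the
#' records, `samples.csv` all retained samples). `read_results()` restores
#' the result from the JSON; a schema mismatch raises an explicit version
#' error.
#'
#' @param result A `screen_result`.
#' @param dir Output directory (created if missing).
#' @param model Optional model for the dominant-parameter table (defaults to
#'   the built-in design when resolvable).
#' @return `write_results()`: the path of `result.json`, invisibly.
#'   `read_results()`: a `screen_result`.
#' @export
write_results <- function(result, dir, model = NULL) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    schema = RESULT_SCHEMA,
    design = result$design,
    config = result$config,
    counts = result$counts,
    phenotypes = result$phenotypes,
    samples = result$samples,
    records = result$records
  )
  path <- file.path(dir, "result.json")
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  utils::write.csv(summarize_counts(result), file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  tab2 <- tryCatch(count_dominant_parameters(result, model),
                   error = function(e) NULL)
  if (!is.null(tab2)) {
    utils::write.csv(tab2, file.path(dir, "table2.csv"), row.names = FALSE)
  }
  if (nrow(result$records)) {
    utils::write.csv(result$records, file.path(dir, "limit_cycles.csv"),
                     row.names = FALSE)
  }
  if (nrow(result$samples)) {
    utils::write.csv(result$samples, file.path(dir, "samples.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @param path Path to a `result.json` (or the directory containing it).
#' @export
read_results <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "result.json")
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("parse error reading results: ", conditionMessage(e))
                      })
  if (is.null(payload$schema) || payload$schema != RESULT_SCHEMA) {
    stop("result schema version mismatch: found ",
         payload$schema %||% "<none>", ", expected ", RESULT_SCHEMA)
  }
  as_tib <- function(x) {
    if (is.null(x) || (is.list(x) && !length(x))) tibble::tibble()
    else tibble::as_tibble(x)
  }
  cfg <- payload$config
  cfg$bounds <- if (is.null(cfg$bounds) || !length(cfg$bounds)) NULL else
    as.numeric(cfg$bounds)
  structure(list(
    design = payload$design,
    config = cfg,
    counts = lapply(payload$counts, function(v) if (is.numeric(v)) v else as.numeric(v)),
    phenotypes = as_tib(payload$phenotypes),
    samples = as_tib(payload$samples),
    records = as_tib(payload$records)
  ), class = "screen_result")
}
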