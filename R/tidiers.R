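# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.screen_result <- function(x, ...) {
  x$phenotypes
}

#' @export
glance.screen_result <- function(x, ...) {
  summarize_counts(x)
}

#' @export
tidy.pca_projection <- function(x, ...) {
  x$scores
}

#' @export
glance.pca_projection <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p,
                 pc1_explained = x$explained[1],
                 pc2_explained = if (length(x$explained) >= 2) x$explained[2] else NA_real_,
                 pc12_explained = sum(x$explained[seq_len(min(2, length(x$explained)))]))
}

#' @export
tidy.bifurcation_scan <- function(x, ...) x$envelope

#' @export
tidy.robustness_scan <- function(x, ...) x$samples

#' @export
tidy.lc_record <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, period = x$period,
                 peak_order = x$peak_order, windows_used = x$windows_used)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.gma_trajectory <- function(object, observables = NULL, window = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    w <- object$windows[window, ]
    df <- df[df$time >= w$start & df$time <= w$end, ]
  }
  long <- tidyr::pivot_longer(df, -"time", names_to = "variable",
                              values_to = "concentration")
  if (!is.null(observables)) {
    long <- long[long$variable %in% observables, ]
    long$variable <- names(observables)[match(long$variable, observables)]
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (a.u.)", colour = NULL)
}

#' @export
autoplot.pca_projection <- function(object, colour = NULL, ...) {
  sc <- object$scores
  colour <- colour %||% intersect(c("design", "case_id"), colnames(sc))[1]
  aes <- if (!is.na(colour) && !is.null(colour)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = factor(.data[[colour]]))
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * (if (length(object$explained) >= 2) object$explained[2] else 0)),
      colour = NULL)
}

#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  env <- object$envelope
  ggplot2::ggplot(env, ggplot2::aes(.data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_min, ymax = .data$env_max),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$env_max)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$env_min)) +
    ggplot2::geom_vline(xintercept = object$lc_value, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$param,
                  y = paste0(object$species, " oscillation envelope"))
}

#' @export
autoplot.robustness_scan <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(.data[[names(g)[1]]], .data[[names(g)[2]]],
                                  fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen") +
    ggplot2::labs(fill = paste0(object$species, " amplitude"))
}

#' @export
autoplot.phase_plane <- function(object, ...) {
  key <- setdiff(colnames(object), c("case_id", "n_positive"))
  cells <- dplyr::summarise(
    dplyr::group_by(object, dplyr::across(dplyr::all_of(key))),
    phenotypes = paste(sort(unique(.data$case_id)), collapse = "+"),
    n_positive_max = max(.data$n_positive), .groups = "drop")
  ggplot2::ggplot(cells, ggplot2::aes(.data[[key[1]]], .data[[key[2]]],
                                      fill = .data$phenotypes)) +
    ggplot2::geom_raster() +
    ggplot2::labs(fill = "valid phenotypes")
}
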