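#' Plot theme and composite trajectories from a score table
#'
#' Mean score per period for the composite (CSDI), the coupling-
#' coordination degree D, and the three themes — the standard summary view
#' of an assessment run.
#'
#' @param object A `csd_scores` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot csd_scores
#' @export
autoplot.csd_scores <- function(object, ...) {
  h <- attr(object, "hierarchy")
  series <- c("CSDI", "D", h$themes$theme)
  long <- tibble::as_tibble(object)[c("entity", "period", series)] |>
    tidyr::pivot_longer(cols = dplyr::all_of(series),
                        names_to = "series", values_to = "score") |>
    dplyr::group_by(.data$period, .data$series) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$score,
                                     colour = .data$series,
                                     group = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Period", y = "Mean score (0-100)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the permutation distribution of a Moran test
#'
#' @param object A `moran_test`.
#' @param ... Unused.
#' @return A ggplot: histogram of permuted statistics with the observed I.
#' @method autoplot moran_test
#' @export
autoplot.moran_test <- function(object, ...) {
  df <- tibble::tibble(I = object$perm_I)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$I)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$I, colour = "red") +
    ggplot2::geom_vline(xintercept = object$expected_I, linetype = "dashed") +
    ggplot2::labs(x = "Moran's I (permutation null)", y = "Count",
                  title = sprintf("Observed I = %.3f, p = %.4g",
                                  object$I, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' Plot Jenks class intervals
#'
#' @param object A `jenks_breaks`.
#' @param ... Unused.
#' @return A ggplot: the classified values on a strip, coloured by class.
#' @method autoplot jenks_breaks
#' @export
autoplot.jenks_breaks <- function(object, ...) {
  iv <- object$intervals
  iv$class <- factor(iv$class, labels = as.character(utils::as.roman(iv$class)))
  ggplot2::ggplot(iv, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                   ymin = 0, ymax = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::labs(x = "Score", y = "Class size", fill = "Class",
                  title = sprintf("Jenks natural breaks (k = %d, GVF = %.3f)",
                                  object$k, object$gvf)) +
    ggplot2::theme_minimal()
}

#' Tile plot of the pairwise interaction-detector matrix
#'
#' @param x A `geodetector_result` from [geodetector()].
#' @return A ggplot: overlay q values with interaction categories.
#' @export
plot_interaction_matrix <- function(x) {
  stopifnot(inherits(x, "geodetector_result"))
  df <- x$interactions
  if (nrow(df) == 0) stop("no interactions to plot", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2,
                                   fill = .data$q12)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n%s", .data$q12, .data$category)), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "q(X1∩X2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
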