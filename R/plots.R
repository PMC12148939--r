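#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_histogram
#'   geom_vline geom_hline geom_smooth facet_grid facet_wrap labs
#'   theme_minimal vars
NULL

#' Plot a rolling -log10 p-value track
#'
#' Manhattan-style track of window means per scaffold with the empirical
#' outlier threshold as a horizontal line.
#'
#' @param object An `er_rolling` track from [rolling_log10p()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_rolling <- function(object, ...) {
  ggplot(object, aes(x = .data$pos, y = .data$value)) +
    geom_line(linewidth = 0.3, colour = "grey30") +
    geom_hline(yintercept = attr(object, "threshold"),
               colour = "orange", linetype = 2) +
    facet_grid(cols = vars(.data$scaffold), scales = "free_x",
               space = "free_x") +
    labs(x = "position", y = expression(rolling~-log[10]~italic(p))) +
    theme_minimal()
}

#' Plot the random-angle null with the observed mean angle
#'
#' @param object An `er_angle_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_angle_null <- function(object, ...) {
  p <- ggplot(tidy(object), aes(x = .data$mean_angle)) +
    geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    labs(x = "mean pairwise angle (degrees)", y = "iterations") +
    theme_minimal()
  if (!is.null(object$observed)) {
    p <- p + geom_vline(xintercept = object$observed, colour = "red")
  }
  p
}

#' Plot genomic offsets against phenotypic and fitness offsets
#'
#' Scatter of the genomic offset versus the phenotypic and relative-fitness
#' offsets, faceted by within/between background, with per-reference linear
#' trends.
#'
#' @param object An `er_offsets` table from [offset_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_offsets <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("phenotypic_offset", "fitness_offset"),
    names_to = "response", values_to = "offset"
  )
  ggplot(long, aes(x = .data$genomic_offset, y = .data$offset,
                   colour = .data$regime)) +
    geom_point(size = 1.6) +
    geom_smooth(aes(group = .data$reference), method = "lm", se = FALSE,
                linewidth = 0.4, colour = "grey40", formula = y ~ x) +
    facet_grid(rows = vars(.data$response), cols = vars(.data$group),
               scales = "free") +
    labs(x = "genomic offset", y = "offset") +
    theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' @param object An `er_perm` from [permutation_regime_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_perm <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_statistic)) +
    geom_histogram(bins = 40, fill = "grey70", colour = NA) +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = paste("hot - cold difference in mean", object$statistic),
         y = "permutations") +
    theme_minimal()
}
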