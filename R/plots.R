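# ggplot2 methods for the package's result objects.

#' Plot an empirical Rxy distribution
#'
#' Histogram of the simulated Rxy samples with the fitted normal density
#' and, for forced distributions, a dashed line at the class's expected
#' forced value.
#'
#' @param object An `rxy_distribution`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rxy_distribution <- function(object, bins = 50, ...) {
  df <- tidy(object)
  expected <- relatedness_classes()
  exp_val <- if (object$forced) {
    expected$expected_forced_rxy[expected$class == object$class]
  } else {
    expected$expected_diploid_rxy[expected$class == object$class]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rxy)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::stat_function(
      fun = dnorm, args = list(mean = object$mu, sd = object$sigma),
      colour = "steelblue", linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = exp_val, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Rxy", y = "Density",
      title = sprintf("%s (%s), %d dyads x %d loci",
                      object$class,
                      if (object$forced) "forced pseudo-haploid" else "diploid",
                      object$n_dyads, object$n_loci),
      subtitle = sprintf("fitted normal: mu = %.4f, sigma = %.4f",
                         object$mu, object$sigma)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay class distributions for one dyad panel
#'
#' Density curves of several empirical Rxy distributions (typically the
#' three relatedness classes simulated on one shared-locus panel), with an
#' optional vertical line marking an observed coefficient.
#'
#' @param dists List of `rxy_distribution` objects.
#' @param observed Optional observed Rxy to mark.
#' @return A ggplot object.
#' @export
plot_rxy_distributions <- function(dists, observed = NULL) {
  stopifnot(is.list(dists),
            all(vapply(dists, inherits, logical(1), "rxy_distribution")))
  df <- bind_rows(purrr::map(dists, tidy))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rxy, colour = .data$class,
                                        fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::labs(x = "Rxy", y = "Density", colour = "Class",
                  fill = "Class") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, linetype = "dashed",
                                 colour = "black")
  }
  p
}

#' Plot trio hypothesis posteriors
#'
#' Bar chart of per-hypothesis posterior probabilities on a log10 scale
#' (posteriors of rejected hypotheses span many orders of magnitude).
#'
#' @param object A `trio_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trio_report <- function(object, ...) {
  df <- tidy(object)
  df$label <- paste0(df$hypothesis, ": ", df$rel_ab, "/", df$rel_ac, "/",
                     df$rel_bc)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$hypothesis),
                                   y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Posterior probability (log scale)") +
    ggplot2::theme_minimal()
}
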