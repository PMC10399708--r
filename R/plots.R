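#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ASCN fit
#'
#' Segment-level logR and folded BAF tracks with the assigned
#' allele-specific copy numbers, facetted by chromosome.
#'
#' @param object An `ascn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ascn_fit <- function(object, ...) {
  segs <- as_tibble(object$segments)
  long <- tidyr::pivot_longer(
    segs %>% mutate(total = .data$nA + .data$nB),
    cols = c("logR", "baf"), names_to = "signal", values_to = "value"
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$value, yend = .data$value,
                   colour = factor(.data$total)),
      linewidth = 1.2
    ) +
    ggplot2::facet_grid(signal ~ chrom, scales = "free",
                        space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = NULL, colour = "total CN",
      title = sprintf("purity %.2f, ploidy %.1f", object$purity,
                      object$ploidy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot scar scores
#'
#' Bar chart of the three scar components with the HRD sum and cutoff.
#'
#' @param object A `scar_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scar_scores <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = toupper(.data$component),
                                  y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "events",
                  title = sprintf("HRD = %d (%s at cutoff %d)",
                                  object$hrd, object$status,
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot an experiment series
#'
#' HRD score (and its components) against the experiment's factor level:
#' purity for dilution series, depth for titration series; concordance
#' experiments are drawn as per-panel score distributions.
#'
#' @param object An `hrd_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hrd_experiment <- function(object, ...) {
  d <- tidy(object)
  lab <- attr(object, "label")
  if (lab == "panel_concordance") {
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$panel, y = .data$hrd)) +
        ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
        ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
        ggplot2::labs(x = NULL, y = "HRD score") +
        ggplot2::theme_minimal()
    )
  }
  xvar <- if ("purity" %in% names(d)) "purity" else "depth"
  long <- tidyr::pivot_longer(d, cols = c("loh", "tai", "lst", "hrd"),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                     colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "events") +
    ggplot2::theme_minimal()
}

#' Panel QC plots
#'
#' Histogram of inter-SNP distances (and GC when available).
#'
#' @param object A `panel_qc` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.panel_qc <- function(object, ...) {
  d <- tibble(distance = object$distances)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance / 1e3)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue") +
    ggplot2::labs(x = "inter-SNP distance (kb)", y = "count") +
    ggplot2::theme_minimal()
}
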