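#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ASCN fit into its segment table
#'
#' @param x An `ascn_fit`.
#' @param ... Unused.
#' @return The segment tibble with assigned copy numbers.
#' @exportS3Method generics::tidy
tidy.ascn_fit <- function(x, ...) {
  as_tibble(x$segments)
}

#' One-row summary of an ASCN fit
#'
#' @param x An `ascn_fit`.
#' @param ... Unused.
#' @return Tibble with `purity`, `ploidy`, `loglik`, `identifiable`,
#'   `n_segments`, `n_sites`.
#' @exportS3Method generics::glance
glance.ascn_fit <- function(x, ...) {
  tibble(purity = x$purity, ploidy = x$ploidy, loglik = x$loglik,
         identifiable = x$identifiable, n_segments = nrow(x$segments),
         n_sites = x$n_sites)
}

#' Tidy scar scores into long form
#'
#' @param x A `scar_scores` object.
#' @param ... Unused.
#' @return Tibble with one row per score component.
#' @exportS3Method generics::tidy
tidy.scar_scores <- function(x, ...) {
  tibble(component = c("loh", "tai", "lst"),
         count = c(x$loh, x$tai, x$lst))
}

#' One-row summary of scar scores
#'
#' @param x A `scar_scores` object.
#' @param ... Unused.
#' @return Tibble with the three counts, `hrd`, `status`, `cutoff`.
#' @exportS3Method generics::glance
glance.scar_scores <- function(x, ...) {
  tibble(loh = x$loh, tai = x$tai, lst = x$lst, hrd = x$hrd,
         status = x$status, cutoff = x$cutoff)
}

#' Tidy an experiment result
#'
#' @param x An `hrd_experiment`.
#' @param ... Unused.
#' @return The per-level result tibble.
#' @exportS3Method generics::tidy
tidy.hrd_experiment <- function(x, ...) {
  tibble::as_tibble(unclass2(x))
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "hrd_experiment")
  x
}

#' Summary statistics of an experiment result
#'
#' @param x An `hrd_experiment`.
#' @param ... Unused.
#' @return One-row tibble: experiment label, number of levels, and (for
#'   concordance experiments) the minimum between-panel R-squared and
#'   AUC.
#' @exportS3Method generics::glance
glance.hrd_experiment <- function(x, ...) {
  r2 <- attr(x, "r2")
  auc <- attr(x, "auc")
  tibble(
    label = attr(x, "label"),
    n_levels = nrow(x),
    min_r2 = if (!is.null(r2)) min(r2) else NA_real_,
    min_auc = if (!is.null(auc)) min(auc) else NA_real_
  )
}
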