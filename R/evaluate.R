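#' Heterozygous-site counts in genomic bins
#'
#' Divides the genome into fixed-width bins (3 Mb by default) and counts
#' the sites in each bin that look heterozygous: depth above
#' `depth_factor` times the sample mean depth and variant allele fraction
#' within `[vaf_low, vaf_high]`. This is the capture-homogeneity diagnostic
#' used to compare panel designs.
#'
#' @param obs Observation tibble.
#' @param genome A [genome_build()].
#' @param bin_width Bin width in bp. Default 3e6.
#' @param vaf_low,vaf_high Inclusive VAF window. Defaults 0.3 and 0.7.
#' @param depth_factor Sites must exceed this fraction of the sample mean
#'   depth. Default 0.2.
#' @param sample Which channel to assess: `"tumor"` or `"normal"`.
#' @return Tibble `chrom`, `start`, `end`, `n_het` (one row per bin).
#' @export
het_bin_counts <- function(obs, genome, bin_width = 3e6,
                           vaf_low = 0.3, vaf_high = 0.7,
                           depth_factor = 0.2,
                           sample = c("tumor", "normal")) {
  sample <- match.arg(sample)
  obs <- arrange(as_tibble(obs), .data$chrom, .data$pos)
  if (sample == "tumor") {
    depth <- obs$t_ref + obs$t_alt; alt <- obs$t_alt
  } else {
    depth <- obs$n_ref + obs$n_alt; alt <- obs$n_alt
  }
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  keep <- depth > depth_factor * mean(depth) &
    !is.na(vaf) & vaf >= vaf_low & vaf <= vaf_high
  bins <- tile_windows(genome, bin_width)
  hits <- obs[keep, c("chrom", "pos")]
  hits$bin <- floor(hits$pos / bin_width) + 1
  counts <- dplyr::count(hits, .data$chrom, .data$bin, name = "n_het")
  bins %>%
    dplyr::left_join(counts, by = c("chrom", "window" = "bin")) %>%
    mutate(n_het = dplyr::coalesce(.data$n_het, 0L)) %>%
    select("chrom", "start", "end", "n_het")
}

#' Heterozygosity rate of called genotypes
#'
#' Fraction of called sites that are heterozygous. Accepts either a
#' character vector of genotypes (`"het"`, `"hom_ref"`, `"hom_alt"`, `NA`
#' for missing) or an observation tibble (whose `normal_gt` column is
#' used).
#'
#' @param x Genotype vector or observation tibble.
#' @return Heterozygous fraction among called sites.
#' @export
heterozygosity_rate <- function(x) {
  gt <- if (is.data.frame(x)) x$normal_gt else x
  called <- !is.na(gt)
  if (!any(called)) abort("all genotypes are missing.")
  sum(gt[called] == "het") / sum(called)
}

#' Tie-corrected rank AUC
#'
#' Area under the ROC curve computed by the rank-sum (Mann-Whitney)
#' statistic with midranks for ties.
#'
#' @param scores Numeric predictor.
#' @param labels Logical (or 0/1) truth labels.
#' @return AUC in \[0, 1\]; `NA` when only one class is present.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# all-diploid companion profile sharing a tumor's chromosomes (the diluent
# for in-silico purity mixing)
diploid_profile <- function(truth) {
  segs <- truth$segments %>%
    group_by(.data$chrom) %>%
    summarise(start = min(.data$start), end = max(.data$end)) %>%
    mutate(nA = 1, nB = 1)
  structure(list(purity = 1, ploidy = 2, segments = segs,
                 ledger = list(loh = 0, tai = 0, lst = 0), seed = NULL),
            class = "truth_profile")
}

pipeline_row <- function(obs, genome, cutoff = 42, ...) {
  fit <- fit_ascn(obs, genome, ...)
  sc <- score_hrd(fit, genome, cutoff = cutoff)
  tibble(purity_hat = fit$purity, ploidy_hat = fit$ploidy,
         loh = sc$loh, tai = sc$tai, lst = sc$lst, hrd = sc$hrd,
         status = sc$status)
}

new_experiment <- function(tbl, label, ...) {
  structure(as_tibble(tbl),
            class = c("hrd_experiment", class(as_tibble(tbl))),
            label = label, ...)
}

#' In-silico purity dilution series
#'
#' Simulates a pure tumor and a matched pure normal over the panel (one
#' shared germline), then for each requested purity mixes their tumor-
#' channel reads with [mix_purity()] and runs the full inference pipeline
#' ([fit_ascn()] + [score_hrd()]). Mirrors the wet-lab question of how far
#' tumor-cell content can drop before the HRD score degrades.
#'
#' @param truth A [simulate_truth_profile()] result (purity 1).
#' @param panel Panel tibble.
#' @param genome A [genome_build()].
#' @param purities Mixing fractions in (0, 1].
#' @param depth Mean sequencing depth. Default 300.
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [fit_ascn()].
#' @return An `hrd_experiment` tibble with one row per purity level
#'   (`purity`, fitted purity/ploidy and the scar scores), carrying the
#'   truth scores as attribute `truth_scores`.
#' @export
run_dilution_series <- function(truth, panel, genome,
                                purities = seq(0.1, 1.0, by = 0.1),
                                depth = 300, seed = NULL, ...) {
  if (any(purities <= 0 | purities > 1)) {
    abort("`purities` must lie in (0, 1].")
  }
  maf <- panel_maf(panel)
  gt <- with_seed(child_seed(seed, 1), {
    u <- runif(nrow(panel))
    p_het <- 2 * maf * (1 - maf)
    ifelse(u < p_het, "het",
           ifelse(u < p_het + maf^2, "hom_alt", "hom_ref"))
  })
  tumor_obs <- simulate_observations(truth, panel, depth,
                                     seed = child_seed(seed, 2),
                                     genotypes = gt)
  normal_obs <- simulate_observations(diploid_profile(truth), panel, depth,
                                      seed = child_seed(seed, 3),
                                      genotypes = gt)
  rows <- purrr::map_dfr(seq_along(purities), function(i) {
    mixed <- mix_purity(tumor_obs, normal_obs, purities[i],
                        seed = child_seed(seed, 10 + i))
    dplyr::bind_cols(tibble(purity = purities[i]),
                     pipeline_row(mixed, genome, ...))
  })
  new_experiment(rows, label = "purity_dilution",
                 truth_scores = score_hrd(truth, genome))
}

#' Sequencing-depth titration series
#'
#' Simulates observations at the highest requested depth and binomially
#' thins them to each lower level with [downsample_depth()], running the
#' full inference pipeline per level. Mirrors the question of how much
#' sequencing a reliable HRD score needs.
#'
#' @param truth A [simulate_truth_profile()] result.
#' @param panel Panel tibble.
#' @param genome A [genome_build()].
#' @param depths Target mean depths; default `c(50, 100, 150, 200, 250)`.
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [fit_ascn()].
#' @return An `hrd_experiment` tibble with one row per depth.
#' @export
run_depth_series <- function(truth, panel, genome,
                             depths = c(50, 100, 150, 200, 250),
                             seed = NULL, ...) {
  if (any(depths <= 0)) abort("`depths` must be positive.")
  dmax <- max(depths)
  full <- simulate_observations(truth, panel, dmax,
                                seed = child_seed(seed, 1))
  rows <- purrr::map_dfr(seq_along(depths), function(i) {
    obs <- downsample_depth(full, depths[i] / dmax,
                            seed = child_seed(seed, 10 + i))
    dplyr::bind_cols(tibble(depth = depths[i]),
                     pipeline_row(obs, genome, ...))
  })
  new_experiment(rows, label = "depth_titration",
                 truth_scores = score_hrd(truth, genome))
}

#' Panel-subset concordance and ROC analysis
#'
#' Scores each sample of a cohort through the pipeline restricted to each
#' candidate panel, then summarises between-panel agreement as squared
#' Pearson correlation of the HRD score vectors and, when truth scores are
#' supplied, the rank AUC of each panel's scores against the truth HRD
#' labels at the cutoff.
#'
#' @param cohort_obs List of observation tibbles (one per sample), each
#'   covering at least the union of the panels' sites.
#' @param panels Named list of panel tibbles; each must be a subset of the
#'   observed sites of every sample.
#' @param genome A [genome_build()].
#' @param truth_scores Optional numeric vector of truth HRD scores (one per
#'   sample) from which positivity labels are derived.
#' @param cutoff HRD cutoff for labels and classification. Default 42.
#' @param ... Passed to [fit_ascn()].
#' @return An `hrd_experiment` tibble (one row per sample x panel) with
#'   attributes `r2` (panel x panel matrix) and `auc` (named vector, when
#'   labels were available).
#' @export
panel_concordance <- function(cohort_obs, panels, genome,
                              truth_scores = NULL, cutoff = 42, ...) {
  if (is.null(names(panels)) || any(names(panels) == "")) {
    abort("`panels` must be a named list.")
  }
  rows <- purrr::map_dfr(seq_along(cohort_obs), function(s) {
    obs <- as_tibble(cohort_obs[[s]])
    key <- paste0(obs$chrom, ":", obs$pos)
    purrr::map_dfr(names(panels), function(pn) {
      p <- panels[[pn]]
      pkey <- paste0(p$chrom, ":", p$pos)
      if (!all(pkey %in% key)) {
        abort(paste0("panel `", pn,
                     "` is not a subset of the observed sites of sample ",
                     s, "."))
      }
      sub <- obs[key %in% pkey, ]
      dplyr::bind_cols(tibble(sample = s, panel = pn),
                       pipeline_row(sub, genome, cutoff = cutoff, ...))
    })
  })
  wide <- rows %>%
    select("sample", "panel", "hrd") %>%
    tidyr::pivot_wider(names_from = "panel", values_from = "hrd") %>%
    arrange(.data$sample)
  mat <- as.matrix(wide[, names(panels), drop = FALSE])
  r2 <- stats::cor(mat)^2
  auc <- NULL
  if (!is.null(truth_scores)) {
    if (length(truth_scores) != length(cohort_obs)) {
      abort("`truth_scores` must have one value per sample.")
    }
    labels <- truth_scores >= cutoff
    auc <- vapply(names(panels),
                  function(pn) rank_auc(mat[, pn], labels), numeric(1))
  }
  new_experiment(rows, label = "panel_concordance", r2 = r2, auc = auc,
                 truth_scores = truth_scores)
}

#' @export
print.hrd_experiment <- function(x, ...) {
  cat("<hrd_experiment> ", attr(x, "label"), "\n", sep = "")
  NextMethod()
}
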