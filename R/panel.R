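#' Panel design configuration
#'
#' Thresholds for the SNP backbone panel selection rules: population
#' minor-allele-frequency floor, exon exclusion distance, Hardy-Weinberg
#' significance level, spacing window, and probe GC bounds.
#'
#' @param populations Names of the population frequency columns expected on
#'   candidate tables (`maf_<pop>` etc.).
#' @param rank_population Population whose allele frequency ranks candidates
#'   inside a spacing window (the design maximises heterozygosity in this
#'   population; for the original panel this is the East-Asian/Chinese
#'   frequency).
#' @param min_maf Minor allele frequency must be strictly greater than this
#'   in every population. Default 0.01.
#' @param exon_distance Minimum distance (bp) from a SNP to the nearest exon
#'   base; a SNP exactly at this distance passes. Default 200.
#' @param hwe_p SNPs with an exact Hardy-Weinberg p-value below this in any
#'   population are removed. Default 1e-4.
#' @param spacing Width (bp) of the selection windows; one SNP is kept per
#'   window. Default 50000.
#' @param gc_bounds Closed interval of acceptable probe-window GC fraction.
#'   Default `c(0.25, 0.75)`.
#' @return A list of class `design_config`.
#' @export
design_config <- function(populations = c("EAS", "EUR", "AFR", "AMR"),
                          rank_population = "EAS",
                          min_maf = 0.01,
                          exon_distance = 200,
                          hwe_p = 1e-4,
                          spacing = 50000,
                          gc_bounds = c(0.25, 0.75)) {
  if (!rank_population %in% populations) {
    abort("`rank_population` must be one of `populations`.")
  }
  if (min_maf <= 0 || exon_distance <= 0 || hwe_p <= 0 || spacing <= 0) {
    abort("all thresholds must be positive.")
  }
  if (gc_bounds[1] >= gc_bounds[2]) abort("gc_bounds must satisfy low < high.")
  structure(
    list(populations = populations, rank_population = rank_population,
         min_maf = min_maf, exon_distance = exon_distance, hwe_p = hwe_p,
         spacing = spacing, gc_bounds = gc_bounds),
    class = "design_config"
  )
}

candidate_id <- function(candidates) {
  if ("id" %in% names(candidates) && !anyNA(candidates$id)) {
    as.character(candidates$id)
  } else {
    paste0(candidates$chrom, ":", candidates$pos)
  }
}

# Distance (bp) from single-base positions to the nearest exon base on the
# same chromosome; Inf when the chromosome has no exons.
exon_distances <- function(chrom, pos, exons) {
  out <- rep(Inf, length(pos))
  if (is.null(exons) || nrow(exons) == 0) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ex <- exons[exons$chrom == ch, , drop = FALSE]
    if (nrow(ex) == 0) next
    ex <- ex[order(ex$start), , drop = FALSE]
    p <- pos[sel]
    i <- findInterval(p, ex$start)
    d_prev <- ifelse(i >= 1,
                     ifelse(p < ex$end[pmax(i, 1)], 0,
                            p - (ex$end[pmax(i, 1)] - 1)),
                     Inf)
    d_next <- ifelse(i < nrow(ex), ex$start[pmin(i + 1, nrow(ex))] - p, Inf)
    out[sel] <- pmin(d_prev, d_next)
  }
  out
}

#' Apply the per-site panel design filters
#'
#' Evaluates the four site-level selection rules on every candidate SNP:
#' minor allele frequency strictly above the floor in all populations, no
#' exon base within the exclusion distance, exact Hardy-Weinberg p-value at
#' or above the threshold in all populations, and (when a GC value is
#' present) probe GC within bounds. Rules are checked in that order and a
#' rejected SNP is labelled with the first rule it fails.
#'
#' The surviving set is a pure function of the candidate set: input order
#' does not matter (rows are sorted internally).
#'
#' @param candidates Tibble with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `maf_<pop>` and genotype counts `n_rr_<pop>`, `n_ra_<pop>`,
#'   `n_aa_<pop>` for every configured population, and optionally `gc`.
#' @param exons Tibble of exon intervals (`chrom`, `start`, `end`; 0-based
#'   half-open), or `NULL` for none.
#' @param config A [design_config()].
#' @return The candidate tibble, sorted by position, with logical `pass` and
#'   character `reason` (`NA` for passing SNPs; otherwise `"maf"`,
#'   `"exon_distance"`, `"hwe"` or `"gc"`).
#' @export
apply_site_filters <- function(candidates, exons = NULL,
                               config = design_config()) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0) {
    return(mutate(cand, pass = logical(0), reason = character(0)))
  }
  maf_cols <- paste0("maf_", config$populations)
  gt_cols <- as.vector(outer(c("n_rr_", "n_ra_", "n_aa_"),
                             config$populations, paste0))
  missing_cols <- setdiff(c("chrom", "pos", maf_cols, gt_cols), names(cand))
  if (length(missing_cols) > 0) {
    abort(paste0("candidate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cand <- arrange(cand, .data$chrom, .data$pos)
  for (cc in c(maf_cols, gt_cols)) {
    if (anyNA(cand[[cc]])) {
      bad <- candidate_id(cand)[which(is.na(cand[[cc]]))[1]]
      abort(paste0("missing value in `", cc, "` for SNP ", bad))
    }
  }
  maf <- as.matrix(cand[, maf_cols])
  if (any(maf < 0 | maf > 0.5)) {
    abort("minor allele frequencies must lie in [0, 0.5].")
  }
  fail_maf <- apply(maf <= config$min_maf, 1, any)

  dist <- exon_distances(cand$chrom, cand$pos, exons)
  fail_exon <- dist < config$exon_distance

  hwe_min <- rep(1, nrow(cand))
  for (pop in config$populations) {
    pv <- mapply(hwe_exact_test,
                 cand[[paste0("n_rr_", pop)]],
                 cand[[paste0("n_ra_", pop)]],
                 cand[[paste0("n_aa_", pop)]])
    hwe_min <- pmin(hwe_min, pv)
  }
  fail_hwe <- hwe_min < config$hwe_p

  if ("gc" %in% names(cand)) {
    fail_gc <- !is.na(cand$gc) &
      (cand$gc < config$gc_bounds[1] | cand$gc > config$gc_bounds[2])
  } else {
    fail_gc <- rep(FALSE, nrow(cand))
  }

  reason <- rep(NA_character_, nrow(cand))
  reason[fail_gc] <- "gc"
  reason[fail_hwe] <- "hwe"
  reason[fail_exon] <- "exon_distance"
  reason[fail_maf] <- "maf"
  mutate(cand, pass = is.na(reason), reason = reason)
}

#' Select one SNP per spacing window
#'
#' Tiles the genome into `spacing`-width windows and keeps, in every window
#' that holds at least one passing candidate, the candidate with the highest
#' allele frequency in the ranking population (ties broken by smaller
#' position). Windows without a candidate are recorded as coverage gaps.
#'
#' @param passing Output of [apply_site_filters()] (rows with `pass = FALSE`
#'   are dropped automatically), or any candidate tibble already filtered.
#' @param genome A [genome_build()].
#' @param config A [design_config()].
#' @return A tibble of class `panel_design`, sorted by position, with
#'   attributes `spacing`, `config` and `qc` (window/gap counts).
#' @export
select_spaced <- function(passing, genome, config = design_config()) {
  cand <- as_tibble(passing)
  if ("pass" %in% names(cand)) cand <- filter(cand, .data$pass)
  rank_col <- paste0("maf_", config$rank_population)
  if (nrow(cand) > 0 && !rank_col %in% names(cand)) {
    abort(paste0("candidate table is missing column `", rank_col, "`."))
  }
  n_windows <- sum(ceiling(genome$length / config$spacing))
  if (nrow(cand) == 0) {
    panel <- cand
  } else {
    if (!all(cand$chrom %in% genome$chrom)) {
      abort("candidates on chromosomes absent from the genome build.")
    }
    panel <- cand %>%
      mutate(.win = floor(.data$pos / config$spacing)) %>%
      arrange(.data$chrom, .data$.win,
              dplyr::desc(.data[[rank_col]]), .data$pos) %>%
      group_by(.data$chrom, .data$.win) %>%
      slice(1) %>%
      ungroup() %>%
      select(-".win") %>%
      arrange(.data$chrom, .data$pos)
  }
  new_panel(panel, spacing = config$spacing, config = config,
            qc = list(n_windows = n_windows,
                      n_gaps = n_windows - nrow(panel)))
}

new_panel <- function(tbl, spacing, config = NULL, qc = NULL) {
  structure(as_tibble(tbl),
            class = c("panel_design", class(as_tibble(tbl))),
            spacing = spacing, config = config, qc = qc)
}

#' Thin a panel to every k-th SNP
#'
#' In-silico panel subsetting: keeps every `keep_every`-th SNP in genomic
#' order within each chromosome (the first SNP of each chromosome is always
#' kept), emulating the derivation of lower-density panels from a dense one.
#'
#' @param panel A `panel_design` tibble.
#' @param keep_every Integer >= 1; 1 returns the panel unchanged.
#' @return A `panel_design` with roughly `1/keep_every` of the SNPs and
#'   spacing scaled accordingly.
#' @export
subset_panel <- function(panel, keep_every) {
  if (!is.numeric(keep_every) || length(keep_every) != 1L ||
      keep_every < 1 || keep_every != round(keep_every)) {
    abort("`keep_every` must be a single integer >= 1.")
  }
  out <- as_tibble(panel) %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$chrom) %>%
    slice(seq(1, dplyr::n(), by = keep_every)) %>%
    ungroup()
  sp <- attr(panel, "spacing")
  new_panel(out, spacing = if (is.null(sp)) NULL else sp * keep_every,
            config = attr(panel, "config"), qc = attr(panel, "qc"))
}

#' Panel quality-control summary
#'
#' Direct-count summaries of a panel: SNP count, per-chromosome density,
#' the inter-SNP distance distribution, the GC distribution (when present)
#' and the coverage-gap count from selection.
#'
#' @param panel A `panel_design` tibble.
#' @param genome A [genome_build()].
#' @return A list of class `panel_qc` with elements `summary` (one-row
#'   tibble), `per_chromosome` (tibble) and `distances` (numeric vector of
#'   successive inter-SNP distances within chromosomes).
#' @export
panel_qc <- function(panel, genome) {
  p <- arrange(as_tibble(panel), .data$chrom, .data$pos)
  dists <- numeric(0)
  if (nrow(p) > 1) {
    dists <- unlist(lapply(split(p$pos, p$chrom), function(x) diff(sort(x))),
                    use.names = FALSE)
  }
  per_chrom <- genome %>%
    as_tibble() %>%
    select("chrom", "length") %>%
    dplyr::left_join(dplyr::count(p, .data$chrom, name = "n_snps"),
                     by = "chrom") %>%
    mutate(n_snps = dplyr::coalesce(.data$n_snps, 0L),
           density_per_mb = .data$n_snps / (.data$length / 1e6))
  qc <- attr(panel, "qc")
  summary <- tibble(
    n_snps = nrow(p),
    n_chromosomes = length(unique(p$chrom)),
    n_gaps = if (!is.null(qc)) qc$n_gaps else NA_integer_,
    median_spacing = if (length(dists)) median(dists) else NA_real_,
    mean_spacing = if (length(dists)) mean(dists) else NA_real_,
    gc_min = if ("gc" %in% names(p) && nrow(p)) min(p$gc, na.rm = TRUE) else NA_real_,
    gc_max = if ("gc" %in% names(p) && nrow(p)) max(p$gc, na.rm = TRUE) else NA_real_
  )
  structure(list(summary = summary, per_chromosome = per_chrom,
                 distances = dists),
            class = "panel_qc")
}

#' @export
print.panel_qc <- function(x, ...) {
  cat("<panel_qc>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.panel_design <- function(x, ...) {
  sp <- attr(x, "spacing")
  cat("<panel_design> ", nrow(x), " SNPs",
      if (!is.null(sp)) paste0(", target spacing ", format(sp, big.mark = ","), " bp"),
      "\n", sep = "")
  NextMethod()
}
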