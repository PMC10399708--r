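SEX_CHROMS <- c("chrX", "chrY", "X", "Y")

check_segments <- function(segments) {
  req <- c("chrom", "start", "end", "nA", "nB")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  s <- arrange(as_tibble(segments), .data$chrom, .data$start)
  if (any(s$end <= s$start)) abort("segments must have end > start.")
  if (any(s$nA < s$nB) || any(s$nB < 0)) {
    abort("segments must satisfy nA >= nB >= 0.")
  }
  ov <- s %>% group_by(.data$chrom) %>%
    summarise(bad = any(.data$start < lag(.data$end), na.rm = TRUE))
  if (any(ov$bad)) {
    abort(paste0("overlapping segments on ",
                 paste(ov$chrom[ov$bad], collapse = ", ")))
  }
  s
}

#' Merge and smooth an allele-specific copy-number profile
#'
#' Prepares a segment profile for scar scoring: (1) adjacent segments with
#' identical (nA, nB) are merged; (2) iteratively, the shortest segment
#' under 3 Mb is removed and its interval absorbed — flanks with equal copy
#' number merge across it, otherwise each flank extends to the removed
#' segment's midpoint; (3) step 1 is re-applied until no segment under the
#' threshold remains. Small aberrations (the "variations < 3 Mb" of the LST
#' definition) therefore never contribute to any score.
#'
#' @param segments Segment tibble with `chrom`, `start`, `end`, `nA`, `nB`
#'   (an [fit_ascn()] result's `$segments` works directly).
#' @param min_size Smoothing threshold in bp. Default 3e6.
#' @return The normalised segment tibble.
#' @export
normalize_profile <- function(segments, min_size = 3e6) {
  if (inherits(segments, "ascn_fit")) segments <- segments$segments
  s <- check_segments(segments)
  if (nrow(s) == 0) return(s)
  out <- lapply(split(s, s$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    repeat {
      d <- merge_equal_adjacent(d)
      small <- which(d$end - d$start < min_size)
      if (length(small) == 0) break
      k <- small[which.min((d$end - d$start)[small])]
      d <- absorb_segment(d, k)
    }
    d
  })
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

merge_equal_adjacent <- function(d) {
  if (nrow(d) < 2) return(d)
  new_run <- c(TRUE, d$nA[-1] != d$nA[-nrow(d)] | d$nB[-1] != d$nB[-nrow(d)])
  g <- cumsum(new_run)
  if (max(g) == nrow(d)) return(d)
  merged <- lapply(split(seq_len(nrow(d)), g), function(ix) {
    r <- d[ix[1], , drop = FALSE]
    r$end <- d$end[ix[length(ix)]]
    if ("n_sites" %in% names(d)) r$n_sites <- sum(d$n_sites[ix])
    if ("n_baf" %in% names(d)) r$n_baf <- sum(d$n_baf[ix])
    r
  })
  bind_rows(merged)
}

absorb_segment <- function(d, k) {
  n <- nrow(d)
  left <- if (k > 1) k - 1 else NA
  right <- if (k < n) k + 1 else NA
  if (!is.na(left) && !is.na(right) &&
      d$nA[left] == d$nA[right] && d$nB[left] == d$nB[right]) {
    d$end[left] <- d$end[right]
    if ("n_sites" %in% names(d)) {
      d$n_sites[left] <- d$n_sites[left] + d$n_sites[right]
    }
    if ("n_baf" %in% names(d)) d$n_baf[left] <- d$n_baf[left] + d$n_baf[right]
    d <- d[-c(k, right), , drop = FALSE]
  } else if (!is.na(left) && !is.na(right)) {
    mid <- floor((d$start[k] + d$end[k]) / 2)
    d$end[left] <- mid
    d$start[right] <- mid
    d <- d[-k, , drop = FALSE]
  } else if (!is.na(left)) {
    d$end[left] <- d$end[k]
    d <- d[-k, , drop = FALSE]
  } else if (!is.na(right)) {
    d$start[right] <- d$start[k]
    d <- d[-k, , drop = FALSE]
  } else {
    d <- d[-k, , drop = FALSE]
  }
  d
}

drop_sex_segments <- function(s, drop_sex) {
  if (drop_sex) s[!s$chrom %in% SEX_CHROMS, , drop = FALSE] else s
}

#' Count HRD-LOH events
#'
#' Counts loss-of-heterozygosity segments (nB = 0 with at least one
#' remaining copy, nA >= 1) longer than `min_size` that do not span the
#' entire covered extent of their chromosome. Homozygous deletions
#' (nA = nB = 0) are not LOH events.
#'
#' @param profile Normalised segment tibble (see [normalize_profile()]).
#' @param genome A [genome_build()].
#' @param min_size Minimum segment length in bp; segments must be strictly
#'   longer. Default 15e6.
#' @param drop_sex Exclude sex chromosomes. Default `TRUE`.
#' @return Integer count.
#' @export
count_hrd_loh <- function(profile, genome, min_size = 15e6, drop_sex = TRUE) {
  s <- drop_sex_segments(check_segments(profile), drop_sex)
  if (nrow(s) == 0) return(0L)
  total <- 0L
  for (ch in unique(s$chrom)) {
    d <- s[s$chrom == ch, ]
    ext <- c(min(d$start), max(d$end))
    hit <- d$nB == 0 & d$nA >= 1 & (d$end - d$start) > min_size &
      !(d$start == ext[1] & d$end == ext[2])
    total <- total + sum(hit)
  }
  as.integer(total)
}

#' Count telomeric allelic imbalance (TAI) events
#'
#' Counts maximal runs of consecutive allelically imbalanced segments
#' (nA != nB) that touch the first or last covered position of their
#' chromosome (the sub-telomere) and whose interval does not overlap the
#' centromere. A run touching both ends while avoiding the centromere is
#' counted once.
#'
#' @param profile Normalised segment tibble.
#' @param genome A [genome_build()].
#' @param min_size Minimum run length in bp (0 = no minimum beyond the
#'   3-Mb smoothing). Default 0.
#' @param drop_sex Exclude sex chromosomes. Default `TRUE`.
#' @return Integer count.
#' @export
count_tai <- function(profile, genome, min_size = 0, drop_sex = TRUE) {
  s <- drop_sex_segments(check_segments(profile), drop_sex)
  if (nrow(s) == 0) return(0L)
  total <- 0L
  for (ch in unique(s$chrom)) {
    d <- s[s$chrom == ch, ]
    gi <- match(ch, genome$chrom)
    if (is.na(gi)) abort(paste0("unknown chromosome: ", ch))
    ext <- c(min(d$start), max(d$end))
    imb <- d$nA != d$nB
    if (!any(imb)) next
    run_id <- cumsum(c(TRUE, diff(imb) != 0 |
                         d$start[-1] != d$end[-nrow(d)]))
    for (r in unique(run_id[imb])) {
      ix <- which(run_id == r & imb)
      if (length(ix) == 0) next
      rs <- d$start[ix[1]]; re <- d$end[ix[length(ix)]]
      touches <- rs == ext[1] || re == ext[2]
      crosses_cen <- rs < genome$cen_end[gi] && re > genome$cen_start[gi]
      if (touches && !crosses_cen && (re - rs) >= min_size) {
        total <- total + 1L
      }
    }
  }
  as.integer(total)
}

#' Count large-scale state transitions (LST)
#'
#' Counts chromosomal breaks between adjacent segments that differ in
#' (nA, nB) when both flanking segments are at least `min_block` long.
#' Breaks located at the centromere (boundary inside the centromere
#' interval, i.e. the flanks lie on different arms) are not counted. The
#' profile must already be smoothed (see [normalize_profile()]): the
#' definition applies "after filtering and smoothing of all variations
#' < 3 Mb".
#'
#' @param profile Normalised segment tibble.
#' @param genome A [genome_build()].
#' @param min_block Minimum length of each flanking segment in bp.
#'   Default 11e6.
#' @param drop_sex Exclude sex chromosomes. Default `TRUE`.
#' @return Integer count.
#' @export
count_lst <- function(profile, genome, min_block = 11e6, drop_sex = TRUE) {
  s <- drop_sex_segments(check_segments(profile), drop_sex)
  if (nrow(s) < 2) return(0L)
  total <- 0L
  for (ch in unique(s$chrom)) {
    d <- s[s$chrom == ch, ]
    gi <- match(ch, genome$chrom)
    if (is.na(gi)) abort(paste0("unknown chromosome: ", ch))
    if (nrow(d) < 2) next
    for (i in seq_len(nrow(d) - 1)) {
      if (d$end[i] != d$start[i + 1]) next   # not adjacent (coverage gap)
      if (d$nA[i] == d$nA[i + 1] && d$nB[i] == d$nB[i + 1]) next
      if (d$end[i] - d$start[i] < min_block) next
      if (d$end[i + 1] - d$start[i + 1] < min_block) next
      b <- d$end[i]
      if (b >= genome$cen_start[gi] && b <= genome$cen_end[gi]) next
      total <- total + 1L
    }
  }
  as.integer(total)
}

#' Genomic scar scores and HRD classification
#'
#' Computes the three genomic scar counts — HRD-LOH, telomeric allelic
#' imbalance and large-scale state transitions — on a (by default, freshly
#' normalised) allele-specific copy-number profile, sums them into the HRD
#' score, and classifies the sample against the clinical cutoff
#' (HRD >= 42 is positive; the comparison is inclusive).
#'
#' @param profile Segment tibble or an [fit_ascn()] result.
#' @param genome A [genome_build()].
#' @param cutoff HRD positivity cutoff. Default 42.
#' @param normalize Apply [normalize_profile()] first (idempotent on an
#'   already-normalised profile). Default `TRUE`.
#' @param min_tai_size Minimum TAI run size in bp. Default 0.
#' @param drop_sex Exclude sex chromosomes from all counts. Default `TRUE`.
#' @return A list of class `scar_scores`: `loh`, `tai`, `lst`, `hrd`
#'   (their sum), `status` (`"positive"`/`"negative"`) and `cutoff`.
#' @examples
#' g <- toy_genome()
#' segs <- tibble::tibble(
#'   chrom = "chrA", start = c(0, 20e6, 40e6), end = c(20e6, 40e6, 120e6),
#'   nA = c(2, 1, 1), nB = c(1, 0, 1)
#' )
#' score_hrd(segs, g)
#' @export
score_hrd <- function(profile, genome, cutoff = 42, normalize = TRUE,
                      min_tai_size = 0, drop_sex = TRUE) {
  if (inherits(profile, "ascn_fit")) profile <- profile$segments
  if (inherits(profile, "truth_profile")) profile <- profile$segments
  prof <- if (normalize) normalize_profile(profile) else
    check_segments(profile)
  loh <- count_hrd_loh(prof, genome, drop_sex = drop_sex)
  tai <- count_tai(prof, genome, min_size = min_tai_size,
                   drop_sex = drop_sex)
  lst <- count_lst(prof, genome, drop_sex = drop_sex)
  hrd <- loh + tai + lst
  structure(
    list(loh = loh, tai = tai, lst = lst, hrd = hrd,
         status = if (hrd >= cutoff) "positive" else "negative",
         cutoff = cutoff),
    class = "scar_scores"
  )
}

#' @export
print.scar_scores <- function(x, ...) {
  cat("<scar_scores> LOH=", x$loh, " TAI=", x$tai, " LST=", x$lst,
      " | HRD=", x$hrd, " (", x$status, " at cutoff ", x$cutoff, ")\n",
      sep = "")
  invisible(x)
}
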