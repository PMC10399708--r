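#' Specification of planted scar events for a synthetic tumor
#'
#' Describes how many copy-number events of each scar class to plant and
#' their size ranges. Events are constructed so that, by design, scoring the
#' noise-free truth segments returns exactly the planted counts:
#'
#' * LOH events are interstitial loss-of-heterozygosity segments longer than
#'   15 Mb, isolated by short (< 11 Mb) imbalanced buffer segments so the
#'   flanking breakpoints do not qualify as large-scale transitions.
#' * TAI events are imbalanced segments shorter than 11 Mb anchored at a
#'   chromosome end, not crossing the centromere.
#' * LST events are pairs of adjacent >= 11 Mb blocks with different
#'   allele-specific copy number, again isolated by short buffers so exactly
#'   one qualifying break is created.
#' * Decoy segments are sub-3-Mb aberrations that the smoothing step must
#'   remove; they contribute to no score.
#'
#' @param n_loh,n_tai,n_lst,n_decoy Event counts (>= 0).
#' @param loh_size Length range (bp) of the LOH core segment; must exceed
#'   15 Mb. Default 20-40 Mb.
#' @param tai_size Length range of the telomeric imbalanced segment; must be
#'   >= 3 Mb and < 11 Mb. Default 5-10 Mb.
#' @param lst_size Length range of each of the two transition blocks; must
#'   be >= 11 Mb. Default 12-15 Mb.
#' @param decoy_size Length range of decoy segments; must be < 3 Mb.
#'   Default 1-2.5 Mb.
#' @param buffer_size Length range of isolation buffers; must be >= 3 Mb and
#'   < 11 Mb. Default 3.5-8 Mb.
#' @param gap_min Minimum stretch of diploid background separating events
#'   from each other and from chromosome ends/centromeres. Default 5 Mb.
#' @return A list of class `event_spec`.
#' @export
event_spec <- function(n_loh = 0, n_tai = 0, n_lst = 0, n_decoy = 0,
                       loh_size = c(20e6, 40e6),
                       tai_size = c(5e6, 10e6),
                       lst_size = c(12e6, 15e6),
                       decoy_size = c(1e6, 2.5e6),
                       buffer_size = c(3.5e6, 8e6),
                       gap_min = 5e6) {
  counts <- c(n_loh, n_tai, n_lst, n_decoy)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("event counts must be non-negative integers.")
  }
  check_range <- function(r, lo, hi, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      abort(paste0("`", what, "` must be an increasing range within [",
                   lo, ", ", hi, "] bp."))
    }
  }
  check_range(loh_size, 15e6 + 1, Inf, "loh_size")
  check_range(tai_size, 3e6, 11e6 - 1, "tai_size")
  check_range(lst_size, 11e6, Inf, "lst_size")
  check_range(decoy_size, 1, 3e6 - 1, "decoy_size")
  check_range(buffer_size, 3e6, 11e6 - 1, "buffer_size")
  if (gap_min < 3e6) abort("`gap_min` must be at least 3 Mb.")
  structure(
    list(n_loh = n_loh, n_tai = n_tai, n_lst = n_lst, n_decoy = n_decoy,
         loh_size = loh_size, tai_size = tai_size, lst_size = lst_size,
         decoy_size = decoy_size, buffer_size = buffer_size,
         gap_min = gap_min),
    class = "event_spec"
  )
}

runif1 <- function(r) round(runif(1, r[1], r[2]))

# Reserve a slot of width `w` inside one chromosome arm, at least `gap`
# away from anything already placed. `free` is a data frame of free
# intervals. Returns the updated free list and the chosen start, or NULL
# when nothing fits.
reserve_slot <- function(free, genome, w, gap) {
  cand <- list()
  for (i in seq_len(nrow(free))) {
    ch <- free$chrom[i]
    gi <- match(ch, genome$chrom)
    arms <- list(c(0, genome$cen_start[gi]),
                 c(genome$cen_end[gi], genome$length[gi]))
    for (a in arms) {
      lo <- max(free$start[i] + gap, a[1])
      hi <- min(free$end[i] - gap, a[2]) - w
      if (hi >= lo) {
        cand[[length(cand) + 1]] <- list(row = i, lo = lo, hi = hi)
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  widths <- vapply(cand, function(x) x$hi - x$lo + 1, numeric(1))
  pick <- cand[[sample.int(length(cand), 1, prob = widths)]]
  # pack towards the low end of the slot (small jitter) so repeated
  # placements fragment the free space as little as possible
  jitter <- min(pick$hi - pick$lo, gap)
  ev_start <- round(pick$lo + runif(1, 0, jitter))
  i <- pick$row
  old <- free[i, ]
  free <- free[-i, , drop = FALSE]
  add <- tibble(chrom = old$chrom,
                start = c(old$start, ev_start + w + gap),
                end = c(ev_start - gap, old$end))
  free <- bind_rows(free, add[add$end - add$start > 0, ])
  list(free = free, chrom = old$chrom, start = ev_start)
}

#' Simulate a truth profile with planted scar events
#'
#' Builds a piecewise-constant allele-specific copy-number genome on a
#' diploid (1,1) background with the events requested in `spec` planted at
#' random positions, subject to: events lie entirely within one chromosome
#' arm, never touch a chromosome end (except TAI events, which must), and
#' are separated from each other and from arm boundaries by at least
#' `gap_min` of background. The generator's contract is that scoring the
#' returned truth segments reproduces the planted event ledger exactly.
#'
#' @param genome A [genome_build()]; sex chromosomes should normally be
#'   excluded (see [grch37_genome()]).
#' @param spec An [event_spec()].
#' @param purity Tumor purity in (0, 1]. Default 1.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A list of class `truth_profile` with elements `purity`, `ploidy`
#'   (length-weighted mean total copy number), `segments` (tibble `chrom`,
#'   `start`, `end`, `nA`, `nB`), `ledger` (planted `loh`, `tai`, `lst`
#'   counts) and `seed`.
#' @export
simulate_truth_profile <- function(genome, spec, purity = 1, seed = NULL) {
  if (purity <= 0 || purity > 1) abort("`purity` must lie in (0, 1].")
  with_seed(seed, {
    # random packing can fail on a heavily loaded genome even when
    # capacity exists; redraw the whole placement a few times before
    # declaring the spec infeasible
    attempt <- 0
    repeat {
      attempt <- attempt + 1
      placed <- tryCatch(place_events(genome, spec),
                         error = function(e) e)
      if (!inherits(placed, "error")) break
      if (attempt >= 30) abort(conditionMessage(placed))
    }
    segs <- fill_background(placed, genome)
    ploidy <- sum((segs$nA + segs$nB) * (segs$end - segs$start)) /
      sum(segs$end - segs$start)
    structure(
      list(purity = purity, ploidy = ploidy, segments = segs,
           ledger = list(loh = spec$n_loh, tai = spec$n_tai,
                         lst = spec$n_lst),
           seed = seed),
      class = "truth_profile"
    )
  })
}

# One placement attempt; errors when an event cannot be placed.
place_events <- function(genome, spec) {
  {
    gap <- spec$gap_min
    free <- tibble(chrom = genome$chrom, start = 0, end = genome$length)
    pieces <- list()

    # telomeric events claim a chromosome end each
    if (spec$n_tai > 0) {
      ends <- expand.grid(chrom = genome$chrom, side = c("p", "q"),
                          stringsAsFactors = FALSE)
      ends <- ends[sample.int(nrow(ends)), , drop = FALSE]
      taken <- 0
      for (i in seq_len(nrow(ends))) {
        if (taken == spec$n_tai) break
        ch <- ends$chrom[i]
        gi <- match(ch, genome$chrom)
        s <- runif1(spec$tai_size)
        fi <- which(free$chrom == ch &
                      if (ends$side[i] == "p") free$start == 0
                      else free$end == genome$length[gi])
        if (length(fi) != 1) next
        if (ends$side[i] == "p") {
          if (s + gap > min(free$end[fi], genome$cen_start[gi])) next
          ev_start <- 0
          free$start[fi] <- s + gap
        } else {
          if (genome$length[gi] - s - gap <
              max(free$start[fi], genome$cen_end[gi])) next
          ev_start <- genome$length[gi] - s
          free$end[fi] <- ev_start - gap
        }
        taken <- taken + 1
        pieces[[length(pieces) + 1]] <-
          tibble(chrom = ch, start = ev_start, end = ev_start + s,
                 nA = 2, nB = 1)
      }
      if (taken < spec$n_tai) {
        abort(paste0("infeasible event spec: could only place ", taken,
                     " of ", spec$n_tai, " TAI events."))
      }
    }

    place_composite <- function(free, sizes, cn, what) {
      w <- sum(sizes)
      slot <- reserve_slot(free, genome, w, gap)
      if (is.null(slot)) {
        abort(paste0("infeasible event spec: no room for a ", what,
                     " event of ", round(w / 1e6, 1), " Mb."))
      }
      starts <- slot$start + cumsum(c(0, sizes[-length(sizes)]))
      pieces[[length(pieces) + 1]] <<-
        tibble(chrom = slot$chrom, start = starts, end = starts + sizes,
               nA = cn[, 1], nB = cn[, 2])
      slot$free
    }

    # draw composite event sizes up front, then place widest-first so
    # big events land in big arms before fragmentation sets in
    comps <- list()
    for (k in seq_len(spec$n_loh)) {
      comps[[length(comps) + 1]] <- list(
        what = "LOH",
        sizes = c(runif1(spec$buffer_size), runif1(spec$loh_size),
                  runif1(spec$buffer_size)),
        cn = rbind(c(2, 1), c(1, 0), c(2, 1))
      )
    }
    for (k in seq_len(spec$n_lst)) {
      comps[[length(comps) + 1]] <- list(
        what = "LST",
        sizes = c(runif1(spec$buffer_size), runif1(spec$lst_size),
                  runif1(spec$lst_size), runif1(spec$buffer_size)),
        cn = rbind(c(3, 1), c(2, 1), c(2, 2), c(3, 1))
      )
    }
    for (k in seq_len(spec$n_decoy)) {
      comps[[length(comps) + 1]] <- list(
        what = "decoy", sizes = runif1(spec$decoy_size),
        cn = rbind(c(3, 1))
      )
    }
    if (length(comps) > 0) {
      ord <- order(-vapply(comps, function(x) sum(x$sizes), numeric(1)))
      for (ev in comps[ord]) {
        free <- place_composite(free, ev$sizes, ev$cn, ev$what)
      }
    }

    if (length(pieces)) bind_rows(pieces) else
      tibble(chrom = character(), start = numeric(), end = numeric(),
             nA = numeric(), nB = numeric())
  }
}

# Fill uncovered stretches of every chromosome with diploid (1,1) segments
# so truth segments tile each chromosome exactly.
fill_background <- function(events, genome) {
  out <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    bounds <- c(0, rbind(ev$start, ev$end), genome$length[i])
    gaps_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
    gaps_end <- bounds[seq(2, length(bounds), by = 2)]
    keep <- gaps_end > gaps_start
    bg <- tibble(chrom = ch, start = gaps_start[keep], end = gaps_end[keep],
                 nA = 1, nB = 1)
    out[[i]] <- bind_rows(ev, bg) %>% arrange(.data$start)
  }
  bind_rows(out)
}

#' Uniformly spaced synthetic SNP panel
#'
#' One SNP at the midpoint of every spacing window, with population minor
#' allele frequencies drawn uniformly from `maf_range`. This emulates the
#' backbone geometry of a designed panel (even 50-kb coverage, high-MAF
#' sites) for simulation studies.
#'
#' @param genome A [genome_build()].
#' @param spacing Window width in bp. Default 50000.
#' @param maf_range Range of per-SNP minor allele frequencies.
#'   Default `c(0.2, 0.5)`.
#' @param seed Integer seed or `NULL`.
#' @return A `panel_design` tibble with columns `chrom`, `pos`, `maf`.
#' @export
uniform_panel <- function(genome, spacing = 50000, maf_range = c(0.2, 0.5),
                          seed = NULL) {
  with_seed(seed, {
    w <- tile_windows(genome, spacing)
    panel <- tibble(
      chrom = w$chrom,
      pos = pmin(w$start + floor(spacing / 2), w$end - 1),
      maf = runif(nrow(w), maf_range[1], maf_range[2])
    )
    new_panel(panel, spacing = spacing)
  })
}

panel_maf <- function(panel) {
  if ("maf" %in% names(panel)) return(panel$maf)
  cfg <- attr(panel, "config")
  if (!is.null(cfg)) {
    col <- paste0("maf_", cfg$rank_population)
    if (col %in% names(panel)) return(panel[[col]])
  }
  abort("panel has no `maf` column (or configured maf_<population> column).")
}

#' Simulate tumor/normal read counts over a panel
#'
#' Draws per-SNP sequencing observations under the purity-ploidy mixture
#' model. The normal genotype is Hardy-Weinberg given the SNP's population
#' MAF; normal depth is Poisson(`mean_depth`); tumor depth is Poisson of
#' `mean_depth` times the expected relative depth
#' \eqn{R = (p(nA+nB) + 2(1-p)) / (p\psi + 2(1-p))}; and the tumor
#' alternate-allele count is binomial with the expected B-allele fraction
#' \eqn{(p\,nB + (1-p)) / (p(nA+nB) + 2(1-p))} at heterozygous sites, with
#' the allele playing the B role randomised per site.
#'
#' @param truth A [simulate_truth_profile()] result.
#' @param panel A panel tibble (`chrom`, `pos`, `maf`); every SNP must fall
#'   inside a truth segment.
#' @param mean_depth Target mean sequencing depth (> 0).
#' @param seed Integer seed or `NULL`.
#' @param genotypes Optional character vector (`"hom_ref"`, `"het"`,
#'   `"hom_alt"`) fixing the germline genotype per panel SNP, e.g. to reuse
#'   one germline across samples; drawn from the MAF when `NULL`.
#' @param overdispersion Depth overdispersion; 0 (default) gives Poisson
#'   depths, values > 0 use a negative binomial with that dispersion.
#' @return Tibble of class `site_obs`: `chrom`, `pos`, `n_ref`, `n_alt`,
#'   `t_ref`, `t_alt`, `normal_gt`.
#' @export
simulate_observations <- function(truth, panel, mean_depth, seed = NULL,
                                  genotypes = NULL, overdispersion = 0) {
  if (nrow(panel) == 0) abort("`panel` is empty.")
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  maf <- panel_maf(panel)
  segs <- truth$segments
  n <- nrow(panel)
  idx <- integer(n)
  for (ch in unique(panel$chrom)) {
    sel <- which(panel$chrom == ch)
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) {
      abort(paste0("panel SNPs on chromosome ", ch,
                   " fall outside every truth segment."))
    }
    j <- findInterval(panel$pos[sel], s$start)
    if (any(j < 1) || any(panel$pos[sel] >= s$end[pmax(j, 1)])) {
      abort(paste0("panel SNP outside every truth segment on ", ch, "."))
    }
    idx[sel] <- which(segs$chrom == ch)[j]
  }
  nA <- segs$nA[idx]
  nB <- segs$nB[idx]
  tot <- nA + nB
  p <- truth$purity
  psi <- truth$ploidy

  with_seed(seed, {
    if (is.null(genotypes)) {
      u <- runif(n)
      p_het <- 2 * maf * (1 - maf)
      p_aa <- maf^2
      genotypes <- ifelse(u < p_het, "het",
                          ifelse(u < p_het + p_aa, "hom_alt", "hom_ref"))
    } else if (length(genotypes) != n) {
      abort("`genotypes` must have one entry per panel SNP.")
    }
    rdepth <- function(mu) {
      if (overdispersion > 0) {
        stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
      } else {
        rpois(n, mu)
      }
    }
    n_depth <- rdepth(rep(mean_depth, n))
    n_alt <- integer(n)
    het <- genotypes == "het"
    n_alt[het] <- rbinom(sum(het), n_depth[het], 0.5)
    n_alt[genotypes == "hom_alt"] <- n_depth[genotypes == "hom_alt"]

    rel_depth <- (p * tot + 2 * (1 - p)) / (p * psi + 2 * (1 - p))
    t_depth <- rdepth(mean_depth * rel_depth)
    baf <- rep(0, n)
    b_het <- (p * nB[het] + (1 - p)) / (p * tot[het] + 2 * (1 - p))
    flip <- runif(sum(het)) < 0.5
    baf[het] <- ifelse(flip, 1 - b_het, b_het)
    baf[genotypes == "hom_alt"] <- 1
    t_alt <- rbinom(n, t_depth, baf)

    obs <- tibble(
      chrom = panel$chrom, pos = panel$pos,
      n_ref = n_depth - n_alt, n_alt = n_alt,
      t_ref = t_depth - t_alt, t_alt = t_alt,
      normal_gt = genotypes
    )
    structure(arrange(obs, .data$chrom, .data$pos),
              class = c("site_obs", class(obs)))
  })
}

check_same_sites <- function(a, b) {
  a <- arrange(as_tibble(a), .data$chrom, .data$pos)
  b <- arrange(as_tibble(b), .data$chrom, .data$pos)
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) || !all(a$pos == b$pos)) {
    abort("site mismatch: the two observation sets cover different SNPs.")
  }
  list(a = a, b = b)
}

#' Dilute tumor reads with normal reads (in-silico purity mixing)
#'
#' Emulates a lower-purity specimen by count-level mixing: each tumor read
#' is kept with probability `fraction` and each read of the diluent's tumor
#' channel with probability `1 - fraction`, and the two thinned counts are
#' summed (ref and alt separately). `fraction = 1` returns the tumor counts
#' unchanged; `fraction = 0` returns the diluent counts.
#'
#' @param tumor_obs,normal_obs Observation tibbles over the same site set;
#'   `normal_obs` is typically a simulated pure-normal sample sharing the
#'   germline genotypes.
#' @param fraction Mixing weight of the tumor sample, in \[0, 1\].
#' @param seed Integer seed or `NULL`.
#' @return An observation tibble; the germline (normal-channel) counts are
#'   taken from `tumor_obs`.
#' @export
mix_purity <- function(tumor_obs, normal_obs, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  z <- check_same_sites(tumor_obs, normal_obs)
  t <- z$a; d <- z$b
  with_seed(seed, {
    n <- nrow(t)
    out <- mutate(
      t,
      t_ref = rbinom(n, t$t_ref, fraction) + rbinom(n, d$t_ref, 1 - fraction),
      t_alt = rbinom(n, t$t_alt, fraction) + rbinom(n, d$t_alt, 1 - fraction)
    )
    structure(out, class = class(t))
  })
}

#' Binomial depth downsampling
#'
#' Keeps every read independently with the given probability (ref and alt,
#' tumor and normal counts thinned separately), emulating lower sequencing
#' depth. Thinning preserves allele-fraction expectations and never
#' increases a count; `fraction = 1` is the identity.
#'
#' @param obs An observation tibble.
#' @param fraction Retention probability in (0, 1].
#' @param seed Integer seed or `NULL`.
#' @return The thinned observation tibble.
#' @export
downsample_depth <- function(obs, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  if (fraction == 1) return(obs)
  with_seed(seed, {
    n <- nrow(obs)
    mutate(obs,
           n_ref = rbinom(n, .data$n_ref, fraction),
           n_alt = rbinom(n, .data$n_alt, fraction),
           t_ref = rbinom(n, .data$t_ref, fraction),
           t_alt = rbinom(n, .data$t_alt, fraction))
  })
}

#' Synthetic candidate SNP table for panel-design studies
#'
#' Generates a population-variant-style candidate table over a genome:
#' uniformly placed positions with per-population minor allele frequencies,
#' Hardy-Weinberg genotype counts (with controllable fractions of low-MAF
#' and HWE-violating sites) and probe GC values. Used to exercise the panel
#' design rules without any external download.
#'
#' @param genome A [genome_build()].
#' @param n Number of candidate SNPs.
#' @param populations Population names. Default the [design_config()] four.
#' @param n_genotyped Individuals genotyped per population. Default 500.
#' @param frac_low_maf Fraction of sites given a sub-1% MAF in one
#'   population. Default 0.1.
#' @param frac_hwe_bad Fraction of sites given strongly non-HWE genotype
#'   counts in one population. Default 0.05.
#' @param seed Integer seed or `NULL`.
#' @return A candidate tibble suitable for [apply_site_filters()].
#' @export
simulate_candidates <- function(genome, n,
                                populations = c("EAS", "EUR", "AFR", "AMR"),
                                n_genotyped = 500,
                                frac_low_maf = 0.1, frac_hwe_bad = 0.05,
                                seed = NULL) {
  with_seed(seed, {
    lens <- genome$length
    ch <- sample(genome$chrom, n, replace = TRUE, prob = lens / sum(lens))
    pos <- floor(runif(n) * lens[match(ch, genome$chrom)])
    cand <- tibble(chrom = ch, pos = pos,
                   ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   gc = runif(n, 0.2, 0.8))
    low <- runif(n) < frac_low_maf
    low_pop <- sample(seq_along(populations), n, replace = TRUE)
    bad <- runif(n) < frac_hwe_bad
    bad_pop <- sample(seq_along(populations), n, replace = TRUE)
    for (k in seq_along(populations)) {
      maf <- runif(n, 0.05, 0.5)
      maf[low & low_pop == k] <- runif(sum(low & low_pop == k), 0.0005, 0.009)
      p_rr <- (1 - maf)^2; p_ra <- 2 * maf * (1 - maf)
      g <- t(vapply(seq_len(n), function(i) {
        as.vector(stats::rmultinom(1, n_genotyped,
                                   c(p_rr[i], p_ra[i], 1 - p_rr[i] - p_ra[i])))
      }, numeric(3)))
      # distort selected sites: push all heterozygotes into homozygotes
      distort <- bad & bad_pop == k & maf > 0.05
      g[distort, 1] <- g[distort, 1] + ceiling(g[distort, 2] / 2)
      g[distort, 3] <- g[distort, 3] + floor(g[distort, 2] / 2)
      g[distort, 2] <- 0
      cand[[paste0("maf_", populations[k])]] <- maf
      cand[[paste0("n_rr_", populations[k])]] <- g[, 1]
      cand[[paste0("n_ra_", populations[k])]] <- g[, 2]
      cand[[paste0("n_aa_", populations[k])]] <- g[, 3]
    }
    cand <- distinct(cand, .data$chrom, .data$pos, .keep_all = TRUE)
    arrange(cand, .data$chrom, .data$pos)
  })
}

#' Simulate a cohort of tumors with varied scar burden
#'
#' Draws a target HRD burden per tumor and splits it into LOH/TAI/LST
#' events, then builds each truth profile with [simulate_truth_profile()].
#' The draw is stratified: about a quarter of the cohort comes from the
#' top quarter of `hrd_range` and a quarter from the bottom quarter, the
#' rest from the full range. With the default range the upper stratum lies
#' above the clinical cutoff of 42, so every cohort contains both HRD-
#' positive and HRD-negative tumors — the panel-concordance and ROC
#' experiments need both classes present regardless of seed.
#'
#' @param genome A [genome_build()].
#' @param n Number of tumors.
#' @param purity_range Per-tumor purity range. Default `c(0.4, 1)`.
#' @param hrd_range Range of total planted event counts per tumor.
#'   Default `c(4, 56)`.
#' @param n_decoy Decoy segments per tumor. Default 3.
#' @param seed Integer seed or `NULL`.
#' @return List of `truth_profile` objects.
#' @export
simulate_cohort <- function(genome, n, purity_range = c(0.4, 1),
                            hrd_range = c(4, 56), n_decoy = 3,
                            seed = NULL) {
  lo <- hrd_range[1]; hi <- hrd_range[2]
  q1 <- lo + floor((hi - lo) / 4)
  q3 <- lo + ceiling(3 * (hi - lo) / 4)
  draws <- with_seed(seed, {
    n_high <- if (n >= 2) max(1L, n %/% 4L) else 0L
    n_low <- n_high
    target <- c(
      if (n_high > 0) sample(q3:hi, n_high, replace = TRUE),
      if (n_low > 0) sample(lo:q1, n_low, replace = TRUE),
      sample(lo:hi, n - n_high - n_low, replace = TRUE)
    )
    target <- sample(target)          # shuffle stratum order
    split <- t(vapply(target, function(tt) {
      as.vector(stats::rmultinom(1, tt, c(0.3, 0.4, 0.3)))
    }, numeric(3)))
    # telomeric events are capped by available chromosome ends
    cap <- max(2L, 2L * nrow(genome) - 4L)
    excess <- pmax(split[, 2] - cap, 0)
    split[, 2] <- split[, 2] - excess
    split[, 1] <- split[, 1] + excess
    tibble(
      purity = runif(n, purity_range[1], purity_range[2]),
      n_loh = split[, 1], n_tai = split[, 2], n_lst = split[, 3]
    )
  })
  lapply(seq_len(n), function(i) {
    simulate_truth_profile(
      genome,
      event_spec(n_loh = draws$n_loh[i], n_tai = draws$n_tai[i],
                 n_lst = draws$n_lst[i], n_decoy = n_decoy),
      purity = draws$purity[i],
      seed = child_seed(seed, 100 + i)
    )
  })
}

#' @export
print.truth_profile <- function(x, ...) {
  cat("<truth_profile> purity ", x$purity, ", ploidy ",
      round(x$ploidy, 3), ", ", nrow(x$segments), " segments; planted ",
      "LOH=", x$ledger$loh, " TAI=", x$ledger$tai, " LST=", x$ledger$lst,
      "\n", sep = "")
  invisible(x)
}
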