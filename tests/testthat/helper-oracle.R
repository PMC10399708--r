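# Independent brute-force reference implementations, written as plain loops
# over data frames. These deliberately share no code with the package: they
# are the oracles the fast implementations are checked against.

oracle_merge_equal <- function(d) {
  d <- d[order(d$start), , drop = FALSE]
  i <- 1
  while (i < nrow(d)) {
    if (d$nA[i] == d$nA[i + 1] && d$nB[i] == d$nB[i + 1]) {
      d$end[i] <- d$end[i + 1]
      d <- d[-(i + 1), , drop = FALSE]
    } else {
      i <- i + 1
    }
  }
  d
}

oracle_smooth_chrom <- function(d, min_size = 3e6) {
  repeat {
    d <- oracle_merge_equal(d)
    lens <- d$end - d$start
    if (!any(lens < min_size)) break
    k <- which(lens == min(lens[lens < min_size]) & lens < min_size)[1]
    n <- nrow(d)
    if (n == 1) {
      d <- d[0, , drop = FALSE]
      next
    }
    if (k > 1 && k < n && d$nA[k - 1] == d$nA[k + 1] &&
        d$nB[k - 1] == d$nB[k + 1]) {
      d$end[k - 1] <- d$end[k + 1]
      d <- d[-c(k, k + 1), , drop = FALSE]
    } else if (k > 1 && k < n) {
      mid <- floor((d$start[k] + d$end[k]) / 2)
      d$end[k - 1] <- mid
      d$start[k + 1] <- mid
      d <- d[-k, , drop = FALSE]
    } else if (k == 1) {
      d$start[2] <- d$start[1]
      d <- d[-1, , drop = FALSE]
    } else {
      d$end[n - 1] <- d$end[n]
      d <- d[-n, , drop = FALSE]
    }
  }
  d
}

oracle_smooth <- function(segs, min_size = 3e6) {
  out <- NULL
  for (ch in unique(segs$chrom)) {
    d <- segs[segs$chrom == ch, , drop = FALSE]
    out <- rbind(out, oracle_smooth_chrom(as.data.frame(d), min_size))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_loh <- function(prof, genome) {
  count <- 0
  for (ch in unique(prof$chrom)) {
    d <- prof[prof$chrom == ch, , drop = FALSE]
    lo <- min(d$start); hi <- max(d$end)
    for (i in seq_len(nrow(d))) {
      if (d$nB[i] == 0 && d$nA[i] >= 1 &&
          (d$end[i] - d$start[i]) > 15e6 &&
          !(d$start[i] == lo && d$end[i] == hi)) {
        count <- count + 1
      }
    }
  }
  count
}

oracle_tai <- function(prof, genome) {
  count <- 0
  for (ch in unique(prof$chrom)) {
    d <- prof[prof$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gi <- which(genome$chrom == ch)
    lo <- min(d$start); hi <- max(d$end)
    i <- 1
    while (i <= nrow(d)) {
      if (d$nA[i] != d$nB[i]) {
        j <- i
        while (j < nrow(d) && d$nA[j + 1] != d$nB[j + 1] &&
               d$start[j + 1] == d$end[j]) {
          j <- j + 1
        }
        rs <- d$start[i]; re <- d$end[j]
        touches <- (rs == lo) || (re == hi)
        overlaps_cen <- rs < genome$cen_end[gi] && re > genome$cen_start[gi]
        if (touches && !overlaps_cen) count <- count + 1
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  count
}

oracle_lst <- function(prof, genome) {
  count <- 0
  for (ch in unique(prof$chrom)) {
    d <- prof[prof$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gi <- which(genome$chrom == ch)
    if (nrow(d) < 2) next
    for (i in 1:(nrow(d) - 1)) {
      same <- d$nA[i] == d$nA[i + 1] && d$nB[i] == d$nB[i + 1]
      adjacent <- d$end[i] == d$start[i + 1]
      big <- (d$end[i] - d$start[i]) >= 11e6 &&
        (d$end[i + 1] - d$start[i + 1]) >= 11e6
      at_cen <- d$end[i] >= genome$cen_start[gi] &&
        d$end[i] <= genome$cen_end[gi]
      if (adjacent && !same && big && !at_cen) count <- count + 1
    }
  }
  count
}

oracle_scores <- function(segs, genome) {
  prof <- oracle_smooth(as.data.frame(segs))
  list(loh = oracle_loh(prof, genome),
       tai = oracle_tai(prof, genome),
       lst = oracle_lst(prof, genome))
}

# Random raw profile over a genome: contiguous segments covering each
# chromosome, lengths spanning the 3/11/15-Mb decision thresholds.
random_profile <- function(genome, max_segs = 20) {
  n_chrom <- sample(seq_len(nrow(genome)), 1)
  chroms <- sample(genome$chrom, n_chrom)
  states <- rbind(c(1, 1), c(1, 0), c(2, 1), c(2, 2), c(2, 0),
                  c(3, 1), c(0, 0), c(3, 2), c(4, 2))
  remaining <- max_segs
  out <- NULL
  for (ch in chroms) {
    len <- genome$length[genome$chrom == ch]
    k <- sample(seq_len(max(1, min(remaining, 8))), 1)
    remaining <- remaining - k
    # mixture of tiny and large pieces
    raw <- stats::rexp(k) * sample(c(2e6, 12e6, 20e6), k, replace = TRUE)
    cuts <- c(0, round(cumsum(raw) / sum(raw) * len))
    cuts[k + 1] <- len
    cuts <- unique(cuts)
    kk <- length(cuts) - 1
    if (kk < 1) next
    si <- sample(seq_len(nrow(states)), kk, replace = TRUE)
    out <- rbind(out, data.frame(
      chrom = ch, start = cuts[-(kk + 1)], end = cuts[-1],
      nA = states[si, 1], nB = states[si, 2]
    ))
    if (remaining <= 0) break
  }
  out
}

# Monte-Carlo permutation oracle for the exact Hardy-Weinberg test: shuffle
# the alleles into random genotype pairs and compare heterozygote-count
# probabilities empirically.
oracle_hwe_mc <- function(n_rr, n_ra, n_aa, reps = 20000) {
  n <- n_rr + n_ra + n_aa
  n_alt <- 2 * n_aa + n_ra
  alleles <- c(rep(1, n_alt), rep(0, 2 * n - n_alt))
  hets <- replicate(reps, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  tab <- table(hets) / reps
  p_obs <- tab[as.character(n_ra)]
  if (is.na(p_obs)) p_obs <- 0
  sum(tab[tab <= p_obs * (1 + 1e-9)])
}

# All-pairs AUC oracle with half-credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force panel design: rules applied literally, one candidate at a
# time, then per-window max-EAS selection.
oracle_design <- function(cand, exons, config, genome) {
  keep <- rep(TRUE, nrow(cand))
  reason <- rep(NA_character_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    gcv <- if ("gc" %in% names(cand)) cand$gc[i] else NA
    if (!is.na(gcv) && (gcv < config$gc_bounds[1] ||
                        gcv > config$gc_bounds[2])) {
      keep[i] <- FALSE; reason[i] <- "gc"
    }
    for (pop in config$populations) {
      pv <- hwe_exact_test(cand[[paste0("n_rr_", pop)]][i],
                           cand[[paste0("n_ra_", pop)]][i],
                           cand[[paste0("n_aa_", pop)]][i])
      if (pv < config$hwe_p) { keep[i] <- FALSE; reason[i] <- "hwe" }
    }
    if (!is.null(exons) && nrow(exons) > 0) {
      dmin <- Inf
      for (j in seq_len(nrow(exons))) {
        if (exons$chrom[j] != cand$chrom[i]) next
        p <- cand$pos[i]
        d <- if (p >= exons$start[j] && p < exons$end[j]) 0
          else if (p < exons$start[j]) exons$start[j] - p
          else p - (exons$end[j] - 1)
        dmin <- min(dmin, d)
      }
      if (dmin < config$exon_distance) {
        keep[i] <- FALSE; reason[i] <- "exon_distance"
      }
    }
    for (pop in config$populations) {
      if (cand[[paste0("maf_", pop)]][i] <= config$min_maf) {
        keep[i] <- FALSE; reason[i] <- "maf"
      }
    }
  }
  surv <- cand[keep, , drop = FALSE]
  rank_col <- paste0("maf_", config$rank_population)
  sel <- NULL
  for (ch in genome$chrom) {
    len <- genome$length[genome$chrom == ch]
    nw <- ceiling(len / config$spacing)
    for (wi in seq_len(nw)) {
      w0 <- (wi - 1) * config$spacing
      inw <- surv[surv$chrom == ch & surv$pos >= w0 &
                    surv$pos < w0 + config$spacing, , drop = FALSE]
      if (nrow(inw) == 0) next
      best <- inw[order(-inw[[rank_col]], inw$pos), , drop = FALSE][1, ]
      sel <- rbind(sel, as.data.frame(best))
    }
  }
  list(keep = keep, reason = reason, panel = sel)
}

# NOTE on oracle_design reason labels: the loops above overwrite the reason
# in reverse priority order so the final label matches "first failing rule".
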