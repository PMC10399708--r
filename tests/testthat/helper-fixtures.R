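# Shared fixtures: small genomes and simulation shortcuts used across the
# test files. Everything is generated in code; no binary fixtures.

toy <- toy_genome()

# one ~100-Mb chromosome for micro tests
mini_genome <- genome_build(
  data.frame(chrom = "chr1", length = 100e6,
             cen_start = 45e6, cen_end = 48e6),
  build = "mini"
)

# GRCh37 subsets used by the simulation-heavy tests
grch37_sub <- function(rows) {
  g <- grch37_genome(autosomes_only = TRUE)
  genome_build(as.data.frame(g)[rows, ], build = "GRCh37-subset")
}

# candidate tibble builder: one row per SNP with identical population
# genotype counts drawn from HWE at the given MAF unless overridden
make_candidates <- function(chrom, pos, mafs, n = 200, gc = 0.5,
                            pops = c("EAS", "EUR", "AFR", "AMR"),
                            gt_override = NULL) {
  k <- length(pos)
  cand <- tibble::tibble(chrom = chrom, pos = pos,
                         ref = "A", alt = "C", gc = gc)
  for (pi in seq_along(pops)) {
    maf <- if (is.matrix(mafs)) mafs[, pi] else mafs
    n_aa <- round(n * maf^2)
    n_ra <- round(n * 2 * maf * (1 - maf))
    g <- cbind(n - n_ra - n_aa, n_ra, n_aa)
    if (!is.null(gt_override) && !is.null(gt_override[[pops[pi]]])) {
      g <- matrix(rep(gt_override[[pops[pi]]], k), k, 3, byrow = TRUE)
    }
    cand[[paste0("maf_", pops[pi])]] <- maf
    cand[[paste0("n_rr_", pops[pi])]] <- g[, 1]
    cand[[paste0("n_ra_", pops[pi])]] <- g[, 2]
    cand[[paste0("n_aa_", pops[pi])]] <- g[, 3]
  }
  cand
}

# segments tibble shorthand
seg_tbl <- function(chrom, start, end, nA, nB) {
  tibble::tibble(chrom = chrom, start = start, end = end, nA = nA, nB = nB)
}

# forward-model noiseless segment means for a given truth
model_segments <- function(states, lengths, purity, ploidy,
                           n_sites = 200, chrom = "chr1") {
  starts <- c(0, cumsum(lengths)[-length(lengths)])
  tibble::tibble(
    chrom = chrom, start = starts, end = starts + lengths,
    n_sites = n_sites, n_baf = round(n_sites * 0.4),
    logR = log2(expected_depth_ratio(purity, ploidy,
                                     states[, 1], states[, 2])),
    baf = expected_baf(purity, states[, 1], states[, 2])
  )
}
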