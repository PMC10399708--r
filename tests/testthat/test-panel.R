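cfg <- design_config()

test_that("site filters implement the selection rules with labelled reasons", {
  exons <- tibble::tibble(chrom = "chr1", start = 10000, end = 10500)
  cand <- make_candidates(
    chrom = "chr1",
    pos = c(
      5000,    # clean: passes everything
      20000,   # low MAF in one population
      10650,   # 150 bp from exon end -> rejected
      10700,   # exactly 200 bp from exon end (pos - (end-1) = 201) -> passes
      30000,   # HWE violation in one population
      40000    # GC out of bounds
    ),
    mafs = 0.25
  )
  cand$maf_EUR[2] <- 0.005
  cand$n_rr_AFR[5] <- 90; cand$n_ra_AFR[5] <- 0; cand$n_aa_AFR[5] <- 10
  cand$gc[6] <- 0.9
  res <- apply_site_filters(cand, exons, cfg)
  res <- res[order(res$pos), ]
  expect_equal(res$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$reason[res$pos == 20000], "maf")
  expect_equal(res$reason[res$pos == 10650], "exon_distance")
  expect_equal(res$reason[res$pos == 30000], "hwe")
  expect_equal(res$reason[res$pos == 40000], "gc")
  # distance exactly at the threshold passes: exon [10000,10500), SNP 10699
  d200 <- make_candidates("chr1", 10699, 0.25)
  expect_true(apply_site_filters(d200, exons, cfg)$pass)
  # 199 bp fails
  d199 <- make_candidates("chr1", 10698, 0.25)
  expect_false(apply_site_filters(d199, exons, cfg)$pass)
})

test_that("a SNP inside an exon is rejected at distance zero", {
  exons <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  cand <- make_candidates("chr1", 1500, 0.3)
  res <- apply_site_filters(cand, exons, cfg)
  expect_false(res$pass)
  expect_equal(res$reason, "exon_distance")
})

test_that("missing population values raise named errors", {
  cand <- make_candidates("chr1", 100, 0.3)
  cand$maf_EAS <- NA_real_
  expect_error(apply_site_filters(cand, NULL, cfg), "maf_EAS")
  cand2 <- make_candidates("chr1", 100, 0.3)
  cand2$maf_EUR <- NULL
  expect_error(apply_site_filters(cand2, NULL, cfg), "maf_EUR")
})

test_that("filtering is order-independent and monotone in thresholds", {
  set.seed(42)
  cand <- simulate_candidates(mini_genome, 300, seed = 5)
  exons <- tibble::tibble(chrom = "chr1",
                          start = seq(1e6, 90e6, by = 5e6),
                          end = seq(1e6, 90e6, by = 5e6) + 2000)
  base <- apply_site_filters(cand, exons, cfg)
  shuffled <- cand[sample.int(nrow(cand)), ]
  again <- apply_site_filters(shuffled, exons, cfg)
  expect_equal(base$pos[base$pass], again$pos[again$pass])
  expect_equal(base$reason, again$reason)

  tighter_maf <- design_config(min_maf = 0.10)
  tighter_exon <- design_config(exon_distance = 2000)
  expect_lte(sum(apply_site_filters(cand, exons, tighter_maf)$pass),
             sum(base$pass))
  expect_lte(sum(apply_site_filters(cand, exons, tighter_exon)$pass),
             sum(base$pass))
})

test_that("select_spaced keeps the top ranking-population SNP per window", {
  # three SNPs inside one 50-kb window: the 0.4-EAS one wins
  cand <- make_candidates("chr1", c(1000, 20000, 40000),
                          mafs = cbind(c(0.1, 0.4, 0.3),
                                       c(0.2, 0.2, 0.2),
                                       c(0.2, 0.2, 0.2),
                                       c(0.2, 0.2, 0.2)))
  panel <- select_spaced(cand, mini_genome, cfg)
  expect_equal(nrow(panel), 1)
  expect_equal(panel$pos, 20000)
  expect_equal(attr(panel, "qc")$n_gaps,
               sum(ceiling(mini_genome$length / 50000)) - 1)

  # ties in the ranking MAF break towards the smaller position
  tie <- make_candidates("chr1", c(10000, 30000), mafs = 0.3)
  expect_equal(select_spaced(tie, mini_genome, cfg)$pos, 10000)

  # one candidate per window -> all selected, ~50 kb apart
  three <- make_candidates("chr1", c(25000, 75000, 125000), mafs = 0.3)
  p3 <- select_spaced(three, mini_genome, cfg)
  expect_equal(nrow(p3), 3)
  expect_equal(diff(p3$pos), c(50000, 50000))

  # empty input: empty panel, all windows are gaps
  p0 <- select_spaced(make_candidates("chr1", numeric(0), numeric(0)),
                      mini_genome, cfg)
  expect_equal(nrow(p0), 0)
  expect_equal(attr(p0, "qc")$n_gaps, attr(p0, "qc")$n_windows)
})

test_that("select_spaced never takes a filtered-out SNP and spacing holds", {
  cand <- simulate_candidates(mini_genome, 2000, seed = 9)
  flt <- apply_site_filters(cand, NULL, cfg)
  panel <- select_spaced(flt, mini_genome, cfg)
  expect_true(all(panel$pos %in% flt$pos[flt$pass]))
  # at most one SNP per 50-kb window, positions unique
  expect_true(all(table(floor(panel$pos / 50000)) <= 1))
  expect_false(any(duplicated(panel$pos)))
})

test_that("subset_panel thins per chromosome with ceiling counts", {
  panel <- uniform_panel(toy, spacing = 50000, seed = 1)
  expect_identical(as.data.frame(subset_panel(panel, 1)),
                   as.data.frame(panel))
  half <- subset_panel(panel, 2)
  per_chrom <- table(panel$chrom)
  expect_equal(as.integer(table(half$chrom)),
               as.integer(ceiling(per_chrom / 2)))
  expect_equal(median(diff(half$pos[half$chrom == "chrA"])),
               2 * median(diff(panel$pos[panel$chrom == "chrA"])))

  # a 52592-SNP synthetic panel thinned 6-fold: counts must equal the
  # per-chromosome ceiling sum computed by brute-force index enumeration
  g <- grch37_genome()
  set.seed(13)
  big <- tibble::tibble(
    chrom = sample(g$chrom, 52592, replace = TRUE,
                   prob = g$length / sum(g$length)),
    pos = sample.int(5e7, 52592, replace = TRUE),
    maf = 0.3
  ) |> dplyr::distinct(chrom, pos, .keep_all = TRUE) |>
    dplyr::arrange(chrom, pos)
  sub6 <- subset_panel(big, 6)
  brute <- sum(vapply(split(big$pos, big$chrom),
                      function(x) length(seq(1, length(x), by = 6)),
                      numeric(1)))
  expect_equal(nrow(sub6), brute)
  expect_equal(brute, sum(ceiling(table(big$chrom) / 6)))
  expect_error(subset_panel(panel, 0), "keep_every")
})

test_that("panel_qc reports direct-count summaries", {
  p <- new_panel_for_test <- tibble::tibble(
    chrom = "chrA", pos = c(0, 50000, 100000), maf = 0.3
  )
  qc <- panel_qc(p, toy)
  expect_equal(qc$distances, c(50000, 50000))
  expect_equal(qc$summary$n_snps, 3)
  qc0 <- panel_qc(p[0, ], toy)
  expect_equal(qc0$summary$n_snps, 0)
  expect_length(qc0$distances, 0)

  # dense candidates: every window occupied, so no distance can exceed
  # twice the spacing, and most sit near the 50-kb target
  dense <- select_spaced(simulate_candidates(mini_genome, 30000, seed = 2),
                         mini_genome, cfg)
  expect_equal(attr(dense, "qc")$n_gaps, 0)
  qcd <- panel_qc(dense, mini_genome)
  expect_true(all(qcd$distances <= 2 * 50000))
  expect_gte(mean(qcd$distances >= 25000 & qcd$distances <= 100000), 0.8)
})

test_that("filters plus selection match the brute-force oracle", {
  cand <- simulate_candidates(mini_genome, 400, seed = 31)
  exons <- tibble::tibble(chrom = "chr1",
                          start = seq(2e6, 98e6, by = 4e6),
                          end = seq(2e6, 98e6, by = 4e6) + 1500)
  flt <- apply_site_filters(cand, exons, cfg)
  panel <- select_spaced(flt, mini_genome, cfg)
  ora <- oracle_design(as.data.frame(cand), as.data.frame(exons), cfg,
                       mini_genome)
  cand_sorted <- cand[order(cand$chrom, cand$pos), ]
  ora_keep <- ora$keep[order(cand$chrom, cand$pos)]
  ora_reason <- ora$reason[order(cand$chrom, cand$pos)]
  expect_equal(flt$pass, ora_keep)
  expect_equal(flt$reason, ora_reason)
  expect_equal(panel$pos, sort(ora$panel$pos))
})
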