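gsim <- grch37_sub(1:6)

test_that("a zero-event profile is fully diploid and scores zero", {
  tr <- simulate_truth_profile(gsim, event_spec(), purity = 1, seed = 1)
  expect_true(all(tr$segments$nA == 1 & tr$segments$nB == 1))
  expect_equal(tr$ploidy, 2)
  sc <- score_hrd(tr, gsim)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(0, 0, 0))
})

test_that("truth profiles are deterministic under a seed and tile genomes", {
  spec <- event_spec(n_loh = 3, n_tai = 4, n_lst = 3, n_decoy = 2)
  a <- simulate_truth_profile(gsim, spec, purity = 0.7, seed = 99)
  b <- simulate_truth_profile(gsim, spec, purity = 0.7, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_truth_profile(gsim, spec, purity = 0.7, seed = 100)
  expect_false(identical(a$segments, c2$segments))

  # segments tile every chromosome: disjoint, sorted, full coverage
  for (ch in gsim$chrom) {
    d <- a$segments[a$segments$chrom == ch, ]
    expect_equal(d$start[1], 0)
    expect_equal(d$end[nrow(d)], gsim$length[gsim$chrom == ch])
    expect_true(all(d$start[-1] == d$end[-nrow(d)]))
  }
  # ploidy is the length-weighted mean copy number
  w <- a$segments$end - a$segments$start
  expect_equal(a$ploidy, sum(w * (a$segments$nA + a$segments$nB)) / sum(w))
})

test_that("scoring planted truth segments reproduces the ledger exactly", {
  set.seed(17)
  for (i in 1:15) {
    spec <- event_spec(n_loh = sample(0:4, 1), n_tai = sample(0:6, 1),
                       n_lst = sample(0:4, 1), n_decoy = sample(0:3, 1))
    tr <- simulate_truth_profile(gsim, spec, purity = 1,
                                 seed = 1000 + i)
    sc <- score_hrd(tr, gsim)
    expect_equal(sc$loh, tr$ledger$loh)
    expect_equal(sc$tai, tr$ledger$tai)
    expect_equal(sc$lst, tr$ledger$lst)
  }
})

test_that("an infeasible event spec errors naming the offending event", {
  tiny <- genome_build(data.frame(chrom = "c", length = 40e6,
                                  cen_start = 19e6, cen_end = 21e6))
  expect_error(
    simulate_truth_profile(tiny, event_spec(n_loh = 2), seed = 1),
    "LOH"
  )
})

test_that("observation counts follow the purity mixture model", {
  # p = 1, diploid (1,1): tumor BAF at het sites is centred on 1/2
  tr <- simulate_truth_profile(gsim, event_spec(), purity = 1, seed = 2)
  panel <- uniform_panel(gsim, spacing = 100000, maf_range = c(0.5, 0.5),
                         seed = 3)
  obs <- simulate_observations(tr, panel, 300, seed = 4)
  het <- obs$normal_gt == "het"
  expect_gt(sum(het), 5000)
  vaf <- obs$t_alt[het] / (obs$t_alt + obs$t_ref)[het]
  se <- sqrt(0.25 / 300 / sum(het))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)
  # mean depths near nominal (relative depth is 1 everywhere)
  expect_lt(abs(mean(obs$t_ref + obs$t_alt) - 300), 1)
  expect_lt(abs(mean(obs$n_ref + obs$n_alt) - 300), 1)

  # p = 0.5, a (1,0) segment: expected BAF is 1/3 (or 2/3 when flipped)
  tr5 <- tr
  tr5$purity <- 0.5
  tr5$segments$nB[1] <- 0   # first segment becomes (1,0)
  tr5$ploidy <- with(tr5$segments, sum((nA + nB) * (end - start)) /
                       sum(end - start))
  seg1 <- tr5$segments[1, ]
  obs5 <- simulate_observations(tr5, panel, 3000, seed = 6)
  in1 <- obs5$chrom == seg1$chrom & obs5$pos < seg1$end &
    obs5$normal_gt == "het"
  vaf5 <- obs5$t_alt[in1] / (obs5$t_alt + obs5$t_ref)[in1]
  folded <- pmin(vaf5, 1 - vaf5)
  expect_gt(sum(in1), 100)
  expect_lt(abs(mean(folded) - 1/3), 0.01)
  # relative depth of the (1,0) segment under the mixture model
  rel <- expected_depth_ratio(0.5, tr5$ploidy, 1, 0)
  expect_lt(abs(mean(obs5$t_ref[in1] + obs5$t_alt[in1]) - 3000 * rel), 30)
})

test_that("simulate_observations enforces panel/truth coverage", {
  tr <- simulate_truth_profile(gsim, event_spec(), seed = 2)
  stray <- tibble::tibble(chrom = "chrZ", pos = 1e6, maf = 0.3)
  expect_error(simulate_observations(tr, stray, 100, seed = 1),
               "outside every truth segment")
  expect_error(simulate_observations(tr, uniform_panel(gsim, 1e6), 0),
               "mean_depth")
})

test_that("mix_purity returns pure inputs at the extremes", {
  tr <- simulate_truth_profile(gsim, event_spec(n_loh = 2), seed = 3)
  panel <- uniform_panel(gsim, spacing = 500000, seed = 4)
  gt <- rep(c("het", "hom_ref"), length.out = nrow(panel))
  a <- simulate_observations(tr, panel, 200, seed = 5, genotypes = gt)
  b <- simulate_observations(simulate_truth_profile(gsim, event_spec(),
                                                    seed = 1),
                             panel, 200, seed = 6, genotypes = gt)
  expect_equal(mix_purity(a, b, 1, seed = 7)$t_ref, a$t_ref)
  expect_equal(mix_purity(a, b, 0, seed = 7)$t_ref, b$t_ref)

  # expectation: mixing a VAF-0 site with a VAF-0.5 site at f = 0.5
  t0 <- a[1:2000, ]; t0$t_ref <- 100L; t0$t_alt <- 0L
  n0 <- b[1:2000, ]; n0$t_ref <- 50L; n0$t_alt <- 50L
  mx <- mix_purity(t0, n0, 0.5, seed = 8)
  vaf <- sum(mx$t_alt) / sum(mx$t_alt + mx$t_ref)
  expect_lt(abs(vaf - 0.25), 0.01)
  # reads conserved in expectation
  expect_lt(abs(mean(mx$t_ref + mx$t_alt) - 100), 2)

  expect_error(mix_purity(a[-1, ], b, 0.5), "site mismatch")
  expect_error(mix_purity(a, b, 1.2), "fraction")
})

test_that("downsample_depth thins binomially and never adds reads", {
  tr <- simulate_truth_profile(gsim, event_spec(), seed = 3)
  panel <- uniform_panel(gsim, spacing = 200000, seed = 4)
  obs <- simulate_observations(tr, panel, 300, seed = 5)
  expect_identical(downsample_depth(obs, 1), obs)
  half <- downsample_depth(obs, 0.5, seed = 6)
  expect_lt(abs(mean(half$t_ref + half$t_alt) - 150), 2)
  for (cc in c("n_ref", "n_alt", "t_ref", "t_alt")) {
    expect_true(all(half[[cc]] <= obs[[cc]]))
  }
  # thinning preserves the allele fraction: VAF-1/3 sites at depth 3000
  deep <- obs[1:3000, ]
  deep$t_ref <- 2000L; deep$t_alt <- 1000L
  thin <- downsample_depth(deep, 0.1, seed = 7)
  vaf <- sum(thin$t_alt) / sum(thin$t_ref + thin$t_alt)
  expect_lt(abs(vaf - 1/3), 3 * sqrt(1/3 * 2/3 / (3000 * 300)))
  expect_error(downsample_depth(obs, 0), "fraction")
  expect_error(downsample_depth(obs, 1.5), "fraction")
})

test_that("stochastic outputs are reproducible under a fixed seed", {
  tr <- simulate_truth_profile(gsim, event_spec(n_tai = 2), seed = 11)
  panel <- uniform_panel(gsim, spacing = 500000, seed = 12)
  o1 <- simulate_observations(tr, panel, 100, seed = 13)
  o2 <- simulate_observations(tr, panel, 100, seed = 13)
  expect_identical(o1, o2)
  expect_identical(downsample_depth(o1, 0.5, seed = 14),
                   downsample_depth(o1, 0.5, seed = 14))
  expect_identical(mix_purity(o1, o2, 0.3, seed = 15),
                   mix_purity(o1, o2, 0.3, seed = 15))
  # the RNG state of the caller is untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simulate_observations(tr, panel, 50, seed = 13))
  expect_equal(runif(1), x)
})

test_that("cohort simulation spans the cutoff with reproducible draws", {
  g <- grch37_genome(autosomes_only = TRUE)
  co <- simulate_cohort(g, 8, seed = 77)
  hrd <- vapply(co, function(tr) {
    tr$ledger$loh + tr$ledger$tai + tr$ledger$lst
  }, numeric(1))
  expect_true(any(hrd >= 42) && any(hrd < 42))
  co2 <- simulate_cohort(g, 8, seed = 77)
  expect_identical(lapply(co, `[[`, "segments"),
                   lapply(co2, `[[`, "segments"))
})
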