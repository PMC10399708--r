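g150 <- genome_build(data.frame(chrom = "chr1", length = 150e6,
                                cen_start = 60e6, cen_end = 63e6))

test_that("normalize_profile merges equals and absorbs sub-3Mb segments", {
  # adjacent identical segments merge
  two <- seg_tbl("chr1", c(0, 30e6), c(30e6, 60e6), c(1, 1), c(1, 1))
  m <- normalize_profile(two)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 60e6))

  # a 2-Mb aberration between equal flanks vanishes entirely
  d <- seg_tbl("chr1", c(0, 30e6, 32e6), c(30e6, 32e6, 150e6),
               c(1, 3, 1), c(1, 1, 1))
  m2 <- normalize_profile(d)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$nA, m2$nB), c(1, 1))
  expect_equal(c(m2$start, m2$end), c(0, 150e6))

  # unequal flanks split the removed interval at its midpoint
  d3 <- seg_tbl("chr1", c(0, 30e6, 32e6), c(30e6, 32e6, 150e6),
                c(1, 3, 2), c(1, 1, 1))
  m3 <- normalize_profile(d3)
  expect_equal(nrow(m3), 2)
  expect_equal(m3$end[1], 31e6)
  expect_equal(m3$start[2], 31e6)

  # empty input passes through
  expect_equal(nrow(normalize_profile(two[0, ])), 0)
  # overlap rejected
  bad <- seg_tbl("chr1", c(0, 20e6), c(30e6, 60e6), 1, 1)
  expect_error(normalize_profile(bad), "overlap")
})

test_that("HRD-LOH counts >15Mb LOH segments short of a whole chromosome", {
  base <- seg_tbl("chr1", c(0, 40e6, 60e6), c(40e6, 60e6, 150e6),
                  c(1, 1, 1), c(0, 1, 1))
  expect_equal(count_hrd_loh(base, g150), 1)

  whole <- seg_tbl("chr1", 0, 150e6, 1, 0)
  expect_equal(count_hrd_loh(whole, g150), 0)

  sizes <- seg_tbl("chr1",
                   c(0, 14e6, 30e6, 60e6),
                   c(14e6, 30e6, 60e6, 150e6),
                   c(1, 2, 1, 1), c(0, 0, 1, 1))
  expect_equal(count_hrd_loh(sizes, g150), 1)   # only the 16-Mb (2,0)
  plus18 <- seg_tbl("chr1",
                    c(0, 14e6, 30e6, 60e6, 63e6, 81e6),
                    c(14e6, 30e6, 60e6, 63e6, 81e6, 150e6),
                    c(1, 2, 1, 1, 1, 1), c(0, 0, 1, 1, 0, 1))
  expect_equal(count_hrd_loh(plus18, g150), 2)

  # homozygous deletions are not LOH
  homdel <- seg_tbl("chr1", c(0, 20e6), c(20e6, 150e6), c(0, 1), c(0, 1))
  expect_equal(count_hrd_loh(homdel, g150), 0)
})

test_that("TAI counts telomere-touching imbalanced runs off the centromere", {
  p_tel <- seg_tbl("chr1", c(0, 30e6), c(30e6, 150e6), c(2, 1), c(1, 1))
  expect_equal(count_tai(p_tel, g150), 1)

  across_cen <- seg_tbl("chr1", c(0, 50e6, 70e6), c(50e6, 70e6, 150e6),
                        c(1, 2, 1), c(1, 1, 1))
  expect_equal(count_tai(across_cen, g150), 0)

  interstitial <- seg_tbl("chr1", c(0, 30e6, 50e6), c(30e6, 50e6, 150e6),
                          c(1, 2, 1), c(1, 1, 1))
  expect_equal(count_tai(interstitial, g150), 0)

  # both telomeres imbalanced: two separate runs
  both <- seg_tbl("chr1", c(0, 20e6, 130e6), c(20e6, 130e6, 150e6),
                  c(2, 1, 3), c(1, 1, 1))
  expect_equal(count_tai(both, g150), 2)

  # a run is maximal: two adjacent imbalanced segments count once
  run2 <- seg_tbl("chr1", c(0, 10e6, 30e6), c(10e6, 30e6, 150e6),
                  c(2, 3, 1), c(1, 1, 1))
  expect_equal(count_tai(run2, g150), 1)

  # minimum size option
  expect_equal(count_tai(p_tel, g150, min_size = 40e6), 0)
})

test_that("LST counts breaks between adjacent >=11Mb differing segments", {
  one <- seg_tbl("chr1", c(0, 20e6), c(20e6, 50e6), c(1, 2), c(1, 1))
  expect_equal(count_lst(one, g150), 1)

  small <- seg_tbl("chr1", c(0, 10e6), c(10e6, 30e6), c(1, 2), c(1, 1))
  expect_equal(count_lst(small, g150), 0)

  # break exactly at the centromere does not count
  at_cen <- seg_tbl("chr1", c(0, 60e6), c(60e6, 150e6), c(1, 2), c(1, 1))
  expect_equal(count_lst(at_cen, g150), 0)
  just_off <- seg_tbl("chr1", c(0, 59e6), c(59e6, 150e6), c(1, 2), c(1, 1))
  expect_equal(count_lst(just_off, g150), 1)

  # 12-Mb (1,1) + 2-Mb (2,1) + 15-Mb (2,2): smoothing then one break
  sm <- seg_tbl("chr1", c(0, 12e6, 14e6), c(12e6, 14e6, 29e6),
                c(1, 2, 2), c(1, 1, 2))
  expect_equal(count_lst(normalize_profile(sm), g150), 1)
})

test_that("score_hrd sums components and applies the inclusive cutoff", {
  # telomeric (2,1) gives TAI; interstitial 20-Mb (1,0) gives LOH; a pair
  # of differing >=11-Mb segments gives one LST (their own break only,
  # flanked by sub-11Mb buffers)
  prof <- seg_tbl("chr1",
                  c(0, 8e6, 28e6, 48e6, 52e6, 64e6, 76e6, 80e6),
                  c(8e6, 28e6, 48e6, 52e6, 64e6, 76e6, 80e6, 150e6),
                  c(2, 1, 1, 3, 2, 2, 3, 1),
                  c(1, 1, 0, 1, 1, 2, 1, 1))
  # NB the (1,1)|(1,0) break also qualifies as an LST (both flanks >=11Mb)
  sc <- score_hrd(prof, g150, drop_sex = FALSE)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(1, 1, 2))
  expect_equal(sc$hrd, sc$loh + sc$tai + sc$lst)

  # inclusive cutoff: hrd == cutoff is positive
  expect_equal(sc$hrd, 4)
  expect_equal(score_hrd(prof, g150, cutoff = 4, drop_sex = FALSE)$status,
               "positive")
  expect_equal(score_hrd(prof, g150, cutoff = 5, drop_sex = FALSE)$status,
               "negative")

  # empty profile scores zero, negative
  sc0 <- score_hrd(seg_tbl(character(0), numeric(0), numeric(0),
                           numeric(0), numeric(0)), g150)
  expect_equal(c(sc0$loh, sc0$tai, sc0$lst, sc0$hrd), c(0, 0, 0, 0))
  expect_equal(sc0$status, "negative")
})

test_that("a fully diploid genome scores zero under any segmentation", {
  set.seed(5)
  for (i in 1:20) {
    segs <- NULL
    for (ch in toy$chrom) {
      len <- toy$length[toy$chrom == ch]
      cuts <- sort(unique(c(0, sample.int(len, sample(1:6, 1)), len)))
      segs <- rbind(segs, data.frame(chrom = ch, start = cuts[-length(cuts)],
                                     end = cuts[-1], nA = 1, nB = 1))
    }
    sc <- score_hrd(segs, toy)
    expect_equal(sc$hrd, 0)
  }
})

test_that("scores are invariant to splitting a segment into equal halves", {
  set.seed(21)
  for (i in 1:25) {
    prof <- random_profile(toy)
    base <- score_hrd(prof, toy, drop_sex = FALSE)
    k <- sample.int(nrow(prof), 1)
    row <- prof[k, ]
    mid <- floor((row$start + row$end) / 2)
    if (mid <= row$start || mid >= row$end) next
    split_prof <- rbind(
      prof[-k, ],
      data.frame(chrom = row$chrom, start = c(row$start, mid),
                 end = c(mid, row$end), nA = row$nA, nB = row$nB)
    )
    sc <- score_hrd(split_prof, toy, drop_sex = FALSE)
    expect_equal(c(sc$loh, sc$tai, sc$lst),
                 c(base$loh, base$tai, base$lst))
  }
})

test_that("scar counts match the brute-force oracle on random profiles", {
  set.seed(33)
  for (i in 1:400) {
    prof <- random_profile(toy)
    norm <- normalize_profile(prof)
    ora <- oracle_scores(prof, toy)
    expect_equal(count_hrd_loh(norm, toy, drop_sex = FALSE), ora$loh)
    expect_equal(count_tai(norm, toy, drop_sex = FALSE), ora$tai)
    expect_equal(count_lst(norm, toy, drop_sex = FALSE), ora$lst)
  }
})

test_that("sex chromosomes are excluded from scoring by default", {
  g <- grch37_genome()
  prof <- seg_tbl(c("chr1", "chr1", "chrX", "chrX"),
                  c(0, 40e6, 0, 40e6), c(40e6, 249250621, 40e6, 155270560),
                  c(1, 1, 1, 1), c(0, 1, 0, 1))
  expect_equal(score_hrd(prof, g)$loh, 1)
  expect_equal(score_hrd(prof, g, drop_sex = FALSE)$loh, 2)
})
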