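b100 <- genome_build("chr1", 100)

test_that("breakpoint union refines segmentations over the common span", {
  a <- quick_profile(b100, "chr1", 0, 100, 2, lab = "LabA")
  b <- quick_profile(b100, "chr1", 0, 100, 2, lab = "LabB")
  tr <- breakpoint_union(list(a, b))
  expect_equal(nrow(tr$intervals), 1)
  expect_equal(c(tr$intervals$start, tr$intervals$end), c(0, 100))

  a2 <- quick_profile(b100, "chr1", c(0, 50), c(50, 100), c(2, 3),
                      lab = "LabA")
  b2 <- quick_profile(b100, "chr1", c(0, 30), c(30, 100), c(2, 2),
                      lab = "LabB")
  tr2 <- breakpoint_union(list(a2, b2))
  expect_equal(tr2$intervals$start, c(0, 30, 50))
  expect_equal(tr2$intervals$end, c(30, 50, 100))
  expect_equal(tr2$cn[, "LabA"], c(2, 2, 3))
  expect_equal(tr2$cn[, "LabB"], c(2, 2, 2))
})

test_that("the track is confined to the intersection of covered spans", {
  b150 <- genome_build("chr1", 150)
  a <- quick_profile(b150, "chr1", 0, 100, 2, lab = "LabA")
  b <- quick_profile(b150, "chr1", 50, 150, 2, lab = "LabB")
  tr <- breakpoint_union(list(a, b))
  expect_equal(c(min(tr$intervals$start), max(tr$intervals$end)), c(50, 100))

  c_ <- quick_profile(b150, "chr1", 120, 150, 2, lab = "LabC")
  expect_error(breakpoint_union(list(a, c_)), "no covered span")
})

test_that("a designed 10% CN discordance yields exactly 90% agreement", {
  a <- quick_profile(b100, "chr1", 0, 100, 2, lab = "LabA")
  b <- quick_profile(b100, "chr1", 0, 100, 2, lab = "LabB")
  cc <- quick_profile(b100, "chr1", c(0, 10), c(10, 100), c(3, 2),
                      lab = "LabC")
  res <- gw_call_agreement(list(a, b, cc), "CN")
  expect_equal(res$percentage, 90)
  expect_equal(res$agreeing_bp, 90)
  expect_equal(res$denominator_bp, 100)
  expect_equal(gw_call_agreement(list(a, b, cc), "LOH")$percentage, 100)
  expect_equal(pairwise_agreement(a, cc, "CN")$percentage, 90)
  expect_equal(pairwise_agreement(a, b, "CN")$percentage, 100)
})

test_that("identical triplicates agree 100% on both channels", {
  p <- lapply(c("LabA", "LabB", "LabC"), function(l) {
    quick_profile(b100, "chr1", c(0, 40), c(40, 100), c(2, 4),
                  loh = c(FALSE, TRUE), lab = l)
  })
  expect_equal(gw_call_agreement(p, "CN")$percentage, 100)
  expect_equal(gw_call_agreement(p, "LOH")$percentage, 100)
})

test_that("interval sweep equals the per-base brute-force oracle exactly", {
  set.seed(99)
  build <- genome_build(c("chr1", "chr2"), c(1000, 800))
  for (i in 1:20) {
    trio <- random_trio(build)
    for (ch in c("CN", "LOH")) {
      fast <- gw_call_agreement(trio, ch)
      slow <- brute_force_agreement(trio, ch)
      expect_identical(fast$agreeing_bp, slow$agreeing_bp)
      expect_identical(fast$denominator_bp, slow$denominator_bp)
      expect_equal(fast$percentage, slow$percentage)
    }
  }
})

test_that("three-way agreement never exceeds any pairwise agreement", {
  set.seed(123)
  build <- genome_build("chr1", 2000)
  for (i in 1:10) {
    trio <- random_trio(build)
    ok <- tryCatch({
      three <- gw_call_agreement(trio, "CN")$percentage
      pairs <- c(pairwise_agreement(trio[[1]], trio[[2]], "CN")$percentage,
                 pairwise_agreement(trio[[1]], trio[[3]], "CN")$percentage,
                 pairwise_agreement(trio[[2]], trio[[3]], "CN")$percentage)
      expect_lte(three, min(pairs) + 1e-9)
      TRUE
    }, error = function(e) FALSE)  # a pair may share no span
    if (!ok) succeed()
  }
})

test_that("agreement is symmetric under replicate permutation and
           invariant under call-preserving refinement", {
  set.seed(77)
  build <- genome_build("chr1", 1000)
  trio <- random_trio(build)
  base <- gw_call_agreement(trio, "CN")$percentage
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(gw_call_agreement(trio[perm], "CN")$percentage, base)
  }
  # split every segment of profile 1 at an internal point
  seg <- trio[[1]]$segments
  split_seg <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    if (s$end - s$start < 2) return(s)
    mid <- floor((s$start + s$end) / 2)
    rbind(transform(s, end = mid), transform(s, start = mid))
  }))
  trio2 <- trio
  trio2[[1]] <- seg_profile(split_seg, build, sample = trio[[1]]$sample,
                            lab = trio[[1]]$lab)
  expect_equal(gw_call_agreement(trio2, "CN")$percentage, base)
})

test_that("sex chromosomes are excluded from the denominator by default", {
  build <- genome_build(c("chr1", "chrX"), c(100, 100))
  mk <- function(cnx, lab) {
    seg_profile(data.frame(chrom = c("chr1", "chrX"), start = 0,
                           end = 100, cn = c(2, cnx), loh = FALSE),
                build, "S1", lab)
  }
  trio <- list(mk(2, "LabA"), mk(2, "LabB"), mk(1, "LabC"))
  expect_equal(gw_call_agreement(trio, "CN")$percentage, 100)
  expect_equal(gw_call_agreement(trio, "CN",
                                 include_sex = TRUE)$percentage, 50)
})

test_that("categorical concordance follows the 0/33/66/100 conventions", {
  expect_equal(categorical_concordance(c(4, 4, 4),
                                       "ploidy_strict")$percentage, 100)
  expect_equal(categorical_concordance(c(4, 4, 2),
                                       "ploidy_strict")$percentage, 66)
  expect_equal(categorical_concordance(
    c("High", "High", "Lower"), "max_agreement")$percentage, 66)
  expect_equal(categorical_concordance(c(2, 3, 4),
                                       "ploidy_strict")$percentage, 0)
  expect_equal(categorical_concordance(c(2, 3, 4),
                                       "max_agreement")$percentage, 33)
  expect_error(categorical_concordance(c(2, NA, NA)), "at least two")
})

test_that("ACF concordance uses the homogeneous label and a tolerance", {
  expect_equal(acf_concordance(c("homogeneous", "homogeneous", "50"))
               $percentage, 66)
  expect_equal(acf_concordance(c(50, 50.5, 49.5))$percentage, 100)
  expect_equal(acf_concordance(c(50, 60, 70))$percentage, 33)
  expect_equal(acf_concordance(c(50, 52, 70), tol = 2)$percentage, 66)
})

mk_trip <- function(build, sample, ndsnpqc = rep(30, 3), ploidy = rep(2, 3),
                    acf = rep(70, 3), cn3 = 2) {
  runs <- lapply(1:3, function(j) {
    cn <- if (j == 3) cn3 else 2
    sample_run(quick_profile(build, "chr1", 0, build$length[1], cn,
                             sample = sample, lab = c("LabA", "LabB",
                                                      "LabC")[j]),
               qc = qc_metrics(0.2, ndsnpqc[j]),
               tuscan = tuscan_estimate(ploidy[j], acf[j]))
  })
  triplicate_set(runs)
}

test_that("cohort summary aggregates agreement and applies the QC filter", {
  build <- genome_build("chr1", 100)
  trips <- list(mk_trip(build, "S1"),
                mk_trip(build, "S2", ndsnpqc = c(30, 30, 20), ploidy =
                          c(4, 4, 4)))
  cs <- cohort_summary(trips)
  expect_equal(cs$cn_agreement, c(100, 100))
  expect_equal(cs$n_qc_pass, 1)
  # S2's ploidy (all 4s, would be 100) is excluded by its ndSNPQC 20 run,
  # so the ploidy mean comes from S1 alone
  expect_equal(cs$mean_ploidy_concordance, 100)
  expect_equal(cs$mean_acf_concordance, 100)

  one <- cohort_summary(list(mk_trip(build, "S1")))
  expect_equal(one$median_cn_agreement, 100)
  expect_equal(one$median_loh_agreement, 100)
})

test_that("lab subset comparison reproduces the Welch t-test construct", {
  expect_warning(res <- lab_subset_comparison(c(90, 90, 90), c(90, 90)),
                 "zero variance")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)

  res2 <- lab_subset_comparison(c(90, 91, 92), c(80, 81, 82))
  expect_lt(res2$p, 0.05)
  expect_equal(res2$difference, 10)
  expect_equal(res2$p,
               stats::t.test(c(90, 91, 92), c(80, 81, 82))$p.value)

  set.seed(55)
  p_null <- replicate(20, {
    x <- stats::rnorm(10, 90, 2)
    lab_subset_comparison(x[1:5], x[6:10])$p
  })
  expect_gt(min(p_null), 0.001)
})
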