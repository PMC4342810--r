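bMb <- genome_build("chr1", 100e6)

test_that("genome baseline is the length-weighted median of segment CN", {
  expect_equal(genome_baseline(quick_profile(bMb, "chr1", 0, 100e6, 2)), 2)
  p2 <- quick_profile(bMb, "chr1", c(0, 90e6), c(90e6, 100e6), c(2, 8))
  expect_equal(genome_baseline(p2), 2)
  p3 <- quick_profile(bMb, "chr1", c(0, 60e6), c(60e6, 100e6), c(3, 2))
  expect_equal(genome_baseline(p3), 3)
})

test_that("sex chromosomes are excluded from the baseline by default", {
  build <- genome_build(c("chr1", "chrX"), c(10e6, 10e6))
  p <- seg_profile(data.frame(chrom = c("chr1", "chrX"), start = 0,
                              end = 10e6, cn = c(2, 1), loh = FALSE),
                   build, "S1", "LabA")
  expect_equal(genome_baseline(p), 2)
  x_only <- seg_profile(data.frame(chrom = "chrX", start = 0, end = 10e6,
                                   cn = 1, loh = FALSE), build, "S1", "A")
  expect_error(genome_baseline(x_only), "autosomal")
})

genes <- data.frame(gene = c("CCND1", "MYC"), chrom = "chr1",
                    start = c(10e6, 50e6), end = c(10.1e6, 50.1e6))

test_that("focal amplifications are flagged on a strict ratio threshold", {
  p <- quick_profile(bMb, "chr1", c(0, 10e6, 10.05e6),
                     c(10e6, 10.05e6, 100e6), c(2, 5, 2))
  hfa <- detect_hfa(p, genes)
  ccnd1 <- hfa[hfa$gene == "CCND1", ]
  expect_equal(ccnd1$ratio, 2.5)
  expect_true(ccnd1$flagged)
  expect_false(hfa$flagged[hfa$gene == "MYC"])

  # ratio exactly at the threshold is NOT flagged
  p22 <- quick_profile(bMb, "chr1", c(0, 10e6, 10.05e6),
                       c(10e6, 10.05e6, 100e6), c(2, 4.4, 2))
  expect_false(detect_hfa(p22, genes)[1, "flagged"])
  expect_equal(detect_hfa(p22, genes)[1, "ratio"], 2.2)

  # a gene outside the covered span is omitted
  p_part <- quick_profile(bMb, "chr1", 0, 20e6, 2)
  expect_identical(detect_hfa(p_part, genes)$gene, "CCND1")
})

test_that("HFA calls are invariant under call-preserving refinement", {
  p <- quick_profile(bMb, "chr1", c(0, 10e6, 10.05e6),
                     c(10e6, 10.05e6, 100e6), c(2, 5, 2))
  split <- quick_profile(bMb, "chr1",
                         c(0, 5e6, 10e6, 10.02e6, 10.05e6),
                         c(5e6, 10e6, 10.02e6, 10.05e6, 100e6),
                         c(2, 2, 5, 5, 2))
  expect_equal(detect_hfa(split, genes), detect_hfa(p, genes))
})

test_that("CNNLOH regions require LOH at diploid copy number and merge", {
  whole <- quick_profile(bMb, "chr1", 0, 100e6, 2, loh = TRUE)
  r <- detect_cnnloh(whole)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 100e6))

  gain_loh <- quick_profile(bMb, "chr1", 0, 100e6, 3, loh = TRUE)
  expect_equal(nrow(detect_cnnloh(gain_loh)), 0)

  abut <- quick_profile(bMb, "chr1", c(0, 30e6, 60e6),
                        c(30e6, 60e6, 100e6), c(2, 2, 3),
                        loh = c(TRUE, TRUE, FALSE))
  r2 <- detect_cnnloh(abut)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(0, 60e6))
})

test_that("every base of a CNNLOH region re-queries as LOH and diploid", {
  set.seed(17)
  build <- genome_build("chr1", 5000)
  for (i in 1:10) {
    p <- random_profile(build, gap_prob = 0)
    regions <- detect_cnnloh(p)
    seg <- p$segments
    for (j in seq_len(nrow(regions))) {
      for (base in seq(regions$start[j], regions$end[j] - 1,
                       length.out = min(20, regions$end[j] -
                                          regions$start[j]))) {
        base <- floor(base)
        hit <- seg[seg$start <= base & seg$end > base, ]
        expect_equal(nrow(hit), 1)
        expect_true(hit$loh)
        expect_equal(as.character(cn_call(hit$cn)), "ND")
      }
    }
  }
})

test_that("mutations co-occurring with CNNLOH are reported by locus", {
  build <- genome_build(c("chr17", "chr10"), c(80e6, 130e6))
  p <- seg_profile(data.frame(chrom = c("chr17", "chr10"), start = 0,
                              end = c(80e6, 130e6), cn = 2,
                              loh = c(TRUE, FALSE)), build, "S1", "LabA")
  loci <- data.frame(sm_id = c("TP53:p.R213*:c.637C>T", "PTEN:p.R130G"),
                     chrom = c("chr17", "chr10"),
                     start = c(7.5e6, 89e6), end = c(7.52e6, 89.1e6))
  calls <- c("TP53:p.R213*:c.637C>T" = "HIGH_CONFIDENCE",
             "PTEN:p.R130G" = "HIGH_CONFIDENCE")
  hits <- sm_in_cnnloh(p, calls, loci)
  expect_equal(hits$sm_id, "TP53:p.R213*:c.637C>T")
  expect_equal(hits$chrom, "chr17")

  # CNNLOH on the other chromosome only -> no co-occurrence
  q <- seg_profile(data.frame(chrom = c("chr17", "chr10"), start = 0,
                              end = c(80e6, 130e6), cn = 2,
                              loh = c(FALSE, TRUE)), build, "S1", "LabA")
  expect_equal(nrow(sm_in_cnnloh(q, calls["TP53:p.R213*:c.637C>T"],
                                 loci)), 0)

  lower <- c("TP53:p.R213*:c.637C>T" = "LOWER_CONFIDENCE")
  expect_equal(nrow(sm_in_cnnloh(p, lower, loci)), 0)
  expect_equal(sm_in_cnnloh(p, lower, loci,
                            include_lower = TRUE)$sm_id[1],
               "TP53:p.R213*:c.637C>T")

  expect_warning(sm_in_cnnloh(p, c(MYSTERY = "HIGH_CONFIDENCE"), loci),
                 "no locus")
})

test_that("recurrence reports the flagged fraction as an integer percent", {
  mk_calls <- function(flagged) {
    data.frame(gene = "CCND1", max_cn = if (flagged) 10 else 2,
               baseline = 2, ratio = if (flagged) 5 else 1,
               flagged = flagged)
  }
  cohort <- c(replicate(12, mk_calls(TRUE), simplify = FALSE),
              replicate(16, mk_calls(FALSE), simplify = FALSE))
  r <- recurrence(cohort, "CCND1")
  expect_equal(r$n_flagged, 12)
  expect_equal(r$n_total, 28)
  expect_equal(r$percentage, 43)
  expect_lt(abs(r$percentage * r$n_total / 100 - r$n_flagged), 0.5 + 1e-9)

  expect_equal(recurrence(cohort, "MYC")$percentage, 0)
  expect_equal(recurrence(replicate(5, mk_calls(TRUE), simplify = FALSE),
                          "CCND1")$percentage, 100)
  expect_error(recurrence(list(), "CCND1"), "non-empty")
})

test_that("samples with multiple actionable amplifications are flagged", {
  calls <- data.frame(gene = c("CCND1", "FGFR1", "MDM4"),
                      max_cn = c(10, 9, 8), baseline = 2,
                      ratio = c(5, 4.5, 4), flagged = TRUE)
  quiet <- data.frame(gene = "CCND1", max_cn = 2, baseline = 2, ratio = 1,
                      flagged = FALSE)
  res <- multiple_actionable(list(TSB00115 = calls, other = quiet),
                             c("CCND1", "FGFR1", "MDM4"))
  expect_true(res$multiple[res$sample == "TSB00115"])
  expect_equal(res$n_actionable_flagged[res$sample == "TSB00115"], 3)
  expect_false(res$multiple[res$sample == "other"])
})

test_that("gene BED files are read as 0-based half-open regions", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t1000000\t1100000\tCCND1"), path)
  g <- read_gene_bed(path)
  expect_equal(g$gene, "CCND1")
  expect_equal(g$start, 1e6)
  writeLines("chr1\t100\t100\tX", path)
  expect_error(read_gene_bed(path), "start < end")
})
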