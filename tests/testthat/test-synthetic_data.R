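test_that("unperturbed replicates agree 100% on every triplicate", {
  cfg <- sim_config(n_samples = 2, discordant_fraction = c(0, 0), seed = 4)
  sim <- simulate_cohort(cfg)
  for (t in sim$triplicates) {
    expect_equal(gw_call_agreement(t, "CN")$percentage, 100)
    expect_equal(gw_call_agreement(t, "LOH")$percentage, 100)
  }
})

test_that("deterministic discordance is recovered exactly as 100(1 - f)", {
  cfg <- sim_config(n_samples = 3, discordant_fraction = c(0, 0.06, 0.10),
                    seed = 9)
  sim <- simulate_cohort(cfg)
  got <- vapply(sim$triplicates, function(t) {
    gw_call_agreement(t, "CN")$percentage
  }, numeric(1))
  expect_equal(got, c(100, 94, 90))
  expect_equal(vapply(sim$truth, function(t) t$designed_cn_discordance,
                      numeric(1), USE.NAMES = FALSE), c(0, 0.06, 0.10))
  expect_equal(cohort_summary(sim$triplicates)$median_cn_agreement, 94)
})

test_that("deterministic-mode agreement matches the per-base oracle", {
  build <- genome_build(c("chr1", "chr2"), c(5000, 5000))
  cfg <- sim_config(build = build, n_samples = 1, n_events = 2,
                    discordant_fraction = 0.07, seed = 12)
  sim <- simulate_cohort(cfg)
  profiles <- lapply(sim$triplicates[[1]]$runs, function(r) r$profile)
  fast <- gw_call_agreement(profiles, "CN")
  slow <- brute_force_agreement(profiles, "CN")
  expect_identical(fast$agreeing_bp, slow$agreeing_bp)
  expect_equal(fast$percentage, 93, tolerance = 1e-6)
})

test_that("simulation output is byte-identical for a fixed seed", {
  cfg <- sim_config(n_samples = 2, seed = 31)
  panel <- read_sm_panel()
  a <- simulate_cohort(cfg, panel = panel)
  b <- simulate_cohort(cfg, panel = panel)
  expect_identical(a, b)
  c_ <- simulate_cohort(sim_config(n_samples = 2, seed = 32),
                        panel = panel)
  expect_false(identical(a, c_))
})

test_that("probe series MAPD recovers the closed-form noise level", {
  build <- genome_build(paste0("chr", 1:3), rep(1e7, 3))
  p <- seg_profile(data.frame(chrom = build$chrom, start = 0, end = 1e7,
                              cn = 2, loh = FALSE), build, "S1", "LabA")
  sigma <- 0.2
  probes <- simulate_probe_series(p, spacing = 300, sigma = sigma,
                                  seed = 71)
  expect_gte(nrow(probes), 99999)
  expect_equal(compute_mapd(probes), sigma * sqrt(2) * stats::qnorm(0.75),
               tolerance = 0.02)
})

test_that("probe log2 ratios follow the tumour-fraction-adjusted CN", {
  build <- genome_build("chr1", 1e6)
  diploid <- seg_profile(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                    cn = 2, loh = FALSE), build, "S", "A")
  pr <- simulate_probe_series(diploid, spacing = 1000, sigma = 1e-4,
                              acf = 100, seed = 5)
  expect_lt(max(abs(pr$log2ratio)), 0.01)

  cn4 <- seg_profile(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                cn = 4, loh = FALSE), build, "S", "A")
  pr4 <- simulate_probe_series(cn4, spacing = 500, sigma = 0.05, acf = 50,
                               seed = 6)
  # adjusted CN = 0.5*4 + 0.5*2 = 3 -> expected ratio log2(3/2)
  expect_equal(mean(pr4$log2ratio), log2(3 / 2), tolerance = 0.01)
})

test_that("mutation scores classify to truth when the spread collapses", {
  panel <- read_sm_panel()[1:5, ]
  positives <- data.frame(sample = c("S1", "S2"),
                          sm_id = panel$sm_id[c(1, 3)])
  sc <- simulate_mutation_scores(positives, panel, c("S1", "S2"),
                                 spread = 1e-9, seed = 8)
  for (i in seq_len(nrow(sc))) {
    calls <- classify_mutation(as.numeric(sc[i, panel$sm_id]),
                               entry = NULL, lower = 4, high = 6)
    truth_pos <- panel$sm_id %in%
      positives$sm_id[positives$sample == sc$sample[i]]
    expect_equal(as.character(calls) == "HIGH_CONFIDENCE", truth_pos)
  }
})

test_that("a positive mean between the thresholds reproduces the
           low-tumour-fraction failure mode", {
  panel <- read_sm_panel()[1:3, ]
  positives <- data.frame(sample = "S1", sm_id = panel$sm_id[1])
  sc <- simulate_mutation_scores(positives, panel, "S1",
                                 positive_mean = 5, spread = 1e-9,
                                 seed = 13)
  calls <- classify_mutation(sc[[panel$sm_id[1]]], 4, 6)
  expect_true(all(calls == "LOWER_CONFIDENCE"))
  expect_equal(sensitivity(calls)$sensitivity, 0)
})

test_that("with default parameters nearly all positives call high-confidence", {
  panel <- read_sm_panel()
  positives <- data.frame(sample = sprintf("S%02d", 1:20),
                          sm_id = panel$sm_id[1:20])
  sc <- simulate_mutation_scores(positives, panel, positives$sample,
                                 seed = 44)
  calls <- character(0)
  for (i in seq_len(nrow(sc))) {
    sm <- positives$sm_id[positives$sample == sc$sample[i]]
    calls <- c(calls, as.character(classify_mutation(sc[[sm]][i], 4, 6)))
  }
  expect_gte(mean(calls == "HIGH_CONFIDENCE"), 0.95)
})

test_that("raising the event-drop probability lowers mean CN agreement", {
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(p) {
    agr <- vapply(1:4, function(s) {
      cfg <- sim_config(n_samples = 2, n_events = 6, jitter_sd = 0,
                        drop_prob = p, flip_prob = 0, seed = 100 + s)
      sim <- simulate_cohort(cfg)
      mean(vapply(sim$triplicates, function(t) {
        gw_call_agreement(t, "CN")$percentage
      }, numeric(1)))
    }, numeric(1))
    mean(agr)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("stochastic event dropping recovers its analytic expectation", {
  # with jitter 0 and drop probability p, a truth event survives in both
  # perturbed replicates with probability (1-p)^2; everywhere else its
  # span disagrees with the truth replicate. CNNLOH events (CN 2) do not
  # contribute CN discordance.
  p <- 0.3
  realized <- vapply(1:40, function(s) {
    cfg <- sim_config(n_samples = 1, n_events = 6, jitter_sd = 0,
                      drop_prob = p, flip_prob = 0, seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    truth_seg <- sim$truth[[1]]$segments
    ev_len <- sum(with(truth_seg[as.character(cn_call(truth_seg$cn)) !=
                                   "ND", ], end - start))
    span <- sum(with(truth_seg, end - start))
    disc <- 100 - gw_call_agreement(sim$triplicates[[1]],
                                    "CN")$percentage
    disc / 100 * span / max(ev_len, 1)
  }, numeric(1))
  expect_equal(mean(realized), 1 - (1 - p)^2, tolerance = 0.15)
})

test_that("events outside the build are rejected", {
  build <- genome_build("chr1", 1000)
  expect_error(seg_profile(data.frame(chrom = "chr1", start = 500,
                                      end = 2000, cn = 3, loh = FALSE),
                           build), "beyond")
})
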