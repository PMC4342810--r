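#' Configuration for the synthetic triplicate generator
#'
#' Describes a scaled-down cross-laboratory study: a small genome, a cohort
#' of samples each with a designed truth profile, and the perturbations
#' that make replicate runs disagree. Defaults emulate a typical in-bounds
#' study run on a 3 x 10 Mb genome; see the package vignette for the
#' reasoning behind each default.
#'
#' Two discordance regimes are supported. When `discordant_fraction` is
#' given (one value per sample), the generator operates deterministically:
#' the third replicate's CN call is altered over exactly that fraction of
#' the covered span, so the realized genome-wide CN agreement is exactly
#' `100 * (1 - f)`. Otherwise replicates 2 and 3 are perturbed
#' stochastically by breakpoint jitter, event dropping and ploidy flips.
#' Replicate 1 (LabA) always equals the truth, so designed discordance is
#' attributable.
#'
#' @param build a [genome_build()] (default 3 chromosomes x 10 Mb).
#' @param n_samples number of samples (default 3).
#' @param ploidy per-sample ploidy, recycled (default 2).
#' @param acf per-sample aberrant cell fraction in percent, recycled
#'   (default 70).
#' @param n_events number of CN/LOH events per truth profile (default 4).
#' @param discordant_fraction optional per-sample designed CN-discordant
#'   fraction in [0, 1]; enables deterministic mode.
#' @param jitter_sd stochastic breakpoint jitter sd in bp (default 5000).
#' @param drop_prob per-replicate per-event drop probability (default 0.1).
#' @param flip_prob per-replicate probability of a discordant reported
#'   ploidy (default 0.03).
#' @param probe_spacing probe grid spacing in bp (default 1000).
#' @param probe_sigma probe log2-ratio noise sd (default 0.2).
#' @param ndsnpqc_mean,ndsnpqc_sd ndSNPQC assignment distribution
#'   (default N(32, 3)).
#' @param sm_positive_mean,sm_negative_mean,sm_spread mutation-score
#'   generation parameters (defaults 9, 1, 0.8 against the shipped panel's
#'   4/6 thresholds, placing >= 95% of positives in the high-confidence
#'   tier).
#' @param seed integer random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(build = genome_build(paste0("chr", 1:3),
                                            rep(1e7, 3)),
                       n_samples = 3, ploidy = 2, acf = 70, n_events = 4,
                       discordant_fraction = NULL,
                       jitter_sd = 5000, drop_prob = 0.1, flip_prob = 0.03,
                       probe_spacing = 1000, probe_sigma = 0.2,
                       ndsnpqc_mean = 32, ndsnpqc_sd = 3,
                       sm_positive_mean = 9, sm_negative_mean = 1,
                       sm_spread = 0.8, seed = 1L) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.null(discordant_fraction)) {
    if (any(discordant_fraction < 0 | discordant_fraction > 1)) {
      stop("discordant fractions must lie in [0, 1]")
    }
  }
  stopifnot(drop_prob >= 0, drop_prob <= 1, flip_prob >= 0, flip_prob <= 1,
            jitter_sd >= 0, probe_spacing > 0, probe_sigma > 0,
            sm_spread >= 0)
  structure(list(build = build, n_samples = n_samples,
                 ploidy = rep_len(ploidy, n_samples),
                 acf = rep_len(acf, n_samples), n_events = n_events,
                 discordant_fraction = discordant_fraction,
                 jitter_sd = jitter_sd, drop_prob = drop_prob,
                 flip_prob = flip_prob, probe_spacing = probe_spacing,
                 probe_sigma = probe_sigma, ndsnpqc_mean = ndsnpqc_mean,
                 ndsnpqc_sd = ndsnpqc_sd,
                 sm_positive_mean = sm_positive_mean,
                 sm_negative_mean = sm_negative_mean, sm_spread = sm_spread,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Overlay event intervals onto per-chromosome baseline segments; events
# must be mutually non-overlapping. Returns a full segment table.
overlay_events <- function(build, baseline_cn, events) {
  base <- GenomicRanges::GRanges(
    seqnames = factor(build$chrom, levels = build$chrom),
    ranges = IRanges::IRanges(start = 1, end = build$length))
  if (nrow(events) == 0) {
    return(data.frame(chrom = build$chrom, start = 0, end = build$length,
                      cn = baseline_cn, loh = FALSE,
                      stringsAsFactors = FALSE))
  }
  ev <- GenomicRanges::GRanges(
    seqnames = factor(events$chrom, levels = build$chrom),
    ranges = IRanges::IRanges(start = events$start + 1, end = events$end))
  rest <- GenomicRanges::setdiff(base, ev)
  seg <- rbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(rest)),
               start = GenomicRanges::start(rest) - 1,
               end = GenomicRanges::end(rest),
               cn = baseline_cn, loh = FALSE, stringsAsFactors = FALSE),
    events[c("chrom", "start", "end", "cn", "loh")])
  seg[order(match(seg$chrom, build$chrom), seg$start), , drop = FALSE]
}

# Random non-overlapping events on a slot grid.
random_events <- function(build, n_events, ploidy) {
  if (n_events == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cn = numeric(), loh = logical(),
                      stringsAsFactors = FALSE))
  }
  # carve each chromosome into 2*n_events slots and occupy distinct slots
  slots <- do.call(rbind, lapply(seq_len(nrow(build)), function(i) {
    k <- max(2, ceiling(2 * n_events / nrow(build)))
    width <- floor(build$length[i] / k)
    data.frame(chrom = build$chrom[i],
               slot_start = (seq_len(k) - 1) * width,
               slot_end = seq_len(k) * width, stringsAsFactors = FALSE)
  }))
  pick <- sample(nrow(slots), min(n_events, nrow(slots)))
  ev <- do.call(rbind, lapply(pick, function(i) {
    w <- slots$slot_end[i] - slots$slot_start[i]
    len <- round(stats::runif(1, 0.2, 0.8) * w)
    start <- slots$slot_start[i] + round(stats::runif(1, 0, w - len))
    cnnloh <- stats::runif(1) < 0.25
    cn <- if (cnnloh) 2 else sample(setdiff(c(0, 1, 3, 4, 5, 7), ploidy), 1)
    loh <- cnnloh || cn < 2
    data.frame(chrom = slots$chrom[i], start = start, end = start + len,
               cn = cn, loh = loh, stringsAsFactors = FALSE)
  }))
  ev[order(match(ev$chrom, build$chrom), ev$start), , drop = FALSE]
}

# Change the CN call of a value: bump up one band, except top band -> 2.
bump_cn <- function(cn) {
  ifelse(as.character(cn_call(cn)) == "HIGH_GAIN", 2, cn + 1)
}

# Alter the CN call over exactly target_len bp taken from the start of the
# genome (segments split as needed).
alter_leading_span <- function(segments, target_len) {
  if (target_len <= 0) return(segments)
  out <- list(); remaining <- target_len
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, , drop = FALSE]
    len <- s$end - s$start
    if (remaining <= 0) {
      out[[length(out) + 1]] <- s
    } else if (len <= remaining) {
      s$cn <- bump_cn(s$cn)
      out[[length(out) + 1]] <- s
      remaining <- remaining - len
    } else {
      head <- s; head$end <- s$start + remaining
      head$cn <- bump_cn(head$cn)
      tail <- s; tail$start <- s$start + remaining
      out[[length(out) + 1]] <- head
      out[[length(out) + 1]] <- tail
      remaining <- 0
    }
  }
  do.call(rbind, out)
}

# Stochastic replicate perturbation on the event list.
perturb_events <- function(events, build, jitter_sd, drop_prob) {
  if (nrow(events) == 0) return(events)
  keep <- stats::runif(nrow(events)) >= drop_prob
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0 || jitter_sd == 0) return(ev)
  for (i in seq_len(nrow(ev))) {
    L <- chrom_length(build, ev$chrom[i])
    ev$start[i] <- max(0, min(ev$end[i] - 1,
                              ev$start[i] + round(stats::rnorm(1, 0,
                                                               jitter_sd))))
    ev$end[i] <- max(ev$start[i] + 1,
                     min(L, ev$end[i] + round(stats::rnorm(1, 0,
                                                           jitter_sd))))
  }
  # resolve any jitter-induced overlap between consecutive events
  ev <- ev[order(match(ev$chrom, build$chrom), ev$start), , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$chrom[i] == ev$chrom[i - 1] && ev$start[i] < ev$end[i - 1]) {
        ev$start[i] <- ev$end[i - 1]
      }
    }
    ev <- ev[ev$start < ev$end, , drop = FALSE]
  }
  ev
}

#' Simulate a triplicate cohort with known truth
#'
#' Generates `n_samples` truth profiles (baseline at the sample's ploidy
#' plus random gain/loss/LOH/CNNLOH events) and three replicate runs per
#' sample across labs LabA/LabB/LabC, complete with QC metrics,
#' ploidy/ACF estimates and mutation scores for the supplied panel. The
#' output is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param panel optional mutation panel ([read_sm_panel()]); when given,
#'   each sample is made truth-positive for one panel SM and scores are
#'   generated for all SMs.
#' @return list: `triplicates` (list of [triplicate_set()]s), `truth`
#'   (per-sample list with the truth segments, the realized designed CN
#'   discordance, SM positives, ploidy, ACF and the MAPD target implied by
#'   `probe_sigma`).
#' @export
simulate_cohort <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  build <- config$build
  labs <- c("LabA", "LabB", "LabC")
  deterministic <- !is.null(config$discordant_fraction)
  if (deterministic) {
    frac <- rep_len(config$discordant_fraction, config$n_samples)
  }
  mapd_target <- config$probe_sigma * sqrt(2) * stats::qnorm(0.75)
  triplicates <- list(); truth <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("S%03d", s)
    ploidy <- config$ploidy[s]
    events <- random_events(build, config$n_events, ploidy)
    truth_seg <- overlay_events(build, ploidy, events)
    total_span <- sum(truth_seg$end - truth_seg$start)
    realized_frac <- 0
    runs <- list()
    for (j in seq_along(labs)) {
      seg <- truth_seg
      rep_ploidy <- ploidy
      if (deterministic) {
        if (j == 3 && frac[s] > 0) {
          target <- round(frac[s] * total_span)
          seg <- alter_leading_span(truth_seg, target)
          realized_frac <- target / total_span
        }
      } else if (j > 1) {
        ev <- perturb_events(events, build, config$jitter_sd,
                             config$drop_prob)
        seg <- overlay_events(build, ploidy, ev)
        if (stats::runif(1) < config$flip_prob) {
          rep_ploidy <- if (ploidy == 2) 4 else ploidy - 1
        }
      }
      profile <- seg_profile(seg, build, sample = sid, lab = labs[j])
      qc <- qc_metrics(
        mapd = max(0, mapd_target + stats::rnorm(1, 0, 0.01)),
        ndsnpqc = max(0, stats::rnorm(1, config$ndsnpqc_mean,
                                      config$ndsnpqc_sd)))
      tuscan <- tuscan_estimate(ploidy = rep_ploidy,
                                acf = config$acf[s])
      runs[[j]] <- sample_run(profile, qc = qc, tuscan = tuscan)
    }
    triplicates[[s]] <- triplicate_set(runs)
    truth[[s]] <- list(sample = sid, segments = truth_seg,
                       designed_cn_discordance = realized_frac,
                       ploidy = ploidy, acf = config$acf[s],
                       mapd_target = mapd_target,
                       sm_positives = character())
  }
  names(truth) <- vapply(truth, function(t) t$sample, character(1))
  if (!is.null(panel)) {
    positives <- data.frame(
      sample = names(truth),
      sm_id = panel$sm_id[1 + (seq_len(config$n_samples) - 1) %%
                            nrow(panel)],
      stringsAsFactors = FALSE)
    scores <- simulate_mutation_scores(
      positives, panel, samples = names(truth), labs = labs,
      positive_mean = config$sm_positive_mean,
      negative_mean = config$sm_negative_mean, spread = config$sm_spread)
    for (s in seq_along(triplicates)) {
      sid <- triplicates[[s]]$sample
      truth[[sid]]$sm_positives <- positives$sm_id[positives$sample == sid]
      for (j in seq_along(labs)) {
        row <- scores[scores$sample == sid & scores$lab == labs[j], ,
                      drop = FALSE]
        v <- as.numeric(row[1, panel$sm_id])
        names(v) <- panel$sm_id
        triplicates[[s]]$runs[[j]]$scores <- v
      }
    }
  }
  list(triplicates = triplicates, truth = truth)
}

#' Simulate a probe-level log2-ratio series over a profile
#'
#' Places probes on a regular genomic grid restricted to the profile's
#' covered span. Each probe's expected log2 ratio follows the
#' tumour-fraction-adjusted copy number: log2(adj / 2) with
#' adj = acf * CN + (1 - acf) * 2 (floored at 0.1 so homozygous losses do
#' not produce infinite ratios), plus Gaussian noise of sd `sigma`. At
#' large probe counts [compute_mapd()] of the result converges to
#' sigma * sqrt(2) * qnorm(0.75).
#'
#' @param profile a [seg_profile()].
#' @param spacing probe spacing in bp (default 1000).
#' @param sigma noise sd (default 0.2).
#' @param acf aberrant cell fraction in percent (default 100).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return data.frame: `probe`, `chrom`, `pos`, `log2ratio`.
#' @export
simulate_probe_series <- function(profile, spacing = 1000, sigma = 0.2,
                                  acf = 100, seed = NULL) {
  stopifnot(inherits(profile, "seg_profile"), spacing > 0)
  if (!is.null(seed)) set.seed(seed)
  seg <- profile$segments
  rows <- lapply(split(seg, seg$chrom), function(s) {
    grid <- seq(min(s$start), max(s$end) - 1, by = spacing)
    gr_probe <- IRanges::IRanges(start = grid + 1, width = 1)
    gr_seg <- IRanges::IRanges(start = s$start + 1, end = s$end)
    hits <- IRanges::findOverlaps(gr_probe, gr_seg)
    data.frame(chrom = s$chrom[1],
               pos = grid[S4Vectors::queryHits(hits)],
               cn = s$cn[S4Vectors::subjectHits(hits)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chrom, profile$build$chrom), out$pos), ,
             drop = FALSE]
  a <- acf / 100
  adj <- pmax(a * out$cn + (1 - a) * 2, 0.1)
  data.frame(probe = sprintf("P%06d", seq_len(nrow(out))),
             chrom = out$chrom, pos = out$pos,
             log2ratio = log2(adj / 2) +
               stats::rnorm(nrow(out), 0, sigma),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a mutation score matrix with known positives
#'
#' Truth-positive (sample, SM) pairs draw scores around `positive_mean`,
#' all other pairs around `negative_mean`, with common sd `spread`; every
#' lab's run of a sample shares the truth but draws independent noise.
#' With the defaults against the shipped panel thresholds at least 95% of
#' positives classify high-confidence; moving `positive_mean` between an
#' SM's thresholds reproduces the low-tumour-fraction failure mode where
#' positives surface only as lower-confidence calls.
#'
#' @param positives data.frame with columns `sample`, `sm_id` of
#'   truth-positive pairs.
#' @param panel mutation panel data.frame.
#' @param samples character vector of sample ids.
#' @param labs character vector of lab ids (default LabA/LabB/LabC).
#' @param positive_mean,negative_mean,spread score distribution parameters.
#' @param seed optional seed; NULL uses the current RNG stream.
#' @return data.frame: `sample`, `lab`, then one numeric column per SM id.
#' @export
simulate_mutation_scores <- function(positives, panel, samples,
                                     labs = c("LabA", "LabB", "LabC"),
                                     positive_mean = 9, negative_mean = 1,
                                     spread = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(lab = labs, sample = samples,
                      stringsAsFactors = FALSE)[, c("sample", "lab")]
  mat <- matrix(NA_real_, nrow = nrow(grid), ncol = nrow(panel),
                dimnames = list(NULL, panel$sm_id))
  for (i in seq_len(nrow(grid))) {
    pos <- positives$sm_id[positives$sample == grid$sample[i]]
    means <- ifelse(panel$sm_id %in% pos, positive_mean, negative_mean)
    mat[i, ] <- stats::rnorm(nrow(panel), means, spread)
  }
  cbind(grid, as.data.frame(mat, check.names = FALSE))
}
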