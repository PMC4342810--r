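#' Common refinement of replicate segmentations
#'
#' Builds the atomic interval track on which replicate agreement is
#' evaluated: the breakpoints of all profiles are pooled, the resulting
#' atomic intervals are restricted to the intersection of the profiles'
#' covered spans (agreement cannot be assessed where a replicate has no
#' call), and each atomic interval is annotated with one CN value and one
#' LOH flag per replicate. Within the common span every atomic interval
#' falls inside exactly one segment of every profile.
#'
#' @param profiles list of two or more [seg_profile()]s over the same
#'   genome build.
#' @param include_sex keep sex chromosomes in the track (default FALSE).
#' @return list of class `atomic_track`: `intervals` (data.frame `chrom`,
#'   `start`, `end`, 0-based half-open), `cn` and `loh` (matrices, one
#'   column per replicate), `labs`, `build`.
#' @export
breakpoint_union <- function(profiles, include_sex = FALSE) {
  if (length(profiles) < 2) stop("need at least two profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1), "seg_profile")))
  build <- profiles[[1]]$build
  for (p in profiles[-1]) {
    if (!identical(p$build$chrom, build$chrom)) {
      stop("profiles must share one genome build")
    }
  }
  grs <- lapply(profiles, profile_granges)
  common <- Reduce(GenomicRanges::intersect,
                   lapply(grs, GenomicRanges::reduce))
  if (!include_sex) {
    keep <- !is_sex_chrom(as.character(GenomicRanges::seqnames(common)))
    common <- common[keep]
  }
  if (length(common) == 0 || sum(GenomicRanges::width(common)) == 0) {
    stop("profiles share no covered span",
         if (!include_sex) " (sex chromosomes excluded)" else "")
  }
  # Pool all breakpoints (plus the common-span boundaries, already among
  # them) and cut into atomic intervals; every atom nests within the
  # common span or lies wholly outside it.
  pool <- c(do.call(c, lapply(grs, GenomicRanges::granges)), common)
  atoms <- GenomicRanges::disjoin(pool)
  atoms <- IRanges::subsetByOverlaps(atoms, common, type = "within")
  k <- length(profiles)
  cn <- matrix(NA_real_, nrow = length(atoms), ncol = k)
  loh <- matrix(NA, nrow = length(atoms), ncol = k)
  for (j in seq_len(k)) {
    hits <- GenomicRanges::findOverlaps(atoms, grs[[j]])
    stopifnot(identical(S4Vectors::queryHits(hits),
                        seq_along(atoms)))  # exactly one segment per atom
    cn[, j] <- grs[[j]]$cn[S4Vectors::subjectHits(hits)]
    loh[, j] <- grs[[j]]$loh[S4Vectors::subjectHits(hits)]
  }
  labs <- vapply(profiles, function(p) p$lab, character(1))
  colnames(cn) <- colnames(loh) <- labs
  structure(list(
    intervals = data.frame(
      chrom = as.character(GenomicRanges::seqnames(atoms)),
      start = GenomicRanges::start(atoms) - 1,
      end = GenomicRanges::end(atoms),
      stringsAsFactors = FALSE),
    cn = cn, loh = loh, labs = labs, build = build),
    class = "atomic_track")
}

#' Genome-wide length-weighted call agreement
#'
#' The study's core reproducibility statistic. Replicate profiles are cut to
#' their common refinement ([breakpoint_union()]); an atomic interval agrees
#' when every replicate carries the same categorical CN call
#' ([cn_call()]; channel `"CN"`) or the same LOH flag (channel `"LOH"`).
#' The genome-wide percentage agreement is 100 x (total agreeing length) /
#' (total common-span length). Agreement always operates on the categorical
#' call, never raw numeric CN.
#'
#' @param x a [triplicate_set()] or a list of >= 2 [seg_profile()]s.
#' @param channel `"CN"` or `"LOH"`.
#' @param include_sex keep sex chromosomes in numerator and denominator
#'   (default FALSE).
#' @param eps diploid-call tolerance passed to [cn_call()].
#' @return list of class `agreement_result`: `channel`, `intervals` (the
#'   atomic track with an `agree` flag), `agreeing_bp`, `denominator_bp`,
#'   `percentage`.
#' @examples
#' b <- genome_build("chr1", 100)
#' p <- function(cn10) seg_profile(
#'   data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 100),
#'              cn = c(cn10, 2), loh = FALSE), b)
#' gw_call_agreement(list(p(2), p(2), p(3)), "CN")$percentage  # 90
#' @export
gw_call_agreement <- function(x, channel = c("CN", "LOH"),
                              include_sex = FALSE, eps = 1e-6) {
  channel <- match.arg(channel)
  profiles <- if (inherits(x, "triplicate_set")) {
    lapply(x$runs, function(r) r$profile)
  } else x
  track <- breakpoint_union(profiles, include_sex = include_sex)
  agree <- track_agreement(track, channel, eps)
  len <- track$intervals$end - track$intervals$start
  agreeing <- sum(len[agree])
  denom <- sum(len)
  intervals <- track$intervals
  intervals$agree <- agree
  structure(list(channel = channel, intervals = intervals,
                 agreeing_bp = agreeing, denominator_bp = denom,
                 percentage = 100 * agreeing / denom),
            class = "agreement_result")
}

track_agreement <- function(track, channel, eps = 1e-6) {
  if (channel == "CN") {
    calls <- apply(track$cn, 2, function(col) as.character(cn_call(col, eps)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  } else {
    calls <- track$loh
  }
  apply(calls, 1, function(r) all(r == r[1]))
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("genome-wide %s call agreement: %.1f%% (%s of %s bp)\n",
              x$channel, x$percentage,
              format(x$agreeing_bp, big.mark = ","),
              format(x$denominator_bp, big.mark = ",")))
  invisible(x)
}

#' @rdname gw_call_agreement
#' @param a,b two [seg_profile()]s.
#' @export
pairwise_agreement <- function(a, b, channel = c("CN", "LOH"),
                               include_sex = FALSE, eps = 1e-6) {
  gw_call_agreement(list(a, b), channel = channel,
                    include_sex = include_sex, eps = eps)
}

#' Concordance of a small set of categorical values
#'
#' For per-triplicate ploidy, ACF and mutation-call concordance. In
#' `max_agreement` mode the percentage is 100 x (size of the largest group
#' of equal values) / n — for three values this is 33, 66 or 100. In
#' `ploidy_strict` mode an all-distinct set scores 0 instead of 33 (no two
#' replicates agree on anything is reported as no concordance), matching
#' the 0/66/100 reporting convention for ploidy. Two-thirds is reported as
#' 66 (floor to integer); the exact fraction is kept alongside.
#'
#' @param values atomic vector of comparable values; NAs are dropped.
#' @param mode `"max_agreement"` or `"ploidy_strict"`.
#' @return list of class `categorical_concordance`: `n`, `max_group`,
#'   `fraction` (exact), `percentage` (floored integer).
#' @examples
#' categorical_concordance(c(4, 4, 2), "ploidy_strict")$percentage  # 66
#' @export
categorical_concordance <- function(values,
                                    mode = c("max_agreement",
                                             "ploidy_strict")) {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least two non-missing values")
  max_group <- max(table(values))
  frac <- max_group / n
  if (mode == "ploidy_strict" && max_group == 1) frac <- 0
  structure(list(mode = mode, n = n, max_group = max_group,
                 fraction = frac,
                 percentage = floor(100 * frac + 1e-9)),
            class = "categorical_concordance")
}

#' Concordance of aberrant-cell-fraction estimates
#'
#' ACF values agree when both are the label `"homogeneous"`, or both are
#' numeric and differ by at most `tol` percentage points (exact matching
#' would be brittle to rounding). The percentage is the size of the largest
#' mutually agreeing group, as in [categorical_concordance()]'s
#' max-agreement mode.
#'
#' @param values vector (character or numeric); numeric ACF percentages
#'   and/or the string "homogeneous". NAs dropped.
#' @param tol numeric agreement tolerance in percentage points (default 1).
#' @return a `categorical_concordance` object.
#' @export
acf_concordance <- function(values, tol = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least two non-missing values")
  homog <- values == "homogeneous"
  num <- suppressWarnings(as.numeric(values))
  agree <- function(i, j) {
    if (homog[i] || homog[j]) return(homog[i] && homog[j])
    abs(num[i] - num[j]) <= tol
  }
  max_group <- max(vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) agree(i, j), logical(1)))
  }, numeric(1)))
  frac <- max_group / n
  structure(list(mode = "max_agreement", n = n, max_group = max_group,
                 fraction = frac,
                 percentage = floor(100 * frac + 1e-9)),
            class = "categorical_concordance")
}

#' Cohort-level agreement summary
#'
#' Computes per-triplicate genome-wide CN and LOH agreement for every
#' triplicate (no QC filter — reproducibility is of interest regardless of
#' basal QC level) and summarises with both median and mean. Ploidy, ACF
#' and (when a panel is supplied) mutation-call concordance means are
#' restricted to triplicates whose three runs all have ndSNPQC >= the
#' filter threshold, since mutation-call accuracy tracks ndSNPQC.
#' Triplicates missing ploidy or ACF in any run are excluded from that
#' concordance mean only.
#'
#' @param triplicates list of [triplicate_set()]s.
#' @param panel optional mutation panel (see [read_sm_panel()]) enabling the
#'   SM concordance mean.
#' @param ndsnpqc_min QC filter threshold (default 26).
#' @param include_sex,eps passed to [gw_call_agreement()].
#' @param acf_tol ACF agreement tolerance (default 1 percentage point).
#' @return list of class `cohort_summary` with per-triplicate vectors and
#'   the summary statistics.
#' @export
cohort_summary <- function(triplicates, panel = NULL, ndsnpqc_min = 26,
                           include_sex = FALSE, eps = 1e-6, acf_tol = 1) {
  if (length(triplicates) < 1) stop("need at least one triplicate")
  stopifnot(all(vapply(triplicates, inherits, logical(1), "triplicate_set")))
  samples <- vapply(triplicates, function(t) t$sample, character(1))
  cn <- vapply(triplicates, function(t) {
    gw_call_agreement(t, "CN", include_sex = include_sex, eps = eps)$percentage
  }, numeric(1))
  loh <- vapply(triplicates, function(t) {
    gw_call_agreement(t, "LOH", include_sex = include_sex,
                      eps = eps)$percentage
  }, numeric(1))
  qc_pass <- vapply(triplicates, function(t) {
    all(vapply(t$runs, function(r) {
      !is.null(r$qc) && r$qc$ndsnpqc >= ndsnpqc_min
    }, logical(1)))
  }, logical(1))
  passing <- triplicates[qc_pass]
  ploidy_pct <- acf_pct <- numeric(0)
  for (t in passing) {
    ploidies <- vapply(t$runs, function(r) {
      if (is.null(r$tuscan)) NA_real_ else as.numeric(r$tuscan$ploidy)
    }, numeric(1))
    if (!anyNA(ploidies)) {
      ploidy_pct <- c(ploidy_pct,
                      categorical_concordance(ploidies,
                                              "ploidy_strict")$percentage)
    }
    acfs <- vapply(t$runs, function(r) {
      if (is.null(r$tuscan) || length(r$tuscan$acf) != 1 ||
          is.na(r$tuscan$acf)) NA_character_
      else as.character(r$tuscan$acf)
    }, character(1))
    if (!anyNA(acfs)) {
      acf_pct <- c(acf_pct, acf_concordance(acfs, tol = acf_tol)$percentage)
    }
  }
  sm_mean <- NA_real_
  if (!is.null(panel) && length(passing) > 0) {
    sm_tab <- sm_concordance_table(triplicates, panel,
                                   ndsnpqc_min = ndsnpqc_min)
    sm_mean <- sm_tab$grand_mean
  }
  structure(list(
    sample = samples,
    cn_agreement = cn, loh_agreement = loh, qc_pass = qc_pass,
    median_cn_agreement = stats::median(cn),
    mean_cn_agreement = mean(cn),
    median_loh_agreement = stats::median(loh),
    mean_loh_agreement = mean(loh),
    n_triplicates = length(triplicates),
    n_qc_pass = sum(qc_pass),
    mean_ploidy_concordance = if (length(ploidy_pct)) mean(ploidy_pct)
                              else NA_real_,
    mean_acf_concordance = if (length(acf_pct)) mean(acf_pct) else NA_real_,
    mean_sm_concordance = sm_mean),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d triplicates (%d pass the QC filter)\n",
              x$n_triplicates, x$n_qc_pass))
  cat(sprintf("  median CN agreement:  %.1f%% (mean %.1f%%)\n",
              x$median_cn_agreement, x$mean_cn_agreement))
  cat(sprintf("  median LOH agreement: %.1f%% (mean %.1f%%)\n",
              x$median_loh_agreement, x$mean_loh_agreement))
  if (!is.na(x$mean_ploidy_concordance)) {
    cat(sprintf("  mean ploidy concordance: %.1f%%\n",
                x$mean_ploidy_concordance))
  }
  if (!is.na(x$mean_acf_concordance)) {
    cat(sprintf("  mean ACF concordance: %.1f%%\n", x$mean_acf_concordance))
  }
  if (!is.na(x$mean_sm_concordance)) {
    cat(sprintf("  mean SM concordance: %.1f%%\n", x$mean_sm_concordance))
  }
  invisible(x)
}

#' Compare pairwise agreements involving a flagged lab with the rest
#'
#' When one laboratory is suspected of a systematic issue, the pairwise
#' agreement percentages of lab pairs involving it are compared against
#' those of pairs not involving it with a two-sample Welch t-test. When
#' both groups are constant (zero pooled variance) the comparison is
#' degenerate: p is reported as 1 for equal means (no evidence of a
#' difference) with a warning flag set.
#'
#' @param with_lab numeric vector of pairwise agreement percentages from
#'   pairs involving the flagged lab.
#' @param without_lab percentages from pairs not involving it.
#' @return list: `mean_with`, `mean_without`, `difference`, `p`,
#'   `degenerate` (TRUE when the zero-variance convention was used).
#' @export
lab_subset_comparison <- function(with_lab, without_lab) {
  with_lab <- as.numeric(with_lab); without_lab <- as.numeric(without_lab)
  if (length(with_lab) < 2 || length(without_lab) < 2) {
    stop("need at least two values in each group")
  }
  m1 <- mean(with_lab); m2 <- mean(without_lab)
  v1 <- stats::var(with_lab); v2 <- stats::var(without_lab)
  degenerate <- (v1 + v2) == 0
  if (degenerate) {
    warning("zero variance in both groups; p set by convention")
    p <- if (m1 == m2) 1 else 0
  } else {
    p <- stats::t.test(with_lab, without_lab)$p.value
  }
  list(mean_with = m1, mean_without = m2, difference = m1 - m2, p = p,
       degenerate = degenerate)
}
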