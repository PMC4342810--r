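#' Read a study manifest
#'
#' Tab-delimited, one row per run: `sample  lab  seg_path  mapd  ndsnpqc
#' ploidy  acf` (`probe_path` optional). Every sample must appear with
#' exactly three labs to enter triplicate analyses; partial samples are
#' excluded with a warning at assembly time.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sample", "lab", "seg_path", "mapd", "ndsnpqc", "ploidy", "acf")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab[c("sample", "lab")])) {
    stop("manifest has duplicated (sample, lab) rows")
  }
  tab
}

#' Assemble triplicates from a manifest
#'
#' Reads each run's SEG profile and bundles QC metrics, ploidy/ACF and
#' (optionally) mutation scores into [triplicate_set()]s. Samples without
#' exactly three labs are dropped with a warning naming them.
#'
#' @param manifest manifest data.frame ([read_manifest()]).
#' @param build a [genome_build()].
#' @param scores optional score table ([read_sm_scores()]): columns
#'   `sample`, `lab`, then SM ids.
#' @return list of [triplicate_set()]s.
#' @export
assemble_triplicates <- function(manifest, build, scores = NULL) {
  counts <- table(manifest$sample)
  partial <- names(counts)[counts != 3]
  if (length(partial)) {
    warning("sample(s) without exactly 3 labs excluded: ",
            paste(partial, collapse = ", "))
    manifest <- manifest[!manifest$sample %in% partial, , drop = FALSE]
  }
  if (nrow(manifest) == 0) stop("no complete triplicate in manifest")
  lapply(split(manifest, manifest$sample), function(m) {
    runs <- lapply(seq_len(nrow(m)), function(i) {
      profile <- read_seg_profile(m$seg_path[i], build, lab = m$lab[i])
      acf <- m$acf[i]
      if (!is.na(suppressWarnings(as.numeric(acf)))) {
        acf <- as.numeric(acf)
      }
      sc <- NULL
      if (!is.null(scores)) {
        row <- scores[scores$sample == m$sample[i] &
                        scores$lab == m$lab[i], , drop = FALSE]
        if (nrow(row) == 1) {
          cols <- setdiff(names(scores), c("sample", "lab"))
          sc <- as.numeric(row[1, cols])
          names(sc) <- cols
        }
      }
      sample_run(profile,
                 qc = qc_metrics(m$mapd[i], m$ndsnpqc[i]),
                 tuscan = tuscan_estimate(m$ploidy[i], acf),
                 scores = sc, sample = m$sample[i], lab = m$lab[i])
    })
    triplicate_set(runs)
  })
}

qc_table_from_triplicates <- function(triplicates) {
  do.call(rbind, lapply(triplicates, function(t) {
    do.call(rbind, lapply(t$runs, function(r) {
      data.frame(sample = r$sample, lab = r$lab,
                 mapd = if (is.null(r$qc)) NA_real_ else r$qc$mapd,
                 ndsnpqc = if (is.null(r$qc)) NA_real_ else r$qc$ndsnpqc,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Run the full cross-laboratory analysis
#'
#' Orchestrates the study pipeline over a set of triplicates: QC statistics
#' (lab-effect ANOVA with pairwise follow-up and within- vs between-sample
#' variance decomposition for MAPD and ndSNPQC), genome-wide CN/LOH
#' agreement with cohort medians, ploidy/ACF concordance means, mutation
#' concordance (when a panel is supplied), sensitivity against orthogonal
#' truth (when a truth table is supplied), and per-sample clinical event
#' scans (when gene regions are supplied).
#'
#' @param triplicates list of [triplicate_set()]s (e.g. from
#'   [assemble_triplicates()] or [simulate_cohort()]).
#' @param panel optional mutation panel.
#' @param truth optional orthogonal truth table ([read_sm_truth()]).
#' @param genes optional gene regions ([read_gene_bed()]).
#' @param ndsnpqc_min QC filter for SM/ploidy/ACF analyses (default 26).
#' @param hfa_threshold focal-amplification ratio threshold (default 2.2).
#' @param acf_tol ACF agreement tolerance (default 1).
#' @param eps diploid-call tolerance (default 1e-6).
#' @param include_sex include sex chromosomes in agreement (default FALSE).
#' @return list of class `study_report`.
#' @export
run_full_analysis <- function(triplicates, panel = NULL, truth = NULL,
                              genes = NULL, ndsnpqc_min = 26,
                              hfa_threshold = 2.2, acf_tol = 1, eps = 1e-6,
                              include_sex = FALSE) {
  stopifnot(all(vapply(triplicates, inherits, logical(1), "triplicate_set")))
  qc_tab <- qc_table_from_triplicates(triplicates)
  qc <- NULL
  if (!anyNA(qc_tab$mapd) && length(unique(qc_tab$lab)) >= 2 &&
      all(table(qc_tab$lab) >= 2)) {
    qc <- list(
      mapd_anova = lab_effect_test(qc_tab, "mapd"),
      ndsnpqc_anova = lab_effect_test(qc_tab, "ndsnpqc"),
      mapd_variance = variance_decomposition(qc_tab, "mapd"),
      ndsnpqc_variance = variance_decomposition(qc_tab, "ndsnpqc"))
  }
  summary <- cohort_summary(triplicates, panel = panel,
                            ndsnpqc_min = ndsnpqc_min,
                            include_sex = include_sex, eps = eps,
                            acf_tol = acf_tol)
  sens <- NULL
  if (!is.null(truth) && !is.null(panel)) {
    sens <- sensitivity_table(triplicates, panel, truth,
                              ndsnpqc_min = ndsnpqc_min)
  }
  clinical <- NULL
  if (!is.null(genes)) {
    hfa <- lapply(triplicates, function(t) {
      detect_hfa(t$runs[[1]]$profile, genes, threshold = hfa_threshold)
    })
    names(hfa) <- vapply(triplicates, function(t) t$sample, character(1))
    cnnloh <- lapply(triplicates, function(t) {
      detect_cnnloh(t$runs[[1]]$profile, genes = genes, eps = eps)
    })
    names(cnnloh) <- names(hfa)
    rec <- do.call(rbind, lapply(unique(genes$gene), function(g) {
      r <- recurrence(hfa, g)
      data.frame(gene = g, n_flagged = r$n_flagged, n_total = r$n_total,
                 pct = r$percentage, stringsAsFactors = FALSE)
    }))
    clinical <- list(hfa = hfa, cnnloh = cnnloh, recurrence = rec)
  }
  structure(list(
    config = list(ndsnpqc_min = ndsnpqc_min, hfa_threshold = hfa_threshold,
                  acf_tol = acf_tol, eps = eps, include_sex = include_sex),
    qc_table = qc_tab, qc = qc, summary = summary,
    sensitivity = sens, clinical = clinical),
    class = "study_report")
}

#' Per-SM sensitivity against orthogonal truth
#'
#' For each SM orthogonally pre-validated positive in at least one sample,
#' collects every run of those samples passing the ndSNPQC filter,
#' classifies its score and computes [sensitivity()]; the panel-wide
#' weighted mean uses validated run counts as weights.
#'
#' @param triplicates list of [triplicate_set()]s whose runs carry scores.
#' @param panel mutation panel.
#' @param truth truth table (`sample`, `sm_id`, `positive`).
#' @param ndsnpqc_min QC filter (default 26).
#' @return list: `per_sm` data.frame (`sm_id`, `n`, `n_high`,
#'   `sensitivity`, `rounded`) and `weighted_mean`.
#' @export
sensitivity_table <- function(triplicates, panel, truth, ndsnpqc_min = 26) {
  pos <- truth[truth$positive, , drop = FALSE]
  rows <- lapply(intersect(unique(pos$sm_id), panel$sm_id), function(sm) {
    entry <- panel[panel$sm_id == sm, , drop = FALSE]
    pos_samples <- pos$sample[pos$sm_id == sm]
    calls <- character(0)
    for (t in triplicates) {
      if (!t$sample %in% pos_samples) next
      for (r in t$runs) {
        if (is.null(r$qc) || r$qc$ndsnpqc < ndsnpqc_min) next
        if (is.null(r$scores) || !sm %in% names(r$scores)) next
        calls <- c(calls, as.character(
          classify_mutation(r$scores[[sm]], entry = entry)))
      }
    }
    if (length(calls) == 0) return(NULL)
    s <- sensitivity(calls)
    data.frame(sm_id = sm, n = s$n, n_high = s$n_high,
               sensitivity = s$sensitivity, rounded = s$rounded,
               stringsAsFactors = FALSE)
  })
  per_sm <- do.call(rbind, rows)
  if (is.null(per_sm) || nrow(per_sm) == 0) {
    stop("no QC-passing runs available for any pre-validated SM")
  }
  list(per_sm = per_sm, weighted_mean = weighted_mean_sensitivity(per_sm))
}

#' @export
print.study_report <- function(x, ...) {
  cat("cross-laboratory study report\n")
  print(x$summary)
  if (!is.null(x$qc)) {
    cat(sprintf("MAPD variance decomposition: within %.3g, global %.3g\n",
                x$qc$mapd_variance$within, x$qc$mapd_variance$global))
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("weighted mean SM sensitivity: %.1f%%\n",
                x$sensitivity$weighted_mean))
  }
  invisible(x)
}

report_as_list <- function(report) {
  out <- list(config = report$config,
              summary = unclass(report$summary))
  if (!is.null(report$qc)) {
    out$qc <- list(
      mapd = list(f = report$qc$mapd_anova$f, p = report$qc$mapd_anova$p,
                  pairwise = report$qc$mapd_anova$pairwise,
                  within_variance = report$qc$mapd_variance$within,
                  global_variance = report$qc$mapd_variance$global),
      ndsnpqc = list(f = report$qc$ndsnpqc_anova$f,
                     p = report$qc$ndsnpqc_anova$p,
                     pairwise = report$qc$ndsnpqc_anova$pairwise,
                     within_variance = report$qc$ndsnpqc_variance$within,
                     global_variance = report$qc$ndsnpqc_variance$global))
  }
  if (!is.null(report$sensitivity)) {
    out$sensitivity = list(per_sm = report$sensitivity$per_sm,
                           weighted_mean = report$sensitivity$weighted_mean)
  }
  if (!is.null(report$clinical)) {
    out$clinical = list(recurrence = report$clinical$recurrence)
  }
  out
}

#' Write a study report to disk
#'
#' `json` writes the full report (deterministic serialization; identical
#' reports give identical bytes); `tsv` writes the per-triplicate agreement
#' table; `markdown` writes a human-readable summary table.
#'
#' @param report a `study_report`.
#' @param path output file path.
#' @param format one of `"json"`, `"tsv"`, `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv",
                                                  "markdown")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else if (format == "tsv") {
    s <- report$summary
    tab <- data.frame(sample = s$sample, cn_agreement = s$cn_agreement,
                      loh_agreement = s$loh_agreement, qc_pass = s$qc_pass,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    s <- report$summary
    fmt_pct <- function(v) {
      if (is.na(v)) "n/a" else sprintf("%.1f%%", v)
    }
    lines <- c(
      "# Cross-laboratory study summary", "",
      "| statistic | value |", "| --- | --- |",
      sprintf("| triplicates | %d |", s$n_triplicates),
      sprintf("| QC-passing triplicates | %d |", s$n_qc_pass),
      sprintf("| median CN agreement | %s |", fmt_pct(s$median_cn_agreement)),
      sprintf("| mean CN agreement | %s |", fmt_pct(s$mean_cn_agreement)),
      sprintf("| median LOH agreement | %s |",
              fmt_pct(s$median_loh_agreement)),
      sprintf("| mean LOH agreement | %s |", fmt_pct(s$mean_loh_agreement)),
      sprintf("| mean ploidy concordance | %s |",
              fmt_pct(s$mean_ploidy_concordance)),
      sprintf("| mean ACF concordance | %s |",
              fmt_pct(s$mean_acf_concordance)),
      sprintf("| mean SM concordance | %s |",
              fmt_pct(s$mean_sm_concordance)))
    if (!is.null(report$sensitivity)) {
      lines <- c(lines, sprintf("| weighted mean SM sensitivity | %s |",
                                fmt_pct(report$sensitivity$weighted_mean)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
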