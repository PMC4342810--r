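#' Median absolute pairwise difference (MAPD)
#'
#' The per-run noise metric: the median of |L(i+1) - L(i)| over adjacent
#' probe pairs in genome order. Pairs spanning a chromosome boundary are
#' excluded — adjacency is only meaningful within a chromosome. For i.i.d.
#' Gaussian noise of sd sigma the statistic converges to
#' sigma * sqrt(2) * qnorm(0.75) ~= 0.954 sigma.
#'
#' @param probes data.frame with columns `chrom`, `pos` and `log2ratio`
#'   (column `probe` optional); positions strictly increasing within a
#'   chromosome.
#' @return non-negative numeric scalar.
#' @export
compute_mapd <- function(probes) {
  req <- c("chrom", "pos", "log2ratio")
  if (!all(req %in% names(probes))) {
    stop("probe series needs columns: ", paste(req, collapse = ", "))
  }
  diffs <- unlist(lapply(split(probes, probes$chrom), function(p) {
    if (nrow(p) < 2) return(numeric(0))
    if (any(diff(p$pos) <= 0)) {
      stop("probe positions must be strictly increasing within a chromosome")
    }
    abs(diff(p$log2ratio))
  }), use.names = FALSE)
  if (length(diffs) == 0) {
    stop("MAPD needs at least 2 probes on some chromosome")
  }
  stats::median(diffs)
}

#' Classify a run's QC metrics as in- or out-of-bounds
#'
#' Defaults follow the assay product guidelines: a run is in-bounds iff
#' MAPD <= 0.3 AND ndSNPQC >= 26 (both boundaries inclusive).
#'
#' @param qc a [qc_metrics()] object, or a numeric MAPD value if `ndsnpqc`
#'   is supplied.
#' @param ndsnpqc ndSNPQC value when `qc` is given as a bare MAPD number.
#' @param max_mapd,min_ndsnpqc configurable thresholds.
#' @return `"in_bounds"` or `"out_of_bounds"`.
#' @examples
#' classify_bounds(qc_metrics(0.3, 26))   # boundary values are in-bounds
#' @export
classify_bounds <- function(qc, ndsnpqc = NULL, max_mapd = 0.3,
                            min_ndsnpqc = 26) {
  if (inherits(qc, "qc_metrics")) {
    mapd <- qc$mapd; nd <- qc$ndsnpqc
  } else {
    mapd <- as.numeric(qc); nd <- as.numeric(ndsnpqc)
  }
  if (mapd <= max_mapd && nd >= min_ndsnpqc) "in_bounds" else "out_of_bounds"
}

#' Read a QC table
#'
#' Tab-delimited `sample  lab  mapd  ndsnpqc`, one row per run.
#'
#' @param path file path.
#' @return data.frame with those four columns.
#' @export
read_qc_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sample", "lab", "mapd", "ndsnpqc")
  if (!all(req %in% names(tab))) {
    stop("QC table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab[c("sample", "lab")])) {
    stop("(sample, lab) pairs must be unique")
  }
  tab
}

#' Test for a laboratory effect on a QC metric
#'
#' One-way ANOVA of the metric across laboratories. When the ANOVA is
#' significant at `alpha`, a pairwise follow-up is run to locate which labs
#' differ: Tukey's HSD at the family level by default, or unadjusted
#' pairwise Welch t-tests (`method = "t"`).
#'
#' @param table QC table (data.frame with `lab` and the metric column).
#' @param metric `"mapd"` or `"ndsnpqc"` (any numeric column name accepted).
#' @param method follow-up flavour, `"tukey"` (default) or `"t"`.
#' @param alpha significance level for triggering the follow-up (default 0.05).
#' @return list of class `anova_result`: `f`, `p`, and `pairwise` (data.frame
#'   `lab1`, `lab2`, `p_adj`, `significant`; empty when the ANOVA is not
#'   significant).
#' @export
lab_effect_test <- function(table, metric = c("mapd", "ndsnpqc"),
                            method = c("tukey", "t"), alpha = 0.05) {
  if (length(metric) > 1) metric <- metric[1]
  method <- match.arg(method)
  if (!metric %in% names(table)) stop("metric column not found: ", metric)
  lab <- factor(table$lab)
  y <- as.numeric(table[[metric]])
  if (nlevels(lab) < 2) stop("need at least two labs")
  counts <- table(lab)
  if (any(counts < 2)) {
    stop("lab(s) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  fit <- stats::aov(y ~ lab)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  # Zero between-group variance: aov returns F = 0 with p = 1; guard NaN from
  # zero within-group variance as well (identical values everywhere).
  if (!is.finite(f)) { f <- 0; p <- 1 }
  pairwise <- data.frame(lab1 = character(), lab2 = character(),
                         p_adj = numeric(), significant = logical(),
                         stringsAsFactors = FALSE)
  if (p < alpha) {
    if (method == "tukey") {
      tk <- stats::TukeyHSD(fit)$lab
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(
        lab1 = vapply(pairs, `[`, character(1), 1),
        lab2 = vapply(pairs, `[`, character(1), 2),
        p_adj = unname(tk[, "p adj"]),
        stringsAsFactors = FALSE)
    } else {
      pt <- stats::pairwise.t.test(y, lab, p.adjust.method = "none",
                                   pool.sd = FALSE)$p.value
      idx <- which(!is.na(pt), arr.ind = TRUE)
      pairwise <- data.frame(
        lab1 = rownames(pt)[idx[, 1]],
        lab2 = colnames(pt)[idx[, 2]],
        p_adj = pt[idx],
        stringsAsFactors = FALSE)
    }
    pairwise$significant <- pairwise$p_adj < alpha
  }
  structure(list(metric = metric, f = f, p = p, method = method,
                 pairwise = pairwise),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA on %s: F = %.4g, p = %.4g\n", x$metric, x$f, x$p))
  if (nrow(x$pairwise)) {
    cat("pairwise follow-up (", x$method, "):\n", sep = "")
    print(x$pairwise)
  }
  invisible(x)
}

#' Within- versus between-sample variance decomposition
#'
#' Compares the mean of within-sample (within-triplicate) variances of a QC
#' metric with the global variance over all runs pooled. A global variance an
#' order of magnitude above the mean within-sample variance indicates that
#' intrinsic sample quality, not laboratory environment, dominates the
#' metric's spread. Sample variance uses the n-1 denominator throughout.
#'
#' @param table QC table with `sample` and the metric column.
#' @param metric metric column name.
#' @return list of class `variance_decomposition`: `within` (mean of
#'   per-sample variances) and `global` (pooled variance).
#' @export
variance_decomposition <- function(table, metric = c("mapd", "ndsnpqc")) {
  if (length(metric) > 1) metric <- metric[1]
  if (!metric %in% names(table)) stop("metric column not found: ", metric)
  y <- as.numeric(table[[metric]])
  groups <- split(y, table$sample)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("sample(s) with a single run: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  structure(list(within = mean(vapply(groups, stats::var, numeric(1))),
                 global = stats::var(y)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("mean within-sample variance %.3g, global variance %.3g\n",
              x$within, x$global))
  invisible(x)
}
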