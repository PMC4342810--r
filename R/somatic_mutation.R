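#' Mutation call tiers
#'
#' @return the three call tiers in increasing order of confidence.
#' @export
mutation_call_levels <- function() {
  c("UNDETECTED", "LOWER_CONFIDENCE", "HIGH_CONFIDENCE")
}

#' Read a somatic-mutation panel definition
#'
#' Tab-delimited `sm_id  gene  lower_threshold  high_threshold`, one row per
#' somatic mutation (SM). Each SM carries its own pair of mutation-score
#' thresholds separating the undetected / lower-confidence /
#' high-confidence tiers; thresholds are user-adjustable, so a panel read
#' from disk may be edited before use.
#'
#' @param path file path; defaults to the representative 74-SM panel shipped
#'   with the package (placeholder thresholds — calibrate for real use).
#' @return data.frame with the four columns; `lower_threshold <
#'   high_threshold` enforced per SM.
#' @export
read_sm_panel <- function(path = system.file("extdata",
                                             "sm_panel_synthetic.tsv",
                                             package = "cnconcord")) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sm_id", "gene", "lower_threshold", "high_threshold")
  if (!all(req %in% names(tab))) {
    stop("panel needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$sm_id)) stop("sm_id values must be unique")
  if (any(tab$lower_threshold >= tab$high_threshold)) {
    stop("each SM needs lower_threshold < high_threshold")
  }
  tab
}

#' Classify a mutation score into a three-tier call
#'
#' A score below the SM's lower-confidence threshold is `UNDETECTED`; at or
#' above it but below the high-confidence threshold, `LOWER_CONFIDENCE`; at
#' or above the high threshold, `HIGH_CONFIDENCE`. A score exactly at a
#' threshold takes the higher tier. Classification is monotone in the
#' score.
#'
#' @param score numeric mutation score(s).
#' @param lower,high the SM's thresholds (`lower < high`). Alternatively
#'   pass a single panel row via `entry`.
#' @param entry optional one-row data.frame with `lower_threshold` and
#'   `high_threshold` columns (overrides `lower`/`high`).
#' @return factor with levels [mutation_call_levels()], same length as
#'   `score`.
#' @export
classify_mutation <- function(score, lower, high, entry = NULL) {
  if (!is.null(entry)) {
    lower <- entry$lower_threshold
    high <- entry$high_threshold
  }
  if (!is.finite(lower) || !is.finite(high) || lower >= high) {
    stop("need finite thresholds with lower < high")
  }
  score <- as.numeric(score)
  if (any(!is.finite(score))) stop("mutation scores must be finite")
  out <- ifelse(score >= high, "HIGH_CONFIDENCE",
         ifelse(score >= lower, "LOWER_CONFIDENCE", "UNDETECTED"))
  factor(out, levels = mutation_call_levels())
}

#' Sensitivity of mutation calls against orthogonal validation
#'
#' Given the calls made on runs orthogonally pre-validated as positive for
#' an SM, sensitivity is the percentage called `HIGH_CONFIDENCE`. Under
#' this stringent convention lower-confidence calls count as negative, so
#' pre-validation false positives deflate (never inflate) the estimate.
#'
#' @param calls vector of mutation calls (factor or character using
#'   [mutation_call_levels()]).
#' @return list of class `sensitivity_result`: `n`, `n_high`, `sensitivity`
#'   (exact percentage) and `rounded` (nearest-integer percent, the
#'   conventional display value).
#' @examples
#' sensitivity(rep("HIGH_CONFIDENCE", 73))$rounded  # 100
#' @export
sensitivity <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) == 0) stop("need at least one call")
  bad <- setdiff(unique(calls), mutation_call_levels())
  if (length(bad)) stop("unknown call value(s): ", paste(bad, collapse = ", "))
  n_high <- sum(calls == "HIGH_CONFIDENCE")
  s <- 100 * n_high / length(calls)
  structure(list(n = length(calls), n_high = n_high, sensitivity = s,
                 rounded = round(s)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity %d%% (%d high-confidence of %d pre-validated runs)\n",
              x$rounded, x$n_high, x$n))
  invisible(x)
}

#' Panel-wide mean sensitivity weighted by validated run counts
#'
#' Each SM's sensitivity is weighted by the number of sample runs
#' pre-validated for it, so SMs validated in many runs dominate:
#' sum(n_i * s_i) / sum(n_i).
#'
#' @param records data.frame with columns `sm_id`, `n` (> 0 validated runs)
#'   and `sensitivity` (percent).
#' @return weighted mean sensitivity in percent (full precision).
#' @export
weighted_mean_sensitivity <- function(records) {
  req <- c("sm_id", "n", "sensitivity")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) == 0) stop("need at least one SM record")
  if (any(records$n <= 0)) stop("each SM needs n > 0 validated runs")
  sum(records$n * records$sensitivity) / sum(records$n)
}

#' Read a mutation score matrix
#'
#' Tab-delimited: columns `sample`, `lab`, then one column per SM id
#' (`.` and special characters in ids survive via check.names = FALSE).
#'
#' @param path file path.
#' @return data.frame, one row per run.
#' @export
read_sm_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  if (!all(c("sample", "lab") %in% names(tab))) {
    stop("score table needs 'sample' and 'lab' columns")
  }
  tab
}

#' Read an orthogonal validation truth table
#'
#' Tab-delimited `sample  sm_id  positive  method`; `positive` in 0/1.
#'
#' @param path file path.
#' @return data.frame with logical `positive`.
#' @export
read_sm_truth <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sample", "sm_id", "positive")
  if (!all(req %in% names(tab))) {
    stop("truth table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab[c("sample", "sm_id")])) {
    stop("(sample, sm_id) pairs must be unique")
  }
  tab$positive <- tab$positive != 0
  tab
}

#' Cross-laboratory mutation-call concordance
#'
#' For every triplicate whose three runs all pass the ndSNPQC filter,
#' classifies each panel SM's score in each run and scores the triple of
#' calls with max-agreement concordance (largest agreeing group / 3; 33,
#' 66 or 100). Returns the per-SM mean across passing triplicates and the
#' grand mean pooled over all (triplicate x SM) cells.
#'
#' @param triplicates list of [triplicate_set()]s whose runs carry `scores`.
#' @param panel panel data.frame ([read_sm_panel()]).
#' @param ndsnpqc_min QC filter threshold (default 26); runs without QC
#'   metrics fail the filter.
#' @return list of class `sm_concordance`: `per_cell` (data.frame sample x
#'   sm_id with the concordance percentage), `per_sm` (mean per SM),
#'   `grand_mean`, `n_triplicates_used`.
#' @export
sm_concordance_table <- function(triplicates, panel, ndsnpqc_min = 26) {
  stopifnot(all(vapply(triplicates, inherits, logical(1), "triplicate_set")))
  passing <- Filter(function(t) {
    all(vapply(t$runs, function(r) {
      !is.null(r$qc) && r$qc$ndsnpqc >= ndsnpqc_min
    }, logical(1)))
  }, triplicates)
  if (length(passing) == 0) {
    stop("no triplicate passes the ndSNPQC >= ", ndsnpqc_min, " filter")
  }
  cells <- do.call(rbind, lapply(passing, function(t) {
    do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      sm <- panel$sm_id[i]
      scores <- vapply(t$runs, function(r) {
        if (is.null(r$scores) || !sm %in% names(r$scores)) NA_real_
        else r$scores[[sm]]
      }, numeric(1))
      if (anyNA(scores)) return(NULL)
      calls <- classify_mutation(scores, panel$lower_threshold[i],
                                 panel$high_threshold[i])
      data.frame(sample = t$sample, sm_id = sm,
                 concordance = categorical_concordance(
                   as.character(calls), "max_agreement")$percentage,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(cells) || nrow(cells) == 0) {
    stop("no (triplicate, SM) cell had scores in all three runs")
  }
  per_sm <- stats::aggregate(concordance ~ sm_id, cells, mean)
  structure(list(per_cell = cells, per_sm = per_sm,
                 grand_mean = mean(cells$concordance),
                 n_triplicates_used = length(passing)),
            class = "sm_concordance")
}

#' @export
print.sm_concordance <- function(x, ...) {
  cat(sprintf("SM concordance over %d QC-passing triplicates: grand mean %.1f%%\n",
              x$n_triplicates_used, x$grand_mean))
  invisible(x)
}
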