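#' Read gene regions from a BED4 file
#'
#' `chrom  start  end  gene`, 0-based half-open on disk (BED convention),
#' no header; `#` comment lines ignored.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 4) stop("BED4 needs chrom, start, end, gene columns")
  out <- data.frame(gene = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("gene regions must satisfy start < end")
  out
}

#' Genome-wide copy-number baseline of a profile
#'
#' The length-weighted median of segment CN values over autosomes: the
#' smallest CN value at which at least half the covered autosomal length is
#' at or below it. Used as the denominator when scoring focal
#' amplifications, so a tetraploid genome is not wall-to-wall "amplified".
#'
#' @param profile a [seg_profile()].
#' @param include_sex include sex chromosomes (default FALSE).
#' @return numeric baseline CN.
#' @export
genome_baseline <- function(profile, include_sex = FALSE) {
  stopifnot(inherits(profile, "seg_profile"))
  seg <- profile$segments
  if (!include_sex) seg <- seg[!is_sex_chrom(seg$chrom), , drop = FALSE]
  if (nrow(seg) == 0) stop("no autosomal coverage in profile")
  weighted_median(seg$cn, seg$end - seg$start)
}

# Length-weighted median: lower weighted median (smallest value whose
# cumulative weight reaches half the total); midpoint convention when the
# half falls exactly between two values.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  if (cw[i] == half && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Detect high focal amplifications over gene regions
#'
#' For each gene, the maximum CN among segments overlapping the gene by at
#' least 1 bp (amplifications are defined by their peak) is divided by the
#' genome baseline; a gene is flagged when the ratio strictly exceeds the
#' threshold (default 2.2). Genes with no overlapping segment are omitted.
#'
#' @param profile a [seg_profile()].
#' @param genes gene-region data.frame ([read_gene_bed()]).
#' @param threshold flagging ratio (default 2.2, strict inequality).
#' @param baseline optional precomputed baseline; default
#'   [genome_baseline()] of the profile.
#' @return data.frame: `gene`, `max_cn`, `baseline`, `ratio`, `flagged`.
#' @export
detect_hfa <- function(profile, genes, threshold = 2.2, baseline = NULL) {
  stopifnot(inherits(profile, "seg_profile"))
  if (is.null(baseline)) baseline <- genome_baseline(profile)
  if (baseline == 0) stop("genome baseline is zero; ratio undefined")
  gr_seg <- profile_granges(profile)
  gr_gene <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = profile$build$chrom),
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
  if (length(hits) == 0) {
    return(data.frame(gene = character(), max_cn = numeric(),
                      baseline = numeric(), ratio = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  max_cn <- tapply(gr_seg$cn[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
  idx <- as.integer(names(max_cn))
  out <- data.frame(gene = genes$gene[idx],
                    max_cn = as.numeric(max_cn),
                    baseline = baseline,
                    stringsAsFactors = FALSE)
  out$ratio <- out$max_cn / baseline
  out$flagged <- out$ratio > threshold
  rownames(out) <- NULL
  out
}

#' Detect copy-neutral LOH regions
#'
#' Maximal merged intervals where the LOH flag is set and the CN call is
#' normal diploid (`ND`) — acquired uniparental disomy. LOH over a gained
#' or lost segment is not copy-neutral and is not reported. Abutting
#' qualifying segments are merged.
#'
#' @param profile a [seg_profile()].
#' @param genes optional gene-region data.frame; when given, each region is
#'   annotated with the genes it overlaps.
#' @param eps diploid-call tolerance ([cn_call()]).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open), and
#'   `genes` (comma-separated, when `genes` supplied).
#' @export
detect_cnnloh <- function(profile, genes = NULL, eps = 1e-6) {
  stopifnot(inherits(profile, "seg_profile"))
  seg <- profile$segments
  keep <- seg$loh & cn_call(seg$cn, eps) == "ND"
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    if (!is.null(genes)) out$genes <- character()
    return(out)
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = factor(seg$chrom, levels = profile$build$chrom),
    ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    gr_gene <- GenomicRanges::GRanges(
      seqnames = factor(genes$chrom, levels = profile$build$chrom),
      ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
    hits <- GenomicRanges::findOverlaps(gr, gr_gene)
    out$genes <- vapply(seq_len(nrow(out)), function(i) {
      g <- genes$gene[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      paste(g, collapse = ",")
    }, character(1))
  }
  out
}

#' Somatic mutations co-occurring with copy-neutral LOH
#'
#' Reports every called mutation whose genomic locus intersects a
#' copy-neutral LOH region of the same profile — the pattern of a mutation
#' whose wild-type allele was lost and replaced by the mutant copy. Only
#' `HIGH_CONFIDENCE` calls count by default, consistent with the stringent
#' sensitivity convention; set `include_lower = TRUE` to also report
#' lower-confidence calls. Mutations with no known locus are skipped with
#' a warning.
#'
#' @param profile a [seg_profile()].
#' @param sm_calls named vector of mutation calls keyed by SM id.
#' @param sm_loci data.frame mapping SM ids to regions: columns `sm_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param include_lower also report LOWER_CONFIDENCE calls (default FALSE).
#' @param eps diploid-call tolerance.
#' @return data.frame: `sm_id`, `call`, `chrom`, `start`, `end` of the
#'   CNNLOH region hit.
#' @export
sm_in_cnnloh <- function(profile, sm_calls, sm_loci, include_lower = FALSE,
                         eps = 1e-6) {
  wanted <- "HIGH_CONFIDENCE"
  if (include_lower) wanted <- c(wanted, "LOWER_CONFIDENCE")
  calls <- as.character(sm_calls)
  names(calls) <- names(sm_calls)
  called <- names(calls)[calls %in% wanted]
  empty <- data.frame(sm_id = character(), call = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  if (length(called) == 0) return(empty)
  unknown <- setdiff(called, sm_loci$sm_id)
  if (length(unknown)) {
    warning("no locus known for SM(s), skipped: ",
            paste(unknown, collapse = ", "))
    called <- setdiff(called, unknown)
  }
  if (length(called) == 0) return(empty)
  regions <- detect_cnnloh(profile, eps = eps)
  if (nrow(regions) == 0) return(empty)
  loci <- sm_loci[match(called, sm_loci$sm_id), , drop = FALSE]
  gr_reg <- GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = profile$build$chrom),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
  gr_loc <- GenomicRanges::GRanges(
    seqnames = factor(loci$chrom, levels = profile$build$chrom),
    ranges = IRanges::IRanges(start = loci$start + 1, end = loci$end))
  hits <- GenomicRanges::findOverlaps(gr_loc, gr_reg)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(sm_id = called[qi],
             call = calls[called[qi]],
             chrom = regions$chrom[si],
             start = regions$start[si],
             end = regions$end[si],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort recurrence of a flagged gene amplification
#'
#' Fraction of samples in which the gene carries a flagged focal
#' amplification, as an integer percentage.
#'
#' @param cohort_calls list (one element per sample) of [detect_hfa()]
#'   outputs.
#' @param gene gene symbol.
#' @return list: `n_flagged`, `n_total`, `percentage` (nearest integer).
#' @examples
#' # 12 of 28 samples flagged -> 43%
#' @export
recurrence <- function(cohort_calls, gene) {
  if (length(cohort_calls) == 0) stop("cohort must be non-empty")
  flagged <- vapply(cohort_calls, function(calls) {
    any(calls$flagged[calls$gene == gene])
  }, logical(1))
  n <- length(cohort_calls)
  list(gene = gene, n_flagged = sum(flagged), n_total = n,
       percentage = round(100 * sum(flagged) / n))
}

#' Samples with multiple clinically actionable amplifications
#'
#' Flags samples in which at least `min_genes` genes from a user-supplied
#' actionable-gene list carry flagged focal amplifications.
#'
#' @param cohort_calls list (one element per sample, named by sample id) of
#'   [detect_hfa()] outputs.
#' @param actionable_genes character vector of gene symbols.
#' @param min_genes minimum number of flagged actionable genes (default 2).
#' @return data.frame: `sample`, `n_actionable_flagged`, `genes`
#'   (comma-separated), `multiple` flag.
#' @export
multiple_actionable <- function(cohort_calls, actionable_genes,
                                min_genes = 2) {
  ids <- names(cohort_calls)
  if (is.null(ids)) ids <- as.character(seq_along(cohort_calls))
  rows <- lapply(seq_along(cohort_calls), function(i) {
    calls <- cohort_calls[[i]]
    g <- unique(calls$gene[calls$flagged & calls$gene %in% actionable_genes])
    data.frame(sample = ids[i], n_actionable_flagged = length(g),
               genes = paste(sort(g), collapse = ","),
               multiple = length(g) >= min_genes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
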