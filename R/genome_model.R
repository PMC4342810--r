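#' Construct a genome build
#'
#' A genome build is the ordered set of chromosome names and lengths that all
#' profiles in an analysis share. Chromosome order is the order given here
#' (never lexicographic), so genome-wide concatenation is deterministic.
#'
#' @param chrom character vector of unique chromosome names, in genome order.
#' @param length integer-like vector of chromosome lengths in bp, all > 0.
#' @return An object of class `genome_build`: a data.frame with columns
#'   `chrom` and `length`, rows in genome order.
#' @examples
#' genome_build(c("chr1", "chr2"), c(1e7, 5e6))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("genome build needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Read a genome build from a two-column TSV
#'
#' Expects tab-delimited `chrom<TAB>length` with or without a header line;
#' a header is detected by a non-numeric second field in the first row.
#'
#' @param path file path.
#' @return A [genome_build()] object.
#' @export
read_genome_build <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE, comment.char = "#")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE, comment.char = "#")
  genome_build(tab[[1]], tab[[2]])
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome build:", nrow(x), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp\n")
  invisible(x)
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  build$length[i]
}

#' Identify sex chromosomes by name
#'
#' Sex chromosomes are carried in profiles but excluded from agreement
#' denominators and genome baselines by default (male X hemizygosity would
#' distort diploid-relative calls).
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

#' Translate numeric copy number to a categorical CN call
#'
#' Copy-number values estimated from tumour profiles are simplified to five
#' categorical calls before agreement is assessed: `HIGH_LOSS` (CN < 1),
#' `LOSS` (1 <= CN < 2), `ND` (normal diploid, CN = 2 within tolerance
#' `eps`), `GAIN` (2 < CN <= 3) and `HIGH_GAIN` (CN > 3). The tolerance
#' keeps floating-point representations of 2 from being misclassified.
#'
#' @param cn numeric vector of non-negative copy-number values.
#' @param eps tolerance on |CN - 2| for the diploid call (default 1e-6).
#' @return factor with levels `HIGH_LOSS`, `LOSS`, `ND`, `GAIN`, `HIGH_GAIN`.
#' @examples
#' cn_call(c(0.5, 1, 2, 3, 3.5))
#' @export
cn_call <- function(cn, eps = 1e-6) {
  cn <- as.numeric(cn)
  if (any(!is.finite(cn))) stop("copy-number values must be finite")
  if (any(cn < 0)) stop("copy-number values must be non-negative")
  out <- ifelse(abs(cn - 2) <= eps, "ND",
         ifelse(cn < 1, "HIGH_LOSS",
         ifelse(cn < 2, "LOSS",
         ifelse(cn <= 3, "GAIN", "HIGH_GAIN"))))
  factor(out, levels = cn_call_levels())
}

#' @rdname cn_call
#' @export
cn_call_levels <- function() {
  c("HIGH_LOSS", "LOSS", "ND", "GAIN", "HIGH_GAIN")
}

#' Construct a segmented profile
#'
#' A segmented profile is one laboratory's run of one sample: an ordered,
#' non-overlapping set of genomic segments each carrying a numeric copy
#' number and an LOH flag. Coordinates are 0-based half-open internally.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `cn`,
#'   `loh` (logical or 0/1).
#' @param build a [genome_build()].
#' @param sample sample identifier.
#' @param lab laboratory identifier.
#' @return An object of class `seg_profile`.
#' @export
seg_profile <- function(segments, build, sample = NA_character_,
                        lab = NA_character_) {
  stopifnot(inherits(build, "genome_build"))
  req <- c("chrom", "start", "end", "cn", "loh")
  if (!all(req %in% names(segments))) {
    stop("segments need columns: ", paste(req, collapse = ", "))
  }
  seg <- data.frame(chrom = as.character(segments$chrom),
                    start = as.numeric(segments$start),
                    end = as.numeric(segments$end),
                    cn = as.numeric(segments$cn),
                    loh = as.logical(segments$loh),
                    stringsAsFactors = FALSE)
  if (nrow(seg) > 0) {
    ci <- match(seg$chrom, build$chrom)
    if (anyNA(ci)) {
      stop("unknown chromosome(s): ",
           paste(unique(seg$chrom[is.na(ci)]), collapse = ", "))
    }
    if (any(seg$start >= seg$end)) stop("segments must satisfy start < end")
    if (any(seg$start < 0)) stop("segment start before chromosome start")
    too_far <- seg$end > build$length[ci]
    if (any(too_far)) {
      stop("segment beyond chromosome length: ",
           paste0(seg$chrom[too_far][1], ":", seg$start[too_far][1], "-",
                  seg$end[too_far][1]))
    }
    seg <- seg[order(ci, seg$start), , drop = FALSE]
    rownames(seg) <- NULL
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      if (nrow(s) > 1) {
        bad <- which(s$start[-1] < s$end[-nrow(s)])
        if (length(bad)) {
          stop(sprintf("overlapping segments on %s: [%g,%g) and [%g,%g)",
                       ch, s$start[bad[1]], s$end[bad[1]],
                       s$start[bad[1] + 1], s$end[bad[1] + 1]))
        }
      }
    }
    if (any(!is.finite(seg$cn)) || any(seg$cn < 0)) {
      stop("segment CN values must be finite and non-negative")
    }
    if (anyNA(seg$loh)) stop("LOH flags must be TRUE/FALSE (or 0/1)")
  }
  structure(list(sample = as.character(sample), lab = as.character(lab),
                 segments = seg, build = build),
            class = "seg_profile")
}

#' @export
print.seg_profile <- function(x, ...) {
  cat(sprintf("segmented profile: sample %s, lab %s, %d segments, %s bp covered\n",
              x$sample, x$lab, nrow(x$segments),
              format(sum(x$segments$end - x$segments$start), big.mark = ",")))
  invisible(x)
}

# GRanges view of a profile's segments (internal 0-based half-open ->
# 1-based closed GRanges).
profile_granges <- function(profile) {
  seg <- profile$segments
  GenomicRanges::GRanges(
    seqnames = factor(seg$chrom, levels = profile$build$chrom),
    ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end),
    cn = seg$cn, loh = seg$loh)
}

#' Read a segmented profile from a SEG file
#'
#' The on-disk dialect is tab-delimited with header
#' `sample  chrom  start  end  cn  loh` (`loh` in 0/1), coordinates 1-based
#' inclusive (IGV SEG convention); `#`-prefixed lines are ignored. Internally
#' coordinates become 0-based half-open.
#'
#' @param path file path.
#' @param build a [genome_build()].
#' @param lab laboratory id to record (default taken from the file name's
#'   `sample` column only covers the sample id).
#' @return A [seg_profile()].
#' @export
read_seg_profile <- function(path, build, lab = NA_character_) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("sample", "chrom", "start", "end", "cn", "loh")
  if (!all(req %in% names(tab))) {
    stop("SEG file must have columns: ", paste(req, collapse = ", "))
  }
  sample_id <- if (nrow(tab) > 0) as.character(tab$sample[1]) else NA_character_
  seg <- data.frame(chrom = tab$chrom,
                    start = tab$start - 1,  # 1-based inclusive -> 0-based
                    end = tab$end,          # inclusive end -> exclusive end
                    cn = tab$cn,
                    loh = tab$loh != 0,
                    stringsAsFactors = FALSE)
  seg_profile(seg, build, sample = sample_id, lab = lab)
}

#' Write a segmented profile as a SEG file
#'
#' Inverse of [read_seg_profile()]: coordinates written 1-based inclusive.
#' Round-trip through read/write is the identity on valid profiles.
#'
#' @param profile a [seg_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg_profile <- function(profile, path) {
  stopifnot(inherits(profile, "seg_profile"))
  seg <- profile$segments
  out <- data.frame(sample = rep(profile$sample, nrow(seg)),
                    chrom = seg$chrom,
                    start = seg$start + 1,
                    end = seg$end,
                    cn = seg$cn,
                    loh = as.integer(seg$loh),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Covered span of a profile
#'
#' The minimal sorted list of disjoint intervals whose union equals the union
#' of segment extents; abutting segments are merged. Total length equals the
#' sum of segment lengths because segments never overlap.
#'
#' @param profile a [seg_profile()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
covered_span <- function(profile) {
  stopifnot(inherits(profile, "seg_profile"))
  if (nrow(profile$segments) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  red <- GenomicRanges::reduce(profile_granges(profile))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1,
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

#' Per-run quality-control metrics
#'
#' @param mapd median absolute pairwise difference of genome-adjacent probe
#'   log2 ratios (noise metric), >= 0.
#' @param ndsnpqc vendor-computed normal-diploid SNP QC score, >= 0; consumed
#'   as given, never computed here.
#' @return list of class `qc_metrics`.
#' @export
qc_metrics <- function(mapd, ndsnpqc) {
  mapd <- as.numeric(mapd); ndsnpqc <- as.numeric(ndsnpqc)
  if (!is.finite(mapd) || mapd < 0) stop("mapd must be a non-negative number")
  if (!is.finite(ndsnpqc) || ndsnpqc < 0) {
    stop("ndsnpqc must be a non-negative number")
  }
  structure(list(mapd = mapd, ndsnpqc = ndsnpqc), class = "qc_metrics")
}

#' Tumour ploidy / aberrant-cell-fraction estimate
#'
#' Output of the upstream ploidy/purity estimator, consumed as given. ACF is
#' a percentage in (0, 100] or the label `"homogeneous"` (no aberrant
#' fraction resolvable); ploidy is a positive integer or NA.
#'
#' @param ploidy positive integer or NA.
#' @param acf numeric percentage in (0, 100], the string "homogeneous", or NA.
#' @return list of class `tuscan_estimate`.
#' @export
tuscan_estimate <- function(ploidy = NA, acf = NA) {
  if (!is.na(ploidy)) {
    ploidy <- as.numeric(ploidy)
    if (!is.finite(ploidy) || ploidy <= 0 || ploidy != round(ploidy)) {
      stop("ploidy must be a positive integer or NA")
    }
  }
  if (length(acf) == 1 && !is.na(acf) && !identical(acf, "homogeneous")) {
    acf <- as.numeric(acf)
    if (!is.finite(acf) || acf <= 0 || acf > 100) {
      stop("numeric acf must be in (0, 100]")
    }
  }
  structure(list(ploidy = ploidy, acf = acf), class = "tuscan_estimate")
}

#' One laboratory's run of one sample
#'
#' Bundles the segmented profile with its QC metrics, ploidy/ACF estimate and
#' per-mutation scores.
#'
#' @param profile a [seg_profile()].
#' @param qc a [qc_metrics()] or NULL.
#' @param tuscan a [tuscan_estimate()] or NULL.
#' @param scores named numeric vector of mutation scores keyed by SM id, or
#'   NULL.
#' @param sample,lab identifiers; default taken from the profile.
#' @return list of class `sample_run`.
#' @export
sample_run <- function(profile, qc = NULL, tuscan = NULL, scores = NULL,
                       sample = profile$sample, lab = profile$lab) {
  stopifnot(inherits(profile, "seg_profile"))
  if (!is.null(qc)) stopifnot(inherits(qc, "qc_metrics"))
  if (!is.null(tuscan)) stopifnot(inherits(tuscan, "tuscan_estimate"))
  if (!is.null(scores) && is.null(names(scores))) {
    stop("mutation scores must be named by SM id")
  }
  structure(list(sample = as.character(sample), lab = as.character(lab),
                 profile = profile, qc = qc, tuscan = tuscan,
                 scores = scores),
            class = "sample_run")
}

#' The three runs of one sample across laboratories
#'
#' @param runs list of exactly three [sample_run()]s sharing one sample id,
#'   with distinct lab ids.
#' @return list of class `triplicate_set`.
#' @export
triplicate_set <- function(runs) {
  if (length(runs) != 3) stop("a triplicate has exactly three runs")
  stopifnot(all(vapply(runs, inherits, logical(1), "sample_run")))
  samples <- vapply(runs, function(r) r$sample, character(1))
  labs <- vapply(runs, function(r) r$lab, character(1))
  if (length(unique(samples)) != 1) {
    stop("all three runs must share one sample id")
  }
  if (anyDuplicated(labs)) stop("the three runs must come from distinct labs")
  structure(list(sample = samples[1], runs = runs), class = "triplicate_set")
}

#' @export
print.triplicate_set <- function(x, ...) {
  cat(sprintf("triplicate: sample %s, labs %s\n", x$sample,
              paste(vapply(x$runs, function(r) r$lab, character(1)),
                    collapse = "/")))
  invisible(x)
}
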