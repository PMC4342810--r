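# Independent oracles and fixture builders shared across test files.

# Per-base brute-force agreement: evaluates the call at every single base of
# the genome, independent of the interval-sweep implementation. Only viable
# on tiny genomes (<= ~10 kb).
brute_force_agreement <- function(profiles, channel = "CN", eps = 1e-6,
                                  include_sex = FALSE) {
  build <- profiles[[1]]$build
  agree_len <- 0
  denom <- 0
  for (ci in seq_len(nrow(build))) {
    ch <- build$chrom[ci]
    if (!include_sex && is_sex_chrom(ch)) next
    L <- build$length[ci]
    per <- lapply(profiles, function(p) {
      cn <- rep(NA_real_, L)
      loh <- rep(NA, L)
      seg <- p$segments[p$segments$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(seg))) {
        idx <- (seg$start[i] + 1):seg$end[i]
        cn[idx] <- seg$cn[i]
        loh[idx] <- seg$loh[i]
      }
      list(cn = cn, loh = loh)
    })
    covered <- Reduce(`&`, lapply(per, function(v) !is.na(v$cn)))
    if (!any(covered)) next
    vals <- if (channel == "CN") {
      vapply(per, function(v) as.character(cn_call(v$cn[covered], eps)),
             character(sum(covered)))
    } else {
      vapply(per, function(v) v$loh[covered], logical(sum(covered)))
    }
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    agree <- apply(vals, 1, function(r) all(r == r[1]))
    agree_len <- agree_len + sum(agree)
    denom <- denom + sum(covered)
  }
  list(agreeing_bp = agree_len, denominator_bp = denom,
       percentage = 100 * agree_len / denom)
}

# One-way ANOVA from the explicit sum-of-squares formulas.
anova_oracle <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  k <- nlevels(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Random segmented profile on a (tiny) build: random breakpoints, random CN
# and LOH per segment, optional coverage gaps.
random_profile <- function(build, sample = "S1", lab = "LabA",
                           gap_prob = 0.15) {
  segs <- do.call(rbind, lapply(seq_len(nrow(build)), function(ci) {
    L <- build$length[ci]
    nb <- sample(0:4, 1)
    bounds <- sort(unique(c(0, if (nb > 0) sample(seq_len(L - 1), nb), L)))
    df <- data.frame(chrom = build$chrom[ci],
                     start = utils::head(bounds, -1),
                     end = utils::tail(bounds, -1),
                     stringsAsFactors = FALSE)
    df$cn <- sample(c(0, 1, 2, 2, 2.5, 3, 4), nrow(df), replace = TRUE)
    df$loh <- stats::runif(nrow(df)) < 0.3
    df[stats::runif(nrow(df)) >= gap_prob, , drop = FALSE]
  }))
  seg_profile(segs, build, sample = sample, lab = lab)
}

# A random trio guaranteed to share covered span (retries on empty overlap).
random_trio <- function(build) {
  repeat {
    trio <- lapply(c("LabA", "LabB", "LabC"), function(l) {
      random_profile(build, lab = l)
    })
    ok <- tryCatch({
      breakpoint_union(trio)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(trio)
  }
}

# Quick single-chromosome profile builder for hand fixtures.
quick_profile <- function(build, chrom, start, end, cn, loh = FALSE,
                          sample = "S1", lab = "LabA") {
  seg_profile(data.frame(chrom = chrom, start = start, end = end, cn = cn,
                         loh = loh, stringsAsFactors = FALSE),
              build, sample = sample, lab = lab)
}
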