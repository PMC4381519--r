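#' Local protected background of accessible segments
#'
#' For each MAR, pools the methylated/total counts of every MPR overlapping
#' the window extending `flank` bp beyond the MAR on both sides (0-based
#' half-open; an MPR starting exactly at the window end is excluded).  When
#' no MPR falls in the window the chromosome-wide pooled MPR rate is used
#' and flagged.
#'
#' @param mars Data.frame of MAR segments (`chrom`, `start`, `end`,
#'   `n_meth`, `n_total`).
#' @param mprs Data.frame of MPR segments with the same columns.
#' @param flank Window half-width in bp (default 100000, i.e. +/-100 kb).
#' @return `mars` with added columns `bg_meth`, `bg_total`, `bg_rate`,
#'   `bg_fallback`.
#' @export
local_background <- function(mars, mprs, flank = 100000) {
  mars$bg_meth <- 0
  mars$bg_total <- 0
  mars$bg_fallback <- FALSE
  for (ch in unique(mars$chrom)) {
    mi <- which(mars$chrom == ch)
    pj <- which(mprs$chrom == ch)
    if (!length(pj)) {
      mars$bg_fallback[mi] <- TRUE
      next
    }
    win <- .halfopen_to_iranges(pmax(mars$start[mi] - flank, 0),
                                mars$end[mi] + flank)
    mpr_ir <- .halfopen_to_iranges(mprs$start[pj], mprs$end[pj])
    hits <- IRanges::findOverlaps(win, mpr_ir)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    mars$bg_meth[mi] <- vapply(seq_along(mi), function(i)
      sum(mprs$n_meth[pj][sh[qh == i]]), 0)
    mars$bg_total[mi] <- vapply(seq_along(mi), function(i)
      sum(mprs$n_total[pj][sh[qh == i]]), 0)
    none <- tabulate(qh, length(mi)) == 0
    if (any(none)) {
      mars$bg_fallback[mi[none]] <- TRUE
      mars$bg_meth[mi[none]] <- sum(mprs$n_meth[pj])
      mars$bg_total[mi[none]] <- sum(mprs$n_total[pj])
    }
  }
  mars$bg_rate <- ifelse(mars$bg_total > 0,
                         mars$bg_meth / mars$bg_total, NA_real_)
  mars
}

#' One-tailed binomial test of a MAR against its background
#'
#' Exact upper-tail probability `P[X >= k]` for `X ~ Binomial(n, p0)`:
#' the chance of observing at least the MAR's methylated count if its sites
#' were labeled at the local protected-background rate.
#'
#' @param k Methylated count(s).
#' @param n Total count(s); `n = 0` yields p = 1.
#' @param p0 Background rate(s) in `[0, 1]`.
#' @return Vector of exact p-values.
#' @examples
#' mar_binomial_test(15, 20, 0.5)   # 21700 / 2^20
#' @export
mar_binomial_test <- function(k, n, p0) {
  stopifnot(all(k >= 0), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values; monotone in the input p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values (empty input gives empty output).
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Call nucleosome-depleted regions
#'
#' Scores every MAR against its local MPR background with the exact
#' one-tailed binomial test, corrects across all MARs by Benjamini-Hochberg,
#' and applies the NDR rule: FDR-corrected p-value below `fdr` (default
#' 0.01) and length strictly greater than `min_len` bp (default 100).
#'
#' @param segments Segment data.frame from [segment_calls()] /
#'   [assemble_segments()] (MARs and MPRs together), or a MAR data.frame
#'   already carrying `bg_rate` columns.
#' @param flank Background window half-width in bp.
#' @param fdr Significance cutoff on the q-value.
#' @param min_len NDRs must be strictly longer than this many bp.
#' @return Data.frame of MARs with `bg_rate`, `p_value`, `q_value`,
#'   `is_significant`, `is_ndr`.
#' @export
call_ndrs <- function(segments, flank = 100000, fdr = 0.01, min_len = 100) {
  mars <- segments[segments$state == "MAR", , drop = FALSE]
  if (is.null(mars$bg_rate)) {
    mprs <- segments[segments$state == "MPR", , drop = FALSE]
    mars <- local_background(mars, mprs, flank = flank)
  }
  if (!nrow(mars)) {
    mars$p_value <- numeric(0); mars$q_value <- numeric(0)
    mars$is_significant <- logical(0); mars$is_ndr <- logical(0)
    return(mars)
  }
  p0 <- ifelse(is.na(mars$bg_rate), 1, mars$bg_rate)
  mars$p_value <- mar_binomial_test(mars$n_meth, mars$n_total, p0)
  mars$q_value <- bh_fdr(mars$p_value)
  mars$is_significant <- mars$q_value < fdr
  mars$is_ndr <- mars$is_significant & (mars$end - mars$start > min_len)
  rownames(mars) <- NULL
  mars
}

#' Intersect NDR calls across biological replicates
#'
#' Keeps only NDRs supported in both replicates: calls overlapping by at
#' least 1 bp are paired, the reported interval is the union of the
#' overlapping pair, and transitively overlapping chains are merged into a
#' single interval.
#'
#' @param ndrs_rep1,ndrs_rep2 NDR data.frames (rows with `is_ndr = TRUE`
#'   are used when the column is present).
#' @return Data.frame of replicate-supported intervals with support counts
#'   `n_rep1`, `n_rep2`.
#' @export
intersect_replicates <- function(ndrs_rep1, ndrs_rep2) {
  pick <- function(x) {
    if (!is.null(x$is_ndr)) x <- x[x$is_ndr, , drop = FALSE]
    x[, c("chrom", "start", "end")]
  }
  a <- pick(ndrs_rep1); b <- pick(ndrs_rep2)
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    ira <- .halfopen_to_iranges(ai$start, ai$end)
    irb <- .halfopen_to_iranges(bi$start, bi$end)
    merged <- IRanges::reduce(c(ira, irb), min.gapwidth = 0L)
    na <- IRanges::countOverlaps(merged, ira)
    nb <- IRanges::countOverlaps(merged, irb)
    keep <- na > 0 & nb > 0
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(merged)[keep] - 1L,
      end = IRanges::end(merged)[keep],
      n_rep1 = na[keep], n_rep2 = nb[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_rep1 = integer(0),
                      n_rep2 = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
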