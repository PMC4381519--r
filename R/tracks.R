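#' Z-score normalize a binned signal track
#'
#' Standardizes bin values against the genome-wide mean and standard
#' deviation (population form, dividing by the root mean squared
#' deviation), the normalization applied to ChIP-seq enrichment before
#' cross-sample comparison.  Missing bins stay missing.
#'
#' @param track Data.frame with columns `chrom`, `start`, `end`, `value`
#'   (see [read_bedgraph()]).
#' @return The track with `value` replaced by its z-score.
#' @export
zscore_track <- function(track) {
  v <- track$value
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least 2 non-missing bins")
  m <- mean(v[ok])
  s <- sqrt(mean((v[ok] - m)^2))
  if (s == 0) stop("zero variance: z-score undefined")
  track$value <- (v - m) / s
  track
}

#' Pool cytosine calls into a fixed-width binned track
#'
#' @param calls Cytosine call data.frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin Bin width in bp (default 10).
#' @return bedGraph-style data.frame of pooled levels, one row per covered
#'   bin.
#' @export
bin_calls <- function(calls, chrom_lengths, bin = 10) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    ci <- which(calls$chrom == ch & calls$n_total > 0)
    if (!length(ci)) next
    bi <- calls$pos[ci] %/% bin
    meth <- rowsum(calls$n_meth[ci], bi)
    tot <- rowsum(calls$n_total[ci], bi)
    starts <- as.integer(rownames(meth)) * bin
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = pmin(starts + bin, chrom_lengths[[ch]]),
                            value = meth[, 1] / tot[, 1],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Anchor-aligned profile matrix and metaplot
#'
#' Aggregates a levels source around a set of anchors (NDR centers, TSSs)
#' into a matrix of transcription-oriented positional bins, the input to
#' heatmaps, metaplots and profile clustering.  Minus-strand rows are
#' reversed so column 1 is always the most upstream bin.
#'
#' @param x Either a cytosine call data.frame (per-bin values are pooled
#'   levels over contributing sites) or a binned track data.frame with a
#'   `value` column (per-bin values are means over overlapping track bins).
#' @param anchors Data.frame with `chrom`, `pos` and optionally `strand`
#'   (assumed `"+"` when absent).
#' @param flank Half-width of the window in bp (default 1000).
#' @param bin Bin width in bp (default 10); the matrix has
#'   `2 * flank / bin` columns.
#' @return An object of class `profile_matrix`: list with `matrix` (rows =
#'   anchors), `metaplot` (column means ignoring missing), `offsets`
#'   (bin-start offsets relative to the anchor), `anchors`, `flank`, `bin`.
#'   Anchors on chromosomes absent from `x` are dropped with a warning;
#'   windows extending past position 0 keep `NA` in the clipped bins.
#' @export
aggregate_profile <- function(x, anchors, flank = 1000, bin = 10) {
  stopifnot(flank %% bin == 0)
  is_calls <- all(c("n_meth", "n_total") %in% names(x))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  ncol <- 2L * flank %/% bin
  drop <- !(anchors$chrom %in% unique(x$chrom))
  if (any(drop)) {
    warning(sum(drop), " anchor(s) on chromosomes absent from the signal ",
            "source were dropped")
    anchors <- anchors[!drop, , drop = FALSE]
  }
  nr <- nrow(anchors)
  meth <- matrix(0, nr, ncol)
  tot <- matrix(0, nr, ncol)
  val <- matrix(NA_real_, nr, ncol)
  cnt <- matrix(0, nr, ncol)
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    xi <- which(x$chrom == ch)
    if (is_calls) xi <- xi[x$n_total[xi] > 0]
    if (!length(xi)) next
    wir <- .halfopen_to_iranges(pmax(anchors$pos[ai] - flank, 0),
                                anchors$pos[ai] + flank)
    xir <- if (is_calls) IRanges::IRanges(x$pos[xi] + 1L, width = 1L)
    else .halfopen_to_iranges(x$start[xi], x$end[xi])
    hits <- IRanges::findOverlaps(wir, xir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (!length(qh)) next
    p <- if (is_calls) x$pos[xi][sh]
    else (x$start[xi][sh] + x$end[xi][sh]) / 2
    off <- ifelse(anchors$strand[ai][qh] == "+",
                  p - anchors$pos[ai][qh],
                  anchors$pos[ai][qh] - p)
    cj <- floor((off + flank) / bin) + 1L
    keep <- cj >= 1L & cj <= ncol
    qh <- qh[keep]; sh <- sh[keep]; cj <- cj[keep]
    key <- (cj - 1L) * nr + ai[qh]       # column-major linear index
    if (is_calls) {
      acc <- rowsum(cbind(x$n_meth[xi][sh], x$n_total[xi][sh]), key)
      at <- as.integer(rownames(acc))
      meth[at] <- meth[at] + acc[, 1]
      tot[at] <- tot[at] + acc[, 2]
    } else {
      v <- x$value[xi][sh]
      nz <- !is.na(v)
      acc <- rowsum(cbind(v[nz], 1), key[nz])
      at <- as.integer(rownames(acc))
      old <- val[at]
      val[at] <- ifelse(is.na(old), acc[, 1], old + acc[, 1])
      cnt[at] <- cnt[at] + acc[, 2]
    }
  }
  mat <- if (is_calls) ifelse(tot > 0, meth / tot, NA_real_)
  else ifelse(cnt > 0, val / cnt, NA_real_)
  structure(list(matrix = mat,
                 metaplot = colMeans(mat, na.rm = TRUE),
                 offsets = seq(-flank, flank - bin, by = bin),
                 anchors = anchors, flank = flank, bin = bin),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$matrix), "anchors x", ncol(x$matrix),
      "bins (flank", x$flank, "bp, bin", x$bin, "bp)\n")
  invisible(x)
}

#' Hierarchical clustering of profile rows
#'
#' Average-linkage clustering on Euclidean distances over an optional
#' column restriction (e.g. the bins within +/-250 bp of the anchor),
#' returning cluster labels and the dendrogram leaf order used to render
#' heatmaps.
#'
#' @param x A `profile_matrix` or a plain numeric matrix.
#' @param k Number of clusters.
#' @param restrict_bp Optional `c(min, max)` offset range in bp selecting
#'   the columns used for the distance (requires a `profile_matrix`).
#' @param restrict Optional explicit column indices (alternative to
#'   `restrict_bp`).
#' @return List with `labels` (integer cluster ids), `order` (leaf order)
#'   and the `hclust` tree.  Rows with missing values in the restricted
#'   columns are assigned cluster `NA` with a warning.
#' @export
hcluster_rows <- function(x, k, restrict_bp = NULL, restrict = NULL) {
  mat <- if (inherits(x, "profile_matrix")) x$matrix else x
  if (!is.null(restrict_bp)) {
    if (!inherits(x, "profile_matrix"))
      stop("restrict_bp needs a profile_matrix")
    restrict <- which(x$offsets >= restrict_bp[1] &
                        x$offsets < restrict_bp[2])
  }
  sub <- if (is.null(restrict)) mat else mat[, restrict, drop = FALSE]
  ok <- stats::complete.cases(sub)
  if (sum(ok) < k) stop("fewer complete rows than clusters requested")
  if (!all(ok))
    warning(sum(!ok), " row(s) with missing values excluded from ",
            "clustering")
  tree <- hclust(dist(sub[ok, , drop = FALSE]), method = "average")
  labels <- rep(NA_integer_, nrow(mat))
  labels[ok] <- cutree(tree, k = k)
  list(labels = labels, order = which(ok)[tree$order], tree = tree)
}

#' Megabase-scale window summaries
#'
#' Tiles each chromosome with non-overlapping fixed windows and reports the
#' pooled GCH accessibility, pooled HCG methylation and mean value of each
#' supplied signal track per window, excluding track bins inside CpG
#' islands from the track means.  Windows are ranked (descending) by the
#' chosen column; low-accessibility tails flag candidate partially
#' methylated / heterochromatic domains.
#'
#' @param gch_calls,hcg_calls Cytosine call data.frames.
#' @param tracks Named list of binned track data.frames (values typically
#'   z-scores, see [zscore_track()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window size in bp (default 1e6).
#' @param cgi Optional CpG-island interval data.frame (`chrom`, `start`,
#'   `end`); track bins overlapping a CGI are excluded from track means.
#' @param rank_by Column to rank by (default `"accessibility"`).
#' @param min_coverage Track means for windows with a smaller fraction of
#'   non-missing bins are reported `NA` (default 0.1).
#' @return Data.frame with one row per window, sorted by `rank_by`
#'   descending, with a `rank` column.
#' @export
window_summarize <- function(gch_calls, hcg_calls, tracks = list(),
                             chrom_lengths, window = 1e6, cgi = NULL,
                             rank_by = "accessibility",
                             min_coverage = 0.1) {
  rows <- list()
  for (ch in names(chrom_lengths)) {
    n_win <- ceiling(chrom_lengths[[ch]] / window)
    w <- data.frame(chrom = ch, start = (seq_len(n_win) - 1) * window)
    w$end <- pmin(w$start + window, chrom_lengths[[ch]])
    pool <- function(calls) {
      ci <- which(calls$chrom == ch & calls$n_total > 0)
      wi <- calls$pos[ci] %/% window + 1L
      meth <- vapply(seq_len(n_win), function(i) sum(calls$n_meth[ci][wi == i]), 0)
      tot <- vapply(seq_len(n_win), function(i) sum(calls$n_total[ci][wi == i]), 0)
      ifelse(tot > 0, meth / tot, NA_real_)
    }
    w$accessibility <- pool(gch_calls)
    w$methylation <- pool(hcg_calls)
    for (tn in names(tracks)) {
      tr <- tracks[[tn]]
      ti <- which(tr$chrom == ch)
      excl <- rep(FALSE, length(ti))
      if (!is.null(cgi)) {
        gi <- which(cgi$chrom == ch)
        if (length(gi)) {
          ov <- IRanges::countOverlaps(
            .halfopen_to_iranges(tr$start[ti], tr$end[ti]),
            .halfopen_to_iranges(cgi$start[gi], cgi$end[gi]))
          excl <- ov > 0
        }
      }
      ti <- ti[!excl & !is.na(tr$value[ti])]
      wi <- tr$start[ti] %/% window + 1L
      bw <- if (length(ti)) stats::median(tr$end[ti] - tr$start[ti]) else 1
      w[[tn]] <- vapply(seq_len(n_win), function(i) {
        sel <- wi == i
        cov <- sum(sel) * bw / (w$end[i] - w$start[i])
        if (cov < min_coverage) NA_real_ else mean(tr$value[ti][sel])
      }, 0)
    }
    rows[[ch]] <- w
  }
  out <- do.call(rbind, rows)
  if (!rank_by %in% names(out)) stop("unknown rank_by column: ", rank_by)
  out <- out[order(-out[[rank_by]], out$chrom, out$start), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
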