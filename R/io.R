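#' Classify a cytosine trinucleotide context
#'
#' NOMe-seq partitions cytosines by trinucleotide context: `GCH` (H = A, C or
#' T) reports M.CviPI accessibility, `HCG` reports endogenous CpG
#' methylation, and `GCG` is ambiguous between the two signals and excluded
#' from every analysis.
#'
#' @param trinucleotide Character vector of 3-mers, each centred on the
#'   cytosine and written 5'->3' on the strand that carries the C.
#' @param strand Optional strand vector; entries of `"-"` indicate that the
#'   3-mer is given in plus-strand (reference) orientation and is
#'   reverse-complemented before classification.
#' @return Character vector over `"GCH"`, `"HCG"`, `"GCG"`, `"other"`.
#' @examples
#' classify_context(c("GCA", "ACG", "GCG", "TCT"))
#' @export
classify_context <- function(trinucleotide, strand = "+") {
  tri <- toupper(trinucleotide)
  if (!all(grepl("^[ACGT]{3}$", tri)))
    stop("trinucleotides must be 3-mers over A/C/G/T")
  strand <- rep_len(strand, length(tri))
  rc <- strand == "-"
  if (any(rc)) tri[rc] <- chartr("ACGT", "TGCA", sapply(
    strsplit(tri[rc], ""), function(x) paste(rev(x), collapse = "")))
  if (!all(substr(tri, 2, 2) == "C"))
    stop("centre base must be C on the given strand")
  first <- substr(tri, 1, 1)
  last <- substr(tri, 3, 3)
  out <- rep("other", length(tri))
  out[first == "G" & last != "G"] <- "GCH"
  out[first != "G" & last == "G"] <- "HCG"
  out[first == "G" & last == "G"] <- "GCG"
  out
}

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a cytosine report
#'
#' Reads a six-column TSV of per-cytosine methylation calls (chrom, 0-based
#' position, strand, context, methylated count, total count), validates it,
#' and returns records sorted by chromosome and position.
#'
#' @param path TSV path; `.gz` files are decompressed transparently.
#' @param context_filter Optional character vector of contexts to keep
#'   (e.g. `"GCH"`); ambiguous `GCG` records are dropped whenever a filter is
#'   supplied.
#' @return A data.frame of cytosine calls with columns `chrom`, `pos`,
#'   `strand`, `context`, `n_meth`, `n_total`.
#' @export
read_cytosine_report <- function(path, context_filter = NULL) {
  con <- .open_maybe_gz(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    read.table(con, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "integer", "character",
                              "character", "integer", "integer"),
               col.names = c("chrom", "pos", "strand", "context",
                             "n_meth", "n_total")),
    error = function(e) stop("malformed cytosine report '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(is.na(df$pos) | is.na(df$n_meth) | is.na(df$n_total) |
                 !df$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed cytosine report '", path, "' at line ", bad[1])
  over <- which(df$n_meth > df$n_total)
  if (length(over))
    stop("n_meth > n_total in '", path, "' at line ", over[1])
  if (!is.null(context_filter)) df <- df[df$context %in% context_filter, ]
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_cytosine_report
#' @param calls Data.frame of cytosine calls (see [read_cytosine_report()]).
#' @export
write_cytosine_report <- function(calls, path) {
  .stopifnot_calls(calls)
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  write.table(calls[, c("chrom", "pos", "strand", "context",
                        "n_meth", "n_total")],
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.check_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop("intervals need columns chrom, start, end")
  if (any(x$start >= x$end))
    stop("empty or inverted interval: start must be < end (0-based half-open)")
  invisible(x)
}

#' BED input and output
#'
#' Minimal BED3/BED6 reader and writer.  Coordinates are 0-based half-open
#' both on disk and in the returned data.frame, so round trips are exact.
#'
#' @param path File path (`.gz` supported).
#' @return `read_bed` returns a data.frame with columns `chrom`, `start`,
#'   `end` and, when present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  con <- .open_maybe_gz(path, "rt")
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cn[seq_len(min(ncol(df), 6))]
  .check_intervals(df)
  df
}

#' @rdname read_bed
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`; six columns are written when a strand is
#'   present (missing names become `"."`, missing scores 0).
#' @export
write_bed <- function(intervals, path) {
  .check_intervals(intervals)
  df <- intervals
  if ("strand" %in% names(df)) {
    if (is.null(df$name)) df$name <- "."
    if (is.null(df$score)) df$score <- 0
    df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  } else {
    keep <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
    df <- df[, keep]
  }
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' bedGraph input and output
#'
#' Four-column binned signal tracks (chrom, start, end, value), 0-based
#' half-open, as produced by binning ChIP-seq enrichment.
#'
#' @param path File path (`.gz` supported).
#' @export
read_bedgraph <- function(path) {
  con <- .open_maybe_gz(path, "rt")
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  .check_intervals(df)
  df
}

#' @rdname read_bedgraph
#' @param track Data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  .check_intervals(track)
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  write.table(track[, c("chrom", "start", "end", "value")], con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Pooled methylation level
#'
#' Aggregate level of a set of cytosine calls.  The default pools counts
#' (`sum(n_meth) / sum(n_total)`), matching the binomial significance test
#' applied downstream; `per_site = TRUE` averages per-site ratios instead,
#' for sensitivity checks.
#'
#' @param calls Cytosine call data.frame.
#' @param per_site Average per-site ratios rather than pooling counts.
#' @return A single fraction, or `NA` when no reads are present.
#' @export
methylation_level <- function(calls, per_site = FALSE) {
  if (per_site) {
    r <- calls$n_meth / calls$n_total
    return(mean(r[is.finite(r)]))
  }
  tot <- sum(calls$n_total)
  if (tot == 0) return(NA_real_)
  sum(calls$n_meth) / tot
}
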