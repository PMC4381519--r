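#' Assemble decoded states into MAR/MPR segments
#'
#' Collapses a per-site Viterbi path into maximal same-state runs per chain
#' and enforces the minimum-evidence rule that a segment must contain at
#' least `min_sites` contiguous GCH sites.  Runs that fall short are
#' absorbed into a flanking run rather than deleted, so segments tile every
#' chain: by the alternation of states both flanks of an interior short run
#' share the opposite state (the emission evidence ties), and the run merges
#' into its preceding neighbour; chain-terminal short runs merge into their
#' only neighbour.  Chains with fewer than `min_sites` sites in total yield
#' no segments.
#'
#' @param calls Sorted GCH call data.frame (as decoded).
#' @param path State path aligned to `calls` (factor or character over
#'   `protected`/`accessible`), e.g. from [predict.nome_hmm()].
#' @param min_sites Minimum GCH sites per segment (default 3).
#' @param max_gap Chain-break distance in bp; must match the value used for
#'   decoding.
#' @return A data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open; the end covers the final GpC dinucleotide, i.e. last site
#'   position + 2), `state` (`MAR` = accessible, `MPR` = protected),
#'   `n_sites`, pooled `n_meth`/`n_total`, `level`, and
#'   `is_mononucleosome` for MPRs of 100-200 bp flanked by MARs on both
#'   sides.
#' @export
assemble_segments <- function(calls, path, min_sites = 3, max_gap = 500) {
  .stopifnot_calls(calls)
  path <- as.character(path)
  stopifnot(length(path) == nrow(calls),
            all(path %in% c("protected", "accessible")))
  offsets <- .chain_offsets(calls, max_gap)
  segs <- list()
  for (ci in seq_len(length(offsets) - 1L)) {
    s <- offsets[ci] + 1L; e <- offsets[ci + 1L]
    if (e < s) next
    r <- rle(path[s:e])
    runs <- data.frame(state = r$values,
                       from = cumsum(c(0L, r$lengths[-length(r$lengths)])) +
                         s,
                       len = r$lengths)
    runs$to <- runs$from + runs$len - 1L
    # absorb short runs (leftmost first) until all runs meet min_sites
    repeat {
      short <- which(runs$len < min_sites)
      if (!length(short) || nrow(runs) == 1L) break
      i <- short[1]
      if (i == 1L) {                      # terminal: only neighbour is 2
        runs$from[2] <- runs$from[1]
        runs$len[2] <- runs$len[2] + runs$len[1]
        runs <- runs[-1, , drop = FALSE]
      } else if (i == nrow(runs)) {
        runs$to[i - 1] <- runs$to[i]
        runs$len[i - 1] <- runs$len[i - 1] + runs$len[i]
        runs <- runs[-i, , drop = FALSE]
      } else {                            # interior: flanks share a state
        runs$to[i - 1] <- runs$to[i + 1]
        runs$len[i - 1] <- runs$len[i - 1] + runs$len[i] + runs$len[i + 1]
        runs <- runs[-c(i, i + 1), , drop = FALSE]
      }
    }
    if (nrow(runs) == 1L && runs$len[1] < min_sites) next
    runs$chain <- ci
    segs[[length(segs) + 1L]] <- runs
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      n_sites = integer(0), n_meth = integer(0),
                      n_total = integer(0), level = numeric(0),
                      is_mononucleosome = logical(0), chain = integer(0)))
  runs <- do.call(rbind, segs)
  out <- data.frame(
    chrom = calls$chrom[runs$from],
    start = calls$pos[runs$from],
    end = calls$pos[runs$to] + 2L,
    state = ifelse(runs$state == "accessible", "MAR", "MPR"),
    n_sites = runs$len,
    n_meth = vapply(seq_len(nrow(runs)), function(i)
      sum(calls$n_meth[runs$from[i]:runs$to[i]]), 0),
    n_total = vapply(seq_len(nrow(runs)), function(i)
      sum(calls$n_total[runs$from[i]:runs$to[i]]), 0),
    chain = runs$chain,
    stringsAsFactors = FALSE)
  out$level <- ifelse(out$n_total > 0, out$n_meth / out$n_total, NA_real_)
  # the +2 dinucleotide extension must not run into the next segment
  nseg0 <- nrow(out)
  if (nseg0 > 1) {
    same <- out$chain[-nseg0] == out$chain[-1]
    out$end[-nseg0][same] <- pmin(out$end[-nseg0][same],
                                  out$start[-1][same])
  }
  len <- out$end - out$start
  nseg <- nrow(out)
  same_chain_prev <- c(FALSE, out$chain[-1] == out$chain[-nseg])
  same_chain_next <- c(out$chain[-nseg] == out$chain[-1], FALSE)
  prev_mar <- c(NA, out$state[-nseg] == "MAR") & same_chain_prev
  next_mar <- c(out$state[-1] == "MAR", NA) & same_chain_next
  out$is_mononucleosome <- out$state == "MPR" & len >= 100 & len <= 200 &
    prev_mar & next_mar
  out$is_mononucleosome[is.na(out$is_mononucleosome)] <- FALSE
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "state", "n_sites", "n_meth",
          "n_total", "level", "is_mononucleosome", "chain")]
}

#' Segment a sample's GCH series with a fitted HMM
#'
#' Convenience wrapper: Viterbi-decode `calls` under `object` and assemble
#' MAR/MPR segments.
#'
#' @inheritParams predict.nome_hmm
#' @inheritParams assemble_segments
#' @return A segment data.frame (see [assemble_segments()]).
#' @export
segment_calls <- function(object, newdata, min_sites = 3) {
  newdata <- .sort_calls(newdata)
  path <- predict(object, newdata, type = "viterbi")
  assemble_segments(newdata, path, min_sites = min_sites,
                    max_gap = object$max_gap)
}

#' Write segments as BED6
#'
#' Name column carries the state (MAR/MPR), score `round(1000 * level)`.
#'
#' @param segments Segment data.frame.
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end, name = segments$state,
                    score = ifelse(is.na(segments$level), 0,
                                   round(1000 * segments$level)),
                    strand = ".")
  write_bed(bed, path)
}
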