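#' Transcription-oriented promoter window
#'
#' The classification window extends from 300 bp upstream to 500 bp
#' downstream of the TSS, mirrored on minus-strand promoters so the window
#' is always transcription-oriented (0-based half-open).
#'
#' @param tss TSS position(s), 0-based.
#' @param strand `"+"` or `"-"`, recycled.
#' @param upstream,downstream Window extent in bp (defaults 300 / 500).
#' @param chrom_length Optional chromosome length; windows are clipped to
#'   `[0, chrom_length)` and flagged.
#' @return Data.frame with `start`, `end` and logical `clipped`.
#' @examples
#' promoter_window(10000, "+")   # [9700, 10500)
#' promoter_window(10000, "-")   # [9501, 10301), same 800-bp width
#' @export
promoter_window <- function(tss, strand, upstream = 300, downstream = 500,
                            chrom_length = NULL) {
  strand <- rep_len(strand, length(tss))
  stopifnot(all(strand %in% c("+", "-")))
  start <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream + 1)
  clipped <- rep(FALSE, length(tss))
  if (any(start < 0)) { clipped[start < 0] <- TRUE; start <- pmax(start, 0) }
  if (!is.null(chrom_length) && any(end > chrom_length)) {
    clipped[end > chrom_length] <- TRUE
    end <- pmin(end, chrom_length)
  }
  data.frame(start = start, end = end, clipped = clipped)
}

#' Summarize HCG methylation over promoter windows
#'
#' Pools HCG calls within each promoter's transcription-oriented
#' classification window.
#'
#' @param calls HCG cytosine call data.frame for one sample.
#' @param promoters Data.frame with `chrom`, `tss`, `strand` (and
#'   optionally `gene`, `is_cgi`).
#' @param upstream,downstream Window extent in bp.
#' @return `promoters` with `n_hcg_sites` (covered sites), `n_reads`
#'   (pooled total count) and pooled `level` per promoter.
#' @export
summarize_promoter_windows <- function(calls, promoters, upstream = 300,
                                       downstream = 500) {
  win <- promoter_window(promoters$tss, promoters$strand,
                         upstream, downstream)
  n_sites <- integer(nrow(promoters))
  n_reads <- numeric(nrow(promoters))
  n_meth <- numeric(nrow(promoters))
  for (ch in unique(promoters$chrom)) {
    pi <- which(promoters$chrom == ch)
    ci <- which(calls$chrom == ch & calls$n_total > 0)
    if (!length(ci)) next
    wir <- .halfopen_to_iranges(win$start[pi], win$end[pi])
    sir <- IRanges::IRanges(calls$pos[ci] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(wir, sir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    n_sites[pi] <- tabulate(qh, length(pi))
    n_reads[pi] <- vapply(seq_along(pi), function(i)
      sum(calls$n_total[ci][sh[qh == i]]), 0)
    n_meth[pi] <- vapply(seq_along(pi), function(i)
      sum(calls$n_meth[ci][sh[qh == i]]), 0)
  }
  promoters$n_hcg_sites <- n_sites
  promoters$n_reads <- n_reads
  promoters$level <- ifelse(n_reads > 0, n_meth / n_reads, NA_real_)
  promoters
}

#' Classify promoters by endogenous methylation in two samples
#'
#' Applies the two-sample promoter methylation classification: promoters
#' passing the coverage filter in both samples (at least `min_sites` HCG
#' sites and `min_reads` reads in the window) are called unmethylated in a
#' sample when the pooled level is below `unmeth` (5%), and methylated when
#' at or above `meth_a` (60%) in sample A or `meth_b` (25%) in sample B.
#' Classes: `UU` (unmethylated in both), `MU` (methylated in A only),
#' `MM` (methylated in both).  Promoters in the gap zone between the
#' cutoffs, failing a filter, or unmethylated in A but methylated in B
#' ("UM", counted with a warning) are `unclassified`.
#'
#' @param summary_a,summary_b Promoter summaries from
#'   [summarize_promoter_windows()] for samples A (parental, HCT116-like)
#'   and B (demethylated, DKO1-like), row-aligned.
#' @param min_sites,min_reads Coverage filters per sample.
#' @param unmeth,meth_a,meth_b Classification cutoffs (fractions).
#' @return Character vector of class labels.
#' @export
classify_promoters <- function(summary_a, summary_b, min_sites = 3,
                               min_reads = 10, unmeth = 0.05,
                               meth_a = 0.60, meth_b = 0.25) {
  stopifnot(nrow(summary_a) == nrow(summary_b))
  pass <- summary_a$n_hcg_sites >= min_sites &
    summary_b$n_hcg_sites >= min_sites &
    summary_a$n_reads >= min_reads & summary_b$n_reads >= min_reads
  la <- summary_a$level; lb <- summary_b$level
  lab <- rep("unclassified", nrow(summary_a))
  ok <- pass & !is.na(la) & !is.na(lb)
  lab[ok & la < unmeth & lb < unmeth] <- "UU"
  lab[ok & la >= meth_a & lb >= meth_b] <- "MM"
  lab[ok & la >= meth_a & lb < unmeth] <- "MU"
  um <- sum(ok & la < unmeth & lb >= meth_b)
  if (um > 0)
    warning(um, " promoter(s) unmethylated in A but methylated in B; ",
            "reported as unclassified")
  lab
}

#' Positional autocorrelation of GpC accessibility
#'
#' Quantifies nucleosome phasing downstream of TSSs: for every promoter of
#' a class, sites 0-`max_dist` bp downstream (transcription-oriented) are
#' paired within the promoter, the pair distance is binned, and the Pearson
#' correlation of the two sites' methylation levels is computed per lag bin
#' over all pairs pooled across promoters.  A phased nucleosome array shows
#' a positive peak at its repeat length; unphased chromatin stays within
#' the sampling-noise band.
#'
#' @param calls GCH cytosine call data.frame for one sample.
#' @param promoters Data.frame with `chrom`, `tss`, `strand` (one class).
#' @param max_dist Maximum downstream distance in bp (default 700).
#' @param bin Lag bin width in bp (default 10).
#' @param min_pairs Bins with fewer pairs are reported `NA` (default 30).
#' @param min_total Sites with fewer reads are dropped (default 3).
#' @return Data.frame with `lag` (bin start, bp), `r`, `n_pairs`; the
#'   self-pair bin at lag 0 has r = 1 by construction.
#' @export
phasing_autocorrelation <- function(calls, promoters, max_dist = 700,
                                    bin = 10, min_pairs = 30,
                                    min_total = 3) {
  if (nrow(promoters) < 2) stop("need at least 2 promoters")
  calls <- calls[calls$n_total >= min_total, , drop = FALSE]
  xs <- list(); ys <- list(); lags <- list()
  for (ch in unique(promoters$chrom)) {
    pi <- which(promoters$chrom == ch)
    ci <- which(calls$chrom == ch)
    if (!length(ci)) next
    pos <- calls$pos[ci]
    lev <- calls$n_meth[ci] / calls$n_total[ci]
    for (i in pi) {
      d <- if (promoters$strand[i] == "+") pos - promoters$tss[i]
      else promoters$tss[i] - pos
      sel <- which(d >= 0 & d <= max_dist)
      if (length(sel) < 2) next
      dd <- d[sel]; ll <- lev[sel]
      o <- order(dd)
      dd <- dd[o]; ll <- ll[o]
      m <- length(dd)
      ij <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
      lags[[length(lags) + 1L]] <- dd[ij[, 2]] - dd[ij[, 1]]
      xs[[length(xs) + 1L]] <- ll[ij[, 1]]
      ys[[length(ys) + 1L]] <- ll[ij[, 2]]
    }
  }
  lag_breaks <- seq(0, max_dist + bin, by = bin)
  out <- data.frame(lag = head(lag_breaks, -1))
  out$r <- NA_real_
  out$n_pairs <- 0L
  if (!length(lags)) return(out)
  lag <- unlist(lags); x <- unlist(xs); y <- unlist(ys)
  bi <- findInterval(lag, lag_breaks)
  for (b in unique(bi)) {
    sel <- bi == b
    n <- sum(sel)
    out$n_pairs[b] <- n
    if (n < min_pairs) next
    if (sd(x[sel]) == 0 || sd(y[sel]) == 0) next   # zero variance: undefined
    out$r[b] <- cor(x[sel], y[sel])
  }
  out
}

#' Subcluster MU promoters into NP and NDR chromatin configurations
#'
#' Hierarchically clusters MU promoters on their anchor-aligned
#' accessibility profiles in the demethylated sample (average linkage,
#' Euclidean distance), cuts the tree at k = 2, and labels the cluster
#' whose members more often contain a called NDR overlapping the promoter
#' window as `"NDR"`, the other as `"NP"` (nucleosome positioning without
#' depletion).  Profiles are used unnormalized by default: the two
#' configurations differ in absolute central accessibility, which
#' per-row standardization obscures; `normalize = TRUE` standardizes rows
#' for sensitivity checks.
#'
#' @param profile Numeric matrix, rows = MU promoters, columns =
#'   transcription-oriented positional bins (see [aggregate_profile()]).
#' @param has_ndr Logical vector per promoter: a replicate-supported NDR
#'   overlaps the promoter's −300/+500 window.
#' @param normalize Standardize each row to mean 0, sd 1 before
#'   clustering (default `FALSE`).
#' @return List with `labels` (character, `"NP"`/`"NDR"`), `order`
#'   (dendrogram leaf order) and the `hclust` tree.
#' @export
subcluster_mu <- function(profile, has_ndr, normalize = FALSE) {
  stopifnot(is.matrix(profile), length(has_ndr) == nrow(profile))
  if (nrow(profile) < 4)
    stop("need at least 4 promoters to subcluster")
  pm <- profile
  pm[is.na(pm)] <- mean(pm, na.rm = TRUE)
  if (normalize) {
    rs <- apply(pm, 1, sd)
    pm <- (pm - rowMeans(pm)) / ifelse(rs > 0, rs, 1)
  }
  d <- dist(pm)
  if (max(d) == 0) {
    warning("all profiles identical; returning a single cluster")
    lab <- if (mean(has_ndr) > 0.5) "NDR" else "NP"
    return(list(labels = rep(lab, nrow(pm)), order = seq_len(nrow(pm)),
                tree = NULL))
  }
  tree <- hclust(d, method = "average")
  grp <- cutree(tree, k = 2)
  frac <- tapply(has_ndr, grp, mean)
  ndr_grp <- as.integer(names(frac)[which.max(frac)])
  list(labels = ifelse(grp == ndr_grp, "NDR", "NP"),
       order = tree$order, tree = tree)
}

#' Build the full promoter chromatin table
#'
#' Runs window summarization on both samples, classifies promoters, and,
#' when NDR calls and GCH calls are supplied, subclusters the MU class into
#' NP/NDR configurations on demethylated-sample accessibility profiles.
#'
#' @param promoters Data.frame with `gene`, `chrom`, `tss`, `strand`,
#'   `is_cgi`.
#' @param hcg_a,hcg_b HCG calls for samples A and B.
#' @param gch_b GCH calls for sample B (for MU subclustering); optional.
#' @param ndrs Replicate-supported NDR intervals in sample B; optional.
#' @param subcluster_bin Bin width (bp) of the accessibility profile used
#'   for NP/NDR subclustering; 50 bp keeps rows near-complete at typical
#'   GCH spacing (heatmap rendering may still use 10-bp bins).
#' @param ... Cutoffs passed to [classify_promoters()].
#' @return `promoters` with per-sample summary columns (`_a`/`_b`
#'   suffixes), `class_label` and `mu_subclass`.
#' @export
promoter_chromatin_table <- function(promoters, hcg_a, hcg_b,
                                     gch_b = NULL, ndrs = NULL,
                                     subcluster_bin = 50, ...) {
  sa <- summarize_promoter_windows(hcg_a, promoters)
  sb <- summarize_promoter_windows(hcg_b, promoters)
  out <- promoters
  out$n_hcg_sites_a <- sa$n_hcg_sites; out$n_reads_a <- sa$n_reads
  out$level_a <- sa$level
  out$n_hcg_sites_b <- sb$n_hcg_sites; out$n_reads_b <- sb$n_reads
  out$level_b <- sb$level
  out$class_label <- classify_promoters(sa, sb, ...)
  out$mu_subclass <- "none"
  mu <- which(out$class_label == "MU")
  if (length(mu) >= 4 && !is.null(gch_b) && !is.null(ndrs)) {
    anchors <- data.frame(chrom = out$chrom[mu], pos = out$tss[mu],
                          strand = out$strand[mu])
    prof <- aggregate_profile(gch_b, anchors, bin = subcluster_bin)
    win <- promoter_window(out$tss[mu], out$strand[mu])
    has_ndr <- vapply(seq_along(mu), function(i) {
      nd <- ndrs[ndrs$chrom == out$chrom[mu[i]], , drop = FALSE]
      any(nd$start < win$end[i] & nd$end > win$start[i])
    }, TRUE)
    out$mu_subclass[mu] <- subcluster_mu(prof$matrix, has_ndr)$labels
  }
  out
}
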