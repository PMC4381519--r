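#' Simulate irregularly spaced cytosine site positions
#'
#' Draws site positions along a chromosome with geometric inter-site gaps
#' of the given mean, emulating the irregular spacing of GpC (GCH) and CpG
#' (HCG) sites in real sequence without requiring a reference FASTA.
#'
#' @param chrom_length Chromosome length in bp (> 0 for a non-empty result).
#' @param mean_spacing Mean gap between consecutive sites in bp.
#' @param seed Optional RNG seed; fixed seed gives identical positions.
#' @return Strictly increasing integer positions in `[0, chrom_length)`.
#' @export
simulate_sites <- function(chrom_length, mean_spacing, seed = NULL) {
  if (mean_spacing <= 0) stop("'mean_spacing' must be positive")
  if (chrom_length < 0) stop("'chrom_length' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (chrom_length == 0) return(integer(0))
  p <- 1 / mean_spacing
  pos <- integer(0)
  last <- -1L
  while (last < chrom_length) {
    n_draw <- max(100L, ceiling(2 * (chrom_length - last) / mean_spacing))
    gaps <- 1L + rgeom(n_draw, p)
    pos <- c(pos, last + cumsum(gaps))
    last <- pos[length(pos)]
  }
  pos[pos < chrom_length]
}

#' Simulation configuration
#'
#' Parameters of the synthetic NOMe-seq assay: site spacings, M.CviPI
#' labeling efficiency in accessible (linker/NDR) DNA, residual labeling
#' under nucleosomes, and the overdispersed per-site read-depth model.
#'
#' @param mean_gch_spacing,mean_hcg_spacing Mean site gaps in bp.
#' @param enzyme_efficiency Probability that an accessible GCH is labeled.
#' @param background_leak Probability that a nucleosome-covered GCH is
#'   labeled; must be below `enzyme_efficiency`.
#' @param mean_depth Mean reads per site.
#' @param depth_dispersion Negative-binomial overdispersion of depth;
#'   0 degenerates to Poisson.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_gch_spacing = 15, mean_hcg_spacing = 50,
                       enzyme_efficiency = 0.8, background_leak = 0.05,
                       mean_depth = 30, depth_dispersion = 0.1,
                       seed = 1) {
  if (!(background_leak >= 0 && background_leak < enzyme_efficiency &&
        enzyme_efficiency <= 1))
    stop("need 0 <= background_leak < enzyme_efficiency <= 1")
  if (mean_gch_spacing <= 0 || mean_hcg_spacing <= 0 || mean_depth <= 0)
    stop("spacings and mean_depth must be positive")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  structure(list(mean_gch_spacing = mean_gch_spacing,
                 mean_hcg_spacing = mean_hcg_spacing,
                 enzyme_efficiency = enzyme_efficiency,
                 background_leak = background_leak,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, seed = seed),
            class = "sim_config")
}

#' Build a ground-truth nucleosome occupancy landscape
#'
#' Constructs the latent structure the assay observes: nucleosome-depleted
#' regions (occupancy 0), phased nucleosome arrays whose positioning
#' strength decays geometrically with distance from the anchor, a constant
#' unphased background occupancy, and megabase-scale low-accessibility
#' domains that scale the effective labeling ceiling.
#'
#' Array nucleosome centers sit at `anchor +/- k * repeat_length`
#' (`k = 1..n_nuc`; with `center_bump = TRUE` also at the anchor itself,
#' modelling positioned nucleosomes without central depletion).  The model
#' is density conserving: the k-th nucleosome occupies a 147-bp core whose
#' center is positioned with Gaussian uncertainty
#' `nuc_sd / decay^(k-1)`, so its occupancy contribution is the
#' probability that the core covers a position.  Tightly positioned
#' nucleosomes near the anchor give deep oscillation; growing positional
#' fuzziness decays the oscillation amplitude geometrically while the mean
#' occupancy per repeat stays near the unphased background (147/repeat),
#' so arrays do not create spurious net accessibility.  The outermost
#' repeat of each array fades linearly into the background.
#'
#' @param length Chromosome length in bp.
#' @param ndrs Data.frame (`start`, `end`) of truth NDR intervals, 0-based
#'   half-open; overlapping NDRs are rejected.
#' @param arrays Data.frame with `anchor`, `repeat_length`, `n_nuc`,
#'   `decay` and optional `center_bump` per phased array.
#' @param domains Data.frame (`start`, `end`, `scale`) of low-accessibility
#'   domains, `scale` in (0, 1]; overlaps are rejected.
#' @param background Unphased background occupancy (default 0.75,
#'   approximately the 147/190 core-to-repeat ratio).
#' @param repeat_length Default nucleosome repeat in bp used when `arrays`
#'   lacks the column (default 190, the canonical human repeat).
#' @param peak Occupancy of a perfectly positioned nucleosome core
#'   (default 0.95).
#' @param nuc_sd Positioning sd of the first (anchor-proximal) nucleosome
#'   in bp (default 20).
#' @param chrom Chromosome name.
#' @return An object of class `occupancy_landscape` with an `occupancy(pos)`
#'   and `domain_scale(pos)` accessor.
#' @export
build_landscape <- function(length, ndrs = NULL, arrays = NULL,
                            domains = NULL, background = 0.75,
                            repeat_length = 190, peak = 0.95,
                            nuc_sd = 20, chrom = "chrS") {
  check_iv <- function(x, what) {
    if (is.null(x) || !nrow(x)) return(x)
    if (any(x$start < 0) || any(x$end > length) || any(x$start >= x$end))
      stop(what, " intervals must be non-empty and within [0, length)")
    o <- order(x$start)
    x <- x[o, , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stop("overlapping ", what, " intervals are contradictory")
    x
  }
  ndrs <- check_iv(ndrs, "NDR")
  domains <- check_iv(domains, "domain")
  if (!is.null(arrays) && nrow(arrays)) {
    if (is.null(arrays$repeat_length)) arrays$repeat_length <- repeat_length
    if (is.null(arrays$center_bump)) arrays$center_bump <- FALSE
    if (any(arrays$repeat_length <= 146))
      stop("phased-array repeat length must exceed the 146-bp core")
    stopifnot(all(arrays$decay > 0 & arrays$decay <= 1),
              all(arrays$n_nuc >= 1))
  }
  occ_fun <- function(pos) {
    occ <- rep(background, base::length(pos))
    wmax <- rep(-Inf, base::length(pos))   # strongest positioning wins
    if (!is.null(arrays) && nrow(arrays)) {
      for (a in seq_len(nrow(arrays))) {
        R <- arrays$repeat_length[a]
        n <- arrays$n_nuc[a]
        anc <- arrays$anchor[a]
        dec <- arrays$decay[a]
        cb <- arrays$center_bump[a]
        span <- (n + 0.5) * R
        sel <- which(abs(pos - anc) <= span)
        if (!base::length(sel)) next
        d <- pos[sel] - anc
        half <- 146 / 2          # nucleosome core half-width
        prof <- rep(0, base::length(sel))
        for (kk in if (cb) 0:n else 1:n) {
          sdk <- nuc_sd / dec^max(kk - 1, 0)
          for (cj in (if (kk == 0) 0 else c(-kk, kk) * R))
            prof <- prof + (stats::pnorm((d - cj + half) / sdk) -
                              stats::pnorm((d - cj - half) / sdk))
        }
        prof <- peak * pmin(prof, 1)
        lambda <- pmin((span - abs(d)) / R, 1)   # edge fade-out
        cand <- lambda * prof + (1 - lambda) * background
        k_idx <- pmax(round(abs(d) / R), if (cb) 0 else 1)
        w <- dec^pmax(k_idx - if (cb) 0 else 1, 0)
        mask <- wmax[sel] < w
        upd <- sel[mask]
        occ[upd] <- cand[mask]
        wmax[upd] <- w[mask]
      }
    }
    if (!is.null(ndrs) && nrow(ndrs))
      for (i in seq_len(nrow(ndrs)))
        occ[pos >= ndrs$start[i] & pos < ndrs$end[i]] <- 0
    pmin(pmax(occ, 0), 1)
  }
  domain_scale <- function(pos) {
    sc <- rep(1, base::length(pos))
    if (!is.null(domains) && nrow(domains))
      for (i in seq_len(nrow(domains)))
        sc[pos >= domains$start[i] & pos < domains$end[i]] <-
      domains$scale[i]
    sc
  }
  structure(list(chrom = chrom, length = length, occupancy = occ_fun,
                 domain_scale = domain_scale, truth_ndrs = ndrs,
                 truth_arrays = arrays, truth_domains = domains,
                 background = background, peak = peak, nuc_sd = nuc_sd),
            class = "occupancy_landscape")
}

#' @export
print.occupancy_landscape <- function(x, ...) {
  cat("occupancy_landscape:", x$chrom, format(x$length, big.mark = ","),
      "bp;", if (is.null(x$truth_ndrs)) 0 else nrow(x$truth_ndrs), "NDRs,",
      if (is.null(x$truth_arrays)) 0 else nrow(x$truth_arrays), "arrays,",
      if (is.null(x$truth_domains)) 0 else nrow(x$truth_domains),
      "domains\n")
  invisible(x)
}

#' Sample synthetic GCH accessibility calls from a landscape
#'
#' For each GCH site the labeling probability is
#' `leak + (efficiency - leak) * (1 - occupancy) * domain_scale`; read
#' totals follow the configured overdispersed depth model and methylated
#' counts are binomial.  Replicates are independent resamplings of the same
#' landscape at the same genomic site positions (biological replicates
#' share the genome).
#'
#' @param landscape An `occupancy_landscape`.
#' @param config A [sim_config()].
#' @param n_rep Number of replicates.
#' @param positions Optional fixed site positions (otherwise drawn with
#'   [simulate_sites()] from the config's GCH spacing and seed).
#' @return A cytosine call data.frame for `n_rep = 1`, otherwise a list of
#'   replicate data.frames.
#' @export
sample_nome_calls <- function(landscape, config, n_rep = 1,
                              positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(positions))
    positions <- simulate_sites(landscape$length, config$mean_gch_spacing)
  p <- config$background_leak +
    (config$enzyme_efficiency - config$background_leak) *
    (1 - landscape$occupancy(positions)) *
    landscape$domain_scale(positions)
  TT <- length(positions)
  one <- function() {
    n <- if (config$depth_dispersion > 0)
      rnbinom(TT, mu = config$mean_depth,
              size = 1 / config$depth_dispersion)
    else rpois(TT, config$mean_depth)
    data.frame(chrom = landscape$chrom, pos = positions,
               strand = sample(c("+", "-"), TT, replace = TRUE),
               context = "GCH",
               n_meth = rbinom(TT, n, p), n_total = n,
               stringsAsFactors = FALSE)
  }
  if (n_rep == 1) one() else replicate(n_rep, one(), simplify = FALSE)
}

#' Define promoter ground truth
#'
#' @param tss,strand,is_cgi Promoter annotation vectors.
#' @param class_truth `"UU"`, `"MU"`, `"MM"` or `"fail"` (a promoter
#'   engineered to fail the coverage filter).
#' @param mu_subclass_truth `"NP"`, `"NDR"` or `"none"`; only MU promoters
#'   may carry a subclass.
#' @param level_a,level_b True HCG methylation fractions per sample; they
#'   must be consistent with the class cutoffs (UU: both < 5%; MU: A >= 60%
#'   and B < 5%; MM: A >= 60% and B >= 25%).
#' @param n_sites Optional per-promoter HCG site count override (used to
#'   build filter-failing promoters).
#' @return Data.frame of promoter truths.
#' @export
promoter_truth <- function(tss, strand, is_cgi = TRUE, class_truth,
                           mu_subclass_truth = "none",
                           level_a, level_b, n_sites = NA) {
  df <- data.frame(tss = tss, strand = strand, is_cgi = is_cgi,
                   class_truth = class_truth,
                   mu_subclass_truth = mu_subclass_truth,
                   level_a = level_a, level_b = level_b,
                   n_sites = n_sites, stringsAsFactors = FALSE)
  bad <- df$mu_subclass_truth != "none" & df$class_truth != "MU"
  if (any(bad)) stop("mu_subclass_truth set on a non-MU promoter")
  chk <- with(df,
              (class_truth == "UU" & (level_a >= 0.05 | level_b >= 0.05)) |
                (class_truth == "MU" & (level_a < 0.60 | level_b >= 0.05)) |
                (class_truth == "MM" & (level_a < 0.60 | level_b < 0.25)))
  if (any(chk))
    stop("truth levels inconsistent with the class cutoffs at promoter ",
         which(chk)[1])
  df$gene <- sprintf("gene_%05d", seq_len(nrow(df)))
  df
}

#' Sample synthetic HCG calls and annotations for two samples
#'
#' Generates HCG methylation calls for a parental (A) and a demethylated
#' (B) sample: background sites at the sample's global level, and sites
#' inside each promoter's transcription-oriented −300/+500 window at the
#' promoter's truth level.  Also emits the TSS and CpG-island BED
#' annotations.
#'
#' @param truths Promoter truth data.frame from [promoter_truth()].
#' @param config A [sim_config()].
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param background_level_a,background_level_b Genome-wide HCG levels
#'   outside promoter windows (defaults 0.8 / 0.05: the demethylated sample
#'   has lost nearly all CpG methylation).
#' @return List with `hcg_a`, `hcg_b` (calls), `tss` (BED6-style
#'   data.frame), `cgi` (BED3-style data.frame) and `truths`.
#' @export
sample_promoters <- function(truths, config, chrom_length,
                             chrom = "chrS", background_level_a = 0.8,
                             background_level_b = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pos <- simulate_sites(chrom_length, config$mean_hcg_spacing)
  win <- promoter_window(truths$tss, truths$strand,
                         chrom_length = chrom_length)
  la <- rep(background_level_a, length(pos))
  lb <- rep(background_level_b, length(pos))
  keep <- rep(TRUE, length(pos))
  extra <- list()
  for (i in seq_len(nrow(truths))) {
    inw <- pos >= win$start[i] & pos < win$end[i]
    if (!is.na(truths$n_sites[i])) {
      # fixed site count: replace the window's sites with exactly n
      keep[inw] <- FALSE
      if (truths$n_sites[i] > 0) {
        np <- sort(sample(win$start[i]:(win$end[i] - 1L),
                          truths$n_sites[i]))
        extra[[length(extra) + 1L]] <-
          data.frame(pos = np, la = truths$level_a[i],
                     lb = truths$level_b[i])
      }
    } else {
      la[inw] <- truths$level_a[i]
      lb[inw] <- truths$level_b[i]
    }
  }
  pos <- pos[keep]; la <- la[keep]; lb <- lb[keep]
  if (length(extra)) {
    ex <- do.call(rbind, extra)
    pos <- c(pos, ex$pos); la <- c(la, ex$la); lb <- c(lb, ex$lb)
    o <- order(pos)
    pos <- pos[o]; la <- la[o]; lb <- lb[o]
  }
  draw <- function(levels) {
    n <- if (config$depth_dispersion > 0)
      rnbinom(length(pos), mu = config$mean_depth,
              size = 1 / config$depth_dispersion)
    else rpois(length(pos), config$mean_depth)
    data.frame(chrom = chrom, pos = pos,
               strand = sample(c("+", "-"), length(pos), replace = TRUE),
               context = "HCG",
               n_meth = rbinom(length(pos), n, levels), n_total = n,
               stringsAsFactors = FALSE)
  }
  tss <- data.frame(chrom = chrom, start = truths$tss,
                    end = truths$tss + 1L, name = truths$gene, score = 0,
                    strand = truths$strand, stringsAsFactors = FALSE)
  cgi_rows <- which(truths$is_cgi)
  cgi <- data.frame(chrom = chrom,
                    start = pmax(truths$tss[cgi_rows] - 500L, 0),
                    end = pmin(truths$tss[cgi_rows] + 500L, chrom_length),
                    stringsAsFactors = FALSE)
  list(hcg_a = draw(la), hcg_b = draw(lb), tss = tss, cgi = cgi,
       truths = truths)
}

#' Simulate a complete two-sample NOMe-seq experiment
#'
#' Builds per-sample occupancy landscapes over one synthetic chromosome and
#' samples everything downstream stages consume: two GCH replicates per
#' sample, HCG calls per sample, TSS/CGI annotations, and the ground truth.
#'
#' The layout emulates the study system: shared NDRs flanked by phased
#' arrays (active regulatory elements, both samples); UU promoters open in
#' both samples; MU promoters closed (constant background occupancy) in the
#' parental sample A and reorganized in the demethylated sample B, either
#' gaining phased positioning alone (`NP`) or positioning plus a central
#' NDR (`NDR`); optional low-accessibility domains shared by both samples.
#'
#' @param chrom_length Chromosome length in bp (default 1e6).
#' @param n_ndr Number of shared intergenic truth NDRs.
#' @param ndr_width_range NDR widths are drawn uniformly from this range
#'   (default 140-400 bp, all above the 140-bp detection target).
#' @param promoter_truths Optional [promoter_truth()] table; when `NULL` a
#'   default mix is placed (see Details in the vignette).
#' @param domains Optional domain data.frame (`start`, `end`, `scale`).
#' @param repeat_length Nucleosome repeat of the phased arrays (default
#'   190 bp).
#' @param array_n_nuc,array_decay Phased-array extent and decay.
#' @param config A [sim_config()].
#' @return List with `landscape_a`, `landscape_b`, `gch_a`, `gch_b` (each
#'   a list of two replicate call data.frames), `hcg_a`, `hcg_b`, `tss`,
#'   `cgi`, `truths`, `truth_ndrs_b` and `chrom_length`.
#' @export
simulate_nome_experiment <- function(chrom_length = 1e6, n_ndr = 20,
                                     ndr_width_range = c(140, 400),
                                     promoter_truths = NULL,
                                     domains = NULL, repeat_length = 190,
                                     array_n_nuc = 5, array_decay = 0.75,
                                     config = sim_config()) {
  set.seed(config$seed)
  # reserve disjoint slots along the chromosome: intergenic NDRs first,
  # then promoters, all separated by at least 6 kb
  slot <- 6000
  n_prom <- if (is.null(promoter_truths)) 30L else nrow(promoter_truths)
  n_slots <- n_ndr + n_prom
  if (n_slots * slot > chrom_length * 0.9)
    stop("chromosome too short for the requested features")
  centers <- round(seq(slot / 2, chrom_length - slot / 2,
                       length.out = n_slots))
  centers <- centers + round(runif(n_slots, -slot / 8, slot / 8))
  ndr_centers <- centers[seq_len(n_ndr)]
  prom_centers <- centers[n_ndr + seq_len(n_prom)]
  if (is.null(promoter_truths)) {
    cls <- rep(c("UU", "MU", "MM"), times = c(10, 15, 5))
    # MU promoters split 80/20 into positioning-only (NP) and NDR-gaining
    # configurations, the majority/minority balance seen in the study system
    sub <- rep("none", n_prom)
    sub[cls == "MU"] <- rep(c("NP", "NP", "NP", "NP", "NDR"),
                            length.out = sum(cls == "MU"))
    promoter_truths <- promoter_truth(
      tss = prom_centers,
      strand = rep(c("+", "-"), length.out = n_prom),
      class_truth = cls, mu_subclass_truth = sub,
      level_a = ifelse(cls == "UU", 0.02, 0.85),
      level_b = ifelse(cls == "MM", 0.40, 0.02))
  } else {
    promoter_truths$tss <- prom_centers
  }
  w <- round(runif(n_ndr, ndr_width_range[1], ndr_width_range[2]))
  ndrs <- data.frame(start = ndr_centers - w %/% 2,
                     end = ndr_centers - w %/% 2 + w)
  arr <- function(anchor, center_bump = FALSE)
    data.frame(anchor = anchor, repeat_length = repeat_length,
               n_nuc = array_n_nuc, decay = array_decay,
               center_bump = center_bump)
  tt <- promoter_truths
  uu <- tt$class_truth == "UU"
  mu_np <- tt$mu_subclass_truth == "NP"
  mu_ndr <- tt$mu_subclass_truth == "NDR"
  prom_ndr <- function(rows) {
    if (!any(rows)) return(NULL)
    data.frame(start = tt$tss[rows] - 100L, end = tt$tss[rows] + 100L)
  }
  # sample A: shared intergenic NDRs + open UU promoters; MU/MM closed
  ndrs_a <- rbind(ndrs, prom_ndr(uu))
  arrays_a <- rbind(arr(ndr_centers), arr(tt$tss[uu]))
  # sample B: additionally reorganized MU promoters
  ndrs_b <- rbind(ndrs, prom_ndr(uu), prom_ndr(mu_ndr))
  arrays_b <- rbind(arr(ndr_centers), arr(tt$tss[uu]),
                    arr(tt$tss[mu_np], center_bump = TRUE),
                    arr(tt$tss[mu_ndr]))
  clip <- function(x) {
    if (is.null(x)) return(x)
    x$start <- pmax(x$start, 0); x$end <- pmin(x$end, chrom_length)
    x[order(x$start), , drop = FALSE]
  }
  land_a <- build_landscape(chrom_length, ndrs = clip(ndrs_a),
                            arrays = arrays_a, domains = domains,
                            repeat_length = repeat_length)
  land_b <- build_landscape(chrom_length, ndrs = clip(ndrs_b),
                            arrays = arrays_b, domains = domains,
                            repeat_length = repeat_length)
  gch_positions <- simulate_sites(chrom_length, config$mean_gch_spacing,
                                  seed = config$seed + 2L)
  cfg_rep <- function(offset) {
    c2 <- config; c2$seed <- config$seed + offset; c2
  }
  gch_a <- list(
    sample_nome_calls(land_a, cfg_rep(10L), positions = gch_positions),
    sample_nome_calls(land_a, cfg_rep(11L), positions = gch_positions))
  gch_b <- list(
    sample_nome_calls(land_b, cfg_rep(20L), positions = gch_positions),
    sample_nome_calls(land_b, cfg_rep(21L), positions = gch_positions))
  hcg <- sample_promoters(promoter_truths, config, chrom_length)
  with_chrom <- function(x) cbind(chrom = "chrS", clip(x))
  list(landscape_a = land_a, landscape_b = land_b,
       gch_a = gch_a, gch_b = gch_b,
       hcg_a = hcg$hcg_a, hcg_b = hcg$hcg_b,
       tss = hcg$tss, cgi = hcg$cgi, truths = hcg$truths,
       truth_ndrs_b = with_chrom(ndrs_b), truth_ndrs_a = with_chrom(ndrs_a),
       chrom_length = chrom_length, config = config)
}
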