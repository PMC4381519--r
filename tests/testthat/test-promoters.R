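test_that("promoter windows are transcription-oriented", {
  expect_equal(unlist(promoter_window(10000, "+")[, 1:2]),
               c(start = 9700, end = 10500))
  w_minus <- promoter_window(10000, "-")
  expect_equal(w_minus$end - w_minus$start, 800)
  expect_equal(unlist(w_minus[, 1:2]), c(start = 9501, end = 10301))
  # mirroring twice restores the plus window
  expect_equal(promoter_window(10000, "+"),
               promoter_window(10000, "+"))
  # clipping at the chromosome start is flagged
  expect_true(promoter_window(100, "+")$clipped)
  expect_true(promoter_window(900, "-", chrom_length = 1000)$clipped)
})

mk_summary <- function(level, sites = 10, reads = 200) {
  data.frame(n_hcg_sites = sites, n_reads = reads, level = level)
}

test_that("classification follows the two-sample cutoffs", {
  la <- c(0.02, 0.70, 0.70, 0.10, 0.70, 0.40)
  lb <- c(0.01, 0.03, 0.30, 0.01, 0.10, 0.01)
  expect_equal(
    classify_promoters(mk_summary(la), mk_summary(lb)),
    c("UU", "MU", "MM", "unclassified", "unclassified", "unclassified"))
  # coverage filters push promoters to unclassified
  expect_equal(classify_promoters(mk_summary(0.02, sites = 2),
                                  mk_summary(0.01)), "unclassified")
  expect_equal(classify_promoters(mk_summary(0.02),
                                  mk_summary(0.01, reads = 5)),
               "unclassified")
  # UM is not a class: warned and sunk
  expect_warning(
    lab <- classify_promoters(mk_summary(0.01), mk_summary(0.60)),
    "unmethylated in A")
  expect_equal(lab, "unclassified")
})

test_that("reducing depth can only move promoters to unclassified", {
  set.seed(41)
  tt <- promoter_truth(tss = seq(5000, by = 3000, length.out = 60),
                       strand = "+",
                       class_truth = rep(c("UU", "MM"), 30),
                       level_a = rep(c(0.02, 0.85), 30),
                       level_b = rep(c(0.02, 0.40), 30))
  prom <- data.frame(gene = tt$gene, chrom = "chrS", tss = tt$tss,
                     strand = tt$strand)
  deep <- sample_promoters(tt, sim_config(seed = 42, mean_depth = 40),
                           chrom_length = 2e5)
  lab_deep <- classify_promoters(
    summarize_promoter_windows(deep$hcg_a, prom),
    summarize_promoter_windows(deep$hcg_b, prom))
  thin <- lapply(deep[c("hcg_a", "hcg_b")], function(x) {
    kept <- rbinom(nrow(x), x$n_total, 0.05)
    x$n_meth <- suppressWarnings(
      rhyper(nrow(x), x$n_meth, x$n_total - x$n_meth, kept))
    x$n_total <- kept
    x
  })
  lab_thin <- classify_promoters(
    summarize_promoter_windows(thin$hcg_a, prom),
    summarize_promoter_windows(thin$hcg_b, prom))
  flipped <- lab_deep == "UU" & lab_thin == "MM" |
    lab_deep == "MM" & lab_thin == "UU"
  expect_false(any(flipped))
})

test_that("self-pairs give lag-0 correlation 1", {
  set.seed(43)
  n_prom <- 20
  tss <- seq(2000, by = 2000, length.out = n_prom)
  calls <- do.call(rbind, lapply(tss, function(t0)
    make_calls(pos = t0 + seq(0, 690, 30),
               k = rbinom(24, 20, runif(24)), n = 20)))
  prom <- data.frame(chrom = "chrS", tss = tss, strand = "+")
  ac <- phasing_autocorrelation(calls, prom)
  expect_equal(ac$r[1], 1)
  expect_true(all(ac$r[!is.na(ac$r)] >= -1 & ac$r[!is.na(ac$r)] <= 1))
})

test_that("independent noise stays inside the Monte-Carlo null band", {
  set.seed(44)
  n_prom <- 400
  tss <- seq(2000, by = 1500, length.out = n_prom)
  calls <- do.call(rbind, lapply(tss, function(t0)
    make_calls(pos = t0 + seq(0, 690, 30),
               k = rbinom(24, 25, 0.4), n = 25)))
  prom <- data.frame(chrom = "chrS", tss = tss, strand = "+")
  ac <- phasing_autocorrelation(calls, prom)
  ok <- ac$lag > 0 & !is.na(ac$r)
  expect_true(all(abs(ac$r[ok]) < 3 / sqrt(ac$n_pairs[ok])))
})

test_that("phasing statistic recovers the simulated repeat length", {
  s <- phased_promoter_sim(R = 190, n_prom = 200, seed = 45)
  ac <- phasing_autocorrelation(s$gch_b, s$promoters)
  ok <- ac$lag > 0 & !is.na(ac$r)
  peak <- ac$lag[ok][which.max(ac$r[ok])]
  expect_gte(peak, 180)
  expect_lt(peak, 200)
})

test_that("autocorrelation is invariant under locus mirroring", {
  s <- phased_promoter_sim(R = 190, n_prom = 60, seed = 46)
  L <- max(s$gch_b$pos) + 1000L
  ac <- phasing_autocorrelation(s$gch_b, s$promoters)
  mirrored <- s$gch_b
  mirrored$pos <- L - 1L - mirrored$pos
  mirrored$strand <- ifelse(mirrored$strand == "+", "-", "+")
  prom_m <- s$promoters
  prom_m$tss <- L - 1L - prom_m$tss
  prom_m$strand <- ifelse(prom_m$strand == "+", "-", "+")
  ac_m <- phasing_autocorrelation(mirrored, prom_m)
  expect_equal(ac_m$r, ac$r, tolerance = 1e-12)
  expect_identical(ac_m$n_pairs, ac$n_pairs)
})

test_that("NP/NDR subclustering recovers the truth and its edge cases", {
  s <- phased_promoter_sim(R = 190, n_prom = 200, seed = 47,
                           frac_ndr = 0.2)
  anch <- data.frame(chrom = s$promoters$chrom, pos = s$promoters$tss,
                     strand = s$promoters$strand)
  prof <- aggregate_profile(s$gch_b, anch, bin = 50)
  sc <- subcluster_mu(prof$matrix, s$truth_sub == "NDR")
  expect_gte(mean(sc$labels == s$truth_sub), 0.95)
  # permuting rows permutes labels identically
  perm <- sample(nrow(prof$matrix))
  sc_p <- subcluster_mu(prof$matrix[perm, ], (s$truth_sub == "NDR")[perm])
  expect_identical(sc_p$labels, sc$labels[perm])
  # degenerate identical profiles: flagged single cluster
  flat <- matrix(0.5, 10, 20)
  expect_warning(sc_f <- subcluster_mu(flat, rep(FALSE, 10)), "identical")
  expect_length(unique(sc_f$labels), 1)
  expect_error(subcluster_mu(flat[1:3, ], rep(FALSE, 3)), "at least 4")
})

test_that("promoter truths inconsistent with the cutoffs are rejected", {
  expect_error(promoter_truth(tss = 100, strand = "+",
                              class_truth = "MU", level_a = 0.3,
                              level_b = 0.01), "inconsistent")
  expect_error(promoter_truth(tss = 100, strand = "+",
                              class_truth = "UU",
                              mu_subclass_truth = "NP",
                              level_a = 0.01, level_b = 0.01), "non-MU")
})
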