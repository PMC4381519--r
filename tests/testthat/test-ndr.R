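mk_seg <- function(chrom, start, end, state, k, n) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             n_sites = 3, n_meth = k, n_total = n,
             stringsAsFactors = FALSE)
}

test_that("local background pools MPR counts over the flank window", {
  mars <- mk_seg("chrS", 50000, 50200, "MAR", 90, 100)
  mprs <- rbind(mk_seg("chrS", 10000, 10100, "MPR", 2, 10),
                mk_seg("chrS", 120000, 120100, "MPR", 3, 40))
  bg <- local_background(mars, mprs, flank = 100000)
  expect_equal(bg$bg_rate, 5 / 50)
  expect_false(bg$bg_fallback)
})

test_that("the flank boundary is half-open", {
  mars <- mk_seg("chrS", 200000, 200100, "MAR", 10, 10)
  # MPR starting exactly at mar.end + flank is excluded; 1 bp in is kept
  at_edge <- mk_seg("chrS", 300100, 300200, "MPR", 1, 10)
  inside <- mk_seg("chrS", 300099, 300199, "MPR", 1, 10)
  expect_true(local_background(mars, at_edge)$bg_fallback)
  expect_false(local_background(mars, inside)$bg_fallback)
})

test_that("local background equals a brute-force scan", {
  set.seed(31)
  n_mpr <- 200
  start <- sort(sample.int(2e6, n_mpr))
  mprs <- mk_seg("chrS", start, start + sample.int(300, n_mpr),
                 "MPR", rbinom(n_mpr, 50, 0.1), 50)
  ms <- sort(sample.int(2e6, 30))
  mars <- mk_seg("chrS", ms, ms + 200, "MAR", 40, 50)
  bg <- local_background(mars, mprs, flank = 100000)
  for (i in seq_len(nrow(mars))) {
    hit <- mprs$start < mars$end[i] + 100000 &
      mprs$end > mars$start[i] - 100000
    expect_equal(bg$bg_meth[i], sum(mprs$n_meth[hit]))
    expect_equal(bg$bg_total[i], sum(mprs$n_total[hit]))
  }
})

test_that("exact binomial tail matches direct summation", {
  expect_equal(mar_binomial_test(0, 10, 0.3), 1)
  expect_equal(mar_binomial_test(20, 20, 0.2), 0.2^20)
  expect_equal(mar_binomial_test(15, 20, 0.5), 21700 / 2^20)
  set.seed(32)
  for (i in 1:200) {
    n <- sample(0:60, 1)
    k <- if (n > 0) sample(0:n, 1) else 0
    p0 <- runif(1)
    expect_equal(mar_binomial_test(k, n, p0),
                 sum(dbinom(k:n, n, p0)), tolerance = 1e-12,
                 label = sprintf("k=%d n=%d p0=%.3f", k, n, p0))
  }
  expect_equal(mar_binomial_test(0, 0, 0.5), 1)
})

test_that("BH q-values reproduce the step-up and preserve order", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed: m * p / rank with running minimum from the largest p
  p <- c(0.005, 0.009, 0.05, 0.5)
  expect_equal(bh_fdr(p), c(0.018, 0.018, 4 * 0.05 / 3, 0.5))
  set.seed(33)
  ps <- sort(runif(50))
  expect_true(all(diff(bh_fdr(ps)) >= 0))
  expect_length(bh_fdr(numeric(0)), 0)
})

test_that("NDR rule needs significance and strict length > 100 bp", {
  segs <- rbind(
    mk_seg("chrS", 1000, 1150, "MAR", 100, 100),   # strong, 150 bp
    mk_seg("chrS", 5000, 5100, "MAR", 100, 100),   # strong, exactly 100 bp
    mk_seg("chrS", 9000, 9500, "MAR", 12, 100),    # weak, long
    mk_seg("chrS", seq(2000, 98000, 4000), seq(2200, 98200, 4000),
           "MPR", 10, 100))
  out <- call_ndrs(segs)
  expect_equal(out$is_ndr, c(TRUE, FALSE, FALSE))
  expect_true(out$is_significant[2])   # significant MAR, too short
  expect_false(out$is_significant[3])
})

test_that("null MARs are not called", {
  set.seed(34)
  m <- 2000
  n <- rpois(m, 200)
  k <- rbinom(m, n, 0.15)
  p <- mar_binomial_test(k, n, 0.15)
  expect_lte(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / m))
  expect_lte(sum(bh_fdr(p) < 0.01), 1)
})

test_that("replicate intersection merges overlapping calls", {
  a <- data.frame(chrom = "chrS", start = c(100, 1000),
                  end = c(250, 1200))
  b <- a
  expect_equal(intersect_replicates(a, b)[, c("start", "end")],
               a[, c("start", "end")])
  disj <- data.frame(chrom = "chrS", start = 5000, end = 5100)
  expect_equal(nrow(intersect_replicates(a, disj)), 0)
  # >= 1 bp overlap, union interval reported
  b2 <- data.frame(chrom = "chrS", start = 249, end = 400)
  out <- intersect_replicates(a[1, ], b2)
  expect_equal(out$start, 100)
  expect_equal(out$end, 400)
  # abutting half-open intervals share no base and do not pair
  b3 <- data.frame(chrom = "chrS", start = 250, end = 400)
  expect_equal(nrow(intersect_replicates(a[1, ], b3)), 0)
  # transitive chain collapses to one interval
  a2 <- data.frame(chrom = "chrS", start = c(0, 180), end = c(100, 300))
  b4 <- data.frame(chrom = "chrS", start = 90, end = 200)
  chain <- intersect_replicates(a2, b4)
  expect_equal(nrow(chain), 1)
  expect_equal(c(chain$start, chain$end), c(0, 300))
})

test_that("raising the FDR cutoff never removes a call", {
  set.seed(35)
  start <- sort(sample.int(1e6, 50))
  segs <- rbind(
    mk_seg("chrS", start, start + 150, "MAR",
           rbinom(50, 60, runif(50, 0.1, 0.9)), 60),
    mk_seg("chrS", start + 500, start + 700, "MPR",
           rbinom(50, 60, 0.1), 60))
  loose <- call_ndrs(segs, fdr = 0.05)
  strict <- call_ndrs(segs, fdr = 0.01)
  expect_true(all(which(strict$is_ndr) %in% which(loose$is_ndr)))
})
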