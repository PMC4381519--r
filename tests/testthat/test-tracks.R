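mk_track <- function(values, bin = 10, chrom = "chrS") {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin, value = values,
             stringsAsFactors = FALSE)
}

test_that("z-scoring standardizes against the genome background", {
  z <- zscore_track(mk_track(rep(c(0, 2), 10)))
  expect_equal(z$value, rep(c(-1, 1), 10))
  set.seed(51)
  tr <- mk_track(rnorm(500, 5, 3))
  tr$value[sample(500, 50)] <- NA
  z <- zscore_track(tr)
  v <- z$value[!is.na(z$value)]
  expect_equal(mean(v), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
  # matches a direct two-pass computation
  raw <- tr$value[!is.na(tr$value)]
  expect_equal(v, (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2)))
  expect_true(all(is.na(z$value) == is.na(tr$value)))
  expect_error(zscore_track(mk_track(rep(1, 10))), "variance")
  expect_error(zscore_track(mk_track(3)), "at least 2")
})

test_that("profiles aggregate pooled levels around anchors", {
  # constant level everywhere: every covered bin equals it
  calls <- make_calls(pos = seq(0, 4000, 10), k = 3, n = 10)
  prof <- aggregate_profile(calls, data.frame(chrom = "chrS", pos = 2000),
                            flank = 500, bin = 10)
  expect_equal(dim(prof$matrix), c(1, 100))
  expect_true(all(prof$matrix == 0.3))
  expect_true(all(prof$metaplot == 0.3))
})

test_that("minus-strand rows are the mirror of plus-strand rows", {
  set.seed(52)
  pos <- seq(0, 4000, 15)
  calls <- make_calls(pos, k = rbinom(length(pos), 20, 0.4), n = 20)
  anchors <- data.frame(chrom = "chrS", pos = c(2000, 2000),
                        strand = c("+", "-"))
  prof <- aggregate_profile(calls, anchors, flank = 600, bin = 30)
  expect_equal(prof$matrix[2, ], rev(prof$matrix[1, ]))
  # flipping strands twice restores the matrix
  prof2 <- aggregate_profile(calls, anchors, flank = 600, bin = 30)
  expect_equal(prof2$matrix, prof$matrix)
})

test_that("profile aggregation is linear over binned tracks", {
  set.seed(53)
  t1 <- mk_track(rnorm(400))
  t2 <- mk_track(rnorm(400))
  ts <- t1
  ts$value <- t1$value + t2$value
  anchors <- data.frame(chrom = "chrS", pos = c(1000, 2500, 3100))
  p1 <- aggregate_profile(t1, anchors, flank = 500, bin = 10)
  p2 <- aggregate_profile(t2, anchors, flank = 500, bin = 10)
  ps <- aggregate_profile(ts, anchors, flank = 500, bin = 10)
  expect_equal(ps$matrix, p1$matrix + p2$matrix, tolerance = 1e-12)
})

test_that("anchors off the signal chromosomes are dropped with warning", {
  calls <- make_calls(pos = seq(0, 2000, 10), k = 1, n = 4)
  anchors <- data.frame(chrom = c("chrS", "chrX"), pos = c(1000, 1000))
  expect_warning(prof <- aggregate_profile(calls, anchors, flank = 200),
                 "dropped")
  expect_equal(nrow(prof$matrix), 1)
})

test_that("row clustering separates constructed groups", {
  set.seed(54)
  base <- matrix(rnorm(40 * 60, 0, 0.1), 40, 60)
  base[1:20, 25:35] <- base[1:20, 25:35] + 3   # central blob
  hc <- hcluster_rows(base, k = 2)
  expect_length(unique(hc$labels[1:20]), 1)
  expect_length(unique(hc$labels[21:40]), 1)
  expect_false(hc$labels[1] == hc$labels[40])
  # duplicated rows land together
  dup <- rbind(base, base[1, , drop = FALSE])
  hcd <- hcluster_rows(dup, k = 2)
  expect_equal(hcd$labels[41], hcd$labels[1])
  expect_error(hcluster_rows(base, k = 41), "fewer")
})

test_that("column restriction makes flank-only differences invisible", {
  set.seed(55)
  pos <- seq(0, 40000, 10)
  calls <- make_calls(pos, k = 5, n = 10)
  anchors <- data.frame(chrom = "chrS", pos = c(10000, 20000, 30000))
  prof <- aggregate_profile(calls, anchors, flank = 1000, bin = 10)
  # corrupt flank columns only for one row
  prof$matrix[3, prof$offsets < -400] <- 0.9
  full <- hcluster_rows(prof, k = 2)
  centre <- hcluster_rows(prof, k = 2, restrict_bp = c(-250, 250))
  expect_false(full$labels[3] == full$labels[1])
  d <- dist(prof$matrix[, prof$offsets >= -250 & prof$offsets < 250])
  expect_equal(max(d), 0)   # identical inside the restriction
})

test_that("window summaries equal a brute-force scan and rank correctly", {
  set.seed(56)
  L <- 5e5
  gch <- make_calls(pos = sort(sample.int(L, 3000)),
                    k = rbinom(3000, 20, 0.3), n = 20)
  hcg <- make_calls(pos = sort(sample.int(L, 1000)),
                    k = rbinom(1000, 20, 0.7), n = 20,
                    context = "HCG")
  tr <- mk_track(rnorm(L / 10), bin = 10)
  cgi <- data.frame(chrom = "chrS", start = c(1e4, 3e5),
                    end = c(2e4, 3.2e5))
  ws <- window_summarize(gch, hcg, tracks = list(chip = tr),
                         chrom_lengths = c(chrS = L), window = 1e5,
                         cgi = cgi)
  expect_equal(nrow(ws), 5)
  expect_equal(ws$rank, 1:5)
  expect_true(all(diff(ws$accessibility) <= 0))
  for (i in seq_len(5)) {
    w0 <- ws$start[i]
    sel <- gch$pos >= w0 & gch$pos < w0 + 1e5
    expect_equal(ws$accessibility[i],
                 sum(gch$n_meth[sel]) / sum(gch$n_total[sel]))
    tsel <- tr$start >= w0 & tr$start < w0 + 1e5 &
      !(tr$start < 2e4 & tr$end > 1e4) & !(tr$start < 3.2e5 & tr$end > 3e5)
    expect_equal(ws$chip[i], mean(tr$value[tsel]))
  }
  # constant input gives a constant column
  flat <- make_calls(pos = seq(0, L - 1, 100), k = 2, n = 10)
  wsf <- window_summarize(flat, hcg, chrom_lengths = c(chrS = L),
                          window = 1e5)
  expect_true(all(wsf$accessibility == 0.2))
})
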