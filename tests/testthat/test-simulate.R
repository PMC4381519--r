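test_that("site simulation honours its spacing model", {
  expect_identical(simulate_sites(0, 15, seed = 1), integer(0))
  expect_error(simulate_sites(1000, 0), "positive")
  expect_error(simulate_sites(-5, 10), "non-negative")
  s1 <- simulate_sites(150000, 15, seed = 7)
  s2 <- simulate_sites(150000, 15, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(diff(s1) >= 1))
  expect_true(all(s1 >= 0 & s1 < 150000))
  # expected count 10000 with Poisson-scale fluctuation
  expect_lt(abs(length(s1) - 10000), 4 * sqrt(10000))
})

test_that("landscapes encode NDRs, phased bumps and domains", {
  arrays <- data.frame(anchor = 5000, repeat_length = 190, n_nuc = 4,
                       decay = 0.7)
  land <- build_landscape(10000,
                          ndrs = data.frame(start = 4900, end = 5100),
                          arrays = arrays,
                          domains = data.frame(start = 8000, end = 9500,
                                               scale = 0.4))
  expect_equal(land$occupancy(5000), 0)           # NDR centre
  occ <- land$occupancy(0:9999)
  # first phased nucleosome centre is the occupancy maximum
  expect_equal(which.max(occ) - 1, 5190, tolerance = 2)
  expect_true(all(occ >= 0 & occ <= 1))
  expect_equal(land$domain_scale(c(7999, 8000, 9499, 9500)),
               c(1, 0.4, 0.4, 1))
  expect_error(build_landscape(1000,
                               ndrs = data.frame(start = c(0, 50),
                                                 end = c(100, 150))),
               "contradictory")
  expect_error(build_landscape(1000,
                               ndrs = data.frame(start = 900, end = 1100)),
               "within")
  expect_error(build_landscape(5000,
                               arrays = data.frame(anchor = 2000,
                                                   repeat_length = 120,
                                                   n_nuc = 2,
                                                   decay = 0.8)),
               "146")
})

test_that("accessibility of a phased array oscillates at the repeat", {
  for (R in c(160, 190, 220)) {
    arrays <- data.frame(anchor = 20000, repeat_length = R, n_nuc = 6,
                         decay = 0.9)
    land <- build_landscape(40000, arrays = arrays)
    # one flank of the array, avoiding the open anchor region whose wide
    # plateau dominates short-lag autocorrelation
    x <- 1 - land$occupancy(seq(20000 + R %/% 2, 20000 + 6 * R))
    a <- stats::acf(x, lag.max = round(1.5 * R), plot = FALSE)$acf[-1]
    lags <- seq_along(a)
    sel <- lags > 0.6 * R
    peak <- lags[sel][which.max(a[sel])]
    expect_lt(abs(peak - R), 6, label = paste("repeat", R))
  }
})

test_that("call sampling respects protection, leak and efficiency", {
  flat <- function(level)
    build_landscape(20000, background = level)
  cfg0 <- sim_config(background_leak = 0, enzyme_efficiency = 1, seed = 2)
  closed <- sample_nome_calls(flat(1), cfg0)
  expect_true(all(closed$n_meth == 0))
  open <- sample_nome_calls(flat(1e-12), cfg0)
  expect_true(all(open$n_meth == open$n_total))
  # occupancy 0.5, leak 0, efficiency 0.8: pooled level 0.40
  cfg <- sim_config(background_leak = 0, enzyme_efficiency = 0.8,
                    mean_depth = 30, seed = 3)
  half <- sample_nome_calls(flat(0.5), cfg,
                            positions = seq_len(10000) * 2)
  expect_equal(methylation_level(half), 0.40, tolerance = 0.01)
  expect_true(all(half$n_meth <= half$n_total))
  # determinism under an identical config
  again <- sample_nome_calls(flat(0.5), cfg,
                             positions = seq_len(10000) * 2)
  expect_identical(half, again)
})

test_that("truth NDRs are more labeled than occupied background", {
  land <- build_landscape(50000,
                          ndrs = data.frame(start = c(10000, 30000),
                                            end = c(10300, 30300)))
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed)
    calls <- sample_nome_calls(land, cfg)
    inside <- calls$pos >= 10000 & calls$pos < 10300 |
      calls$pos >= 30000 & calls$pos < 30300
    expect_gt(methylation_level(calls[inside, ]),
              methylation_level(calls[!inside, ]))
  }
})

test_that("promoter sampling hits the class design", {
  tt <- promoter_truth(tss = c(5000, 15000, 25000), strand = "+",
                       class_truth = c("UU", "MU", "MM"),
                       level_a = c(0.01, 0.85, 0.80),
                       level_b = c(0.01, 0.01, 0.40))
  sp <- sample_promoters(tt, sim_config(seed = 8, mean_depth = 40),
                         chrom_length = 40000)
  prom <- data.frame(gene = tt$gene, chrom = "chrS", tss = tt$tss,
                     strand = tt$strand)
  sa <- summarize_promoter_windows(sp$hcg_a, prom)
  sb <- summarize_promoter_windows(sp$hcg_b, prom)
  expect_lt(sa$level[1], 0.05)
  expect_lt(sb$level[1], 0.05)
  expect_equal(classify_promoters(sa, sb), c("UU", "MU", "MM"))
  expect_equal(nrow(sp$tss), 3)
  expect_true(all(sp$cgi$end > sp$cgi$start))
})

test_that("a 2-HCG-site promoter ends up unclassified downstream", {
  tt <- promoter_truth(tss = 5000, strand = "+", class_truth = "UU",
                       level_a = 0.01, level_b = 0.01, n_sites = 2L)
  sp <- sample_promoters(tt, sim_config(seed = 9), chrom_length = 10000)
  prom <- data.frame(gene = "g", chrom = "chrS", tss = 5000,
                     strand = "+")
  lab <- classify_promoters(summarize_promoter_windows(sp$hcg_a, prom),
                            summarize_promoter_windows(sp$hcg_b, prom))
  expect_equal(lab, "unclassified")
})

test_that("the bundled experiment is deterministic and self-consistent", {
  sim1 <- simulate_nome_experiment(chrom_length = 3e5, n_ndr = 5,
                                   config = sim_config(seed = 21))
  sim2 <- simulate_nome_experiment(chrom_length = 3e5, n_ndr = 5,
                                   config = sim_config(seed = 21))
  expect_identical(sim1$gch_a, sim2$gch_a)
  expect_identical(sim1$hcg_b, sim2$hcg_b)
  expect_true(all(sim1$truth_ndrs_b$end <= 3e5))
  # replicates share positions but not counts
  expect_identical(sim1$gch_b[[1]]$pos, sim1$gch_b[[2]]$pos)
  expect_false(identical(sim1$gch_b[[1]]$n_meth, sim1$gch_b[[2]]$n_meth))
})
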