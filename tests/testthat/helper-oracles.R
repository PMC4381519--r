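# Shared fixture builders and independent oracles.

# quick GCH call table on one chromosome
make_calls <- function(pos, k, n, chrom = "chrS", context = "GCH") {
  data.frame(chrom = rep(chrom, length(pos)), pos = as.integer(pos),
             strand = rep("+", length(pos)),
             context = rep(context, length(pos)),
             n_meth = as.integer(rep(k, length.out = length(pos))),
             n_total = as.integer(rep(n, length.out = length(pos))),
             stringsAsFactors = FALSE)
}

rand_chain <- function(T, seed, spacing = 20, depth = 15) {
  set.seed(seed)
  n <- rpois(T, depth)
  make_calls(pos = cumsum(1 + rgeom(T, 1 / spacing)),
             k = rbinom(T, n, runif(T)), n = n)
}

# beta-binomial pmf by an independent product-form evaluation
# (no gamma functions): choose(n,k) * prod(a+i) * prod(b+j) / prod(a+b+l)
bb_pmf_product <- function(k, n, a, b) {
  num1 <- if (k > 0) prod(a + 0:(k - 1)) else 1
  num2 <- if (n - k > 0) prod(b + 0:(n - k - 1)) else 1
  den <- if (n > 0) prod(a + b + 0:(n - 1)) else 1
  choose(n, k) * num1 * num2 / den
}

# exhaustive maximum-likelihood path over all 2^T state sequences of a
# single chain; random continuous parameters make ties have probability 0
oracle_viterbi <- function(calls, object) {
  T <- nrow(calls)
  le <- cbind(dbetabinom(calls$n_meth, calls$n_total,
                         object$emission[1, 1], object$emission[1, 2]),
              dbetabinom(calls$n_meth, calls$n_total,
                         object$emission[2, 1], object$emission[2, 2]))
  la <- log(object$transition)
  lp <- log(object$initial)
  best <- -Inf
  best_path <- NULL
  for (m in 0:(2^T - 1)) {
    s <- as.integer(intToBits(m))[seq_len(T)] + 1L
    sc <- lp[s[1]] + sum(le[cbind(seq_len(T), s)])
    if (T > 1)
      sc <- sc + sum(la[cbind(s[-T], s[-1])])
    if (sc > best) {
      best <- sc
      best_path <- s
    }
  }
  factor(c("protected", "accessible")[best_path],
         levels = c("protected", "accessible"))
}

rand_params <- function(seed) {
  set.seed(seed)
  m <- sort(runif(2, 0.05, 0.95))
  if (m[2] - m[1] < 0.05) m[2] <- min(m[1] + 0.05, 0.99)
  a <- runif(2, 0.6, 0.98)
  nome_hmm_params(mean = m, dispersion = runif(2, 0.01, 0.3),
                  transition = matrix(c(a[1], 1 - a[1], 1 - a[2], a[2]),
                                      2, 2, byrow = TRUE),
                  initial = c(p <- runif(1, 0.1, 0.9), 1 - p))
}

# phased-promoter simulation used by the phasing/subclustering tests:
# `frac_ndr` of promoters gain a central NDR, the rest positioned arrays
# (nucleosome on the TSS), the dominant MU configuration
phased_promoter_sim <- function(R = 190, n_prom = 500, seed = 1,
                                depth = 25, frac_ndr = 0, decay = 0.75) {
  slot <- 3000
  L <- n_prom * slot
  tss <- round(seq(slot / 2, L - slot / 2, length.out = n_prom))
  is_ndr <- seq_len(n_prom) %% round(1 / max(frac_ndr, 1e-9)) == 0 &
    frac_ndr > 0
  arrays <- data.frame(anchor = tss, repeat_length = R, n_nuc = 5,
                       decay = decay, center_bump = !is_ndr)
  ndrs <- if (any(is_ndr))
    data.frame(start = tss[is_ndr] - 100L, end = tss[is_ndr] + 100L)
  else NULL
  land_b <- build_landscape(L, ndrs = ndrs, arrays = arrays)
  land_a <- build_landscape(L)        # closed: constant background
  pos <- simulate_sites(L, 15, seed = seed + 5)
  gb <- sample_nome_calls(land_b, sim_config(seed = seed,
                                             mean_depth = depth),
                          positions = pos)
  ga <- sample_nome_calls(land_a, sim_config(seed = seed + 1,
                                             mean_depth = depth),
                          positions = pos)
  list(gch_a = ga, gch_b = gb,
       promoters = data.frame(chrom = "chrS", tss = tss,
                              strand = rep(c("+", "-"),
                                           length.out = n_prom)),
       truth_sub = ifelse(is_ndr, "NDR", "NP"))
}

overlap_frac <- function(query, subject) {
  if (!nrow(query)) return(NA_real_)
  hits <- vapply(seq_len(nrow(query)), function(i) {
    s <- subject[subject$chrom == query$chrom[i], , drop = FALSE]
    any(s$start < query$end[i] & s$end > query$start[i])
  }, TRUE)
  mean(hits)
}
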