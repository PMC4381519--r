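#' Construct two-state accessibility HMM parameters
#'
#' Builds an (unfitted) `nome_hmm` object describing the two-state
#' beta-binomial hidden Markov model used to segment the ordered GCH
#' methylation series of a NOMe-seq sample.  State 1 ("protected") emits low
#' GpC methylation (nucleosome-occupied DNA, MPR), state 2 ("accessible")
#' high GpC methylation (linker/NDR DNA, MAR).
#'
#' @param mean Length-2 vector of emission means (protected, accessible);
#'   the accessible mean must be strictly larger (identifiability ordering).
#' @param dispersion Length-2 vector of intra-site correlations
#'   `rho = 1 / (alpha + beta + 1)` in (0, 1); `rho -> 0` approaches a
#'   binomial emission.
#' @param transition 2x2 row-stochastic transition matrix between
#'   consecutive GCH sites of a chain.
#' @param initial Length-2 initial state distribution.
#' @param max_gap Chains are broken at inter-site gaps larger than this many
#'   bp and treated as independent sequences (default 500).
#' @return An object of class `nome_hmm`.
#' @seealso [fit_nome_hmm()], [predict.nome_hmm()], [simulate.nome_hmm()]
#' @export
nome_hmm_params <- function(mean = c(0.1, 0.7), dispersion = c(0.05, 0.05),
                            transition = matrix(c(0.95, 0.05, 0.05, 0.95),
                                                2, 2, byrow = TRUE),
                            initial = c(0.5, 0.5), max_gap = 500) {
  stopifnot(length(mean) == 2, length(dispersion) == 2,
            all(mean > 0 & mean < 1), all(dispersion > 0 & dispersion < 1))
  if (mean[2] <= mean[1])
    stop("accessible-state mean must exceed protected-state mean")
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-12)
    stop("initial distribution must sum to 1")
  emission <- rbind(.bb_shape(mean[1], dispersion[1]),
                    .bb_shape(mean[2], dispersion[2]))
  dimnames(emission) <- list(c("protected", "accessible"),
                             c("alpha", "beta"))
  dimnames(transition) <- list(c("protected", "accessible"),
                               c("protected", "accessible"))
  structure(list(emission = emission, transition = transition,
                 initial = setNames(initial, c("protected", "accessible")),
                 max_gap = max_gap, loglik = numeric(0), niter = 0L,
                 converged = NA, n_sites = NA_integer_,
                 n_chains = NA_integer_, call = sys.call()),
            class = "nome_hmm")
}

# 0-based chain offsets: break at chromosome changes and gaps > max_gap.
.chain_offsets <- function(calls, max_gap) {
  n <- nrow(calls)
  if (n == 0) return(0L)
  brk <- which(calls$chrom[-1] != calls$chrom[-n] |
                 calls$pos[-1] - calls$pos[-n] > max_gap)
  as.integer(c(0L, brk, n))
}

.log_emission <- function(calls, emission, lc = NULL) {
  k <- calls$n_meth; n <- calls$n_total
  if (is.null(lc)) lc <- lchoose(n, k)   # constant per data set
  le <- function(a, b) lc + lbeta(k + a, n - k + b) - lbeta(a, b)
  cbind(le(emission[1, 1], emission[1, 2]),
        le(emission[2, 1], emission[2, 2]))
}

.sort_calls <- function(calls) {
  o <- order(calls$chrom, calls$pos)
  if (is.unsorted(o)) calls <- calls[o, ]
  rownames(calls) <- NULL
  calls
}

# Expected complete-data log-likelihood contribution of one state's
# emission, dropping the lchoose(n, k) term (constant across candidates).
.emission_q <- function(par, k, n, g) {
  sum(g * (lbeta(k + par[1], n - k + par[2]) - lbeta(par[1], par[2])))
}

# Generalized-EM emission update: method-of-moments proposal on
# responsibility-weighted counts, with the previous parameters as fallback
# so the Q function (and hence the log-likelihood) never decreases; with
# exact = TRUE an L-BFGS-B refinement of Q on (log alpha, log beta) is
# added to the candidate set.
.update_emission <- function(old, k, n, g, exact = FALSE) {
  use <- n > 0 & g > 0
  k <- k[use]; n <- n[use]; g <- g[use]
  if (!length(k)) return(old)
  mu <- sum(g * k) / sum(g * n)
  mu <- min(max(mu, 1e-4), 1 - 1e-4)
  den <- sum(g * n * (n - 1)) * mu * (1 - mu)
  rho <- if (den > 0)
    sum(g * ((k - n * mu)^2 - n * mu * (1 - mu))) / den else 0.01
  rho <- min(max(rho, 1e-6), 0.95)
  cand <- list(old, .bb_shape(mu, rho))
  q <- vapply(cand, .emission_q, 0, k = k, n = n, g = g)
  if (exact) {
    start <- log(cand[[which.max(q)]])
    opt <- tryCatch(
      optim(start, function(lp) -.emission_q(exp(lp), k, n, g),
            method = "L-BFGS-B", lower = log(1e-3), upper = log(1e6)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      cand <- c(cand, list(setNames(exp(opt$par), c("alpha", "beta"))))
      q <- c(q, .emission_q(exp(opt$par), k, n, g))
    }
  }
  cand[[which.max(q)]]
}

.order_states <- function(object) {
  m <- .bb_mean(object$emission[, 1], object$emission[, 2])
  if (m[1] > m[2]) {
    object$emission <- object$emission[2:1, ]
    object$transition <- object$transition[2:1, 2:1]
    object$initial <- object$initial[2:1]
    dimnames(object$emission) <- list(c("protected", "accessible"),
                                      c("alpha", "beta"))
    dimnames(object$transition) <- list(c("protected", "accessible"),
                                        c("protected", "accessible"))
    names(object$initial) <- c("protected", "accessible")
  }
  object
}

#' Fit the two-state beta-binomial accessibility HMM
#'
#' Fits the model to the ordered GCH series of one sample replicate by
#' expectation-maximization (forward-backward in log space).  Chains are
#' broken at inter-site gaps larger than `max_gap` bp and treated as
#' independent sequences.  The emission M-step uses method-of-moments
#' estimates on responsibility-weighted counts with a likelihood guard
#' (see Details), so the log-likelihood is non-decreasing across iterations.
#'
#' @details The method-of-moments update is fast and usually optimal in
#' practice, but it does not by itself guarantee an increase of the expected
#' complete-data log-likelihood.  Each update therefore keeps the best of
#' (previous parameters, moment estimate) under the Q function, so the
#' update is a generalized EM step; `emission_update = "exact"` adds a
#' quasi-Newton maximization of Q to the candidate set.
#'
#' @param calls GCH cytosine call data.frame (see
#'   [read_cytosine_report()]); sorted internally by chromosome and
#'   position.  At least 100 covered sites are required.
#' @param init Optional starting `nome_hmm` object from
#'   [nome_hmm_params()]; a default moderate-separation start is used
#'   otherwise.
#' @param max_iter,tol EM stops when the log-likelihood gain drops below
#'   `tol` or after `max_iter` iterations (with a warning).
#' @param max_gap Chain-break distance in bp (default 500).
#' @param emission_update `"moment"` (guarded method of moments, default)
#'   or `"exact"` (always refine numerically).
#' @param verbose Print the log-likelihood per iteration.
#' @return A fitted `nome_hmm` object; `$loglik` holds the per-iteration
#'   log-likelihood trace.
#' @examples
#' truth <- nome_hmm_params(mean = c(0.05, 0.75),
#'                          transition = matrix(c(0.98, 0.02, 0.02, 0.98),
#'                                              2, 2, byrow = TRUE))
#' sim <- simulate(truth, positions = seq(0, by = 15, length.out = 2000),
#'                 depth = 30, seed = 1)
#' fit <- fit_nome_hmm(sim)
#' coef(fit)$mean
#' @export
fit_nome_hmm <- function(calls, init = NULL, max_iter = 100, tol = 1e-6,
                         max_gap = 500,
                         emission_update = c("moment", "exact"),
                         verbose = FALSE) {
  emission_update <- match.arg(emission_update)
  .stopifnot_calls(calls)
  calls <- .sort_calls(calls)
  if (sum(calls$n_total > 0) < 100)
    stop("need at least 100 covered GCH sites to fit the HMM")
  if (sum(calls$n_meth) == 0)
    warning("all methylated counts are zero; emission means pinned low")
  object <- if (is.null(init)) nome_hmm_params(max_gap = max_gap) else init
  object$max_gap <- max_gap
  offsets <- .chain_offsets(calls, max_gap)
  n_chains <- length(offsets) - 1L
  k <- calls$n_meth; n <- calls$n_total
  lc <- lchoose(n, k)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- .fb_cpp(.log_emission(calls, object$emission, lc),
                  log(object$transition), log(object$initial), offsets)
    ll_trace <- c(ll_trace, fb$loglik)
    if (verbose) message(sprintf("iter %3d  logLik %.4f", it, fb$loglik))
    if (it > 1 && fb$loglik - ll_trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
    # M-step
    for (s in 1:2)
      object$emission[s, ] <- .update_emission(
        object$emission[s, ], k, n, fb$gamma[, s],
        exact = emission_update == "exact")
    A <- fb$xi
    rs <- rowSums(A)
    for (s in 1:2)
      if (rs[s] > 0) object$transition[s, ] <- A[s, ] / rs[s]
    pi0 <- fb$first / n_chains
    pi0 <- pmin(pmax(pi0, 1e-12), 1)
    object$initial[] <- pi0 / sum(pi0)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations; ",
            "final log-likelihood ", format(ll_trace[length(ll_trace)]))
  object <- .order_states(object)
  object$loglik <- ll_trace
  object$niter <- length(ll_trace)
  object$converged <- converged
  object$n_sites <- nrow(calls)
  object$n_chains <- n_chains
  object$call <- match.call()
  object
}

#' Decode per-site chromatin states
#'
#' Applies the Viterbi algorithm (maximum a posteriori joint state path,
#' log-space arithmetic, ties resolved toward the protected state) or
#' returns per-site posterior state probabilities from the forward-backward
#' recursions.
#'
#' @param object A `nome_hmm` object.
#' @param newdata GCH cytosine call data.frame; sorted internally.
#' @param type `"viterbi"` (default) for the decoded path, `"posterior"`
#'   for a two-column probability matrix.
#' @param ... Unused.
#' @return For `"viterbi"`, a factor with levels `protected`/`accessible`
#'   aligned to the sorted sites; for `"posterior"`, a numeric matrix.
#' @export
predict.nome_hmm <- function(object, newdata,
                             type = c("viterbi", "posterior"), ...) {
  type <- match.arg(type)
  .stopifnot_calls(newdata)
  newdata <- .sort_calls(newdata)
  if (nrow(newdata) == 0)
    return(if (type == "viterbi")
      factor(character(0), levels = c("protected", "accessible"))
      else matrix(numeric(0), 0, 2))
  offsets <- .chain_offsets(newdata, object$max_gap)
  le <- .log_emission(newdata, object$emission)
  if (type == "viterbi") {
    path <- .viterbi_cpp(le, log(object$transition), log(object$initial),
                         offsets)
    factor(c("protected", "accessible")[path + 1L],
           levels = c("protected", "accessible"))
  } else {
    fb <- .fb_cpp(le, log(object$transition), log(object$initial), offsets)
    colnames(fb$gamma) <- c("protected", "accessible")
    fb$gamma
  }
}

#' Simulate GCH calls from the HMM
#'
#' Draws a state path along the supplied site positions (chains broken at
#' `max_gap` as in fitting), then per-site read totals and beta-binomial
#' methylated counts.  Used for parameter-recovery checks and power
#' calculations.
#'
#' @param object A `nome_hmm` object.
#' @param nsim Number of replicate data sets.
#' @param seed Optional RNG seed.
#' @param positions Integer vector of site positions (0-based, sorted).
#' @param chrom Chromosome name for the output records.
#' @param depth Mean read depth per site.
#' @param depth_dispersion Negative-binomial overdispersion of the depth;
#'   0 gives Poisson depths.
#' @param states Optional fixed state path (1 = protected, 2 = accessible)
#'   to condition on instead of simulating one.
#' @param ... Unused.
#' @return A cytosine call data.frame with a `state` attribute holding the
#'   simulated path (a list of data.frames when `nsim > 1`).
#' @export
simulate.nome_hmm <- function(object, nsim = 1, seed = NULL,
                              positions, chrom = "chrS", depth = 30,
                              depth_dispersion = 0, states = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  positions <- sort(as.integer(positions))
  TT <- length(positions)
  one <- function() {
    if (is.null(states)) {
      st <- integer(TT)
      calls0 <- data.frame(chrom = chrom, pos = positions)
      offsets <- .chain_offsets(calls0, object$max_gap)
      for (c in seq_len(length(offsets) - 1L)) {
        s <- offsets[c] + 1L; e <- offsets[c + 1L]
        st[s] <- sample(1:2, 1, prob = object$initial)
        if (e > s) for (t in (s + 1L):e)
          st[t] <- sample(1:2, 1, prob = object$transition[st[t - 1L], ])
      }
    } else st <- states
    n <- if (depth_dispersion > 0)
      rnbinom(TT, mu = depth, size = 1 / depth_dispersion)
    else rpois(TT, depth)
    k <- rbetabinom(n, object$emission[st, 1], object$emission[st, 2])
    out <- data.frame(chrom = chrom, pos = positions,
                      strand = sample(c("+", "-"), TT, replace = TRUE),
                      context = "GCH", n_meth = k, n_total = n,
                      stringsAsFactors = FALSE)
    attr(out, "state") <- st
    out
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @exportS3Method stats::coef
coef.nome_hmm <- function(object, ...) {
  list(emission = object$emission,
       mean = .bb_mean(object$emission[, 1], object$emission[, 2]),
       dispersion = .bb_rho(object$emission[, 1], object$emission[, 2]),
       transition = object$transition,
       initial = object$initial)
}

#' @exportS3Method stats::logLik
logLik.nome_hmm <- function(object, ...) {
  ll <- if (length(object$loglik)) object$loglik[length(object$loglik)]
  else NA_real_
  structure(ll, df = 7L, nobs = object$n_sites, class = "logLik")
}

#' @export
print.nome_hmm <- function(x, ...) {
  m <- .bb_mean(x$emission[, 1], x$emission[, 2])
  cat("Two-state beta-binomial accessibility HMM",
      if (length(x$loglik)) "(fitted)" else "(unfitted)", "\n")
  cat(sprintf("  emission means: protected %.3f, accessible %.3f\n",
              m[1], m[2]))
  cat(sprintf("  self-transitions: %.4f / %.4f; max_gap %d bp\n",
              x$transition[1, 1], x$transition[2, 2], x$max_gap))
  if (length(x$loglik))
    cat(sprintf("  logLik %.2f after %d EM iterations (%s) on %d sites\n",
                x$loglik[length(x$loglik)], x$niter,
                if (isTRUE(x$converged)) "converged" else "not converged",
                x$n_sites))
  invisible(x)
}

#' @exportS3Method base::summary
summary.nome_hmm <- function(object, ...) {
  m <- .bb_mean(object$emission[, 1], object$emission[, 2])
  rho <- .bb_rho(object$emission[, 1], object$emission[, 2])
  out <- list(
    emission = cbind(object$emission, mean = m, rho = rho),
    transition = object$transition,
    initial = object$initial,
    expected_run_sites = 1 / (1 - diag(object$transition)),
    loglik = if (length(object$loglik))
      object$loglik[length(object$loglik)] else NA_real_,
    niter = object$niter, converged = object$converged,
    n_sites = object$n_sites, n_chains = object$n_chains)
  class(out) <- "summary.nome_hmm"
  out
}

#' @export
print.summary.nome_hmm <- function(x, ...) {
  cat("Two-state beta-binomial accessibility HMM\n\nEmission parameters:\n")
  print(round(x$emission, 4))
  cat("\nTransition matrix:\n")
  print(round(x$transition, 4))
  cat("\nInitial distribution:", round(x$initial, 4), "\n")
  cat("Expected run length (sites): protected",
      round(x$expected_run_sites[1], 1), ", accessible",
      round(x$expected_run_sites[2], 1), "\n")
  cat(sprintf("logLik %.2f, %d iterations, %d sites in %d chains\n",
              x$loglik, x$niter, x$n_sites, x$n_chains))
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.nome_hmm <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  if (length(x$loglik))
    plot(seq_along(x$loglik), x$loglik, type = "b", pch = 16,
         xlab = "EM iteration", ylab = "log-likelihood",
         main = "EM trace", ...)
  p <- seq(0.001, 0.999, length.out = 400)
  d1 <- stats::dbeta(p, x$emission[1, 1], x$emission[1, 2])
  d2 <- stats::dbeta(p, x$emission[2, 1], x$emission[2, 2])
  plot(p, d1, type = "l", col = "steelblue", ylim = range(0, d1, d2),
       xlab = "methylation fraction", ylab = "density",
       main = "Emission distributions")
  lines(p, d2, col = "firebrick")
  legend("top", legend = c("protected", "accessible"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
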