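#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution, the emission model of the
#' two-state accessibility HMM: the per-read labeling probability is drawn
#' from `Beta(alpha, beta)` and `k` successes are observed among `n` reads.
#' Evaluated through log-gamma functions so that large counts stay finite.
#'
#' @param k Number of methylated (converted-protected) reads, `0 <= k <= n`.
#' @param n Total read count at the site.
#' @param alpha,beta Positive shape parameters; the mean methylation fraction
#'   is `alpha / (alpha + beta)`.
#' @param log Return the log density (default `TRUE`).
#' @return Numeric vector of (log) probabilities, recycled to the common
#'   length of the inputs.  `k = n = 0` gives probability 1: an uncovered
#'   site carries no information.
#' @examples
#' dbetabinom(3, 10, 1, 1)          # uniform on 0..10 -> 1/11
#' sum(exp(dbetabinom(0:20, 20, 2.5, 1.3)))  # sums to 1
#' @export
dbetabinom <- function(k, n, alpha, beta, log = TRUE) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("'alpha' and 'beta' must be positive")
  if (any(k < 0) || any(k > n))
    stop("'k' must satisfy 0 <= k <= n")
  out <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  if (log) out else exp(out)
}

# mean/overdispersion <-> (alpha, beta); rho = 1/(alpha + beta + 1) is the
# intra-site correlation, rho -> 0 recovers the binomial.
.bb_shape <- function(mu, rho) {
  s <- 1 / rho - 1
  c(alpha = mu * s, beta = (1 - mu) * s)
}

.bb_mean <- function(alpha, beta) alpha / (alpha + beta)

.bb_rho <- function(alpha, beta) 1 / (alpha + beta + 1)

#' Simulate beta-binomial counts
#'
#' @param n_total Integer vector of read totals.
#' @param alpha,beta Shape parameters.
#' @return Integer vector of methylated counts, one per entry of `n_total`.
#' @export
rbetabinom <- function(n_total, alpha, beta) {
  p <- stats::rbeta(length(n_total), alpha, beta)
  stats::rbinom(length(n_total), n_total, p)
}
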