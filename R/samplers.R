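#' Prior scale from an assumed per-locus effect variance
#'
#' The scaled inverse chi-square(v, S2) prior has mean v S2 / (v - 2), so
#' fixing the prior mean of the SNP-effect variance at `expected_sigma_j2`
#' gives S2 = (v - 2) E(sigma_j2) / v.  The conventional methods use v = 4.2.
#'
#' @param v prior degrees of freedom (> 2).
#' @param expected_sigma_j2 assumed per-locus effect variance (> 0).
#' @return The prior scale S2.
#' @export
derive_scale <- function(v, expected_sigma_j2) {
  if (v <= 2) stop("prior mean undefined for v <= 2")
  if (expected_sigma_j2 <= 0) stop("expected_sigma_j2 must be positive")
  (v - 2) * expected_sigma_j2 / v
}

#' Scaled inverse chi-square draws
#'
#' Draws from scaled-inv-chisq(df, scale), i.e. df * scale / chisq(df).
#'
#' @param n number of draws.
#' @param df degrees of freedom.
#' @param scale scale parameter.
#' @return numeric vector of draws.
#' @export
rscinvchisq <- function(n, df, scale) df * scale / rchisq(n, df)

#' Per-locus effect-variance full conditional (BayesA/FA family)
#'
#' sigma_j^2 | alpha_j, v, S2 ~ scaled-inv-chisq(v + 1, (v S2 + alpha_j^2)/(v + 1)):
#' the data add exactly one degree of freedom to the prior.
#'
#' @param alpha_j current effect of the locus.
#' @param v,S2 current prior degrees of freedom and scale.
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
sample_variance_perlocus <- function(alpha_j, v, S2, n = 1) {
  (v * S2 + alpha_j^2) / rchisq(n, v + 1)
}

#' Common effect-variance full conditional (BayesCpi/FCpi family)
#'
#' sigma_a^2 | alpha, v, S2 ~ scaled-inv-chisq(v + q, (v S2 + sum alpha_j^2)/(v + q))
#' where q is the number of loci with a non-zero effect this cycle.
#'
#' @param alpha vector of the q non-zero effects (may be empty).
#' @param v,S2 current prior degrees of freedom and scale.
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
sample_variance_common <- function(alpha, v, S2, n = 1) {
  q <- length(alpha)
  (v * S2 + sum(alpha^2)) / rchisq(n, v + q)
}

#' Mixture-weight full conditional
#'
#' pi | q ~ Beta(P - q + 1, q + 1): pi is the prior probability that a SNP
#' effect is exactly zero, q the current number of non-zero effects.
#'
#' @param P total number of loci.
#' @param q number of non-zero effects.
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
sample_pi <- function(P, q, n = 1) {
  stopifnot(q >= 0, q <= P)
  rbeta(n, P - q + 1, q + 1)
}

#' Scale full conditional under the Gamma(1, 1) prior
#'
#' S2 | v, sigma^2_(1..q) ~ Gamma(shape = v q / 2 + 1,
#' rate = v/2 sum(1/sigma_j^2) + 1); with q = 0 it returns the Gamma(1, 1)
#' prior.
#'
#' @param v current degrees of freedom.
#' @param sigma_j2 vector of the q positive effect variances.
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
sample_scale <- function(v, sigma_j2, n = 1) {
  q <- length(sigma_j2)
  rgamma(n, shape = v * q / 2 + 1, rate = v / 2 * sum(1 / sigma_j2) + 1)
}

#' Exponent of the degrees-of-freedom full conditional
#'
#' eta = 1/2 sum log(sigma_j^2 / S2) + 1/2 sum (S2 / sigma_j^2) + c, where c
#' is lambda for the Exponential(lambda) prior (variant `"exp"`, BayesFA and
#' BayesFCpi) and 1 for the Gamma(4, 1) prior (variant `"gamma4"`, BayesFB).
#' The bound eta >= q/2 + c always holds (t - log t >= 1) and is asserted.
#'
#' @param sigma_j2 positive effect variances entering the likelihood.
#' @param S2 current scale.
#' @param variant `"exp"` or `"gamma4"`.
#' @param lambda rate of the exponential prior (default 0.25).
#' @return eta (scalar).
#' @export
compute_eta <- function(sigma_j2, S2, variant = c("exp", "gamma4"),
                        lambda = 0.25) {
  variant <- match.arg(variant)
  stopifnot(all(sigma_j2 > 0), S2 > 0)
  shift <- if (variant == "exp") lambda else 1
  q <- length(sigma_j2)
  eta <- 0.5 * sum(log(sigma_j2 / S2)) + 0.5 * sum(S2 / sigma_j2) + shift
  if (eta < q / 2 + shift - 1e-8)
    stop("internal error: eta bound violated (numeric corruption)")
  eta
}

.variant_code <- function(variant) {
  switch(match.arg(variant, c("exp", "gamma4")), exp = 1L, gamma4 = 2L)
}

#' Log unnormalised degrees-of-freedom target density
#'
#' log f(x; q, eta) = (q x / 2) log(x/2) - q log Gamma(x/2) - eta x, plus
#' 3 log(x) under the Gamma(4, 1) prior variant.
#'
#' @param x evaluation points (> 0).
#' @param q number of variance terms in the likelihood.
#' @param eta exponent from [compute_eta()].
#' @param variant `"exp"` or `"gamma4"`.
#' @return log density values (unnormalised).
#' @export
log_target_df <- function(x, q, eta, variant = c("exp", "gamma4")) {
  vc <- .variant_code(variant)
  if (any(x <= 0)) stop("x must be positive")
  vapply(x, cpp_log_target_df, numeric(1), q = q, eta = eta, variant = vc)
}

#' Root of the envelope derivative h(x)
#'
#' h(x) = (q/2)\[log(x/2) + 1 - digamma(x/2)\] + 1/x - eta (plus 3/x under
#' the Gamma(4,1) variant) is strictly decreasing from +Inf to q/2 - eta < 0,
#' so its root x* is unique; it is found by exponential bracketing followed
#' by bisection to |h| < 1e-10.  The accept-reject envelope uses the
#' exponential proposal with rate theta = 1/x*.
#'
#' @inheritParams log_target_df
#' @return x*, the root of h.
#' @export
solve_x_star <- function(q, eta, variant = c("exp", "gamma4")) {
  vc <- .variant_code(variant)
  stopifnot(q >= 0, eta > q / 2)
  cpp_solve_x_star(q, eta, vc)
}

#' Accept-reject draws of the prior degrees of freedom
#'
#' Proposes from Exponential(theta = 1/x*) and accepts with probability
#' f(c) / (M g(c)), where log M = log f(x*) - log g(x*).  With q = 0 the
#' target reduces to the prior and is drawn directly.  Envelope domination
#' is checked for every proposal.
#'
#' @param n number of draws.
#' @inheritParams log_target_df
#' @return list with `draws`, `n_proposals`, `n_accepts`,
#'   `n_envelope_violations` and `x_star`.
#' @export
sample_df_accept_reject <- function(n, q, eta, variant = c("exp", "gamma4")) {
  vc <- .variant_code(variant)
  cpp_sample_df(as.integer(n), q, eta, vc)
}

#' One Gibbs update of a single SNP effect
#'
#' Draws alpha_j from its normal full conditional
#' N(C z'r / sigma_e^2, C) with C = sigma_e^2 / (z'z + sigma_e^2/sigma_j^2),
#' where r is the residual with locus j's contribution removed.
#'
#' @param z genotype column of the locus.
#' @param r residual vector excluding locus j.
#' @param sigma_e2 residual variance.
#' @param sigma_j2 effect variance of the locus.
#' @return list with `alpha` (the draw), `mean` and `var` of the full
#'   conditional.  A monomorphic locus (zero genotype variance) gets
#'   `alpha = 0` with a warning.
#' @export
sample_effect <- function(z, r, sigma_e2, sigma_j2) {
  if (var(z) <= 1e-12) {
    warning("monomorphic locus: effect forced to 0")
    return(list(alpha = 0, mean = 0, var = 0))
  }
  C <- sigma_e2 / (sum(z^2) + sigma_e2 / sigma_j2)
  m <- C * sum(z * r) / sigma_e2
  list(alpha = rnorm(1, m, sqrt(C)), mean = m, var = C)
}

#' Genomic estimated breeding values from posterior-mean effects
#'
#' GEBV_i = sum_j Z_ij alpha_j.
#'
#' @param Z N x P genotype code matrix.
#' @param alpha vector of P posterior-mean SNP effects.
#' @return numeric vector of N GEBVs.
#' @export
compute_gebv <- function(Z, alpha) {
  Z <- if (inherits(Z, "genotype_matrix")) Z$codes else as.matrix(Z)
  if (ncol(Z) != length(alpha)) stop("dimension mismatch between Z and alpha")
  drop(Z %*% alpha)
}
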