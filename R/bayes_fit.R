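.method_table <- list(
  bayesA   = list(family = 0L, v_mode = 0L, s2_mode = 0L, default_pi = 0),
  bayesB   = list(family = 1L, v_mode = 0L, s2_mode = 0L, default_pi = 0.996),
  bayesCpi = list(family = 2L, v_mode = 0L, s2_mode = 0L, default_pi = 0.8),
  bayesFA  = list(family = 0L, v_mode = 1L, s2_mode = 1L, default_pi = 0),
  bayesFB  = list(family = 1L, v_mode = 2L, s2_mode = 1L, default_pi = 0.996),
  bayesFCpi = list(family = 2L, v_mode = 1L, s2_mode = 1L, default_pi = 0.8)
)

#' MCMC settings for the Bayesian-alphabet samplers
#'
#' @param n_iter total Gibbs cycles (default 50000).
#' @param burn_in cycles discarded before averaging (default 10000).
#' @param mh_cycles Metropolis-Hastings proposals per locus per cycle for the
#'   B-family variance indicator (default 100).
#' @param seed integer seed for the chain.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 50000, burn_in = 10000, mh_cycles = 100,
                          seed = NULL) {
  stopifnot(burn_in < n_iter, mh_cycles >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 mh_cycles = as.integer(mh_cycles), seed = seed),
            class = "mcmc_settings")
}

#' Fit a Bayesian whole-genome regression model
#'
#' Runs the Gibbs/MH chain for the model y = Xb + Z alpha + e.  Conventional
#' methods (`bayesA`, `bayesB`, `bayesCpi`) fix the SNP-variance prior at
#' v = 4.2 with a scale derived from an assumed per-locus variance; the
#' flexible methods (`bayesFA`, `bayesFB`, `bayesFCpi`) place an
#' Exponential(0.25) (FA, FCpi) or Gamma(4, 1) (FB) prior on the degrees of
#' freedom, sampled by accept-reject, and a Gamma(1, 1) prior on the scale,
#' sampled by Gibbs.
#'
#' @param geno [genotype_matrix()] or plain N x P code matrix (no missing
#'   values; impute first).
#' @param pheno numeric phenotype vector aligned with the genotype rows, or a
#'   phenotype table with `id` and `trait` columns matched against the
#'   genotype ids.
#' @param method one of `"bayesA"`, `"bayesB"`, `"bayesCpi"`, `"bayesFA"`,
#'   `"bayesFB"`, `"bayesFCpi"`.
#' @param X fixed-effect design matrix (default: an intercept column).
#' @param settings an [mcmc_settings()] object.
#' @param pi prior probability of a zero SNP effect for the mixture methods;
#'   defaults: 0.996 (B-family), 0.8 (Cpi-family).  Ignored by the A family.
#' @param sample_pi if `TRUE` (Cpi family) pi is given a Uniform(0, 1) prior
#'   and updated from Beta(P - q + 1, q + 1) each cycle.
#' @param h2_prior assumed heritability used to derive the fixed prior scale
#'   of the conventional methods from the phenotypic variance (default 0.5).
#' @param lambda rate of the exponential prior on v (default 0.25).
#' @param fix_v,fix_scale optional values freezing the degrees of freedom
#'   and/or scale of a flexible method (used to check the reduction to the
#'   conventional counterpart).
#' @return An object of class `bayes_fit`: posterior-mean effects `alpha`,
#'   fixed effects `b`, per-locus `inclusion` frequencies, training `gebv`,
#'   `trace` (per-iteration v, S2, pi, sigma_e2, q, sigma_a2), posterior
#'   `summary` of the hyperparameters, and sampler `diagnostics`.
#' @export
bayes_fit <- function(geno, pheno, method = names(.method_table), X = NULL,
                      settings = mcmc_settings(), pi = NULL, sample_pi = FALSE,
                      h2_prior = 0.5, lambda = 0.25,
                      fix_v = NULL, fix_scale = NULL) {
  method <- match.arg(method)
  spec <- .method_table[[method]]
  Z <- if (inherits(geno, "genotype_matrix")) geno$codes else as.matrix(geno)
  if (anyNA(Z)) stop("genotypes contain missing values; run impute_mean() first")
  y <- if (is.data.frame(pheno)) {
    if (!inherits(geno, "genotype_matrix"))
      stop("phenotype table requires a genotype_matrix with ids")
    idx <- match(geno$ids, pheno$id)
    if (anyNA(idx)) stop("phenotype table does not cover all genotyped ids")
    as.numeric(pheno$trait[idx])
  } else as.numeric(pheno)
  if (length(y) != nrow(Z)) stop("phenotype/genotype dimension mismatch")
  if (anyNA(y)) stop("missing trait values in the reference set")
  if (is.null(X)) X <- matrix(1, length(y), 1)

  pi_use <- if (spec$family == 0L) 0 else (pi %||% spec$default_pi)
  if (pi_use < 0 || pi_use > 1) stop("pi must lie in [0, 1]")
  pi_mode <- if (sample_pi && spec$family == 2L) 1L else 0L

  # fixed prior scale of the conventional methods from the assumed additive
  # variance: E(sigma_j2) = h2 var(y) / ((1 - pi) sum 2 p q)
  p_hat <- colMeans(Z) / 2
  sum2pq <- sum(2 * p_hat * (1 - p_hat))
  if (sum2pq <= 0) stop("all loci monomorphic")
  e_sj2 <- h2_prior * var(y) / ((1 - pi_use) * sum2pq)

  v_mode <- spec$v_mode; s2_mode <- spec$s2_mode
  if (!is.null(fix_v)) v_mode <- 0L
  if (!is.null(fix_scale)) s2_mode <- 0L
  v_init <- fix_v %||% (if (spec$v_mode == 0L) 4.2 else 4)
  S2_init <- fix_scale %||%
    (if (spec$s2_mode == 0L) derive_scale(v_init, e_sj2) else 1)

  st <- settings
  if (!is.null(st$seed)) set.seed(st$seed)
  res <- cpp_bayes_chain(y, X, Z, spec$family, v_mode, s2_mode, pi_mode,
                         v_init, S2_init, pi_use, lambda,
                         st$n_iter, st$burn_in, st$mh_cycles)
  if (res$n_monomorphic > 0)
    warning(res$n_monomorphic, " monomorphic loci: effects forced to 0")

  trace <- as.data.frame(res$trace)
  names(trace) <- c("v", "S2", "pi", "sigma_e2", "q", "sigma_a2")
  trace$iter <- seq_len(nrow(trace))
  kept <- trace[trace$iter > st$burn_in, ]
  qs <- function(v) c(mean = mean(v), median = median(v),
                      q05 = unname(quantile(v, 0.05)),
                      q95 = unname(quantile(v, 0.95)))
  summary <- rbind(v = qs(kept$v), S2 = qs(kept$S2), pi = qs(kept$pi),
                   sigma_e2 = qs(kept$sigma_e2), q = qs(kept$q))

  structure(list(method = method, alpha = drop(res$alpha), b = drop(res$b),
                 inclusion = drop(res$inclusion),
                 gebv = compute_gebv(Z, drop(res$alpha)),
                 trace = trace, summary = summary,
                 settings = st, pi = pi_use,
                 diagnostics = list(
                   ar_proposals = res$ar_proposals,
                   ar_accepts = res$ar_accepts,
                   ar_acceptance_rate =
                     if (res$ar_proposals > 0) res$ar_accepts / res$ar_proposals else NA,
                   ar_envelope_violations = res$ar_envelope_violations,
                   eta_bound_violations = res$eta_bound_violations,
                   mh_acceptance_rate =
                     if (res$mh_proposals > 0) res$mh_accepts / res$mh_proposals else NA)),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d SNP effects, %d iterations (%d burn-in)\n",
              x$method, length(x$alpha), x$settings$n_iter, x$settings$burn_in))
  print(round(x$summary, 4))
  invisible(x)
}

#' Predict GEBVs for new genotypes
#'
#' @param object a [bayes_fit()] result.
#' @param newdata [genotype_matrix()] or code matrix with the same loci.
#' @param ... unused.
#' @return numeric vector of GEBVs.
#' @export
predict.bayes_fit <- function(object, newdata, ...) {
  compute_gebv(newdata, object$alpha)
}
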