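# chain-level behaviour of the Gibbs/MH samplers

make_train <- function(n = 150, p = 60, n_sig = 3, h2 = 0.6, seed = 1) {
  set.seed(seed)
  Z <- matrix(rbinom(n * p, 2, 0.4), n, p) + 0.0
  beta <- rep(0, p)
  beta[sample(p, n_sig)] <- rnorm(n_sig, 0, 1)
  g <- drop(Z %*% beta)
  y <- g + rnorm(n, 0, sqrt(var(g) * (1 - h2) / h2))
  list(Z = Z, y = y, beta = beta)
}

test_that("flexible method with frozen hyperparameters reduces to BayesA", {
  d <- make_train()
  S2 <- derive_scale(4.2, 0.05)
  fa <- bayes_fit(d$Z, d$y, "bayesFA", settings = mcmc_settings(4000, 1000, seed = 1),
                  fix_v = 4.2, fix_scale = S2)
  a1 <- bayes_fit(d$Z, d$y, "bayesA", settings = mcmc_settings(4000, 1000, seed = 2),
                  fix_v = 4.2, fix_scale = S2)
  a2 <- bayes_fit(d$Z, d$y, "bayesA", settings = mcmc_settings(4000, 1000, seed = 3),
                  fix_v = 4.2, fix_scale = S2)
  noise <- sqrt(mean((a1$alpha - a2$alpha)^2))
  expect_lt(sqrt(mean((fa$alpha - a1$alpha)^2)), 3 * noise)
})

test_that("pi = 0 makes the mixture families match the dense sampler", {
  d <- make_train(seed = 2)
  st <- function(s) mcmc_settings(4000, 1000, mh_cycles = 20, seed = s)
  a1 <- bayes_fit(d$Z, d$y, "bayesA", settings = st(1))
  a2 <- bayes_fit(d$Z, d$y, "bayesA", settings = st(2))
  b1 <- bayes_fit(d$Z, d$y, "bayesB", settings = st(3), pi = 0, h2_prior = 0.5)
  b2 <- bayes_fit(d$Z, d$y, "bayesB", settings = st(4), pi = 0, h2_prior = 0.5)
  noise <- sqrt(mean((a1$alpha - a2$alpha)^2) / 2 + mean((b1$alpha - b2$alpha)^2) / 2)
  expect_lt(sqrt(mean((b1$alpha - a1$alpha)^2)), 4 * noise)
  expect_gt(cor(b1$alpha, a1$alpha), 0.95)
})

test_that("pi = 1 excludes every locus", {
  d <- make_train(seed = 3)
  f <- bayes_fit(d$Z, d$y, "bayesB", settings = mcmc_settings(500, 100, seed = 1),
                 pi = 1, fix_scale = 1)
  expect_equal(unname(f$alpha), rep(0, ncol(d$Z)))
  expect_equal(max(f$trace$q), 0)
})

test_that("signal loci are included more often than null loci", {
  set.seed(4)
  n <- 200
  z1 <- rbinom(n, 2, 0.5); z2 <- rbinom(n, 2, 0.5)
  y <- z1 * 1.5 + rnorm(n)
  Z <- cbind(z1, z2) + 0.0
  f <- bayes_fit(Z, y, "bayesB", settings = mcmc_settings(3000, 500, seed = 5),
                 pi = 0.5, h2_prior = 0.5)
  expect_gt(f$inclusion[1], f$inclusion[2])
  fc <- bayes_fit(Z, y, "bayesCpi", settings = mcmc_settings(3000, 500, seed = 6),
                  pi = 0.5, h2_prior = 0.5)
  expect_gt(fc$inclusion[1], fc$inclusion[2])
})

test_that("null data shrink posterior-mean effects toward zero", {
  set.seed(5)
  n <- 150; p <- 40
  Z <- matrix(rbinom(n * p, 2, 0.5), n, p) + 0.0
  y <- rnorm(n)   # independent of genotypes
  short_fit <- bayes_fit(Z, y, "bayesA", settings = mcmc_settings(300, 50, seed = 1))
  long_fit <- bayes_fit(Z, y, "bayesA", settings = mcmc_settings(6000, 1000, seed = 1))
  expect_lt(mean(abs(long_fit$alpha)), mean(abs(short_fit$alpha)) + 0.02)
  # effects are small in absolute terms relative to the phenotype scale
  expect_lt(mean(abs(long_fit$alpha)), 0.1 * sd(y))
})

test_that("GEBVs carry real signal against a permuted-phenotype control", {
  sc <- mini_scenario(n_qtl = 5, h2 = 0.5, snps_per_chr = 50, seed = 51)
  ped <- sc$pop$ped
  g1 <- which(ped$generation == 1)
  Z <- pop_genotypes(sc$pop, 1)$codes
  y <- ped$phenotype[g1]
  st <- mcmc_settings(2000, 500, seed = 7)
  f <- bayes_fit(Z, y, "bayesFA", settings = st)
  set.seed(8)
  fp <- bayes_fit(Z, sample(y), "bayesFA", settings = st)
  acc <- accuracy_tbv(f$gebv, ped$tbv[g1])
  acc_perm <- accuracy_tbv(fp$gebv, ped$tbv[g1])
  expect_gt(acc, acc_perm + 0.2)
})

test_that("flexible chains keep the eta bound and the envelope everywhere", {
  d <- make_train(seed = 6)
  for (m in c("bayesFA", "bayesFB", "bayesFCpi")) {
    f <- bayes_fit(d$Z, d$y, m, settings = mcmc_settings(2000, 500, seed = 9),
                   pi = 0.7)
    expect_equal(f$diagnostics$eta_bound_violations, 0)
    expect_equal(f$diagnostics$ar_envelope_violations, 0)
    expect_gt(f$diagnostics$ar_acceptance_rate, 0)
    # sampled hyperparameters stay positive and finite
    expect_true(all(f$trace$v > 0 & is.finite(f$trace$v)))
    expect_true(all(f$trace$S2 > 0 & is.finite(f$trace$S2)))
  }
})

test_that("sampled pi mode updates pi from its Beta conditional", {
  d <- make_train(n = 120, p = 30, n_sig = 10, seed = 7)
  f <- bayes_fit(d$Z, d$y, "bayesFCpi", settings = mcmc_settings(2000, 500, seed = 10),
                 pi = 0.5, sample_pi = TRUE)
  expect_gt(sd(f$trace$pi), 0)          # pi actually moves
  expect_true(all(f$trace$pi >= 0 & f$trace$pi <= 1))
  f2 <- bayes_fit(d$Z, d$y, "bayesCpi", settings = mcmc_settings(500, 100, seed = 11),
                  pi = 0.8)
  expect_equal(unique(f2$trace$pi), 0.8) # fixed mode stays put
})

test_that("posterior summaries are computed over post-burn-in samples only", {
  d <- make_train(seed = 8)
  f <- bayes_fit(d$Z, d$y, "bayesFA", settings = mcmc_settings(1000, 400, seed = 12))
  kept <- f$trace[f$trace$iter > 400, ]
  expect_equal(unname(f$summary["v", "median"]), median(kept$v))
  expect_equal(unname(f$summary["sigma_e2", "mean"]), mean(kept$sigma_e2))
})
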