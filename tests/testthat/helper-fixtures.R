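# shared fixtures and independent oracles used across test files

# small genotype matrix with optional missing calls
make_geno_fixture <- function(n = 10, p = 20, miss = 0, seed = 42) {
  set.seed(seed)
  codes <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)[rep(seq_len(p), each = n)]),
                  n, p)
  storage.mode(codes) <- "double"
  if (miss > 0) codes[sample(length(codes), round(miss * length(codes)))] <- NA
  genotype_matrix(codes, paste0("ind", seq_len(n)),
                  data.frame(id = paste0("m", seq_len(p))))
}

# scaled-inverse-chi-square density and exact CDF (df*scale/chisq_df)
dscinvchisq <- function(x, df, scale) {
  exp(0.5 * df * log(0.5 * df * scale) - lgamma(0.5 * df) -
        (1 + 0.5 * df) * log(x) - 0.5 * df * scale / x)
}
pscinvchisq <- function(x, df, scale) {
  pchisq(df * scale / x, df, lower.tail = FALSE)
}

# numeric CDF of an unnormalised log-density on (0, upper) by trapezoid rule
numeric_cdf <- function(log_dens, upper, n_grid = 20000) {
  x <- seq(upper / n_grid, upper, length.out = n_grid)
  f <- exp(log_dens(x) - max(log_dens(x)))
  cdf <- c(0, cumsum((f[-1] + f[-n_grid]) / 2 * diff(x)))
  list(x = x, cdf = cdf / cdf[n_grid])
}

# KS distance between draws and a numeric CDF
ks_distance <- function(draws, cdf_obj) {
  cdf_at <- approx(cdf_obj$x, cdf_obj$cdf, xout = sort(draws),
                   yleft = 0, yright = 1)$y
  emp <- seq_along(draws) / length(draws)
  max(abs(cdf_at - emp))
}

# miniature simulated scenario for chain-level tests: keeps the historical
# marker density (2000 SNPs per Morgan) while shrinking the genome
mini_scenario <- function(n_qtl = 10, h2 = 0.5, pop_size = 500,
                          snps_per_chr = 100, n_chr = 2,
                          history_generations = 400,
                          progeny_per_pair = 10, seed = 1) {
  simulate_scenario(n_qtl = n_qtl, h2 = h2, pop_size = pop_size,
                    n_chr = n_chr, snps_per_chr = snps_per_chr,
                    length_morgan = snps_per_chr / 2000,
                    history_generations = history_generations,
                    progeny_per_pair = progeny_per_pair, seed = seed)
}
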