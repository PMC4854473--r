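# cross-validation bookkeeping, accuracy estimators and the experiment driver

test_that("random masking partitions ids into near-equal folds", {
  plan <- random_masking_folds(paste0("i", 1:1136), k = 5, repeats = 10, seed = 1)
  for (r in 1:10) {
    f <- plan$folds[[r]]
    expect_equal(sort(unique(f)), 1:5)
    sizes <- as.vector(table(f))
    expect_equal(sort(sizes), c(227, 227, 227, 227, 228))
    # holding out a 227 fold leaves a 909 reference
    expect_equal(1136 - 227, 909)
    expect_equal(sum(sizes), 1136)
  }
  plan2 <- random_masking_folds(paste0("i", 1:10), k = 5, repeats = 2, seed = 2)
  expect_equal(as.vector(table(plan2$folds[[1]])), rep(2, 5))
})

test_that("cohort masking splits deterministically by birth year", {
  ph <- data.frame(id = paste0("i", 1:5),
                   birth_year = c(2010, 2010, 2012, 2013, 2012))
  plan <- cohort_masking(ph, 2012)
  expect_equal(length(plan$reference), 2)
  expect_equal(length(plan$validation), 3)
  expect_equal(sort(c(plan$reference, plan$validation)), sort(ph$id))
  expect_length(intersect(plan$reference, plan$validation), 0)
  # later cutoff grows the reference monotonically
  sizes <- vapply(c(2011, 2012, 2013),
                  function(cy) length(cohort_masking(ph, cy)$reference),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(cohort_masking(ph, 2009), "empty reference")
  expect_error(cohort_masking(ph, 2020), "empty validation")
})

test_that("TBV accuracy is the Pearson correlation with its edge cases", {
  set.seed(3)
  tbv <- rnorm(50)
  expect_equal(accuracy_tbv(tbv, tbv), 1)
  expect_equal(accuracy_tbv(-tbv, tbv), -1)
  gebv <- rnorm(50)
  oracle <- sum((gebv - mean(gebv)) * (tbv - mean(tbv))) /
    sqrt(sum((gebv - mean(gebv))^2) * sum((tbv - mean(tbv))^2))
  expect_equal(accuracy_tbv(gebv, tbv), oracle, tolerance = 1e-12)
  expect_error(accuracy_tbv(rep(1, 10), tbv[1:10]), "zero variance")
})

test_that("real-data accuracy estimator is scale invariant and self-consistent", {
  set.seed(4)
  gebv <- rnorm(100)
  # proxy = gebv with h2 * phen_var = var(gebv) gives exactly 1
  expect_equal(accuracy_real(gebv, gebv, 0.5, var(gebv) / 0.5), 1)
  proxy <- 0.6 * gebv + rnorm(100)
  a1 <- accuracy_real(gebv, proxy, 0.4, 2.5)
  expect_equal(accuracy_real(gebv * 7.3, proxy, 0.4, 2.5), a1, tolerance = 1e-12)
  # algebraic identity: cov/sqrt(h2 vp vG) = cor * sd(proxy)/sqrt(h2 vp)
  rewrite <- cor(proxy, gebv) * sd(proxy) / sqrt(0.4 * 2.5)
  expect_equal(a1, rewrite, tolerance = 1e-12)
})

test_that("experiment driver completes end-to-end and shapes its table", {
  res <- run_experiment(data.frame(n_qtl = 5, h2 = 0.5, pop_size = 300),
                        methods = "gblup", n_replicates = 1,
                        settings = mcmc_settings(400, 100),
                        seed = 5, snps_per_chr = 40, n_chr = 2,
                        history_generations = 150, progeny_per_pair = 6)
  expect_equal(sort(unique(res$generation)), 1:6)
  expect_true(all(res$accuracy > -1 & res$accuracy < 1))
  expect_false(anyNA(res$accuracy))
  smry <- summarize_experiment(res)
  expect_true(all(c("mean", "sd", "method", "generation") %in% names(smry)))
  expect_equal(nrow(smry), 6)   # one method x one scenario x six generations
})

test_that("prediction accuracy declines from generation 2 to 6 on average", {
  res <- run_experiment(data.frame(n_qtl = 20, h2 = 0.5, pop_size = 300),
                        methods = c("gblup", "bayesFA"), n_replicates = 5,
                        settings = mcmc_settings(1500, 300),
                        seed = 6, snps_per_chr = 100, n_chr = 2,
                        history_generations = 400, progeny_per_pair = 6)
  smry <- summarize_experiment(res)
  for (m in c("gblup", "bayesFA")) {
    acc <- smry$mean[smry$method == m][match(2:6, smry$generation[smry$method == m])]
    # monotone-ish decline: later generations less accurate than generation 2
    expect_gt(acc[1], acc[5])
    expect_gt(mean(acc[1:2]), mean(acc[4:5]))
  }
})

test_that("generation-1 accuracy rises with heritability at fixed QTL count", {
  grid <- data.frame(n_qtl = 20, h2 = c(0.1, 0.8), pop_size = 300)
  res <- run_experiment(grid, methods = "bayesA", n_replicates = 5,
                        settings = mcmc_settings(1500, 300),
                        seed = 7, snps_per_chr = 100, n_chr = 2,
                        history_generations = 400, progeny_per_pair = 6)
  g1 <- res[res$generation == 1, ]
  expect_gt(mean(g1$accuracy[g1$h2 == 0.8]), mean(g1$accuracy[g1$h2 == 0.1]))
})

test_that("reference individuals never lend their own phenotype to validation", {
  # structural check on the fold plan: each individual is validated exactly
  # once per repeat, so its record is outside the reference equations then
  plan <- random_masking_folds(paste0("i", 1:53), k = 5, repeats = 3, seed = 8)
  for (r in 1:3) {
    f <- plan$folds[[r]]
    for (k in 1:5) {
      val <- plan$ids[f == k]
      ref <- plan$ids[f != k]
      expect_length(intersect(val, ref), 0)
      expect_equal(sort(c(val, ref)), sort(plan$ids))
    }
  }
})
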