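#' Random-masking fold assignments for k-fold cross-validation
#'
#' Each repeat partitions the individuals uniformly at random into `k`
#' near-equal folds (sizes differ by at most one; the first `n %% k` folds
#' take the extra individual).  Every individual is validated exactly once
#' per repeat.
#'
#' @param ids individual identifiers.
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed optional integer seed.
#' @return list of class `cv_plan` with `scheme = "random_masking"`, `ids`,
#'   and `folds`, a list of `repeats` integer vectors giving each
#'   individual's fold.
#' @export
random_masking_folds <- function(ids, k = 5, repeats = 10, seed = NULL) {
  n <- length(ids)
  stopifnot(k >= 2, n >= k)
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  folds <- lapply(seq_len(repeats), function(r)
    sample(rep.int(seq_len(k), sizes)))
  structure(list(scheme = "random_masking", ids = ids, k = k,
                 repeats = repeats, folds = folds),
            class = "cv_plan")
}

#' Cohort-masking split by birth year
#'
#' Deterministic split: individuals born before `cutoff_year` form the
#' reference set, those born in or after it the validation set.
#'
#' @param pheno data.frame with columns `id` and `birth_year`.
#' @param cutoff_year integer year.
#' @return list of class `cv_plan` with `reference` and `validation` id
#'   vectors.
#' @export
cohort_masking <- function(pheno, cutoff_year) {
  stopifnot(all(c("id", "birth_year") %in% names(pheno)))
  ref <- pheno$id[pheno$birth_year < cutoff_year]
  val <- pheno$id[pheno$birth_year >= cutoff_year]
  if (!length(ref)) stop("empty reference set at cutoff ", cutoff_year)
  if (!length(val)) stop("empty validation set at cutoff ", cutoff_year)
  structure(list(scheme = "cohort_masking", cutoff_year = cutoff_year,
                 reference = ref, validation = val),
            class = "cv_plan")
}

#' Predictive accuracy against true breeding values
#'
#' Pearson correlation of GEBVs with simulated TBVs over the validation
#' individuals.
#'
#' @param gebv,tbv aligned numeric vectors (length >= 3).
#' @return the correlation.
#' @export
accuracy_tbv <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv), length(gebv) >= 3)
  if (sd(gebv) == 0 || sd(tbv) == 0)
    stop("zero variance: accuracy undefined")
  cor(gebv, tbv)
}

#' Estimated accuracy for real data
#'
#' accuracy = cov(proxy, GEBV) / sqrt(h2 * phen_var * var(GEBV)), where
#' `proxy` is an EBV-like reference value and `phen_var` the phenotypic
#' variance estimated from the full reference analysis.  The estimate is
#' invariant to rescaling the GEBVs.
#'
#' @param gebv genomic predictions of the validation individuals.
#' @param proxy EBV proxy (adjusted phenotype or pedigree EBV; the choice is
#'   the caller's).
#' @param h2 trait heritability in (0, 1].
#' @param phen_var phenotypic variance (> 0).
#' @return the accuracy estimate.
#' @export
accuracy_real <- function(gebv, proxy, h2, phen_var) {
  stopifnot(h2 > 0, h2 <= 1, phen_var > 0, length(gebv) == length(proxy))
  vg <- var(gebv)
  if (vg == 0) stop("zero GEBV variance: accuracy undefined")
  cov(proxy, gebv) / sqrt(h2 * phen_var * vg)
}

.fit_one_method <- function(method, scen, settings, h2_prior, pi_zero) {
  ped <- scen$pop$ped
  g1 <- ped$generation == 1L
  geno_all <- pop_genotypes(scen$pop, generations = sort(unique(
    ped$generation[ped$generation >= 1L])))
  rows_g1 <- which(ped$generation[ped$generation >= 1L] == 1L)
  Z_all <- geno_all$codes
  Z1 <- Z_all[rows_g1, , drop = FALSE]
  y1 <- ped$phenotype[g1]
  if (method == "gblup") {
    y_all <- rep(NA_real_, nrow(Z_all))
    y_all[rows_g1] <- y1
    fit <- gblup_fit(Z_all, y_all)
    list(gebv = fit$gebv, extra = c(v_median = NA, S2_median = NA,
                                    h2_reml = fit$vc$h2))
  } else {
    fit <- bayes_fit(Z1, y1, method = method, settings = settings,
                     pi = if (.method_table[[method]]$family == 0L) NULL else pi_zero,
                     h2_prior = h2_prior)
    list(gebv = compute_gebv(Z_all, fit$alpha),
         extra = c(v_median = unname(fit$summary["v", "median"]),
                   S2_median = unname(fit$summary["S2", "median"]),
                   h2_reml = NA))
  }
}

#' Run a simulation-scenario experiment grid
#'
#' For every scenario x method x replicate: simulate a population, fit on the
#' generation-1 phenotypes, predict all individuals of generations 1-6, and
#' record the per-generation correlation between GEBV and TBV.  A failing
#' method is flagged (`NA` accuracy, with a warning) and the remaining cells
#' proceed.
#'
#' @param scenarios data.frame with columns `n_qtl`, `h2`, `pop_size` (one
#'   row per scenario).
#' @param methods character vector from `gblup`, `bayesA`, `bayesB`,
#'   `bayesCpi`, `bayesFA`, `bayesFB`, `bayesFCpi`.
#' @param n_replicates replicates per scenario.
#' @param settings [mcmc_settings()] for the Bayesian chains.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param snps_per_chr,n_chr,history_generations,progeny_per_pair,mutation_rate
#'   simulator configuration forwarded to [simulate_scenario()].
#' @param length_morgan chromosome length; the default shrinks the map in
#'   proportion to the marker count (2000 SNPs per Morgan, the full-scale
#'   density) so that reduced panels keep the full-scale marker-QTL linkage
#'   disequilibrium.
#' @return data.frame with one row per scenario x replicate x method x
#'   generation: `accuracy`, plus posterior-median `v`/`S2` for the flexible
#'   methods and the REML `h2` for GBLUP.
#' @export
run_experiment <- function(scenarios, methods = c("gblup", "bayesA", "bayesFA"),
                           n_replicates = 2, settings = mcmc_settings(10000, 2000),
                           seed = 1, snps_per_chr = 200, n_chr = 5,
                           length_morgan = snps_per_chr / 2000,
                           history_generations = 2000, progeny_per_pair = 40,
                           mutation_rate = 2.5e-3) {
  stopifnot(all(c("n_qtl", "h2", "pop_size") %in% names(scenarios)))
  methods <- match.arg(methods, c("gblup", names(.method_table)),
                       several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, nrow(scenarios) * n_replicates)
  out <- list()
  P <- snps_per_chr * n_chr
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    for (r in seq_len(n_replicates)) {
      scen <- simulate_scenario(n_qtl = sc$n_qtl, h2 = sc$h2,
                                pop_size = sc$pop_size,
                                n_chr = n_chr, snps_per_chr = snps_per_chr,
                                length_morgan = length_morgan,
                                history_generations = history_generations,
                                mutation_rate = mutation_rate,
                                progeny_per_pair = progeny_per_pair,
                                seed = rep_seeds[(s - 1) * n_replicates + r])
      ped <- scen$pop$ped
      gens <- sort(unique(ped$generation[ped$generation >= 1L]))
      gen_of <- ped$generation[ped$generation >= 1L]
      tbv <- ped$tbv[ped$generation >= 1L]
      pi_zero <- 1 - sc$n_qtl / P
      for (m in methods) {
        res <- tryCatch(
          .fit_one_method(m, scen, settings, h2_prior = sc$h2, pi_zero = pi_zero),
          error = function(e) {
            warning(sprintf("scenario %d replicate %d method %s failed: %s",
                            s, r, m, conditionMessage(e)))
            NULL
          })
        for (g in gens) {
          acc <- if (is.null(res)) NA_real_ else
            accuracy_tbv(res$gebv[gen_of == g], tbv[gen_of == g])
          out[[length(out) + 1L]] <- data.frame(
            scenario = s, n_qtl = sc$n_qtl, h2 = sc$h2, pop_size = sc$pop_size,
            replicate = r, method = m, generation = g, accuracy = acc,
            v_median = if (is.null(res)) NA else unname(res$extra["v_median"]),
            S2_median = if (is.null(res)) NA else unname(res$extra["S2_median"]),
            h2_reml = if (is.null(res)) NA else unname(res$extra["h2_reml"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise an experiment table
#'
#' Mean and SD of accuracy over replicates for each scenario x method x
#' generation cell.
#'
#' @param results output of [run_experiment()].
#' @return aggregated data.frame.
#' @export
summarize_experiment <- function(results) {
  agg <- aggregate(accuracy ~ n_qtl + h2 + pop_size + method + generation,
                   data = results,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- cbind(agg[, setdiff(names(agg), "accuracy")],
               mean = agg$accuracy[, "mean"], sd = agg$accuracy[, "sd"])
  out[order(out$n_qtl, out$h2, out$pop_size, out$generation, out$method), ]
}
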