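# forward simulator: genome construction, meiosis, history, expansion,
# QTL/TBV assignment and phenotype generation

test_that("candidate QTL counts follow the adjacency rule", {
  g <- build_genome(5, 1, 2000, seed = 1)
  expect_equal(sum(g$loci$type == "snp"), 10000)
  expect_equal(sum(g$loci$type == "qtl"), 9995)
  g2 <- build_genome(1, 1, 2, seed = 2)
  expect_equal(sum(g2$loci$type == "qtl"), 1)
  # arbitrary config: sum over chromosomes of (snps - 1)
  g3 <- build_genome(3, 0.5, 7, seed = 3)
  expect_equal(sum(g3$loci$type == "qtl"), 3 * 6)
  expect_warning(build_genome(1, 1, 1), "no candidate")
})

test_that("candidates lie strictly between their flanking SNPs, sorted", {
  g <- build_genome(2, 1, 50, seed = 4)
  for (c in 1:2) {
    loci <- g$loci[g$loci$chr == c, ]
    expect_true(all(diff(loci$pos) > 0))
    sp <- loci$pos[loci$type == "snp"]
    qp <- loci$pos[loci$type == "qtl"]
    expect_true(all(qp > sp[-length(sp)] & qp < sp[-1]))
    expect_true(all(loci$pos >= 0 & loci$pos <= 1))
  }
})

test_that("meiosis has Poisson crossovers at the map length", {
  # fully heterozygous parent: allele switches along the gamete = crossovers
  g <- build_genome(1, 1, 2000, seed = 5)
  L <- nrow(g$loci)
  pop <- structure(list(
    ped = data.frame(id = 1, sire = NA, dam = NA, sex = "M", generation = 0),
    hap = cbind(rep(0L, L), rep(1L, L)), genome = g), class = "population")
  set.seed(6)
  gm <- meiosis(pop, 1, n = 10000)
  switches <- colSums(abs(apply(gm, 2, diff)) > 0)
  se <- sqrt(1 / 10000)  # Poisson(1) mean has sd 1
  expect_lt(abs(mean(switches) - 1.0), 3 * 1 / sqrt(10000) + 0.01)
  # conservation without mutation: every allele is parental
  expect_true(all(gm %in% c(0L, 1L)))
})

test_that("recombination fraction follows the Haldane map function", {
  # two loci 0.5 Morgan apart: c = (1 - exp(-1))/2
  g <- structure(list(chr = data.frame(chr = 1, length = 1),
                      loci = data.frame(chr = 1, pos = c(0.25, 0.75),
                                        type = "snp", id = c("a", "b"))),
                 class = "genome_map")
  pop <- structure(list(
    ped = data.frame(id = 1, sire = NA, dam = NA, sex = "M", generation = 0),
    hap = cbind(c(0L, 0L), c(1L, 1L)), genome = g), class = "population")
  set.seed(7)
  gm <- meiosis(pop, 1, n = 10000)
  rec <- mean(gm[1, ] != gm[2, ])
  expected <- (1 - exp(-2 * 0.5)) / 2
  expect_lt(abs(rec - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("history preserves census and sex structure; drift erodes diversity", {
  g <- build_genome(1, 1, 5, seed = 8)
  p0 <- run_history(g, base_size = 100, n_generations = 3, mutation_rate = 0)
  expect_equal(nrow(p0$ped), 100)
  expect_equal(sum(p0$ped$sex == "M"), 50)
  # monomorphic start + no mutation stays monomorphic
  expect_true(all(p0$hap == 0L))
  # drift oracle on a 5-locus miniature: mean pairwise allele sharing
  # increases with time when mutation is off
  sharing <- function(n_gen, seed) {
    p <- run_history(g, 20, n_gen, 0, founder_freq = 0.5, seed = seed)
    f <- rowMeans(p$hap)
    mean(f^2 + (1 - f)^2)  # probability two random alleles match
  }
  early <- mean(vapply(1:8, function(s) sharing(5, s), numeric(1)))
  late <- mean(vapply(1:8, function(s) sharing(150, s), numeric(1)))
  expect_gt(late, early)
})

test_that("long neutral history keeps most loci segregating at the default rate", {
  g <- build_genome(2, 1, 100, seed = 9)
  p0 <- run_history(g, 100, 1500, mutation_rate = 2.5e-3, seed = 10)
  dose <- p0$hap[, seq(1, 200, 2)] + p0$hap[, seq(2, 200, 2)]
  seg <- mean(apply(dose, 1, function(v) any(v != v[1])))
  expect_gte(seg, 0.8)
})

test_that("expansion produces the printed census sizes and a valid pedigree", {
  g <- build_genome(1, 0.1, 40, seed = 11)
  p0 <- run_history(g, 100, 50, 2.5e-3, seed = 12)
  pop <- expand_and_breed(p0, dam_count = 250, seed = 13)
  cnt <- table(pop$ped$generation)
  expect_equal(as.vector(cnt[as.character(1)]), 2000)
  expect_equal(as.vector(cnt[as.character(2:6)]), rep(500, 5))
  # pedigree validity: sires male, dams female, both from previous generation
  off <- pop$ped[pop$ped$generation >= 1, ]
  sire_row <- match(off$sire, pop$ped$id)
  dam_row <- match(off$dam, pop$ped$id)
  expect_true(all(pop$ped$sex[sire_row] == "M"))
  expect_true(all(pop$ped$sex[dam_row] == "F"))
  expect_true(all(pop$ped$generation[sire_row] == off$generation - 1))
  expect_true(all(pop$ped$generation[dam_row] == off$generation - 1))
  expect_error(expand_and_breed(p0, dam_count = 5000), "exceeds|enough")
})

test_that("bit-reproducibility: identical seeds give identical populations", {
  a <- mini_scenario(seed = 99)
  b <- mini_scenario(seed = 99)
  expect_identical(a$pop$hap, b$pop$hap)
  expect_identical(a$pop$ped, b$pop$ped)
  expect_identical(a$qtl, b$qtl)
})

test_that("TBV is the dose-weighted effect sum over segregating QTL", {
  sc <- mini_scenario(n_qtl = 12, seed = 21)
  pop <- sc$pop
  # brute-force oracle
  dose <- pop$hap[sc$qtl$locus, , drop = FALSE]
  n <- nrow(pop$ped)
  d <- dose[, 2 * seq_len(n) - 1] + dose[, 2 * seq_len(n)]
  oracle <- drop(crossprod(d, sc$qtl$effect))
  expect_equal(pop$ped$tbv, oracle, tolerance = 1e-12)
  # zero dose implies zero TBV; doubling effects doubles TBVs
  zero_dose <- colSums(d) == 0
  if (any(zero_dose)) expect_equal(pop$ped$tbv[zero_dose], rep(0, sum(zero_dose)))
  expect_equal(drop(crossprod(d, 2 * sc$qtl$effect)), 2 * oracle)
  # all chosen QTL segregate in generation 1
  g1 <- which(pop$ped$generation == 1)
  d1 <- d[, g1, drop = FALSE]
  expect_true(all(apply(d1, 1, function(v) any(v != v[1]))))
  # too many QTL requested -> error
  expect_error(assign_qtl_and_tbv(pop, 1e6), "segregate")
})

test_that("phenotypes hit the target heritability and only generation 1", {
  sc <- mini_scenario(n_qtl = 20, h2 = 0.5, seed = 31)
  ped <- sc$pop$ped
  g1 <- ped$generation == 1
  expect_true(all(is.na(ped$phenotype[!g1])))
  expect_false(anyNA(ped$phenotype[g1]))
  # regression of phenotype on TBV is ~1 by construction
  b <- coef(lm(ped$phenotype[g1] ~ ped$tbv[g1]))[2]
  expect_equal(unname(b), 1, tolerance = 0.1)
  # h2 = 1: phenotype equals TBV exactly
  pop1 <- simulate_phenotypes(sc$pop, h2 = 1)
  expect_equal(pop1$ped$phenotype[g1], ped$tbv[g1], tolerance = 1e-12)
})

test_that("realized heritability is near target at full generation-1 size", {
  set.seed(41)
  devs <- vapply(1:3, function(s) {
    sc <- simulate_scenario(n_qtl = 50, h2 = 0.5, pop_size = 500,
                            n_chr = 2, snps_per_chr = 100,
                            length_morgan = 0.05,
                            history_generations = 400, seed = 100 + s)
    ped <- sc$pop$ped
    g1 <- ped$generation == 1
    var(ped$tbv[g1]) / var(ped$phenotype[g1]) - 0.5
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.05)
})
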