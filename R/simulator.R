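#' Build a marker map with candidate QTL between adjacent SNPs
#'
#' SNP positions are drawn uniformly on each chromosome (Morgan scale) and
#' sorted; one candidate QTL is placed at the midpoint of every adjacent SNP
#' pair, so a chromosome with m SNPs carries m - 1 candidates.
#'
#' @param n_chr number of chromosomes.
#' @param length_morgan chromosome length in Morgans.
#' @param snps_per_chr SNPs per chromosome.
#' @param seed optional integer seed.
#' @return An object of class `genome_map`: a list with `chr` (lengths), and
#'   `loci`, a data.frame over all loci (SNPs and candidate QTL interleaved in
#'   map order) with columns `chr`, `pos`, `type` (`"snp"`/`"qtl"`) and `id`.
#' @export
build_genome <- function(n_chr = 5, length_morgan = 1, snps_per_chr = 2000,
                         seed = NULL) {
  stopifnot(n_chr >= 1, snps_per_chr >= 1, length_morgan > 0)
  if (!is.null(seed)) set.seed(seed)
  if (snps_per_chr < 2)
    warning("snps_per_chr < 2: no candidate QTL can be placed")
  loci <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    sp <- sort(runif(snps_per_chr, 0, length_morgan))
    qp <- if (snps_per_chr >= 2) (sp[-1] + sp[-snps_per_chr]) / 2 else numeric(0)
    d <- data.frame(chr = c,
                    pos = c(sp, qp),
                    type = c(rep("snp", length(sp)), rep("qtl", length(qp))),
                    stringsAsFactors = FALSE)
    d[order(d$pos), ]
  }))
  loci$id <- ifelse(loci$type == "snp",
                    paste0("snp_", loci$chr, "_", cumsum(loci$type == "snp")),
                    paste0("qtl_", loci$chr, "_", cumsum(loci$type == "qtl")))
  rownames(loci) <- NULL
  structure(list(chr = data.frame(chr = seq_len(n_chr), length = length_morgan),
                 loci = loci),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %d SNPs, %d candidate QTL\n",
              nrow(x$chr), sum(x$loci$type == "snp"), sum(x$loci$type == "qtl")))
  invisible(x)
}

# chromosome index boundaries (1-based first/last row of loci per chromosome)
.chr_bounds <- function(genome) {
  f <- match(genome$chr$chr, genome$loci$chr)
  l <- nrow(genome$loci) - match(genome$chr$chr, rev(genome$loci$chr)) + 1
  list(first = as.integer(f), last = as.integer(l),
       len = as.numeric(genome$chr$length))
}

.new_population <- function(ped, hap, genome) {
  structure(list(ped = ped, hap = hap, genome = genome), class = "population")
}

#' @export
print.population <- function(x, ...) {
  g <- table(x$ped$generation)
  cat(sprintf("population: %d individuals over generations %s\n",
              nrow(x$ped), paste(names(g), collapse = ", ")))
  invisible(x)
}

#' Neutral constant-size history at mutation-drift equilibrium
#'
#' Starting from `base_size` founders (monomorphic by default, or with
#' founder alleles drawn Bernoulli(`founder_freq`)), evolves the population
#' for `n_generations` non-overlapping generations: random monogamous pairing
#' of all males with all females, two offspring (one of each sex) per pair,
#' gametes formed by Haldane meiosis with recurrent allele-flip mutation.
#'
#' @param genome a [build_genome()] map.
#' @param base_size population size (even; half of each sex).
#' @param n_generations number of historical generations.
#' @param mutation_rate per-locus per-meiosis allele flip probability.  The
#'   default 2.5e-3 gives theta = 4 N mu = 1 at the default `base_size`, so
#'   the stationary allele-frequency distribution is near-uniform and almost
#'   every locus segregates.
#' @param founder_freq `NULL` for monomorphic founders, or an allele
#'   frequency used to draw independent founder alleles.
#' @param seed optional integer seed.
#' @return A `population` holding the final generation (generation index 0).
#' @export
run_history <- function(genome, base_size = 100, n_generations = 2000,
                        mutation_rate = 2.5e-3, founder_freq = NULL,
                        seed = NULL) {
  stopifnot(inherits(genome, "genome_map"), base_size %% 2 == 0, base_size >= 4)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(genome$loci)
  hap0 <- if (is.null(founder_freq)) {
    matrix(0L, L, 2 * base_size)
  } else {
    matrix(as.integer(runif(L * 2 * base_size) < founder_freq), L, 2 * base_size)
  }
  cb <- .chr_bounds(genome)
  hap <- if (n_generations > 0) {
    cpp_evolve_history(hap0, as.integer(n_generations), genome$loci$pos,
                       cb$first, cb$last, cb$len, mutation_rate)
  } else hap0
  ped <- data.frame(id = seq_len(base_size),
                    sire = NA_integer_, dam = NA_integer_,
                    sex = rep(c("M", "F"), each = base_size / 2),
                    generation = 0L, stringsAsFactors = FALSE)
  .new_population(ped, hap, genome)
}

# haplotype column indices of the individuals in the given ped rows
.hap_cols <- function(rows) as.vector(rbind(2L * rows - 1L, 2L * rows))

#' Draw gametes from one individual
#'
#' Performs independent meioses for a single parent: Poisson(map length)
#' crossovers placed uniformly per chromosome (Haldane, no interference) and
#' allele-flip mutation at `mutation_rate` per locus.
#'
#' @param pop a `population`.
#' @param id individual id (row of `pop$ped`).
#' @param n number of gametes.
#' @param mutation_rate per-locus flip probability (default 0).
#' @return Integer matrix, loci x `n`.
#' @export
meiosis <- function(pop, id, n = 1, mutation_rate = 0) {
  row <- match(id, pop$ped$id)
  if (is.na(row)) stop("unknown individual id")
  cb <- .chr_bounds(pop$genome)
  pc <- matrix(rep(c(2L * row - 1L, 2L * row), n), ncol = 2, byrow = TRUE)
  cpp_gametes(pop$hap, pc, pop$genome$loci$pos, cb$first, cb$last, cb$len,
              mutation_rate)
}

#' Expand the base population and breed forward
#'
#' Generation 1 is produced by random monogamous pairing of the generation-0
#' males and females with `progeny_per_pair` offspring per pair (half of each
#' sex); at the defaults this expands 100 founders to 2000 individuals.
#' Generations 2..`generations` are bred by sampling `n_sires` sires (without
#' replacement) from the previous generation's males and `dam_count` dams
#' from its females; dams are split evenly among sires and each dam leaves
#' two offspring (one of each sex), so each later generation has
#' `2 * dam_count` individuals.
#'
#' @param pop0 generation-0 `population` from [run_history()].
#' @param dam_count dams per later generation (250, 500 or 1000 in the
#'   standard scenarios, giving sizes 500/1000/2000).
#' @param n_sires sires per later generation.
#' @param progeny_per_pair progeny per generation-1 mating pair (even).
#' @param generations last generation index to breed (default 6).
#' @param mutation_rate per-locus flip probability during breeding (default 0;
#'   mutation acts during the historical phase).
#' @param seed optional integer seed.
#' @return A `population` containing generations 0..`generations`.
#' @export
expand_and_breed <- function(pop0, dam_count = 500, n_sires = 50,
                             progeny_per_pair = 40, generations = 6,
                             mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(pop0, "population"), progeny_per_pair %% 2 == 0,
            generations >= 1, dam_count %% n_sires == 0)
  if (!is.null(seed)) set.seed(seed)
  genome <- pop0$genome
  cb <- .chr_bounds(genome)
  L <- nrow(genome$loci)

  ped0 <- pop0$ped
  n0 <- nrow(ped0)
  n_pairs <- sum(ped0$sex == "M")
  gen1_n <- n_pairs * progeny_per_pair
  later_n <- 2L * dam_count
  total <- n0 + gen1_n + (generations - 1L) * later_n

  hap <- matrix(0L, L, 2L * total)
  hap[, seq_len(2L * n0)] <- pop0$hap
  ped <- data.frame(id = seq_len(total), sire = NA_integer_, dam = NA_integer_,
                    sex = NA_character_, generation = NA_integer_,
                    stringsAsFactors = FALSE)
  ped[seq_len(n0), ] <- data.frame(id = seq_len(n0), sire = ped0$sire,
                                   dam = ped0$dam, sex = ped0$sex,
                                   generation = 0L)

  breed <- function(sire_rows, dam_rows, off_rows) {
    # one row per offspring; sire gamete then dam gamete
    pc <- matrix(0L, 2L * length(off_rows), 2L)
    pc[seq(1, nrow(pc), 2), ] <- cbind(2L * sire_rows - 1L, 2L * sire_rows)
    pc[seq(2, nrow(pc), 2), ] <- cbind(2L * dam_rows - 1L, 2L * dam_rows)
    gm <- cpp_gametes(hap, pc, genome$loci$pos, cb$first, cb$last, cb$len,
                      mutation_rate)
    cols <- .hap_cols(off_rows)
    hap[, cols] <<- gm
    ped$sire[off_rows] <<- ped$id[sire_rows]
    ped$dam[off_rows] <<- ped$id[dam_rows]
  }

  # generation 1: monogamous pairs, progeny_per_pair offspring each
  males <- which(ped$generation == 0L & ped$sex == "M")
  females <- which(ped$generation == 0L & ped$sex == "F")
  pair_s <- sample(males); pair_d <- sample(females)
  off <- n0 + seq_len(gen1_n)
  sire_rows <- rep(pair_s, each = progeny_per_pair)
  dam_rows <- rep(pair_d, each = progeny_per_pair)
  ped$generation[off] <- 1L
  ped$sex[off] <- rep(rep(c("M", "F"), each = progeny_per_pair / 2), n_pairs)
  breed(sire_rows, dam_rows, off)

  # generations 2..G: n_sires sires x (dam_count/n_sires) dams, 2 offspring/dam
  start <- n0 + gen1_n
  for (g in seq(2L, length.out = generations - 1L)) {
    prev_m <- which(ped$generation == g - 1L & ped$sex == "M")
    prev_f <- which(ped$generation == g - 1L & ped$sex == "F")
    if (length(prev_m) < n_sires) stop("not enough males in generation ", g - 1L)
    if (length(prev_f) < dam_count)
      stop("dam_count exceeds available females in generation ", g - 1L)
    sires <- sample(prev_m, n_sires)
    dams <- sample(prev_f, dam_count)
    sire_of_dam <- rep(sires, each = dam_count / n_sires)
    off <- start + seq_len(later_n)
    ped$generation[off] <- g
    ped$sex[off] <- rep(c("M", "F"), dam_count)
    breed(rep(sire_of_dam, each = 2L), rep(dams, each = 2L), off)
    start <- start + later_n
  }
  .new_population(ped, hap, genome)
}

#' Pick causal QTL and compute true breeding values
#'
#' Chooses `n_qtl` loci among the candidate QTL that segregate in
#' generation 1, draws allele-substitution effects from the standard normal
#' distribution, and sets each individual's TBV to the dose-weighted sum of
#' effects over all generations present.
#'
#' @param pop a `population` with generation 1 present.
#' @param n_qtl number of causal loci (5, 50, 200 or 500 in the standard
#'   scenarios).
#' @param seed optional integer seed.
#' @return list with `qtl` (data.frame: locus row, chr, pos, effect) and
#'   `pop`, the population with a `tbv` column added to `pop$ped`.
#' @export
assign_qtl_and_tbv <- function(pop, n_qtl, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cand <- which(pop$genome$loci$type == "qtl")
  g1 <- which(pop$ped$generation == 1L)
  if (!length(g1)) stop("population has no generation 1")
  dose_g1 <- pop$hap[cand, 2L * g1 - 1L, drop = FALSE] +
             pop$hap[cand, 2L * g1, drop = FALSE]
  seg <- cand[apply(dose_g1, 1, function(v) any(v != v[1]))]
  if (length(seg) < n_qtl)
    stop(sprintf("only %d candidate QTL segregate in generation 1 (need %d)",
                 length(seg), n_qtl))
  qtl_rows <- sort(sample(seg, n_qtl))
  effects <- rnorm(n_qtl)
  all_rows <- seq_len(nrow(pop$ped))
  dose <- pop$hap[qtl_rows, 2L * all_rows - 1L, drop = FALSE] +
          pop$hap[qtl_rows, 2L * all_rows, drop = FALSE]
  pop$ped$tbv <- as.vector(crossprod(dose, effects))
  list(qtl = data.frame(locus = qtl_rows,
                        chr = pop$genome$loci$chr[qtl_rows],
                        pos = pop$genome$loci$pos[qtl_rows],
                        effect = effects),
       pop = pop)
}

#' Assign phenotypes to generation 1
#'
#' Phenotype = TBV + e with e ~ N(0, sigma_e^2) and
#' sigma_e^2 = Var(TBV in generation 1) (1 - h2) / h2, so the realized
#' narrow-sense heritability matches the target up to residual sampling.
#' Only generation-1 individuals receive records.
#'
#' @param pop a `population` with TBVs (see [assign_qtl_and_tbv()]).
#' @param h2 target heritability in (0, 1].
#' @param seed optional integer seed.
#' @return The population with a `phenotype` column (`NA` outside
#'   generation 1).
#' @export
simulate_phenotypes <- function(pop, h2, seed = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  if (is.null(pop$ped$tbv)) stop("assign QTL and TBVs first")
  if (!is.null(seed)) set.seed(seed)
  g1 <- which(pop$ped$generation == 1L)
  vg <- var(pop$ped$tbv[g1])
  if (vg <= 0) stop("zero TBV variance in generation 1: no heritable signal")
  se <- sqrt(vg * (1 - h2) / h2)
  pop$ped$phenotype <- NA_real_
  pop$ped$phenotype[g1] <- pop$ped$tbv[g1] + if (se > 0) rnorm(length(g1), 0, se) else 0
  pop
}

#' Extract SNP genotypes from a simulated population
#'
#' @param pop a `population`.
#' @param generations generation indices to keep (default: all present).
#' @return A [genotype_matrix()] of additive SNP codes (QTL are hidden from
#'   the marker panel).
#' @export
pop_genotypes <- function(pop, generations = NULL) {
  rows <- if (is.null(generations)) seq_len(nrow(pop$ped)) else
    which(pop$ped$generation %in% generations)
  snp <- which(pop$genome$loci$type == "snp")
  dose <- pop$hap[snp, 2L * rows - 1L, drop = FALSE] +
          pop$hap[snp, 2L * rows, drop = FALSE]
  genotype_matrix(t(dose), pop$ped$id[rows],
                  data.frame(id = pop$genome$loci$id[snp],
                             chr = pop$genome$loci$chr[snp],
                             pos = pop$genome$loci$pos[snp],
                             stringsAsFactors = FALSE))
}

#' Simulate a complete genomic-prediction scenario
#'
#' Runs the full pipeline: genome construction, 2000-generation neutral
#' history of 100 individuals, expansion to 2000 in generation 1, breeding of
#' generations 2-6 at the requested size, QTL/TBV assignment and generation-1
#' phenotypes at the requested heritability.
#'
#' @param n_qtl,h2 genetic architecture of the trait.
#' @param pop_size size of generations 2-6 (500, 1000 or 2000).
#' @param n_chr,snps_per_chr,length_morgan genome configuration.
#' @param history_generations,base_size,mutation_rate historical phase.
#' @param progeny_per_pair generation-1 expansion factor.
#' @param generations last generation bred.
#' @param seed integer seed for the whole scenario.
#' @return list with `pop` (pedigree incl. `tbv`/`phenotype`), `qtl`,
#'   `genome` and the scenario parameters.
#' @export
simulate_scenario <- function(n_qtl = 200, h2 = 0.5, pop_size = 1000,
                              n_chr = 5, snps_per_chr = 2000, length_morgan = 1,
                              history_generations = 2000, base_size = 100,
                              mutation_rate = 2.5e-3, progeny_per_pair = 40,
                              generations = 6, seed = NULL) {
  stopifnot(pop_size %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  genome <- build_genome(n_chr, length_morgan, snps_per_chr)
  pop0 <- run_history(genome, base_size, history_generations, mutation_rate)
  pop <- expand_and_breed(pop0, dam_count = pop_size / 2,
                          progeny_per_pair = progeny_per_pair,
                          generations = generations)
  qt <- assign_qtl_and_tbv(pop, n_qtl)
  pop <- simulate_phenotypes(qt$pop, h2)
  list(pop = pop, qtl = qt$qtl, genome = genome,
       params = list(n_qtl = n_qtl, h2 = h2, pop_size = pop_size,
                     snps_per_chr = snps_per_chr, n_chr = n_chr,
                     mutation_rate = mutation_rate, seed = seed))
}
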