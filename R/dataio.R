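#' Genotype matrix container
#'
#' Bundles an N x P matrix of additive genotype codes (0, 1, 2; `NA` for a
#' missing call) with individual identifiers and per-locus metadata.
#'
#' @param codes numeric N x P matrix with entries in \{0, 1, 2, NA\}.
#' @param ids character vector of N unique individual identifiers.
#' @param loci data.frame with one row per locus; must contain a column `id`
#'   and may carry `chr` and `pos` (position in Morgans for simulated maps).
#' @return An object of class `genotype_matrix` with elements `codes`, `ids`,
#'   `loci`, `N` and `P`.
#' @export
genotype_matrix <- function(codes, ids, loci = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (nrow(codes) != length(ids)) stop("nrow(codes) must equal length(ids)")
  if (is.null(loci)) {
    loci <- data.frame(id = colnames(codes) %||% paste0("snp", seq_len(ncol(codes))),
                       stringsAsFactors = FALSE)
  }
  if (nrow(loci) != ncol(codes)) stop("loci must describe every column of codes")
  if (!"id" %in% names(loci)) stop("loci needs an 'id' column")
  if (all(c("chr", "pos") %in% names(loci)) &&
      anyDuplicated(loci[, c("chr", "pos")]) > 0)
    stop("loci must be unique by (chr, pos)")
  bad <- !(codes %in% c(0, 1, 2)) & !is.na(codes)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code at row %d, locus %d (must be 0, 1, 2 or missing)",
                 idx[1], idx[2]))
  }
  rownames(codes) <- ids
  colnames(codes) <- loci$id
  structure(list(codes = codes, ids = as.character(ids), loci = loci,
                 N = nrow(codes), P = ncol(codes)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d missing calls)\n",
              x$N, x$P, sum(is.na(x$codes))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype file
#'
#' Two plain-text dialects are supported.  `matrix-tsv`: a header row of locus
#' ids followed by one row per individual (`id` then P codes, tab separated,
#' missing = `NA`).  `plink-raw`: the PLINK additive recode layout
#' (`FID IID PAT MAT SEX PHENOTYPE` then one dosage column per SNP).
#'
#' @param path file path.
#' @param dialect `"matrix-tsv"` or `"plink-raw"`.
#' @return A [genotype_matrix()].  Individual and locus order follow the file.
#' @export
read_genotypes <- function(path, dialect = c("matrix-tsv", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = if (dialect == "matrix-tsv") "\t" else " ",
                      header = TRUE, na.strings = "NA", data.table = FALSE,
                      colClasses = NULL),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (dialect == "matrix-tsv") {
    ids <- as.character(dt[[1]])
    codes <- as.matrix(dt[, -1, drop = FALSE])
    locus_ids <- colnames(dt)[-1]
  } else {
    meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta_cols %in% names(dt)[1:6]))
      stop("parse error: plink-raw header must start with FID IID PAT MAT SEX PHENOTYPE")
    ids <- as.character(dt[["IID"]])
    codes <- as.matrix(dt[, -(1:6), drop = FALSE])
    locus_ids <- colnames(dt)[-(1:6)]
  }
  storage.mode(codes) <- "double"
  bad <- which(!(codes %in% c(0, 1, 2)) & !is.na(codes), arr.ind = FALSE)
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(codes)) + 1
    stop(sprintf("validation error: non-{0,1,2} genotype code at data row %d", row))
  }
  genotype_matrix(codes, ids, data.frame(id = locus_ids, stringsAsFactors = FALSE))
}

#' Write genotypes in the matrix-tsv dialect
#'
#' Inverse of [read_genotypes()] for the `matrix-tsv` dialect: header of locus
#' ids, then one tab-separated row per individual, missing written as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  fmt <- function(v) ifelse(is.na(v), "NA",
                            ifelse(v == round(v), format(as.integer(round(v))),
                                   format(v)))
  lines <- c(paste(c("id", g$loci$id), collapse = "\t"),
             vapply(seq_len(g$N), function(i)
               paste(c(g$ids[i], fmt(codes[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-delimited with named columns; `id` and `trait` are required, fixed
#' effect covariates (`farm`, `year`, `season`) and `birth_year` are kept when
#' present.
#'
#' @param path file path.
#' @return data.frame with one row per individual.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("id", "trait") %in% names(dt)))
    stop("phenotype table needs columns 'id' and 'trait'")
  dt$id <- as.character(dt$id)
  dt
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.  This
#' is the asymptotic test; it tracks PLINK's default closely for common
#' variants but is not the mid-p exact test.
#'
#' @param n0,n1,n2 counts of the three genotype classes (0, 1 and 2 copies of
#'   the counted allele).
#' @return list with `statistic` (chi-square, 1 df) and `p.value`.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(list(statistic = NA_real_, p.value = NA_real_))
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(list(statistic = 0, p.value = 1))
  expd <- n * c(q^2, 2 * p * q, p^2)
  stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Quality-control filter for a genotype matrix
#'
#' Keeps loci with minor allele frequency strictly above `maf_min`, missing
#' call proportion strictly below `miss_max`, and Hardy-Weinberg chi-square
#' p-value strictly above `hwe_p_min`.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missing proportion (default 0.05).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`, a data.frame with per-locus `maf`, `missing`, `hwe_p`, `pass`
#'   and a comma-joined failure `reason`.
#' @export
qc_filter <- function(g, maf_min = 0.05, miss_max = 0.05, hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  codes <- g$codes
  stats_per_locus <- function(j) {
    v <- codes[, j]
    miss <- mean(is.na(v))
    v <- v[!is.na(v)]
    n0 <- sum(v == 0); n1 <- sum(v == 1); n2 <- sum(v == 2)
    p <- if (length(v)) (2 * n2 + n1) / (2 * length(v)) else NA_real_
    maf <- if (is.na(p)) NA_real_ else min(p, 1 - p)
    hw <- hwe_test(n0, n1, n2)
    c(maf = maf, missing = miss, hwe_p = hw$p.value)
  }
  st <- t(vapply(seq_len(g$P), stats_per_locus, numeric(3)))
  reasons <- character(g$P)
  fail_maf <- is.na(st[, "maf"]) | st[, "maf"] <= maf_min
  fail_mis <- st[, "missing"] >= miss_max
  fail_hwe <- !is.na(st[, "hwe_p"]) & st[, "hwe_p"] <= hwe_p_min
  for (j in seq_len(g$P)) {
    r <- c(if (fail_maf[j]) "maf", if (fail_mis[j]) "missing", if (fail_hwe[j]) "hwe")
    reasons[j] <- paste(r, collapse = ",")
  }
  pass <- !(fail_maf | fail_mis | fail_hwe)
  report <- data.frame(id = g$loci$id, maf = st[, "maf"], missing = st[, "missing"],
                       hwe_p = st[, "hwe_p"], pass = pass, reason = reasons,
                       stringsAsFactors = FALSE)
  if (!any(pass)) warning("no locus passed quality control; empty result")
  out <- genotype_matrix(codes[, pass, drop = FALSE], g$ids,
                         g$loci[pass, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Mean imputation of missing genotype calls
#'
#' Replaces each missing call with the per-locus mean of the non-missing
#' codes (a real value in \[0, 2\]); observed codes are unchanged.
#'
#' @param g a [genotype_matrix()].
#' @return The imputed [genotype_matrix()].
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  nas <- is.na(codes)
  if (!any(nas)) return(g)
  all_missing <- colSums(!nas) == 0
  if (any(all_missing))
    stop("locus with all calls missing: ", g$loci$id[which(all_missing)[1]])
  mu <- colMeans(codes, na.rm = TRUE)
  idx <- which(nas, arr.ind = TRUE)
  codes[idx] <- mu[idx[, 2]]
  g$codes <- codes
  g
}
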