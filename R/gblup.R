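#' Genomic relationship matrix
#'
#' VanRaden method-1 construction: G = W W' / (sum 2 p_j (1 - p_j)) with W
#' the genotype code matrix column-centered by twice the allele frequency
#' estimated from the data.  Monomorphic columns are excluded with a warning.
#'
#' @param g [genotype_matrix()] or plain code matrix without missing values.
#' @return list of class `grm` with `G`, allele frequencies `p` and the
#'   scaling constant `denom`.
#' @export
build_grm <- function(g) {
  Z <- if (inherits(g, "genotype_matrix")) g$codes else as.matrix(g)
  if (anyNA(Z)) stop("missing genotypes: run impute_mean() first")
  p <- colMeans(Z) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic loci excluded from G")
    Z <- Z[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  W <- sweep(Z, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  structure(list(G = tcrossprod(W) / denom, p = p, denom = denom),
            class = "grm")
}

# REML log-likelihood and EM machinery share one eigen-space representation:
# G = U D U', yt = U'y, Xt = U'X, V = sg2 D + se2 I (diagonal).
.reml_loglik <- function(d, yt, Xt, sg2, se2) {
  v <- sg2 * d + se2
  Vx <- Xt / v
  XtVX <- crossprod(Xt, Vx)
  b <- solve(XtVX, crossprod(Vx, yt))
  r <- yt - Xt %*% b
  Py <- r / v
  -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus[1] +
            sum(yt * Py))
}

#' EM-REML variance components for the G-matrix animal model
#'
#' Fits y = Xb + g + e with g ~ N(0, sigma_g^2 G), e ~ N(0, sigma_e^2 I) by
#' EM-REML in the eigenbasis of G.  Iterates until the relative change in
#' both components is below `tol` or `max_iter` iterations; non-convergence
#' returns the last iterate with a warning and `converged = FALSE`.
#'
#' @param y phenotype vector.
#' @param G genomic relationship matrix (or a `grm` object); a 1e-8 diagonal
#'   jitter is added if G is not positive definite.
#' @param X fixed-effect design (default intercept).
#' @param tol relative convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 200).
#' @return list with `sigma_g2`, `sigma_e2`, `h2`, per-iteration `loglik`
#'   trace and `converged`.
#' @export
reml_em <- function(y, G, X = NULL, tol = 1e-8, max_iter = 200) {
  if (inherits(G, "grm")) G <- G$G
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  eg <- eigen(G, symmetric = TRUE)
  d <- eg$values
  if (min(d) < 0) d <- d + abs(min(d)) + 1e-8
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)

  vy <- var(y)
  sg2 <- vy / 2; se2 <- vy / 2
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v <- sg2 * d + se2
    Vx <- Xt / v
    XtVX <- crossprod(Xt, Vx)
    b <- solve(XtVX, crossprod(Vx, yt))
    r <- drop(yt - Xt %*% b)
    Py <- r / v
    # tr(P A) = tr(V^-1 A) - tr((X'V^-1X)^-1 X'V^-1 A V^-1 X) for diagonal A
    XtVX_inv <- solve(XtVX)
    trP  <- sum(1 / v) - sum((Vx %*% XtVX_inv) * Vx)
    trPG <- sum(d / v) - sum((Vx %*% XtVX_inv) * (Vx * d))
    yPGPy <- sum(d * Py^2)
    yPPy  <- sum(Py^2)
    sg2_new <- sg2 + (sg2^2 / n) * (yPGPy - trPG)
    se2_new <- se2 + (se2^2 / n) * (yPPy - trP)
    sg2_new <- max(sg2_new, 1e-10 * vy)
    se2_new <- max(se2_new, 1e-10 * vy)
    ll <- c(ll, .reml_loglik(d, yt, Xt, sg2, se2))
    if (abs(sg2_new - sg2) < tol * max(sg2, 1e-12) &&
        abs(se2_new - se2) < tol * max(se2, 1e-12)) {
      sg2 <- sg2_new; se2 <- se2_new
      converged <- TRUE
      break
    }
    sg2 <- sg2_new; se2 <- se2_new
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter, " iterations")
  list(sigma_g2 = sg2, sigma_e2 = se2, h2 = sg2 / (sg2 + se2),
       loglik = ll, converged = converged, n_iter = length(ll))
}

#' GBLUP prediction of genomic values
#'
#' Solves the single-trait animal model with genomic relationships: fixed
#' effects by GLS on the phenotyped individuals, then
#' gebv = sigma_g^2 G\[, obs\] V^{-1} (y_obs - X_obs b) for all individuals,
#' including those with masked (NA) phenotypes.
#'
#' @param y phenotype vector over all individuals; `NA` marks validation
#'   individuals whose records are masked.
#' @param G genomic relationship matrix over all individuals (or `grm`).
#' @param vc variance components from [reml_em()] (list with `sigma_g2`,
#'   `sigma_e2`).
#' @param X fixed-effect design over all individuals (default intercept).
#' @return numeric vector of GEBVs for all individuals.
#' @export
gblup_predict <- function(y, G, vc, X = NULL) {
  if (inherits(G, "grm")) G <- G$G
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  obs <- which(!is.na(y))
  if (!length(obs)) stop("no observed phenotypes")
  V <- vc$sigma_g2 * G[obs, obs, drop = FALSE]
  diag(V) <- diag(V) + vc$sigma_e2
  ch <- tryCatch(chol(V), error = function(e) {
    diag(V) <- diag(V) + 1e-8 * mean(diag(V))
    chol(V)
  })
  Xo <- X[obs, , drop = FALSE]
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y[obs]))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), Xo))
  b <- solve(crossprod(Xo, Vi_X), crossprod(Xo, Vi_y))
  r <- y[obs] - drop(Xo %*% b)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  drop(vc$sigma_g2 * G[, obs, drop = FALSE] %*% Vi_r)
}

#' Fit GBLUP end to end
#'
#' Builds G from the markers, estimates variance components by EM-REML on
#' the phenotyped individuals, and predicts GEBVs for everyone.
#'
#' @param geno [genotype_matrix()] or code matrix over all individuals.
#' @param y phenotypes with `NA` for validation individuals.
#' @param X optional fixed-effect design.
#' @return list with `gebv`, `vc` and the `grm`.
#' @export
gblup_fit <- function(geno, y, X = NULL) {
  grm <- build_grm(geno)
  obs <- which(!is.na(y))
  if (is.null(X)) X <- matrix(1, length(y), 1)
  vc <- reml_em(y[obs], grm$G[obs, obs, drop = FALSE], X[obs, , drop = FALSE])
  list(gebv = gblup_predict(y, grm, vc, X), vc = vc, grm = grm)
}
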