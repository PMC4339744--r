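#' Fit the per-phenotype null linear mixed model by profile REML
#'
#' Fits `y = Z alpha + B + E` with `var(B) = sigma2_B * Phi` and
#' `var(E) = sigma2_E * I` by restricted maximum likelihood, profiling the
#' total variance out and optimizing the heritability ratio
#' `h = sigma2_B / (sigma2_B + sigma2_E)` on the eigenbasis of `Phi` with
#' Brent's method (tolerance 1e-8 on `h`, search interval
#' `[0, 1 - 1e-6]`).  This has the same stationary points as AI-REML but
#' is exact in one dimension.  Missing phenotype entries are dropped from
#' the fit (with the matching rows/columns of `Z` and `Phi`).
#'
#' @param y numeric phenotype vector of length `N` (`NA` = missing).
#' @param Z `N x c` covariate matrix including an intercept column.
#' @param phi `N x N` positive-definite relationship matrix.
#' @param eig optional precomputed `eigen(phi, symmetric = TRUE)`; only
#'   used when `y` is complete (otherwise the submatrix is decomposed).
#' @return A list of class `null_fit`: `sigma2_B`, `sigma2_E`, `h2`,
#'   `alpha` (GLS fixed effects at the optimum), `loglik` (restricted
#'   log-likelihood up to an additive constant), `n_used`.
#' @export
fit_null_reml <- function(y, Z, phi, eig = NULL) {
  Z <- as.matrix(Z)
  obs <- which(!is.na(y))
  c_ <- ncol(Z)
  if (length(obs) < c_ + 2L)
    stop("need at least ncol(Z) + 2 non-missing observations")
  if (stats::var(y[obs]) == 0)
    stop("constant phenotype: variance components unidentifiable")
  yo <- y[obs]
  Zo <- Z[obs, , drop = FALSE]
  if (qr(Zo)$rank < c_) stop("covariate matrix is rank deficient")
  if (length(obs) < length(y) || is.null(eig))
    eig <- eigen(phi[obs, obs, drop = FALSE], symmetric = TRUE)
  lambda <- eig$values
  if (min(lambda) < 1e-10)
    stop("relationship matrix is not positive definite")
  yt <- crossprod(eig$vectors, yo)
  Zt <- crossprod(eig$vectors, Zo)
  fit <- .reml_profile(lambda, yt, Zt)
  structure(c(fit, list(n_used = length(obs))), class = "null_fit")
}

# Profile restricted log-likelihood over h on the eigenbasis.
# lambda: eigenvalues of Phi; yt, Zt: rotated phenotype/covariates.
.reml_profile <- function(lambda, yt, Zt, h_max = 1 - 1e-6, tol = 1e-8) {
  n <- length(lambda)
  c_ <- ncol(Zt)
  neg2_restricted <- function(h) {
    w <- h * lambda + (1 - h)
    Zw <- Zt / w
    XtWX <- crossprod(Zt, Zw)
    XtWy <- crossprod(Zw, yt)
    alpha <- solve(XtWX, XtWy)
    r <- yt - Zt %*% alpha
    rss <- sum(r * r / w)
    s2 <- rss / (n - c_)
    (n - c_) * log(s2) + sum(log(w)) + determinant(XtWX)$modulus[1]
  }
  # Eigenvalues all (numerically) equal: likelihood is flat in h, the
  # components are separately unidentifiable; report the h = 0 boundary.
  if (diff(range(lambda)) < 1e-10) {
    h_opt <- 0
  } else {
    opt <- stats::optimize(neg2_restricted, c(0, h_max), tol = tol)
    h_opt <- opt$minimum
    # Brent never evaluates the endpoints: accept a boundary solution
    # when it beats the interior optimum.
    if (neg2_restricted(0) <= opt$objective) h_opt <- 0
  }
  w <- h_opt * lambda + (1 - h_opt)
  Zw <- Zt / w
  XtWX <- crossprod(Zt, Zw)
  alpha <- solve(XtWX, crossprod(Zw, yt))
  r <- yt - Zt %*% alpha
  s2 <- sum(r * r / w) / (n - c_)
  list(sigma2_B = h_opt * s2, sigma2_E = (1 - h_opt) * s2, h2 = h_opt,
       alpha = drop(alpha), loglik = -0.5 * neg2_restricted(h_opt))
}

#' Fit null models for all phenotype columns
#'
#' Applies [fit_null_reml] column by column; because the working
#' covariance per phenotype involves only that phenotype's variance
#' components, cross-phenotype polygenic covariances are never needed for
#' the offset.  The eigendecomposition of `phi` is computed once and
#' reused for phenotypes without missing entries.
#'
#' @param Y `N x Q` phenotype matrix (`NA` = missing).
#' @param Z covariate matrix with intercept.
#' @param phi relationship matrix.
#' @param eig optional precomputed `eigen(phi, symmetric = TRUE)`.
#' @return A list of class `null_model` with one `null_fit` per column,
#'   plus attributes `eig` and `phi`.
#' @export
fit_null_model <- function(Y, Z, phi, eig = NULL) {
  Y <- as.matrix(Y)
  if (is.null(eig)) eig <- eigen(phi, symmetric = TRUE)
  fits <- lapply(seq_len(ncol(Y)), function(q)
    fit_null_reml(Y[, q], Z, phi, eig = eig))
  names(fits) <- colnames(Y)
  structure(fits, class = "null_model", eig = eig)
}
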