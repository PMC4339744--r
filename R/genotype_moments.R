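#' BLUE allele frequencies under family correlation
#'
#' The quasi-likelihood maximum (= best linear unbiased) estimator of the
#' mean genotype treats relatives by generalized least squares with the
#' relationship matrix as weight:
#' `g_m = (1' Phi^-1 1)^-1 1' Phi^-1 X^m`, the Phi-weighted mean of the
#' minor-allele counts.  The reported allele frequency is `p_m = g_m / 2`.
#' With `Phi = I` this reduces to half the column mean.
#'
#' @param X `N x M` genotype matrix (minor-allele counts, no missing
#'   entries among the rows used; impute first or restrict to observed).
#' @param phi positive-definite relationship matrix.
#' @return Named list: `freq` (length-M allele frequencies), `mean_geno`
#'   (`2 * freq`), `monomorphic` (logical).
#' @export
blue_allele_freq <- function(X, phi) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing genotypes: impute or subset before BLUE")
  u <- tryCatch(solve(phi, rep(1, nrow(phi))),
                error = function(e) stop("singular relationship matrix"))
  g <- drop(crossprod(u, X)) / sum(u)
  p <- g / 2
  list(freq = p, mean_geno = g, monomorphic = p <= 0 | p >= 1)
}

#' Sample covariance of the per-individual genotype vector
#'
#' `Psi = var(X_ij)` across the tested markers, estimated by the ordinary
#' sample variance-covariance matrix of the rows of `X` (denominator
#' `N - 1`, columns centered at their observed means).  Rows with any
#' missing genotype are dropped.
#'
#' @param X `N x M` genotype matrix.
#' @return `M x M` symmetric covariance matrix.
#' @export
estimate_psi <- function(X) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X)
  if (sum(keep) < 2L) stop("need >= 2 complete genotype rows for Psi")
  stats::cov(X[keep, , drop = FALSE])
}

#' Conditional expectation of missing genotypes given relatives
#'
#' For individuals `U` with missing genotypes and `O` observed, the
#' missing minor-allele counts are replaced per marker by
#' `E(X^U | X^O) = 2 p_m 1 + Phi^UO (Phi^OO)^-1 (X^O - 2 p_m 1)` with the
#' BLUE estimate of `p_m` substituted, i.e. the population mean plus a
#' kinship-weighted deviation of the observed relatives.  Values are
#' clipped to `[0, 2]`; no integer rounding (the score is linear in the
#' genotypes).
#'
#' @param X_obs `N_O x M` observed genotype matrix.
#' @param phi_OO,phi_UO kinship partitions: `O x O` and `U x O` blocks.
#' @return `N_U x M` matrix of imputed (possibly fractional) genotypes.
#' @export
conditional_expect_missing <- function(X_obs, phi_OO, phi_UO) {
  X_obs <- as.matrix(X_obs)
  phi_UO <- matrix(phi_UO, ncol = nrow(X_obs))
  if (nrow(X_obs) == 0L) stop("no observed genotypes to condition on")
  blue <- blue_allele_freq(X_obs, phi_OO)
  dev <- sweep(X_obs, 2L, blue$mean_geno, `-`)
  imp <- outer(rep(1, nrow(phi_UO)), blue$mean_geno) +
    phi_UO %*% solve(phi_OO, dev)
  pmin(pmax(imp, 0), 2)
}
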