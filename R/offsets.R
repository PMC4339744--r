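#' BLUP-adjusted phenotype matrix
#'
#' Subtracts from each phenotype column its fitted mean plus the best
#' linear unbiased predictor of the polygenic effect:
#' `T^q = (I - Z (Z' H^-1 Z)^-1 Z' H^-1 - sigma2_B Phi P) Y^q` with
#' `H = sigma2_B Phi + sigma2_E I` and
#' `P = H^-1 - H^-1 Z (Z' H^-1 Z)^-1 Z' H^-1`, equivalently
#' `T^q = r - sigma2_B Phi H^-1 r` where `r` is the GLS residual.
#' Rows with a missing phenotype are excluded from the projector and set
#' to exactly 0 in the corresponding column of `T` (individuals with
#' missing phenotypes still contribute genotype information downstream).
#'
#' @param Y `N x Q` phenotype matrix (`NA` = missing).  Dichotomous
#'   phenotypes are processed identically to quantitative ones.
#' @param Z covariate matrix including an intercept.
#' @param phi relationship matrix aligned to `Y` rows.
#' @param fits a `null_model` from [fit_null_model] (or a list of
#'   `null_fit` objects) computed on the same `(Y, Z, phi)`.
#' @return `N x Q` matrix `T` with attribute `offset = "blup"`.
#' @export
blup_offset <- function(Y, Z, phi, fits) {
  Y <- as.matrix(Y)
  Z <- as.matrix(Z)
  if (nrow(Y) != nrow(Z) || nrow(Y) != nrow(phi))
    stop("Y, Z and phi must have matching row counts")
  if (length(fits) != ncol(Y))
    stop("one null_fit per phenotype column is required")
  Tm <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (q in seq_len(ncol(Y))) {
    fit <- fits[[q]]
    obs <- which(!is.na(Y[, q]))
    r <- Y[obs, q] - drop(Z[obs, , drop = FALSE] %*% fit$alpha)
    H <- fit$sigma2_B * phi[obs, obs, drop = FALSE] +
      diag(fit$sigma2_E, length(obs))
    Tm[obs, q] <- r - fit$sigma2_B *
      drop(phi[obs, obs, drop = FALSE] %*% solve(H, r))
  }
  structure(Tm, offset = "blup")
}

#' Prevalence-adjusted phenotype matrix
#'
#' For dichotomous phenotypes sampled through ascertained families, the
#' recommended offset is the population prevalence:
#' `t_ijq = y_ijq - K_q` for non-missing entries.  Missing entries are set
#' to 0 (see [zero_missing_phenotypes]).
#'
#' @param Y `N x Q` matrix with 0/1 entries among non-missing values.
#' @param K numeric vector of per-phenotype prevalences in (0, 1).
#' @return `N x Q` matrix `T` with attribute `offset = "prevalence"`.
#' @export
prevalence_offset <- function(Y, K) {
  Y <- as.matrix(Y)
  K <- rep_len(K, ncol(Y))
  if (any(K <= 0 | K >= 1)) stop("prevalences must lie in (0, 1)")
  vals <- Y[!is.na(Y)]
  if (!all(vals %in% c(0, 1)))
    stop("prevalence offset requires dichotomous (0/1) phenotypes")
  Tm <- sweep(Y, 2L, K, `-`)
  Tm[is.na(Tm)] <- 0
  structure(Tm, offset = "prevalence")
}

#' Zero out adjusted phenotypes for missing observations
#'
#' Individuals with a missing phenotype enter the score with
#' `t_ijq = 0`; they remain in the data to sharpen the genotype moment
#' estimates.
#'
#' @param T adjusted phenotype matrix.
#' @param mask logical matrix of the same shape, `TRUE` where the
#'   phenotype is missing.
#' @return `T` with masked entries set to exactly 0.
#' @export
zero_missing_phenotypes <- function(T, mask) {
  T <- as.matrix(T)
  if (!identical(dim(T), dim(as.matrix(mask))))
    stop("mask must match the shape of T")
  T[mask] <- 0
  T
}

#' Classify phenotype columns
#'
#' A column with exactly two distinct non-missing values coded 0/1 is
#' treated as dichotomous, anything else as quantitative.
#'
#' @param Y phenotype matrix.
#' @return character vector, one of `"dichotomous"`/`"quantitative"` per
#'   column.
#' @export
phenotype_kinds <- function(Y) {
  Y <- as.matrix(Y)
  apply(Y, 2L, function(y) {
    u <- unique(y[!is.na(y)])
    if (length(u) == 2L && all(u %in% c(0, 1))) "dichotomous"
    else "quantitative"
  })
}
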