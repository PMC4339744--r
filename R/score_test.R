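#' Phi-weighted centering projector
#'
#' `A = Phi^-1 - Phi^-1 1 (1' Phi^-1 1)^-1 1' Phi^-1`.  `A` annihilates
#' constant vectors (`A 1 = 0`), which is why the test statistic is
#' invariant to the centering constant used for the genotypes; with
#' `Phi = I` it reduces to the ordinary centering projector
#' `I - 11'/N`.
#'
#' @param phi positive-definite relationship matrix.
#' @return Symmetric `N x N` matrix.
#' @export
projection_A <- function(phi) {
  Pinv <- tryCatch(solve(phi),
                   error = function(e) stop("singular relationship matrix"))
  u <- rowSums(Pinv)            # Phi^-1 1
  Pinv - tcrossprod(u) / sum(u)
}

# Shared score/variance core for the V = I quasi-likelihood statistic.
# Returns the Q x M score matrix T' Phi A X and the Q x Q quadratic form
# G = T' Phi A Phi T, both computed through linear solves:
#   Phi A X = X - 1 (1' Phi^-1 X) / (1' Phi^-1 1)
#   Phi A Phi = Phi - 1 1' / (1' Phi^-1 1).
.score_core <- function(T, phi, X) {
  u <- solve(phi, rep(1, nrow(phi)))
  c_ <- sum(u)
  Xc <- X - rep(1, nrow(X)) %o% drop(crossprod(u, X) / c_)
  Smat <- crossprod(T, Xc)
  t1 <- colSums(T)
  G <- crossprod(T, phi %*% T) - tcrossprod(t1) / c_
  list(Smat = Smat, G = G)
}

#' Multivariate quasi-likelihood score vector
#'
#' `S = vec(T' Phi A X)`, the vec (column-stacked, hence marker-major:
#' element `(m - 1) Q + q` is the score of phenotype `q` at marker `m`) of
#' the `Q x M` cross-product between the offset-adjusted phenotypes and
#' the Phi-weighted centered genotypes.
#'
#' @param T `N x Q` adjusted phenotype matrix.
#' @param phi positive-definite relationship matrix.
#' @param X `N x M` genotype matrix.
#' @return Numeric vector of length `M * Q`.
#' @export
mfqls_score <- function(T, phi, X) {
  as.vector(.score_core(as.matrix(T), phi, as.matrix(X))$Smat)
}

#' Variance of the multivariate quasi-likelihood score
#'
#' `var(S) = Psi \%x\% (T' Phi A Phi T)` under
#' `var(vec(X)) = Psi \%x\% Phi`; the Kronecker ordering (markers on the
#' left factor) matches [mfqls_score]'s vec ordering.
#'
#' @inheritParams mfqls_score
#' @param psi `M x M` genotype covariance (see [estimate_psi]).
#' @return `MQ x MQ` symmetric matrix.
#' @export
mfqls_variance <- function(T, phi, psi) {
  T <- as.matrix(T)
  psi <- as.matrix(psi)
  u <- solve(phi, rep(1, nrow(phi)))
  t1 <- colSums(T)
  G <- crossprod(T, phi %*% T) - tcrossprod(t1) / sum(u)
  kronecker(psi, G)
}

# Quadratic form through an eigenvalue-thresholded pseudo-inverse.
# Rank-deficient var(S) (e.g. collinear markers) loses the discarded
# directions and the chi-square df drops to the retained rank.
.chisq_from_score <- function(S, VS, tol = 1e-8) {
  ev <- eigen(VS, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values, 0)
  if (!any(keep))
    return(list(statistic = NA_real_, df = 0L, p_value = NA_real_))
  z <- crossprod(ev$vectors[, keep, drop = FALSE], S)
  stat <- sum(z^2 / ev$values[keep])
  df <- sum(keep)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

.mfqls_result <- function(core, psi, method, n_used, M, Q, note = NULL) {
  S <- as.vector(core$Smat)
  VS <- kronecker(as.matrix(psi), core$G)
  qf <- .chisq_from_score(S, VS)
  structure(list(S = S, V_S = VS, statistic = qf$statistic, df = qf$df,
                 p_value = qf$p_value, method = method, n_used = n_used,
                 M = M, Q = Q, note = note),
            class = "mfqls_result")
}

.no_test <- function(method, n_used, note) {
  structure(list(S = numeric(0), V_S = matrix(0, 0, 0),
                 statistic = NA_real_, df = 0L, p_value = NA_real_,
                 method = method, n_used = n_used, M = 0L, Q = 0L,
                 note = note),
            class = "mfqls_result")
}

# Drop markers monomorphic (constant) among the analyzed individuals.
.drop_monomorphic <- function(X, phi, warn = TRUE) {
  rng <- apply(X, 2L, function(x) diff(range(x)))
  drop_m <- rng == 0
  if (any(drop_m) && warn)
    warning(sum(drop_m), " monomorphic marker(s) removed from the test")
  list(X = X[, !drop_m, drop = FALSE], n_dropped = sum(drop_m))
}

#' Multivariate family-based quasi-likelihood score test (MFQLS)
#'
#' Tests the joint null hypothesis that all `M x Q` marker-phenotype
#' effects are zero via
#' `S' var(S)^-1 S ~ chi-square(MQ)` with `S = vec(T' Phi A X)` and
#' `var(S) = Psi \%x\% (T' Phi A Phi T)`.  Markers monomorphic among the
#' analyzed individuals are removed (all removed gives a no-test
#' sentinel with `p_value = NA`), and a rank-deficient score variance is
#' handled by a pseudo-inverse with correspondingly reduced df.
#'
#' @inheritParams mfqls_variance
#' @param X `N x M` genotype matrix (no missing entries; see
#'   [mfqls_test_missing]).
#' @param psi optional `M x M` genotype covariance; estimated from `X` by
#'   [estimate_psi] when `NULL` (after monomorphic-marker removal).
#' @param method label stored in the result.
#' @return An object of class `mfqls_result` with elements `S`, `V_S`,
#'   `statistic`, `df`, `p_value`, `method`, `n_used`, `M`, `Q`.
#' @export
mfqls_test <- function(T, phi, X, psi = NULL, method = "MFQLS") {
  T <- as.matrix(T)
  X <- as.matrix(X)
  if (nrow(T) != nrow(X) || nrow(T) != nrow(phi))
    stop("T, X and phi must have matching row counts")
  kept <- .drop_monomorphic(X, phi)
  if (ncol(kept$X) == 0L)
    return(.no_test(method, nrow(T), "all markers monomorphic"))
  if (all(T == 0))
    return(.no_test(method, nrow(T), "adjusted phenotypes all zero"))
  X <- kept$X
  if (is.null(psi)) psi <- estimate_psi(X)
  core <- .score_core(T, phi, X)
  .mfqls_result(core, psi, method, nrow(T), ncol(X), ncol(T))
}

#' MFQLS with missing genotypes handled by conditional expectation
#'
#' Individuals with missing genotypes (`U`) but informative phenotypes
#' contribute through the kinship-weighted conditional expectation of
#' their genotypes given the observed set (`O`).  Writing `A` for the
#' centering projector built on `Phi^OO`, the score and variance are
#' `S* = vec(T' Phi[, O] A X^O)` and
#' `var(S*) = Psi \%x\% (T' Phi[, O] A Phi[O, ] T)`; with `U` empty this
#' is exactly [mfqls_test].  `Psi` is estimated from observed individuals
#' only.
#'
#' @param T `N x Q` adjusted phenotype matrix over all individuals.
#' @param phi full `N x N` relationship matrix.
#' @param X_obs `N_O x M` genotypes of the observed individuals.
#' @param obs integer (or logical) index of the observed rows in `phi`.
#' @param psi optional genotype covariance.
#' @param method label stored in the result.
#' @return `mfqls_result`.
#' @export
mfqls_test_missing <- function(T, phi, X_obs, obs, psi = NULL,
                               method = "MFQLS") {
  T <- as.matrix(T)
  X_obs <- as.matrix(X_obs)
  if (is.logical(obs)) obs <- which(obs)
  if (nrow(X_obs) != length(obs))
    stop("X_obs rows must match the observed index")
  phi_OO <- phi[obs, obs, drop = FALSE]
  kept <- .drop_monomorphic(X_obs, phi_OO)
  if (ncol(kept$X) == 0L)
    return(.no_test(method, nrow(T), "all markers monomorphic"))
  X_obs <- kept$X
  if (is.null(psi)) psi <- estimate_psi(X_obs)
  u <- solve(phi_OO, rep(1, length(obs)))
  c_ <- sum(u)
  AX <- solve(phi_OO, X_obs) - u %o% drop(crossprod(u, X_obs) / c_)
  B <- phi[, obs, drop = FALSE]
  Smat <- crossprod(T, B %*% AX)
  K <- crossprod(B, T)                       # Phi[O, ] T
  AK <- solve(phi_OO, K) - u %o% drop(crossprod(u, K) / c_)
  G <- crossprod(K, AK)
  G <- (G + t(G)) / 2
  .mfqls_result(list(Smat = Smat, G = G), psi, method, nrow(T),
                ncol(X_obs), ncol(T))
}

#' Score tests under the alternate working-covariance/offset choices
#'
#' Dispatches the three published configurations of the quasi-likelihood
#' score: `MFQLS` (identity working covariance, BLUP offset), `MMQLS`
#' (identity working covariance, prevalence offset; dichotomous
#' phenotypes only), and `MMASTOR` (per-phenotype mixed-model working
#' covariance `V^q = H^q`, BLUP offset), whose multivariate covariance
#' blocks `Psi_mm' (T^q)' (H^q)^-1 Phi A Phi (H^q')^-1 T^q'` follow from
#' the same covariance algebra; the MMASTOR generalization beyond `V = I`
#' is marked `"extension"` in the result note.
#'
#' @param method one of `"MFQLS"`, `"MMQLS"`, `"MMASTOR"`.
#' @param Y `N x Q` phenotype matrix.
#' @param Z covariate matrix with intercept.
#' @param phi relationship matrix.
#' @param X genotype matrix (complete rows).
#' @param prevalence per-phenotype prevalence (required for MMQLS).
#' @param fits optional prefitted [fit_null_model] (MFQLS/MMASTOR).
#' @param psi optional genotype covariance.
#' @return `mfqls_result`.
#' @export
variant_test <- function(method = c("MFQLS", "MMQLS", "MMASTOR"),
                         Y, Z, phi, X, prevalence = NULL, fits = NULL,
                         psi = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (method == "MMQLS") {
    if (is.null(prevalence))
      stop("MMQLS requires per-phenotype prevalences")
    Tm <- prevalence_offset(Y, prevalence)
    return(mfqls_test(Tm, phi, X, psi = psi, method = "MMQLS"))
  }
  if (is.null(fits)) fits <- fit_null_model(Y, Z, phi)
  Tm <- blup_offset(Y, Z, phi, fits)
  if (method == "MFQLS")
    return(mfqls_test(Tm, phi, X, psi = psi, method = "MFQLS"))
  # MMASTOR: weight each adjusted phenotype by (H^q)^-1; the V = I core
  # applied to the weighted T then yields the generalized blocks.
  Tw <- Tm
  for (q in seq_len(ncol(Tm))) {
    H <- fits[[q]]$sigma2_B * phi + diag(fits[[q]]$sigma2_E, nrow(phi))
    Tw[, q] <- solve(H, Tm[, q])
  }
  res <- mfqls_test(Tw, phi, X, psi = psi, method = "MMASTOR")
  res$note <- "extension"
  res
}

#' @export
print.mfqls_result <- function(x, ...) {
  cat(sprintf("%s score test: M = %d markers, Q = %d phenotypes, N = %d\n",
              x$method, x$M, x$Q, x$n_used))
  if (is.na(x$statistic)) {
    cat("  no test performed:", x$note %||% "degenerate input", "\n")
  } else {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
    if (!is.null(x$note)) cat("  note:", x$note, "\n")
  }
  invisible(x)
}
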