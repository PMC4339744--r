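# Replicate-study engine.
#
# Calibration and power runs test the same few-marker model on thousands
# of simulated datasets that share one relationship matrix, so the
# eigendecomposition of Phi is computed once and every replicate works in
# the rotated basis: with Phi = U L U', T~ = U'T, X~ = U'X and
# u~ = U'1,
#   Phi A X = X - 1 (1' Phi^-1 X) / c   ->  X~ - u~ (u~' L^-1 X~) / c
#   T' Phi A Phi T                      ->  T~' L T~ - (T~'u~)(u~'T~)/c
# with c = u~' L^-1 u~.  For the canonical replicated pedigree only the
# 10 x 10 family block is decomposed and the rotation is applied
# block-wise by reshaping.

# Rotation setup for n identical family blocks.
.block_setup <- function(n_families) {
  phi1 <- kinship_from_pedigree(canonical_pedigree(1L))
  e <- eigen(phi1, symmetric = TRUE)
  b <- nrow(phi1)
  N <- b * n_families
  Ut <- t(e$vectors)
  rot <- function(M) {
    M <- as.matrix(M)
    matrix(Ut %*% matrix(M, nrow = b), nrow = N)
  }
  lam <- rep(e$values, n_families)
  ones_t <- rep(drop(Ut %*% rep(1, b)), n_families)
  list(rot = rot, lam = lam, ones_t = ones_t,
       c_ = sum(ones_t^2 / lam), N = N)
}

# Rotation setup for an arbitrary (e.g. genomic) relationship matrix.
.dense_setup <- function(phi) {
  e <- eigen(phi, symmetric = TRUE)
  if (min(e$values) < 1e-8)
    stop("relationship matrix is numerically singular; add a ridge")
  Ut <- t(e$vectors)
  ones_t <- drop(Ut %*% rep(1, nrow(phi)))
  list(rot = function(M) Ut %*% as.matrix(M), lam = e$values,
       ones_t = ones_t, c_ = sum(ones_t^2 / e$values), N = nrow(phi))
}

# V = I score statistic in the rotated basis.
.stat_rotated <- function(Tt, Xt, lam, ones_t, c_, psi) {
  v <- drop(crossprod(ones_t / lam, Xt)) / c_
  Xc <- Xt - ones_t %o% v
  Smat <- crossprod(Tt, Xc)
  t1 <- drop(crossprod(Tt, ones_t))
  G <- crossprod(Tt, lam * Tt) - tcrossprod(t1) / c_
  .chisq_from_score(as.vector(Smat), kronecker(psi, G))
}

# One simulated dataset -> p-values for the requested methods.
.replicate_once <- function(su, ped, levels, cfg, type, methods,
                            subpop = NULL, shift = NULL, Zt) {
  p_A <- stats::runif(1L, cfg$maf_law[1L], cfg$maf_law[2L])
  p_B <- stats::runif(1L, cfg$maf_law[1L], cfg$maf_law[2L])
  probs <- if (is.null(subpop)) haplotype_freqs(p_A, p_B, cfg$Dprime)
  else .structured_founder_probs(p_A, p_B, cfg$Dprime, cfg$Fst, subpop)
  gen <- simulate_family_genotypes(ped, probs, levels)
  B <- simulate_polygenic(ped, cfg$Sigma_B, levels)
  Y <- assemble_quantitative(gen$X, cfg$beta, cfg$alpha, B, cfg$sigma2_E,
                             shift = shift)
  if (type == "dichotomous") {
    liab_mean <- cfg$alpha + if (is.null(shift)) 0 else cfg$mean_shift / 2
    Y <- dichotomize_liability(Y, cfg$prevalence, liab_mean,
                               sqrt(diag(cfg$Sigma_B) + cfg$sigma2_E))
  }
  psi <- stats::cov(gen$X)
  Xt <- su$rot(gen$X)
  Yt <- su$rot(Y)
  out <- rep(NA_real_, length(methods))
  names(out) <- methods
  need_reml <- any(methods %in% c("MFQLS", "MMASTOR"))
  if (need_reml) {
    Q <- ncol(Y)
    Tt <- matrix(0, su$N, Q)
    Twt <- matrix(0, su$N, Q)
    for (q in seq_len(Q)) {
      fit <- .reml_profile(su$lam, Yt[, q, drop = FALSE], Zt)
      w <- fit$h2 * su$lam + (1 - fit$h2)
      r <- Yt[, q] - drop(Zt %*% fit$alpha)
      Tt[, q] <- r * (1 - fit$h2) / w
      s2 <- fit$sigma2_B + fit$sigma2_E
      Twt[, q] <- Tt[, q] / (s2 * w)      # (H^q)^-1 T^q, rotated
    }
    if ("MFQLS" %in% methods)
      out["MFQLS"] <- .stat_rotated(Tt, Xt, su$lam, su$ones_t, su$c_,
                                    psi)$p_value
    if ("MMASTOR" %in% methods)
      out["MMASTOR"] <- .stat_rotated(Twt, Xt, su$lam, su$ones_t, su$c_,
                                      psi)$p_value
  }
  if ("MMQLS" %in% methods) {
    if (type != "dichotomous")
      stop("MMQLS requires dichotomous phenotypes")
    Tp <- sweep(Y, 2L, cfg$prevalence, `-`)
    out["MMQLS"] <- .stat_rotated(su$rot(Tp), Xt, su$lam, su$ones_t,
                                  su$c_, psi)$p_value
  }
  out
}

.run_replicates <- function(n_reps, su, ped, levels, cfg, type, methods,
                            subpop = NULL, shift = NULL) {
  Zt <- matrix(su$ones_t)                 # intercept-only fixed effects
  P <- matrix(NA_real_, n_reps, length(methods),
              dimnames = list(NULL, methods))
  for (r in seq_len(n_reps))
    P[r, ] <- .replicate_once(su, ped, levels, cfg, type, methods,
                              subpop = subpop, shift = shift, Zt = Zt)
  P
}

.reject_rates <- function(P, alphas) {
  out <- sapply(alphas, function(a) colMeans(P < a, na.rm = TRUE))
  out <- matrix(out, nrow = ncol(P),
                dimnames = list(colnames(P), paste0("alpha", alphas)))
  out
}

#' Empirical type-I error in a homogeneous population
#'
#' Reruns the null calibration study: `n_reps` replicates of
#' `n_families` canonical 10-member families, two test markers with
#' minor-allele frequencies from `U(maf_law)` and LD `Dprime`, phenotype
#' model from the published defaults, `beta = 0`, and the empirical
#' rejection rate of the requested score tests at each significance
#' level.  Uses the cached eigendecomposition of the 10 x 10 kinship
#' block, so a full configuration runs in minutes.
#'
#' @param type `"quantitative"` or `"dichotomous"` (liability threshold).
#' @param Q number of phenotypes (2 or 5).
#' @param Dprime Lewontin's D' between the two test markers.
#' @param n_reps number of replicates.
#' @param n_families families per replicate.
#' @param rho cross-phenotype correlation.
#' @param alphas significance levels evaluated.
#' @param maf_law uniform range of the marker minor-allele frequencies.
#' @param methods score-test variants to evaluate.
#' @return List: `p_values` (`n_reps x methods` matrix), `reject`
#'   (methods x alphas rejection-rate matrix), `mc_se` (binomial standard
#'   errors at the nominal levels), and the settings.
#' @export
calibrate_type1 <- function(type = c("quantitative", "dichotomous"),
                            Q = 2L, Dprime = 0, n_reps = 1000L,
                            n_families = 100L, rho = 0.2,
                            alphas = c(0.005, 0.01, 0.05),
                            maf_law = c(0.1, 0.4), methods = "MFQLS") {
  type <- match.arg(type)
  cfg <- sim_config(n_families = n_families, Q = Q, rho = rho,
                    Dprime = Dprime, maf_law = maf_law,
                    dichotomize = identical(type, "dichotomous"))
  ped <- canonical_pedigree(n_families)
  levels <- .ped_levels(ped)
  su <- .block_setup(n_families)
  P <- .run_replicates(n_reps, su, ped, levels, cfg, type, methods)
  list(p_values = P, reject = .reject_rates(P, alphas),
       mc_se = sqrt(alphas * (1 - alphas) / n_reps), alphas = alphas,
       type = type, Q = Q, Dprime = Dprime, n_reps = n_reps)
}

#' Empirical type-I error under population substructure
#'
#' Two Balding-Nichols subpopulations (fixation index `Fst`), founders
#' labelled independently with probability 0.5, phenotype means shifted
#' by `mean_shift * ancestry`, and the pedigree kinship matrix replaced
#' by the empirical genomic relationship matrix estimated from a
#' simulated panel of common null markers.  The ancestry labels and the
#' panel (hence the GRM and its eigendecomposition) are generated once
#' per configuration and shared across replicates; phenotypes, polygenic
#' effects and test markers are redrawn every replicate conditional on
#' the ancestry labels.
#'
#' @inheritParams calibrate_type1
#' @param Fst Wright's fixation index.
#' @param n_null_markers size of the null panel behind the GRM.
#' @param mean_shift between-subpopulation phenotype mean difference.
#' @param use_grm `FALSE` runs the negative control in which the
#'   pedigree kinship matrix is (incorrectly) kept despite substructure.
#' @return As [calibrate_type1], plus `Fst` and `grm_lambda_range`.
#' @export
calibrate_structured <- function(type = c("quantitative", "dichotomous"),
                                 Q = 2L, Dprime = 0, Fst = 0.01,
                                 n_reps = 1000L, n_families = 100L,
                                 n_null_markers = 10000L, rho = 0.2,
                                 alphas = c(0.005, 0.01, 0.05),
                                 maf_law = c(0.1, 0.5),
                                 mean_shift = 0.2, methods = "MFQLS",
                                 use_grm = TRUE) {
  type <- match.arg(type)
  cfg <- sim_config(n_families = n_families, Q = Q, rho = rho,
                    Dprime = Dprime, maf_law = maf_law, Fst = Fst,
                    mean_shift = mean_shift,
                    dichotomize = identical(type, "dichotomous"))
  ped <- canonical_pedigree(n_families)
  levels <- .ped_levels(ped)
  anc <- .ancestry(ped, levels)
  subpop <- as.integer(anc[levels$founders])
  panel <- simulate_null_panel(ped, n_null_markers, Fst = Fst,
                               founder_subpop = subpop,
                               maf_law = maf_law, levels = levels)
  if (use_grm) {
    phi <- grm_from_genotypes(panel$X)
    phi <- validate_relmatrix(phi, ridge = 1e-6)
    su <- .dense_setup(phi)
  } else {
    su <- .block_setup(n_families)
  }
  P <- .run_replicates(n_reps, su, ped, levels, cfg, type, methods,
                       subpop = subpop, shift = mean_shift * anc)
  list(p_values = P, reject = .reject_rates(P, alphas),
       mc_se = sqrt(alphas * (1 - alphas) / n_reps), alphas = alphas,
       type = type, Q = Q, Dprime = Dprime, Fst = Fst, n_reps = n_reps,
       use_grm = use_grm,
       grm_lambda_range = range(su$lam))
}

#' Empirical power of the score-test variants
#'
#' Same generative model as [calibrate_type1] but with a nonzero
#' `M x Q` effect matrix `beta`; all requested methods are evaluated on
#' common replicates, so power differences are paired.
#'
#' @inheritParams calibrate_type1
#' @param beta scalar or `2 x Q` matrix of per-allele effects.
#' @param alpha significance level at which power is evaluated.
#' @param maf_fixed when non-`NULL`, both markers use this fixed
#'   minor-allele frequency instead of the uniform law.
#' @return List with `power` (per method), `p_values`, and settings.
#' @export
estimate_power <- function(type = c("quantitative", "dichotomous"),
                           Q = 2L, Dprime = 0.5, beta = 0.12,
                           n_reps = 500L, n_families = 100L, rho = 0.2,
                           alpha = 0.005, maf_fixed = 0.2,
                           methods = c("MFQLS", "MMASTOR")) {
  type <- match.arg(type)
  maf_law <- if (is.null(maf_fixed)) c(0.1, 0.4)
  else c(maf_fixed, maf_fixed)
  cfg <- sim_config(n_families = n_families, Q = Q, rho = rho,
                    Dprime = Dprime, maf_law = maf_law, beta = beta,
                    dichotomize = identical(type, "dichotomous"))
  ped <- canonical_pedigree(n_families)
  levels <- .ped_levels(ped)
  su <- .block_setup(n_families)
  P <- .run_replicates(n_reps, su, ped, levels, cfg, type, methods)
  list(power = colMeans(P < alpha, na.rm = TRUE), p_values = P,
       alpha = alpha, beta = beta, type = type, Q = Q, Dprime = Dprime,
       n_reps = n_reps)
}
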