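#' Two-locus haplotype frequencies from allele frequencies and D'
#'
#' With minor-allele frequencies `p_A`, `p_B` and linkage-disequilibrium
#' coefficient `d`, the four haplotype frequencies are
#' `p_AB = p_A p_B + d`, `p_Ab = p_A (1 - p_B) - d`,
#' `p_aB = (1 - p_A) p_B - d`, `p_ab = (1 - p_A)(1 - p_B) + d`.
#' `d` is parameterized through Lewontin's D' for non-negative
#' disequilibrium: `d = Dprime * min(p_A (1 - p_B), (1 - p_A) p_B)`.
#'
#' @param p_A,p_B allele frequencies in (0, 1).
#' @param Dprime Lewontin's D' in `[0, 1]`.
#' @return Named numeric vector `(AB, Ab, aB, ab)` summing to 1, with
#'   attribute `d`.
#' @export
haplotype_freqs <- function(p_A, p_B, Dprime = 0) {
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    stop("allele frequencies must lie in (0, 1)")
  if (Dprime < 0 || Dprime > 1) stop("Dprime must lie in [0, 1]")
  d <- Dprime * min(p_A * (1 - p_B), (1 - p_A) * p_B)
  h <- c(AB = p_A * p_B + d, Ab = p_A * (1 - p_B) - d,
         aB = (1 - p_A) * p_B - d, ab = (1 - p_A) * (1 - p_B) + d)
  if (any(h < -1e-12) || abs(sum(h) - 1) > 1e-12)
    stop("haplotype frequencies out of range")
  structure(pmax(h, 0), d = d)
}

# Parent-before-child generation levels of a pedigree; enables
# vectorized gene dropping across all families at once.
.ped_levels <- function(ped) {
  n <- nrow(ped)
  fa <- match(paste(ped$fid, ped$father), paste(ped$fid, ped$iid))
  mo <- match(paste(ped$fid, ped$mother), paste(ped$fid, ped$iid))
  depth <- rep(NA_integer_, n)
  depth[ped$founder] <- 0L
  lev <- 0L
  while (anyNA(depth)) {
    ready <- is.na(depth) & !is.na(depth[ifelse(is.na(fa), 1L, fa)]) &
      !is.na(depth[ifelse(is.na(mo), 1L, mo)]) &
      depth[ifelse(is.na(fa), 1L, fa)] <= lev &
      depth[ifelse(is.na(mo), 1L, mo)] <= lev
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) stop("pedigree is not acyclic")
    depth[ready] <- lev + 1L
    lev <- lev + 1L
  }
  levels <- lapply(seq_len(max(depth)), function(l) {
    ch <- which(depth == l)
    list(child = ch, fa = fa[ch], mo = mo[ch])
  })
  list(founders = which(ped$founder), levels = levels)
}

# Categorical draw with per-row probabilities (rows x 4 matrix).
.sample_hap <- function(probs) {
  cum <- t(apply(probs, 1L, cumsum))
  u <- stats::runif(nrow(probs))
  1L + (u > cum[, 1L]) + (u > cum[, 2L]) + (u > cum[, 3L])
}

#' Drop two-locus haplotypes through a pedigree
#'
#' Founders receive two haplotypes drawn independently from the
#' four-category haplotype law (Hardy-Weinberg at the haplotype level);
#' each child receives one uniformly chosen haplotype from each parent,
#' with no recombination between the loci.  Haplotypes are coded
#' `1 = AB, 2 = Ab, 3 = aB, 4 = ab`.
#'
#' @param ped a [pedigree]; simulation is vectorized across families.
#' @param founder_probs either a length-4 haplotype frequency vector
#'   (see [haplotype_freqs]) shared by all founders, or a
#'   `n_founders x 4` matrix of per-founder laws (rows in pedigree
#'   founder order), e.g. under population substructure.
#' @param levels optional precomputed `.ped_levels(ped)` (internal
#'   cache for replicate studies).
#' @return List with integer haplotype vectors `H1`, `H2` (length `N`)
#'   and the `N x 2` minor-allele count matrix `X` (locus A, locus B).
#' @export
simulate_family_genotypes <- function(ped, founder_probs, levels = NULL) {
  if (is.null(levels)) levels <- .ped_levels(ped)
  n <- nrow(ped)
  fnd <- levels$founders
  if (is.null(dim(founder_probs)))
    founder_probs <- matrix(founder_probs, length(fnd), 4L, byrow = TRUE)
  if (nrow(founder_probs) != length(fnd))
    stop("founder_probs must have one row per founder")
  H1 <- H2 <- integer(n)
  H1[fnd] <- .sample_hap(founder_probs)
  H2[fnd] <- .sample_hap(founder_probs)
  for (lv in levels$levels) {
    pick_f <- stats::runif(length(lv$child)) < 0.5
    pick_m <- stats::runif(length(lv$child)) < 0.5
    H1[lv$child] <- ifelse(pick_f, H1[lv$fa], H2[lv$fa])
    H2[lv$child] <- ifelse(pick_m, H1[lv$mo], H2[lv$mo])
  }
  hasA <- c(1L, 1L, 0L, 0L)   # haplotypes carrying the locus-A minor allele
  hasB <- c(1L, 0L, 1L, 0L)
  X <- cbind(A = hasA[H1] + hasA[H2], B = hasB[H1] + hasB[H2])
  list(H1 = H1, H2 = H2, X = X)
}

#' Additive polygenic effects over a pedigree
#'
#' Founders draw their length-`Q` polygenic vector i.i.d. from
#' `MVN(0, Sigma_B)`; each child receives the average of the parental
#' vectors plus an independent segregation term from
#' `MVN(0, 0.5 Sigma_B)`, so every individual is marginally
#' `MVN(0, Sigma_B)` and parent-offspring covariance is `0.5 Sigma_B`.
#'
#' @param ped a [pedigree].
#' @param Sigma_B positive semidefinite `Q x Q` polygenic covariance.
#' @param levels optional precomputed `.ped_levels(ped)`.
#' @return `N x Q` matrix of polygenic effects.
#' @export
simulate_polygenic <- function(ped, Sigma_B, levels = NULL) {
  if (is.null(levels)) levels <- .ped_levels(ped)
  Sigma_B <- as.matrix(Sigma_B)
  Q <- ncol(Sigma_B)
  n <- nrow(ped)
  B <- matrix(0, n, Q)
  if (all(Sigma_B == 0)) return(B)
  L <- chol(Sigma_B + diag(1e-12, Q))
  fnd <- levels$founders
  B[fnd, ] <- matrix(stats::rnorm(length(fnd) * Q), length(fnd)) %*% L
  for (lv in levels$levels) {
    seg <- matrix(stats::rnorm(length(lv$child) * Q),
                  length(lv$child)) %*% (L * sqrt(0.5))
    B[lv$child, ] <- (B[lv$fa, , drop = FALSE] +
                        B[lv$mo, , drop = FALSE]) / 2 + seg
  }
  B
}

#' Assemble quantitative phenotypes
#'
#' `y_ijq = alpha_q + sum_m x_ijm beta_mq + b_ijq + e_ijq` with
#' independent `e_ijq ~ N(0, sigma2_E[q])`, plus an optional
#' per-individual mean shift (used for the between-subpopulation
#' phenotype difference).
#'
#' @param X `N x M` genotype matrix.
#' @param beta `M x Q` effect matrix (0 under the null).
#' @param alpha length-`Q` phenotype means.
#' @param B `N x Q` polygenic matrix.
#' @param sigma2_E length-`Q` residual variances.
#' @param shift optional length-`N` vector added to every phenotype
#'   column (e.g. `mean_shift * ancestry`).
#' @return `N x Q` phenotype (liability) matrix.
#' @export
assemble_quantitative <- function(X, beta, alpha, B, sigma2_E,
                                  shift = NULL) {
  B <- as.matrix(B)
  N <- nrow(B)
  Q <- ncol(B)
  beta <- matrix(beta, ncol = Q)
  E <- matrix(stats::rnorm(N * Q), N) %*% diag(sqrt(sigma2_E), Q)
  Y <- rep(1, N) %o% alpha + as.matrix(X) %*% beta + B + E
  if (!is.null(shift)) Y <- Y + shift
  Y
}

#' Liability-threshold dichotomization
#'
#' Affected iff the liability exceeds the upper-`K_q` quantile of the
#' theoretical marginal liability law (so the expected affected fraction
#' equals the target prevalence and case counts are binomial rather than
#' fixed per replicate).
#'
#' @param Y liability matrix (`N x Q`).
#' @param K per-phenotype prevalence in (0, 1).
#' @param liab_mean,liab_sd length-`Q` theoretical marginal mean and SD
#'   of the null liability (`alpha_q` and
#'   `sqrt(Sigma_B[q,q] + sigma2_E[q])` in the simulator).
#' @return 0/1 matrix of the same shape, with attribute `threshold`.
#' @export
dichotomize_liability <- function(Y, K, liab_mean, liab_sd) {
  Q <- ncol(Y)
  K <- rep_len(K, Q)
  if (any(K <= 0 | K >= 1)) stop("prevalence must lie in (0, 1)")
  thr <- stats::qnorm(1 - K, mean = rep_len(liab_mean, Q),
                      sd = rep_len(liab_sd, Q))
  D <- sweep(Y, 2L, thr, `>`) + 0
  structure(D, threshold = thr)
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Two subpopulation frequencies drawn independently from
#' `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`; both have mean `p`
#' and variance `Fst p (1 - p)`.
#'
#' @param p ancestral allele frequency in (0, 1).
#' @param Fst Wright's fixation index in (0, 1).
#' @param n_pops number of subpopulations (default 2).
#' @return Numeric vector of subpopulation frequencies.
#' @export
balding_nichols_freqs <- function(p, Fst, n_pops = 2L) {
  if (Fst <= 0 || Fst >= 1) stop("Fst must lie in (0, 1)")
  if (p <= 0 || p >= 1) stop("ancestral frequency must lie in (0, 1)")
  r <- (1 - Fst) / Fst
  stats::rbeta(n_pops, p * r, (1 - p) * r)
}

#' Published default phenotype model parameters
#'
#' Polygenic covariance, residual variances and prevalences used in the
#' calibration study: for `Q = 2`, `Sigma_B = [[1, rho sqrt(2)],
#' [rho sqrt(2), 2]]`, `sigma2_E = (1, 2)`, prevalences `(0.1, 0.2)`;
#' for `Q = 5`, diagonal `(1, 1, 2, 2, 2)` with correlations `rho`
#' between the unit-variance pair, `2 rho` among the variance-2 block and
#' `sqrt(2) rho` across, `sigma2_E = (1, ..., 5)`, prevalences
#' `(0.1, 0.1, 0.2, 0.2, 0.3)`.
#'
#' @param Q number of phenotypes (2 or 5 for the published settings).
#' @param rho cross-phenotype correlation parameter.
#' @return `default_Sigma_B`: `Q x Q` matrix; `default_sigma2_E` and
#'   `default_prevalence`: length-`Q` vectors.
#' @export
default_Sigma_B <- function(Q, rho) {
  if (Q == 2L) {
    matrix(c(1, rho * sqrt(2), rho * sqrt(2), 2), 2L)
  } else if (Q == 5L) {
    S <- matrix(0, 5L, 5L)
    diag(S) <- c(1, 1, 2, 2, 2)
    S[1L, 2L] <- S[2L, 1L] <- rho
    S[1:2, 3:5] <- sqrt(2) * rho
    S[3:5, 1:2] <- sqrt(2) * rho
    S[3:5, 3:5][upper.tri(S[3:5, 3:5])] <- 2 * rho
    S[3:5, 3:5][lower.tri(S[3:5, 3:5])] <- 2 * rho
    S
  } else stop("published settings define Q = 2 or Q = 5")
}

#' @rdname default_Sigma_B
#' @export
default_sigma2_E <- function(Q) {
  if (Q == 2L) c(1, 2) else if (Q == 5L) as.numeric(1:5)
  else stop("published settings define Q = 2 or Q = 5")
}

#' @rdname default_Sigma_B
#' @export
default_prevalence <- function(Q) {
  if (Q == 2L) c(0.1, 0.2) else if (Q == 5L) c(0.1, 0.1, 0.2, 0.2, 0.3)
  else stop("published settings define Q = 2 or Q = 5")
}

#' Simulation configuration
#'
#' Collects the generative-model parameters; defaults are the stated
#' calibration conditions (100 canonical 10-member families, two test
#' markers with minor-allele frequencies from `U(0.1, 0.4)`,
#' `rho = 0.2`, `beta = 0`, published `Sigma_B`/`sigma2_E`/prevalence).
#'
#' @param n_families number of canonical families.
#' @param Q number of phenotypes (2 or 5 unless all phenotype parameters
#'   are supplied explicitly).
#' @param rho cross-phenotype correlation parameter.
#' @param Dprime Lewontin's D' between the two test loci.
#' @param maf_law range of the uniform law for the test-locus (ancestral,
#'   under substructure) minor-allele frequencies.
#' @param beta `M x Q` effect matrix or scalar (recycled); 0 = null.
#' @param alpha length-`Q` phenotype means.
#' @param Sigma_B,sigma2_E,prevalence phenotype model parameters;
#'   `NULL` = published defaults for `Q`.
#' @param dichotomize transform liabilities to 0/1 phenotypes.
#' @param Fst fixation index for two-subpopulation substructure;
#'   `NULL` = homogeneous population.
#' @param mean_shift between-subpopulation phenotype mean difference
#'   (applied as `mean_shift * ancestry proportion`).
#' @param n_null_markers size of the genome-wide null panel used for the
#'   empirical relationship matrix (0 = none).
#' @param family_level_ancestry assign whole families (rather than each
#'   founder) to a subpopulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 100L, Q = 2L, rho = 0.2, Dprime = 0,
                       maf_law = c(0.1, 0.4), beta = 0, alpha = NULL,
                       Sigma_B = NULL, sigma2_E = NULL, prevalence = NULL,
                       dichotomize = FALSE, Fst = NULL, mean_shift = 0.2,
                       n_null_markers = 0L,
                       family_level_ancestry = FALSE) {
  if (!is.null(Fst) && (Fst <= 0 || Fst >= 1))
    stop("Fst must lie in (0, 1); omit it for a homogeneous population")
  cfg <- list(
    n_families = as.integer(n_families), Q = as.integer(Q), rho = rho,
    Dprime = Dprime, maf_law = maf_law,
    beta = matrix(beta, nrow = 2L, ncol = Q),
    alpha = alpha %||% rep(0, Q),
    Sigma_B = Sigma_B %||% default_Sigma_B(Q, rho),
    sigma2_E = sigma2_E %||% default_sigma2_E(Q),
    prevalence = prevalence %||% default_prevalence(Q),
    dichotomize = dichotomize, Fst = Fst, mean_shift = mean_shift,
    n_null_markers = as.integer(n_null_markers),
    family_level_ancestry = family_level_ancestry)
  if (min(eigen(cfg$Sigma_B, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("Sigma_B must be positive semidefinite")
  class(cfg) <- "sim_config"
  cfg
}

# Founder subpopulation labels and propagated ancestry proportions.
# Founders get a Bernoulli(0.5) label (optionally shared family-wide);
# each non-founder's ancestry proportion is the mean of its parents'.
.ancestry <- function(ped, levels, family_level = FALSE) {
  anc <- rep(NA_real_, nrow(ped))
  fnd <- levels$founders
  if (family_level) {
    fam_lab <- stats::rbinom(length(unique(ped$fid)), 1L, 0.5)
    anc[fnd] <- fam_lab[match(ped$fid[fnd], unique(ped$fid))]
  } else {
    anc[fnd] <- stats::rbinom(length(fnd), 1L, 0.5)
  }
  for (lv in levels$levels)
    anc[lv$child] <- (anc[lv$fa] + anc[lv$mo]) / 2
  anc
}

# Two-subpopulation haplotype laws sharing D' (per-founder 4-col matrix).
.structured_founder_probs <- function(p_A, p_B, Dprime, Fst, subpop) {
  pA <- balding_nichols_freqs(p_A, Fst)
  pB <- balding_nichols_freqs(p_B, Fst)
  h1 <- haplotype_freqs(pA[1L], pB[1L], Dprime)
  h2 <- haplotype_freqs(pA[2L], pB[2L], Dprime)
  rbind(h1, h2)[subpop + 1L, , drop = FALSE]
}

#' Genome-wide null marker panel
#'
#' Simulates unlinked biallelic markers unrelated to the phenotypes:
#' founder allele counts are binomial in their (sub)population frequency
#' and children inherit one allele per parent by Mendelian transmission.
#' Ancestral frequencies are drawn from `U(maf_law)`; under substructure
#' each marker's subpopulation frequencies come from the Balding-Nichols
#' model and markers are redrawn until both subpopulation minor-allele
#' frequencies exceed `maf_min` (common variants only, mirroring the
#' stated panel filter).
#'
#' @param ped a [pedigree].
#' @param n_markers panel size.
#' @param Fst optional fixation index.
#' @param founder_subpop 0/1 founder labels (required with `Fst`).
#' @param maf_law uniform range for ancestral frequencies.
#' @param maf_min post-filter minor-allele frequency bound.
#' @param levels optional precomputed `.ped_levels(ped)`.
#' @return List: `X` (`N x n_markers` counts), `freq_pop` (2 x M matrix
#'   of subpopulation frequencies, identical rows when unstructured).
#' @export
simulate_null_panel <- function(ped, n_markers, Fst = NULL,
                                founder_subpop = NULL,
                                maf_law = c(0.1, 0.4), maf_min = 0.1,
                                levels = NULL) {
  if (is.null(levels)) levels <- .ped_levels(ped)
  n <- nrow(ped)
  fnd <- levels$founders
  # per-marker subpopulation frequencies, filtered to common variants
  freq <- matrix(0, 2L, 0L)
  while (ncol(freq) < n_markers) {
    need <- n_markers - ncol(freq)
    p0 <- stats::runif(ceiling(need * 1.5), maf_law[1L], maf_law[2L])
    if (is.null(Fst)) {
      cand <- rbind(p0, p0)
    } else {
      r <- (1 - Fst) / Fst
      cand <- rbind(stats::rbeta(length(p0), p0 * r, (1 - p0) * r),
                    stats::rbeta(length(p0), p0 * r, (1 - p0) * r))
    }
    ok <- cand[1L, ] > maf_min & cand[1L, ] < 1 - maf_min &
      cand[2L, ] > maf_min & cand[2L, ] < 1 - maf_min
    freq <- cbind(freq, cand[, ok, drop = FALSE])
  }
  freq <- freq[, seq_len(n_markers), drop = FALSE]
  if (is.null(Fst)) {
    pf <- matrix(freq[1L, ], length(fnd), n_markers, byrow = TRUE)
  } else {
    if (is.null(founder_subpop))
      stop("founder_subpop labels required with Fst")
    pf <- freq[founder_subpop + 1L, , drop = FALSE]
  }
  X <- matrix(0L, n, n_markers)
  X[fnd, ] <- matrix(stats::rbinom(length(pf), 2L, pf), length(fnd))
  for (lv in levels$levels) {
    k <- length(lv$child)
    from_fa <- matrix(stats::rbinom(k * n_markers, 1L,
                                    X[lv$fa, , drop = FALSE] / 2), k)
    from_mo <- matrix(stats::rbinom(k * n_markers, 1L,
                                    X[lv$mo, , drop = FALSE] / 2), k)
    X[lv$child, ] <- from_fa + from_mo
  }
  list(X = X, freq_pop = freq)
}

#' Simulate a complete family dataset
#'
#' Draws test-locus haplotypes, polygenic effects, residuals and (when
#' requested) the dichotomized phenotypes and a genome-wide null panel,
#' under either a homogeneous population or two Balding-Nichols
#' subpopulations with a phenotype mean shift proportional to ancestry.
#'
#' @param cfg a [sim_config].
#' @return List of class `sim_dataset`: `ped`, `X` (N x 2 test
#'   genotypes), `Y` (quantitative phenotypes / liabilities), `Yd`
#'   (0/1 phenotypes when `cfg$dichotomize`), `B` (polygenic), `ancestry`
#'   (when structured), `null_panel` (when requested), `maf` (drawn
#'   test-locus frequencies), `hap_probs`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- canonical_pedigree(cfg$n_families)
  levels <- .ped_levels(ped)
  p_A <- stats::runif(1L, cfg$maf_law[1L], cfg$maf_law[2L])
  p_B <- stats::runif(1L, cfg$maf_law[1L], cfg$maf_law[2L])
  anc <- NULL
  if (is.null(cfg$Fst)) {
    probs <- haplotype_freqs(p_A, p_B, cfg$Dprime)
    shift <- NULL
    subpop <- NULL
  } else {
    anc <- .ancestry(ped, levels, cfg$family_level_ancestry)
    subpop <- as.integer(anc[levels$founders])
    probs <- .structured_founder_probs(p_A, p_B, cfg$Dprime, cfg$Fst,
                                       subpop)
    shift <- cfg$mean_shift * anc
  }
  gen <- simulate_family_genotypes(ped, probs, levels)
  B <- simulate_polygenic(ped, cfg$Sigma_B, levels)
  Y <- assemble_quantitative(gen$X, cfg$beta, cfg$alpha, B, cfg$sigma2_E,
                             shift = shift)
  out <- list(ped = ped, X = gen$X, Y = Y, B = B, ancestry = anc,
              maf = c(p_A = p_A, p_B = p_B), hap_probs = probs)
  if (cfg$dichotomize) {
    liab_mean <- cfg$alpha +
      if (is.null(cfg$Fst)) 0 else cfg$mean_shift / 2
    liab_sd <- sqrt(diag(cfg$Sigma_B) + cfg$sigma2_E)
    out$Yd <- dichotomize_liability(Y, cfg$prevalence, liab_mean, liab_sd)
  }
  if (cfg$n_null_markers > 0L) {
    out$null_panel <- simulate_null_panel(
      ped, cfg$n_null_markers, Fst = cfg$Fst, founder_subpop = subpop,
      maf_law = cfg$maf_law, levels = levels)
  }
  class(out) <- "sim_dataset"
  out
}
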