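# Independent oracles used across the suite.  Each is a deliberately
# naive route (dense formulas, recursion, brute-force simulation) kept
# separate from the package's optimized implementations.

# Kinship coefficient by direct recursion on the deeper individual.
# Works on a single-family pedigree data frame; O(2^depth) but fine for
# toy pedigrees.
oracle_kinship <- function(ped) {
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  depth <- function(i) if (is.na(fa[i])) 0L else 1L + max(depth(fa[i]),
                                                          depth(mo[i]))
  d <- vapply(seq_len(nrow(ped)), depth, integer(1))
  kin <- function(a, b) {
    if (a == b) {
      if (is.na(fa[a])) return(0.5)
      return(0.5 * (1 + kin(fa[a], mo[a])))
    }
    if (d[a] < d[b]) return(kin(b, a))
    if (is.na(fa[a])) return(0)         # both founders or a founder
    0.5 * (kin(fa[a], b) + kin(mo[a], b))
  }
  n <- nrow(ped)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) K[i, j] <- K[j, i] <- kin(i, j)
  K
}

# Monte-Carlo inbreeding coefficient by gene dropping: probability that
# the two alleles of `target` are identical by descent.
oracle_gene_drop_inbreeding <- function(ped, target, n_drops = 1e5) {
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  ord <- order(vapply(seq_len(nrow(ped)), function(i) {
    depth <- function(k) if (is.na(fa[k])) 0L else
      1L + max(depth(fa[k]), depth(mo[k]))
    depth(i)
  }, integer(1)))
  n <- nrow(ped)
  A1 <- matrix(0L, n_drops, n)
  A2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[, i] <- lab + 1L
      A2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, fa[i]], A2[, fa[i]])
      pick <- stats::runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, mo[i]], A2[, mo[i]])
    }
  }
  ti <- match(target, ped$iid)
  mean(A1[, ti] == A2[, ti])
}

# Random symmetric positive-definite matrix with unit-scale diagonal.
random_pd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  S <- crossprod(A) / n + diag(0.5, n)
  S
}

# Literal sum-over-individuals score: S = sum_ij {I_M (x) (T_ij e_ij')}
# vec(X - 1 ghat') with the BLUE mean genotype ghat.
oracle_score <- function(T, phi, X) {
  N <- nrow(T); Q <- ncol(T); M <- ncol(X)
  ghat <- drop(solve(crossprod(rep(1, N), solve(phi, rep(1, N)))) %*%
                 crossprod(solve(phi, rep(1, N)), X))
  Xc <- X - rep(1, N) %o% ghat
  S <- numeric(M * Q)
  for (i in seq_len(N)) {
    e <- rep(0, N); e[i] <- 1
    S <- S + kronecker(diag(M), T[i, ] %o% e) %*% as.vector(Xc)
  }
  drop(S)
}

# Covariance double sum: sum over (ij, i'j') of
# Psi (x) (T_ij e_ij' Phi A Phi e_i'j' T_i'j'').
oracle_variance <- function(T, phi, X, psi) {
  N <- nrow(T); Q <- ncol(T); M <- ncol(X)
  A <- solve(phi) - solve(phi) %*% rep(1, N) %*%
    solve(t(rep(1, N)) %*% solve(phi) %*% rep(1, N)) %*%
    t(rep(1, N)) %*% solve(phi)
  PAP <- phi %*% A %*% phi
  V <- matrix(0, M * Q, M * Q)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    V <- V + kronecker(psi, (T[i, ] %o% T[j, ]) * PAP[i, j])
  }
  V
}

# Dense restricted log-likelihood (up to constant), independent of the
# eigenbasis route: direct determinants and solves at given (h).
oracle_reml_neg2 <- function(h, y, Z, phi) {
  n <- length(y); c_ <- ncol(Z)
  V <- h * phi + (1 - h) * diag(n)
  Vi <- solve(V)
  XtVX <- t(Z) %*% Vi %*% Z
  alpha <- solve(XtVX, t(Z) %*% Vi %*% y)
  r <- y - Z %*% alpha
  s2 <- drop(t(r) %*% Vi %*% r) / (n - c_)
  (n - c_) * log(s2) + determinant(V)$modulus[1] +
    determinant(XtVX)$modulus[1]
}

# Small random null dataset on the canonical pedigree, in-memory.
make_toy_data <- function(n_fam = 3, Q = 2, seed = 1) {
  set.seed(seed)
  cfg <- sim_config(n_families = n_fam, Q = Q)
  sim <- simulate_dataset(cfg)
  phi <- kinship_from_pedigree(sim$ped)
  list(sim = sim, phi = phi,
       Z = matrix(1, nrow(phi), 1), N = nrow(phi))
}
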