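test_that("projection_A is the centering projector under phi = I and
           annihilates constants in general", {
  A <- projection_A(diag(5))
  expect_equal(A, diag(5) - matrix(1 / 5, 5, 5), tolerance = 1e-12)
  set.seed(301)
  for (k in 1:5) {
    phi <- random_pd(5)
    A <- projection_A(phi)
    expect_lt(max(abs(A %*% rep(1, 5))), 1e-10)
    expect_equal(A, t(A), tolerance = 1e-10)
    # two-route check against the dense display
    Pi <- solve(phi)
    A2 <- Pi - Pi %*% rep(1, 5) %*%
      solve(t(rep(1, 5)) %*% Pi %*% rep(1, 5)) %*% t(rep(1, 5)) %*% Pi
    expect_equal(A, A2, tolerance = 1e-8)
  }
})

test_that("score and variance equal the literal Kronecker / double-sum
           oracles on random instances", {
  set.seed(302)
  for (k in 1:12) {
    N <- sample(6:12, 1)
    M <- sample(1:3, 1)
    Q <- sample(1:3, 1)
    phi <- random_pd(N)
    T <- matrix(rnorm(N * Q), N)
    X <- matrix(rbinom(N * M, 2, 0.4), N)
    psi <- estimate_psi(X) + diag(0.1, M)   # keep PD for tiny N
    S <- mfqls_score(T, phi, X)
    expect_equal(S, oracle_score(T, phi, X), tolerance = 1e-8)
    V <- mfqls_variance(T, phi, psi)
    expect_equal(V, oracle_variance(T, phi, X, psi), tolerance = 1e-8)
  }
})

test_that("degenerate inputs: zero T, monomorphic markers, orthogonal T", {
  set.seed(303)
  phi <- kinship_from_pedigree(canonical_pedigree(2))
  N <- nrow(phi)
  X <- matrix(rbinom(N * 2, 2, 0.3), N)
  expect_equal(mfqls_score(matrix(0, N, 2), phi, X), rep(0, 4))
  # constant marker columns are annihilated by A
  expect_equal(mfqls_score(matrix(rnorm(N * 2), N), phi,
                           matrix(1, N, 2)), rep(0, 4),
               tolerance = 1e-10)
  res <- suppressWarnings(mfqls_test(matrix(rnorm(N)), phi,
                                     matrix(2, N, 2)))
  expect_true(is.na(res$p_value))
  expect_identical(res$df, 0L)
  res0 <- mfqls_test(matrix(0, N, 1), phi, X)
  expect_true(is.na(res0$p_value))
})

test_that("scalar path (M = Q = 1, phi = I) equals the independently
           coded centered cross-product statistic", {
  set.seed(304)
  N <- 40
  y <- rnorm(N)
  X <- matrix(rbinom(N, 2, 0.3))
  Tm <- matrix(y - mean(y))
  res <- mfqls_test(Tm, diag(N), X, psi = estimate_psi(X))
  Xc <- X - mean(X)
  stat <- drop(crossprod(Tm, Xc))^2 /
    (var(X[, 1]) * (sum(Tm^2) - sum(Tm)^2 / N))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$df, 1L)
})

test_that("statistic is invariant to constant genotype shifts and
           individual reordering", {
  set.seed(305)
  d <- make_toy_data(n_fam = 3, seed = 305)
  fits <- fit_null_model(d$sim$Y, d$Z, d$phi)
  Tm <- blup_offset(d$sim$Y, d$Z, d$phi, fits)
  X <- d$sim$X
  psi <- estimate_psi(X)
  s1 <- mfqls_test(Tm, d$phi, X, psi = psi)$statistic
  Xs <- sweep(X, 2, c(0.7, -1.3), `+`)       # arbitrary constants per marker
  s2 <- mfqls_test(Tm, d$phi, Xs, psi = psi)$statistic
  expect_equal(s1, s2, tolerance = 1e-10)
  per <- sample(d$N)
  s3 <- mfqls_test(Tm[per, ], d$phi[per, per], X[per, ],
                   psi = psi)$statistic
  expect_equal(s1, s3, tolerance = 1e-8)
})

test_that("rank-deficient score variance drops df via the pseudo-inverse", {
  set.seed(306)
  d <- make_toy_data(n_fam = 3, seed = 306)
  fits <- fit_null_model(d$sim$Y, d$Z, d$phi)
  Tm <- blup_offset(d$sim$Y, d$Z, d$phi, fits)
  X <- cbind(d$sim$X[, 1], d$sim$X[, 1])     # perfectly collinear markers
  res <- mfqls_test(Tm, d$phi, X, psi = estimate_psi(X))
  expect_lt(res$df, 4L)
  expect_true(is.finite(res$statistic))
  expect_gte(res$statistic, 0)
})

test_that("missing-genotype path reduces exactly to the complete path and
           matches the completed-genotype oracle", {
  set.seed(307)
  d <- make_toy_data(n_fam = 1, seed = 307)
  fits <- fit_null_model(d$sim$Y, d$Z, d$phi)
  Tm <- blup_offset(d$sim$Y, d$Z, d$phi, fits)
  X <- d$sim$X
  psi <- estimate_psi(X)
  full <- mfqls_test(Tm, d$phi, X, psi = psi)
  red <- mfqls_test_missing(Tm, d$phi, X, seq_len(d$N), psi = psi)
  expect_equal(red$statistic, full$statistic, tolerance = 1e-10)
  expect_equal(red$S, full$S, tolerance = 1e-10)

  # one missing individual with nonzero phenotype: oracle completes X by
  # the conditional expectation and applies the plain V = I score
  obs <- setdiff(seq_len(d$N), 4L)
  Xo <- X[obs, , drop = FALSE]
  psi_o <- estimate_psi(Xo)
  res <- mfqls_test_missing(Tm, d$phi, Xo, obs, psi = psi_o)
  phi_OO <- d$phi[obs, obs]
  imp <- conditional_expect_missing(Xo, phi_OO, d$phi[4L, obs,
                                                      drop = FALSE])
  Xstar <- X
  Xstar[4L, ] <- imp
  Xstar <- Xstar[c(obs, 4L), ]
  Tstar <- Tm[c(obs, 4L), ]
  blue <- blue_allele_freq(Xo, phi_OO)
  Sor <- as.vector(crossprod(Tstar,
                             sweep(Xstar, 2, blue$mean_geno, `-`)))
  expect_equal(res$S, Sor, tolerance = 1e-8)
  expect_true(is.finite(res$statistic))
})

test_that("zero-T rows for the unobserved set match dropping them while
           keeping the kinship structure", {
  set.seed(308)
  d <- make_toy_data(n_fam = 1, seed = 308)
  Tm <- matrix(rnorm(d$N * 2), d$N)
  X <- d$sim$X
  obs <- 1:8
  Tz <- Tm
  Tz[9:10, ] <- 0
  psi <- estimate_psi(X[obs, , drop = FALSE])
  a <- mfqls_test_missing(Tz, d$phi, X[obs, ], obs, psi = psi)
  # dropping the zero-T rows entirely but keeping the same Phi^OO
  b <- mfqls_test(Tz[obs, ], d$phi[obs, obs], X[obs, ], psi = psi)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
})

test_that("variant_test dispatches the three configurations coherently", {
  set.seed(309)
  cfg <- sim_config(n_families = 40, Q = 2, dichotomize = TRUE)
  sim <- simulate_dataset(cfg)
  phi <- kinship_from_pedigree(sim$ped)
  Z <- matrix(1, nrow(phi))
  r_mf <- variant_test("MFQLS", sim$Yd, Z, phi, sim$X)
  r_mq <- variant_test("MMQLS", sim$Yd, Z, phi, sim$X,
                       prevalence = cfg$prevalence)
  r_ma <- variant_test("MMASTOR", sim$Yd, Z, phi, sim$X)
  for (r in list(r_mf, r_mq, r_ma)) {
    expect_true(is.finite(r$statistic))
    expect_identical(r$df, 4L)
    expect_gt(r$p_value, 0)
  }
  expect_identical(r_ma$note, "extension")
  expect_error(variant_test("MMQLS", sim$Yd, Z, phi, sim$X),
               "prevalence")
})

test_that("MMASTOR with sigma2_B = 0 equals MFQLS (scalar V factors
           cancel)", {
  set.seed(310)
  N <- 30
  phi <- kinship_from_pedigree(canonical_pedigree(3))
  Y <- matrix(rnorm(N * 2), N)           # no polygenic signal
  X <- matrix(rbinom(N * 2, 2, 0.3), N)
  Z <- matrix(1, N)
  fits <- fit_null_model(Y, Z, phi)
  # force the boundary fit to make the identity exact
  for (q in 1:2) {
    tot <- fits[[q]]$sigma2_B + fits[[q]]$sigma2_E
    fits[[q]]$sigma2_B <- 0
    fits[[q]]$sigma2_E <- tot
    fits[[q]]$h2 <- 0
  }
  a <- variant_test("MFQLS", Y, Z, phi, X, fits = fits)
  b <- variant_test("MMASTOR", Y, Z, phi, X, fits = fits)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
})
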