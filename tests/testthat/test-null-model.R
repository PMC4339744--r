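test_that("profile REML matches a dense grid-search oracle on a toy
           pedigree", {
  set.seed(101)
  ped <- pedigree("f", c("a", "b", "c", "d", "e", "g"),
                  father = c(NA, NA, "a", "a", NA, "c"),
                  mother = c(NA, NA, "b", "b", NA, "e"))
  phi <- kinship_from_pedigree(ped)
  Z <- cbind(1, rnorm(6))
  y <- rnorm(6) + c(0.5, -0.2, 0.8, 0.3, 0, 1)
  fit <- fit_null_reml(y, Z, phi)
  h_grid <- seq(0, 1 - 1e-6, length.out = 200)
  neg2 <- vapply(h_grid, oracle_reml_neg2, numeric(1), y = y, Z = Z,
                 phi = phi)
  # returned optimum at least as good as every grid point
  expect_lte(oracle_reml_neg2(fit$h2, y, Z, phi), min(neg2) + 1e-6)
  # and the variance components are consistent with h2
  expect_equal(fit$sigma2_B / (fit$sigma2_B + fit$sigma2_E), fit$h2,
               tolerance = 1e-8)
})

test_that("phi = I collapses to the boundary OLS solution", {
  set.seed(102)
  y <- rnorm(30, mean = 2)
  Z <- matrix(1, 30)
  fit <- fit_null_reml(y, Z, diag(30))
  expect_equal(fit$h2, 0)
  expect_equal(fit$sigma2_E, var(y), tolerance = 1e-10)
  expect_equal(fit$alpha, mean(y), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("REML degenerate inputs error cleanly", {
  phi <- kinship_from_pedigree(canonical_pedigree(1))
  expect_error(fit_null_reml(rep(1, 10), matrix(1, 10), phi), "constant")
  expect_error(fit_null_reml(c(1, 2, rep(NA, 8)), matrix(1, 10), phi),
               "non-missing")
})

test_that("REML recovers (1, 1) variance components on simulated
           families", {
  set.seed(103)
  n_fam <- 120                      # smaller than the acceptance run
  cfg <- sim_config(n_families = n_fam, Q = 2, rho = 0.2)
  sim <- simulate_dataset(cfg)
  phi <- kinship_from_pedigree(sim$ped)
  fit <- fit_null_reml(sim$Y[, 1], matrix(1, nrow(phi)), phi)
  expect_lt(abs(fit$sigma2_B - 1), 0.25)
  expect_lt(abs(fit$sigma2_E - 1), 0.25)
})

test_that("REML is invariant to adding a constant when Z has an
           intercept", {
  set.seed(104)
  d <- make_toy_data(n_fam = 4, seed = 104)
  y <- d$sim$Y[, 1]
  f1 <- fit_null_reml(y, d$Z, d$phi)
  f2 <- fit_null_reml(y + 100, d$Z, d$phi)
  expect_equal(f1$sigma2_B, f2$sigma2_B, tolerance = 1e-6)
  expect_equal(f1$sigma2_E, f2$sigma2_E, tolerance = 1e-6)
  expect_equal(f2$alpha[1] - f1$alpha[1], 100, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("BLUP offset equals the printed projector evaluated term by
           term", {
  set.seed(105)
  ped <- pedigree("f", c("a", "b", "c", "d", "e", "g"),
                  father = c(NA, NA, "a", "a", NA, "c"),
                  mother = c(NA, NA, "b", "b", NA, "e"))
  phi <- kinship_from_pedigree(ped)
  Z <- cbind(1, rnorm(6))
  Y <- matrix(rnorm(12), 6)
  # fixed, well-conditioned variance components (the printed projector
  # holds for any (sigma2_B, sigma2_E), not only the REML optimum)
  fits <- lapply(1:2, function(q) {
    H <- 0.8 * phi + 1.2 * diag(6)
    Hi <- solve(H)
    alpha <- solve(t(Z) %*% Hi %*% Z, t(Z) %*% Hi %*% Y[, q])
    structure(list(sigma2_B = 0.8, sigma2_E = 1.2, h2 = 0.4,
                   alpha = drop(alpha)), class = "null_fit")
  })
  Tm <- blup_offset(Y, Z, phi, fits)
  for (q in 1:2) {
    H <- fits[[q]]$sigma2_B * phi + fits[[q]]$sigma2_E * diag(6)
    Hi <- solve(H)
    P <- Hi - Hi %*% Z %*% solve(t(Z) %*% Hi %*% Z) %*% t(Z) %*% Hi
    proj <- diag(6) - Z %*% solve(t(Z) %*% Hi %*% Z) %*% t(Z) %*% Hi -
      fits[[q]]$sigma2_B * phi %*% P
    expect_equal(Tm[, q], drop(proj %*% Y[, q]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # T = sigma2_E H^-1 r with Z' H^-1 r = 0, so the adjusted
    # phenotypes are plainly orthogonal to the covariates
    expect_lt(max(abs(t(Z) %*% Tm[, q])), 1e-8)
    r <- Y[, q] - Z %*% fits[[q]]$alpha
    expect_equal(Tm[, q], fits[[q]]$sigma2_E * drop(Hi %*% r),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("with sigma2_B = 0 and intercept-only Z the offset is GLS mean
           centering", {
  set.seed(106)
  phi <- random_pd(8)
  Y <- matrix(rnorm(8))
  fits <- list(structure(list(sigma2_B = 0, sigma2_E = 1, h2 = 0,
                              alpha = mean(Y)), class = "null_fit"))
  Tm <- blup_offset(Y, matrix(1, 8), phi, fits)
  expect_equal(drop(Tm), drop(Y - mean(Y)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("BLUP offset zeroes missing phenotypes and is permutation
           equivariant", {
  set.seed(107)
  d <- make_toy_data(n_fam = 3, seed = 107)
  Y <- d$sim$Y
  Y[c(3, 17), 1] <- NA
  fits <- fit_null_model(Y, d$Z, d$phi)
  Tm <- blup_offset(Y, d$Z, d$phi, fits)
  expect_identical(Tm[c(3, 17), 1], c(0, 0))
  # permutation equivariance
  per <- sample(d$N)
  fits_p <- fit_null_model(Y[per, , drop = FALSE], d$Z,
                           d$phi[per, per])
  Tp <- blup_offset(Y[per, , drop = FALSE], d$Z, d$phi[per, per],
                    fits_p)
  expect_equal(unname(Tp), unname(Tm[per, ]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("prevalence offset subtracts K and centers exactly at the
           affected fraction", {
  Y <- cbind(c(1, 0, 0, NA), c(0, 1, 1, 0))
  Tm <- prevalence_offset(Y, c(0.1, 0.5))
  expect_equal(Tm[1, 1], 0.9)
  expect_equal(Tm[2, 1], -0.1)
  expect_equal(Tm[4, 1], 0)               # missing zeroed
  expect_equal(sum(Tm[, 2]), 0)           # affected fraction == K
  expect_error(prevalence_offset(cbind(c(0, 2)), 0.1), "dichotomous")
  expect_error(prevalence_offset(Y, 1.2), "\\(0, 1\\)")
})

test_that("zero_missing_phenotypes masks exactly the requested cells", {
  T0 <- matrix(rnorm(12), 4)
  mask <- matrix(FALSE, 4, 3)
  expect_identical(zero_missing_phenotypes(T0, mask), T0)
  mask[2, 3] <- TRUE
  T1 <- zero_missing_phenotypes(T0, mask)
  expect_identical(T1[2, 3], 0)
  expect_identical(T1[-2, ], T0[-2, ])
  mask[4, ] <- TRUE
  expect_identical(zero_missing_phenotypes(T0, mask)[4, ], rep(0, 3))
})
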