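test_that("haplotype frequencies follow the two-locus table with
           Lewontin scaling", {
  h0 <- haplotype_freqs(0.3, 0.2, 0)
  expect_equal(unname(h0["AB"]), 0.3 * 0.2)        # linkage equilibrium
  h <- haplotype_freqs(0.2, 0.2, 0.5)
  expect_equal(attr(h, "d"), 0.08)
  expect_equal(unname(h), c(0.12, 0.08, 0.08, 0.72), ignore_attr = TRUE)
  # conservation for arbitrary valid inputs
  set.seed(401)
  for (k in 1:20) {
    hh <- haplotype_freqs(runif(1, .05, .95), runif(1, .05, .95),
                          runif(1))
    expect_equal(sum(hh), 1, tolerance = 1e-12)
    expect_true(all(hh >= 0))
  }
  expect_error(haplotype_freqs(0, 0.2, 0.5), "\\(0, 1\\)")
  expect_error(haplotype_freqs(0.2, 0.2, 1.5), "\\[0, 1\\]")
})

test_that("Mendelian transmission: certainty, closure and founder HWE", {
  ped <- canonical_pedigree(1)
  # both parents ab/ab -> children all (0, 0)
  probs <- c(AB = 0, Ab = 0, aB = 0, ab = 1)
  g <- simulate_family_genotypes(ped, probs)
  expect_true(all(g$X == 0))
  # transmission closure over replicates
  set.seed(402)
  probs <- haplotype_freqs(0.3, 0.2, 0.5)
  ok <- TRUE
  for (r in 1:200) {
    g <- simulate_family_genotypes(ped, probs)
    fa <- match(ped$father, ped$iid)
    mo <- match(ped$mother, ped$iid)
    for (i in which(!ped$founder)) {
      ok <- ok && g$H1[i] %in% c(g$H1[fa[i]], g$H2[fa[i]]) &&
        g$H2[i] %in% c(g$H1[mo[i]], g$H2[mo[i]])
    }
  }
  expect_true(ok)
  # founder genotype frequencies at locus A match HWE(p_A)
  set.seed(403)
  p_A <- 0.3
  probs <- haplotype_freqs(p_A, 0.2, 0)
  fnd <- pedigree(sprintf("f%d", 1:50000), sprintf("i%d", 1:50000))
  gf <- simulate_family_genotypes(fnd, probs)
  counts <- tabulate(gf$X[, 1] + 1L, 3L) / 50000
  hwe <- c((1 - p_A)^2, 2 * p_A * (1 - p_A), p_A^2)
  for (k in 1:3)
    expect_lt(abs(counts[k] - hwe[k]),
              3 * sqrt(hwe[k] * (1 - hwe[k]) / 50000))
})

test_that("polygenic effects have the additive-model moments", {
  ped <- canonical_pedigree(1)
  expect_true(all(simulate_polygenic(ped, matrix(0, 2, 2)) == 0))
  set.seed(404)
  Sigma_B <- default_Sigma_B(2, 0.2)
  n_rep <- 20000
  big <- canonical_pedigree(n_rep / 10)
  B <- simulate_polygenic(big, Sigma_B)
  child_idx <- seq(7, nrow(big), by = 10)     # o11 of each family
  par_idx <- seq(3, nrow(big), by = 10)       # p1 (father of o11)
  # marginal variance of offspring equals Sigma_B
  v <- var(B[child_idx, ])
  expect_lt(abs(v[1, 1] - Sigma_B[1, 1]), 0.08)
  expect_lt(abs(v[2, 2] - Sigma_B[2, 2]), 0.16)
  # parent-offspring covariance is 0.5 Sigma_B
  cv <- cov(B[par_idx, 1], B[child_idx, 1])
  expect_lt(abs(cv - 0.5 * Sigma_B[1, 1]), 0.08)
})

test_that("quantitative assembly has the stated mean/variance structure", {
  ped <- canonical_pedigree(1)
  X <- matrix(0L, 10, 2)
  Y <- assemble_quantitative(X, matrix(0, 2, 2), c(3, -1),
                             matrix(0, 10, 2), c(0, 0))
  expect_equal(Y, cbind(rep(3, 10), rep(-1, 10)), ignore_attr = TRUE)
  # moment check at large N, founders only
  set.seed(405)
  n <- 40000
  fnd <- pedigree(sprintf("f%d", 1:n), sprintf("i%d", 1:n))
  probs <- haplotype_freqs(0.3, 0.2, 0)
  g <- simulate_family_genotypes(fnd, probs)
  Sigma_B <- default_Sigma_B(2, 0.2)
  B <- simulate_polygenic(fnd, Sigma_B)
  beta <- matrix(c(0.3, 0, 0, 0), 2)
  Y <- assemble_quantitative(g$X, beta, c(0, 0), B, c(1, 2))
  v_th <- Sigma_B[1, 1] + 1 + 0.3^2 * 2 * 0.3 * 0.7
  expect_lt(abs(var(Y[, 1]) - v_th), 0.06)
  # founder cross-phenotype correlation matches the closed form
  r_th <- Sigma_B[1, 2] / sqrt((Sigma_B[1, 1] + 1) * (Sigma_B[2, 2] + 2))
  expect_lt(abs(cor(Y[, 1], Y[, 2]) - r_th), 0.02)
})

test_that("liability thresholding preserves prevalence and is monotone", {
  set.seed(406)
  n <- 100000
  Y <- cbind(rnorm(n, 0, sqrt(2)))
  D <- dichotomize_liability(Y, 0.1, 0, sqrt(2))
  expect_lt(abs(mean(D) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  D5 <- dichotomize_liability(Y, 0.5, 0, sqrt(2))
  expect_lt(abs(mean(D5) - 0.5), 3 * sqrt(0.25 / n))
  thr <- vapply(c(0.1, 0.2, 0.3), function(k)
    attr(dichotomize_liability(Y, k, 0, sqrt(2)), "threshold"),
    numeric(1))
  expect_true(all(diff(thr) < 0))            # monotone decreasing in K
  expect_error(dichotomize_liability(Y, 1.1, 0, 1), "\\(0, 1\\)")
})

test_that("Balding-Nichols parameterization and moments", {
  # printed parameterization: p = 0.3, Fst = 0.05 -> Beta(5.7, 13.3)
  r <- (1 - 0.05) / 0.05
  expect_equal(0.3 * r, 5.7)
  expect_equal(0.7 * r, 13.3)
  set.seed(407)
  draws <- replicate(20000, balding_nichols_freqs(0.3, 0.05)[1])
  expect_lt(abs(mean(draws) - 0.3), 3 * sd(draws) / sqrt(20000))
  # theoretical variance Fst * p * (1-p)
  expect_lt(abs(var(draws) - 0.05 * 0.3 * 0.7), 0.002)
  # small Fst concentrates at the ancestral frequency
  tight <- replicate(2000, balding_nichols_freqs(0.3, 0.001)[1])
  expect_lt(sd(tight), 0.02)
  expect_error(balding_nichols_freqs(0.3, 0), "Fst")
})

test_that("structured dataset: founder labels, ancestry propagation and
           realized marker Fst", {
  set.seed(408)
  cfg <- sim_config(n_families = 200, Q = 2, Fst = 0.05,
                    n_null_markers = 2000, maf_law = c(0.1, 0.5))
  sim <- simulate_dataset(cfg)
  anc <- sim$ancestry
  fnd <- sim$ped$founder
  expect_true(all(anc[fnd] %in% c(0, 1)))
  expect_lt(abs(mean(anc[fnd]) - 0.5), 3 * sqrt(0.25 / sum(fnd)))
  # children ancestry is the parental mean
  expect_true(all(anc[!fnd] %in% c(0, 0.25, 0.5, 0.75, 1)))
  # realized Hudson-type Fst over the panel, founders split by label
  X <- sim$null_panel$X[fnd, ]
  lab <- anc[fnd]
  p1 <- colMeans(X[lab == 0, ]) / 2
  p2 <- colMeans(X[lab == 1, ]) / 2
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- mean(num - (p1 * (1 - p1) / (sum(lab == 0) * 2) +
                           p2 * (1 - p2) / (sum(lab == 1) * 2))) /
    mean(den)
  expect_lt(abs(fst_hat - 0.05), 0.012)
  expect_error(sim_config(Fst = 0), "Fst")
})

test_that("generators are exactly reproducible from the seed", {
  cfg <- sim_config(n_families = 5, Q = 2, Dprime = 0.5)
  set.seed(409)
  a <- simulate_dataset(cfg)
  set.seed(409)
  b <- simulate_dataset(cfg)
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)
})
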