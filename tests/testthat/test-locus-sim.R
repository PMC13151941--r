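test_that("make_ld produces block AR(1) structure with closed-form entries", {
  spec <- locus_spec(6, block_sizes = c(3, 3), rho = c(0.9, 0.5))
  R <- make_ld(spec)
  expect_equal(unname(R[1, 3]), 0.81)
  expect_equal(unname(R[4, 5]), 0.5)
  expect_equal(unname(R[1, 4]), 0)           # zero across blocks
  expect_true(isSymmetric(unclass(R)))
  expect_equal(unname(diag(R)), rep(1, 6))

  # rho = 0 gives the identity
  R0 <- make_ld(locus_spec(5, rho = 0))
  expect_equal(unname(unclass(R0)), diag(5))

  expect_error(locus_spec(4, rho = 1), "rho")
  expect_error(locus_spec(4, rho = -0.1), "rho")
})

test_that("AR(1) LD matrices are positive semi-definite (eigen oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    sizes <- c(80, 70, 50)
    spec <- locus_spec(200, block_sizes = sizes, rho = runif(3, 0, 0.99),
                      seed = seed)
    R <- make_ld(spec)
    expect_gte(min(eigen(unclass(R), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("draw_zscores follows the RSS mean and covariance", {
  spec <- locus_spec(5, rho = 0.8)
  R <- make_ld(spec)
  # null: element-wise mean within 3 SE of 0, empirical covariance near R
  Z <- sapply(1:5000, function(i) draw_zscores(R, rep(0, 5), 1000, seed = i))
  se <- 1 / sqrt(5000)
  expect_true(all(abs(rowMeans(Z)) < 3 * se * 1.5))
  expect_lt(max(abs(cov(t(Z)) - unclass(R))), 0.08)

  # planted single causal: E[z_j] = sqrt(n) * b_j at the causal (R_jj = 1)
  b <- c(0, 0, 0.05, 0, 0)
  zm <- rowMeans(sapply(1:2000, function(i) draw_zscores(R, b, 50000, seed = i)))
  expect_equal(unname(zm[3]), sqrt(50000) * 0.05, tolerance = 0.02)
})

test_that("identity-LD null z-scores are iid standard normal (KS oracle)", {
  R <- make_ld(locus_spec(10, rho = 0))
  z <- as.vector(sapply(1:1000, function(i) draw_zscores(R, rep(0, 10), 100, seed = i)))
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("zscore and genotype draws are reproducible and reject bad input", {
  R <- make_ld(locus_spec(8, rho = 0.7))
  expect_identical(draw_zscores(R, rep(0, 8), 100, seed = 3),
                   draw_zscores(R, rep(0, 8), 100, seed = 3))
  expect_identical(draw_genotypes(R, 0.3, 50, seed = 3),
                   draw_genotypes(R, 0.3, 50, seed = 3))
  bad <- unclass(R); bad[1, 2] <- bad[2, 1] <- 2   # not PSD
  expect_error(draw_zscores(bad, rep(0, 8), 100, seed = 1),
               "positive semi-definite")
  expect_error(draw_genotypes(R, 0.6, 10, seed = 1), "mafs")
})

test_that("genotype dosages match target frequency and independence", {
  R <- make_ld(locus_spec(5, rho = 0))
  X <- draw_genotypes(R, 0.5, 20000, seed = 11)
  expect_true(all(abs(colMeans(X) - 1) < 0.02))   # 2 * maf = 1
  cors <- cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)
})

test_that("genotype-level marginal z-scores track one RSS draw", {
  spec <- quick_locus(m = 40, rho = 0.9, causal = c(10, 30), b = 0.15,
                      n = 50000, seed = 21)
  sim <- simulate_locus(spec, genotypes = TRUE, n_genotype_samples = 50000)
  z_geno <- marginal_z(scale(sim$genotypes), sim$phenotypes$gwas)
  # RSS draw on the realized dosage LD at matched n: the two routes agree
  # up to their independent noise
  z_rss <- draw_zscores(cor(sim$genotypes), sim$truth$gwas$b, 50000,
                        seed = 99)
  expect_gt(cor(z_geno, z_rss), 0.95)
  # and the analytic mean under the dosage LD explains the genotype scan
  mu <- sqrt(50000) * drop(cor(sim$genotypes) %*% sim$truth$gwas$b)
  expect_gt(cor(z_geno, mu), 0.95)
})

test_that("simulated locus round-trips its planted truth", {
  spec <- quick_locus(m = 30, causal = c(5, 25), seed = 4)
  sim <- simulate_locus(spec)
  expect_equal(sim$truth$gwas$index, c(5L, 25L))
  expect_equal(sim$truth$gwas$b[c(5, 25)], c(0.05, 0.05))
  expect_equal(length(sim$zscores$gwas), nrow(sim$ld))
  sim2 <- simulate_locus(spec)
  expect_identical(sim$zscores, sim2$zscores)
})
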