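make_twas_fixture <- function(seed = 1, m = 25, rho = 0.8) {
  spec <- quick_locus(m = m, rho = rho, seed = seed)
  R <- make_ld(spec)
  z <- draw_zscores(R, rep(0, m), 1000, seed = seed) + 1
  list(R = R,
       st = summary_stats(rownames(R), "chr9", seq_len(m), z = z, n = 1000))
}

test_that("weight training schemes behave at their closed-form cases", {
  fx <- make_twas_fixture()
  st3 <- summary_stats(c("a", "b", "c"), "chr9", 1:3, z = c(1, 5, 2), n = 100)
  R3 <- diag(3); dimnames(R3) <- list(st3$id, st3$id)
  expect_equal(build_weights(st3, R3, "top1")$w, c(0, 1, 0))
  expect_warning(
    w0 <- build_weights(summary_stats(c("a", "b"), "chr9", 1:2,
                                      z = c(0, 0), n = 10),
                        diag(2), "top1"),
    "first variant")
  expect_equal(w0$w, c(1, 0))
  # ridge with huge lambda is proportional to z
  wr <- build_weights(fx$st, fx$R, "ridge", lambda = 1e8)
  expect_gt(abs(cor(wr$w, fx$st$z)), 1 - 1e-6)
  # ridge solves the linear system (direct solve oracle), up to rescaling
  w1 <- build_weights(fx$st, fx$R, "ridge", lambda = 0.1)
  oracle <- solve(unclass(fx$R) + diag(0.1, 25), fx$st$z)
  expect_gt(abs(cor(w1$w, oracle)), 1 - 1e-10)
})

test_that("TWAS statistic reduces correctly and bounds its rho vector", {
  fx <- make_twas_fixture(seed = 4)
  w_ind <- structure(list(gene = "g", ids = fx$st$id,
                          w = as.numeric(fx$st$id == fx$st$id[7]),
                          method = "top1"), class = "expression_weights")
  tw <- twas_z(w_ind, fx$st, fx$R)
  expect_equal(tw$z, fx$st$z[7])             # single-variant model
  expect_true(all(abs(tw$rho) <= 1 + 1e-8))
  # orthogonal weights under identity LD give Z = 0
  stI <- summary_stats(c("a", "b"), "chr9", 1:2, z = c(2, 2), n = 100)
  wI <- structure(list(gene = "g", ids = stI$id, w = c(1, -1),
                       method = "topk"), class = "expression_weights")
  expect_equal(twas_z(wI, stI, diag(2))$z, 0)
  w_bad <- structure(list(gene = "g", ids = stI$id, w = c(0, 0),
                          method = "topk"), class = "expression_weights")
  expect_error(twas_z(w_bad, stI, diag(2)), "degenerate")
})

test_that("conditioning on genes reduces to identity and self-conditioning", {
  fx <- make_twas_fixture(seed = 9)
  expect_equal(condition_gwas_on_genes(fx$st, fx$R, list())$z_cond, fx$st$z)
  # gene = indicator on variant 7: conditioning zeroes that variant
  w_ind <- structure(list(gene = "g7", ids = fx$st$id,
                          w = as.numeric(fx$st$id == fx$st$id[7]),
                          method = "top1"), class = "expression_weights")
  cond <- condition_gwas_on_genes(fx$st, fx$R, list(w_ind))
  j <- match(fx$st$id[7], cond$id)
  if (!is.na(j)) expect_lt(abs(cond$z_cond[j]), 1e-3)
  # SNPs uncorrelated with the gene are unchanged: block-diagonal case
  spec2 <- locus_spec(20, block_sizes = c(10, 10), rho = 0.9, seed = 2)
  R2 <- make_ld(spec2)
  z2 <- draw_zscores(R2, rep(0, 20), 1000, seed = 3)
  st2 <- summary_stats(rownames(R2), "chr9", 1:20, z = z2, n = 1000)
  wB <- structure(list(gene = "gB", ids = st2$id,
                       w = c(rep(0, 10), rep(0.3, 10)), method = "topk"),
                  class = "expression_weights")
  c2 <- condition_gwas_on_genes(st2, R2, list(wB))
  expect_equal(c2$z_cond[match(st2$id[1:10], c2$id)], st2$z[1:10],
               tolerance = 1e-8)
})

test_that("joint TWAS matches the GLS oracle and degenerates correctly", {
  fx <- make_twas_fixture(seed = 12, m = 30)
  wA <- build_weights(fx$st, fx$R, "topk", gene = "A", k = 3)
  stB <- fx$st; stB$z <- rev(stB$z)
  wB <- build_weights(stB, fx$R, "ridge", gene = "B", lambda = 0.5)
  jt <- joint_twas(fx$st, fx$R, list(wA, wB))
  # GLS oracle by direct 2x2 inversion
  aug <- locusdissect:::augment_genes(fx$st, fx$R, list(wA, wB))
  G <- aug$R[aug$gene_ids, aug$gene_ids]
  zg <- aug$stats$z[match(aug$gene_ids, aug$stats$id)]
  Ginv <- solve(G)
  expect_equal(jt$z_joint, unname(drop(Ginv %*% zg) / sqrt(diag(Ginv))),
               tolerance = 1e-10)
  # uncorrelated genes keep their marginal statistics
  stI <- summary_stats(c("a", "b"), "chr9", 1:2, z = c(3, -2), n = 100)
  wa <- structure(list(gene = "ga", ids = stI$id, w = c(1, 0),
                       method = "top1"), class = "expression_weights")
  wb <- structure(list(gene = "gb", ids = stI$id, w = c(0, 1),
                       method = "top1"), class = "expression_weights")
  jI <- joint_twas(stI, diag(2), list(wa, wb))
  expect_equal(jI$z_joint, jI$z_marginal)
  # identical weight vectors are collinear
  expect_error(joint_twas(stI, diag(2), list(wa, wa)), "collinear")
})

test_that("null TWAS p-values are calibrated", {
  m <- 30
  spec <- quick_locus(m = m, rho = 0.9, seed = 33)
  R <- make_ld(spec)
  # eQTL scan with a genuine signal at variant 15 used to train the weights
  ez <- draw_zscores(R, rep(0, m), 3000, seed = 99) + 5 * unclass(R)[, 15]
  est <- summary_stats(rownames(R), "chr9", seq_len(m), z = ez, n = 3000)
  w <- build_weights(est, R, "ridge", lambda = 0.1)
  rej <- 0
  nsim <- 2000
  for (s in seq_len(nsim)) {
    z0 <- draw_zscores(R, rep(0, m), 5000, seed = 1e6 + s)
    st0 <- summary_stats(rownames(R), "chr9", seq_len(m), z = z0, n = 5000)
    if (twas_z(w, st0, R)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.035)
  expect_lt(rej / nsim, 0.065)
})
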