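mut <- function(gene, pc, driver = TRUE) {
  data.frame(gene = gene, protein_change = pc,
             driver_flag = rep_len(driver, length(gene)),
             stringsAsFactors = FALSE)
}

test_that("protein changes parse into residue, position, alternate", {
  p <- parse_protein_change(c("V600E", "Q61*", "G12fs", "p.K601E", "?"))
  expect_equal(p$pos, c(600L, 61L, 12L, 601L, NA))
  expect_equal(p$ref[1], "V")
  expect_equal(p$alt[1], "E")
})

test_that("hotspot model matches by codon position regardless of alternate", {
  expect_equal(classify_sample(mut("BRAF", "V600E"), model_spec(1)), "mutant")
  expect_equal(classify_sample(mut("BRAF", "V600K"), model_spec(1)), "mutant")
  expect_equal(classify_sample(mut("NRAS", "Q61R"), model_spec(1)), "mutant")
  expect_equal(classify_sample(mut("NRAS", "G13D"), model_spec(1)), "mutant")
  # non-hotspot driver: WT under Model 1, mutant under Model 2
  expect_equal(classify_sample(mut("BRAF", "D594N"), model_spec(1)), "WT")
  expect_equal(classify_sample(mut("BRAF", "D594N"), model_spec(2)), "mutant")
  # gene-set growth across models
  expect_equal(classify_sample(mut("KRAS", "G12D"), model_spec(2)), "WT")
  expect_equal(classify_sample(mut("KRAS", "G12D"), model_spec(3)), "mutant")
  expect_equal(classify_sample(mut("NF1", "R1362*"), model_spec(3)), "WT")
  expect_equal(classify_sample(mut("NF1", "R1362*"), model_spec(4)), "mutant")
  expect_equal(classify_sample(mut("MAP2K1", "P124L"), model_spec(4)), "WT")
  expect_equal(classify_sample(mut("MAP2K1", "P124L"), model_spec(5)), "mutant")
  # passenger (non-driver) mutations never qualify beyond Model 1
  expect_equal(classify_sample(mut("BRAF", "A33T", driver = FALSE),
                               model_spec(2)), "WT")
  # no mutations at all
  expect_equal(classify_sample(mut(character(), character())[0, ],
                               model_spec(1)), "WT")
  expect_warning(
    expect_equal(classify_sample(mut("BRAF", "oddball"), model_spec(1)), "WT"),
    "unparseable")
})

test_that("unassessed genes restrict classification per config", {
  m <- mut("NF1", "R1362*")
  expect_equal(classify_sample(m, model_spec(4), assessed_genes = c("BRAF", "NRAS")),
               "WT")     # NF1 not sequenced: WT over assessed genes
  expect_true(is.na(classify_sample(mut("BRAF", "A33T", FALSE), model_spec(4),
                                    assessed_genes = c("BRAF", "NRAS"),
                                    unassessable = "na")))
})

test_that("model nesting holds over fuzzed driver-flagged tables", {
  set.seed(14)
  genes <- default_model5_genes()
  pcs <- c("V600E", "K601E", "Q61R", "G12V", "G13D", "D594N", "R100*", "L50F")
  models <- lapply(1:5, model_spec)
  violations <- 0
  for (i in 1:400) {
    nmut <- sample(0:4, 1)
    muts <- mut(sample(genes, nmut, TRUE), sample(pcs, nmut, TRUE))
    calls <- vapply(models, function(mo) classify_sample(muts, mo), "")
    state <- calls == "mutant"
    if (any(diff(state) < 0)) violations <- violations + 1
  }
  expect_equal(violations, 0)
})

test_that("expression association equals the pooled two-sample t without covariates", {
  co <- make_cohort(cohort_spec(300, delta = 0.8, seed = 6))
  res <- expr_association(co, model_spec(1), covariates = character(),
                          cohort_name = "sim")
  wt <- co$truth$wt
  tt <- stats::t.test(co$samples$expression[wt], co$samples$expression[!wt],
                      var.equal = TRUE)
  expect_equal(res$z, unname(tt$statistic), tolerance = 1e-10)
  expect_gt(res$beta, 0)                      # higher expression in WT
  expect_equal(res$n_wt + res$n_mut, 300)
})

test_that("expression association adjusts for covariates and errors on empty groups", {
  co <- make_cohort(cohort_spec(400, delta = 0.5,
                                covariate_effects = c(age = 1, sex = 0,
                                                      purity = -0.5),
                                seed = 16))
  res <- expr_association(co, model_spec(1), cohort_name = "sim")
  expect_true(all(c("age", "purity") %in% res$covariates))
  expect_equal(res$beta, 0.5, tolerance = 0.35)
  # a covariate missing for the whole cohort is dropped, not fatal
  co$samples$purity <- NA
  res2 <- expr_association(co, model_spec(1), cohort_name = "sim")
  expect_false("purity" %in% res2$covariates)
  # all-WT cohort cannot be compared
  co_wt <- make_cohort(cohort_spec(50, mutation_rates = data.frame(
    gene = "BRAF", protein_change = "V600E", driver = TRUE, rate = 0),
    seed = 1))
  expect_error(expr_association(co_wt, model_spec(1), cohort_name = "allwt"),
               "allwt")
})

test_that("null expression association is calibrated across seeds", {
  hits <- 0
  for (s in 1:150) {
    co <- make_cohort(cohort_spec(400, delta = 0, seed = 5000 + s))
    res <- expr_association(co, model_spec(1), covariates = character(),
                            cohort_name = "sim")
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 1)    # ~5% expected; binomial(150, .05) 99.9% band
  expect_lte(hits, 19)
})

test_that("median dichotomization uses the tie-to-low convention", {
  expect_equal(dichotomize(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(dichotomize(c(1, 2, 3)), c("low", "low", "high"))
  expect_warning(out <- dichotomize(c(2, 2, 2)), "equal")
  expect_equal(out, rep("low", 3))
  # odd-length distinct values: ceiling(n/2) low
  set.seed(9)
  v <- sample(1:99, 51)
  expect_equal(sum(dichotomize(v) == "low"), 26)
})

test_that("stage filtering drops excluded stages and keeps missing", {
  co <- make_cohort(cohort_spec(40, seed = 3))
  co$samples$stage <- rep(c("I", "II", "III", NA), 10)
  f <- filter_stage(co)
  expect_equal(nrow(f$samples), 30)
  expect_false(any(f$samples$stage %in% "I"))
  expect_equal(nrow(filter_stage(co, exclude = character())$samples), 40)
  co$samples$stage <- "I"
  expect_warning(filter_stage(co), "every sample")
})
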