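#' Specify a synthetic tumor cohort
#'
#' Parameters of the generative model used to test the tumor-cohort stages:
#' mutation prevalences per (gene, protein change, driver flag); an
#' expression shift `delta` added to samples that are wild-type under the
#' hotspot model (so `delta > 0` plants the "higher expression in WT"
#' signal); linear covariate effects; and an exponential survival model
#' whose log hazard ratio `log_hr_high_expr` applies to the
#' above-median-expression group, with independent exponential censoring.
#' All times are in days.
#'
#' @param n_samples cohort size.
#' @param mutation_rates data.frame `gene, protein_change, driver, rate`
#'   with per-sample prevalences in `[0, 1]`.
#' @param delta expression shift for hotspot-WT samples (expression units).
#' @param covariate_effects named numeric vector of linear effects for any
#'   of `age, sex, purity` (covariates are generated standardized).
#' @param baseline_hazard exponential event rate per day (> 0).
#' @param log_hr_high_expr log hazard ratio of the high-expression group.
#' @param censor_rate exponential censoring rate per day (0 = no censoring).
#' @param treatment_class `"non-immunotherapy"` or `"immunotherapy"`.
#' @param expr_sd residual sd of expression (default 1).
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_samples,
                        mutation_rates = data.frame(
                          gene = c("BRAF", "NRAS"),
                          protein_change = c("V600E", "Q61R"),
                          driver = TRUE,
                          rate = c(0.4, 0.2)),
                        delta = 0,
                        covariate_effects = c(age = 0, sex = 0, purity = 0),
                        baseline_hazard = 1 / 1000,
                        log_hr_high_expr = 0,
                        censor_rate = 1 / 2000,
                        treatment_class = "non-immunotherapy",
                        expr_sd = 1,
                        seed = 1L) {
  stopifnot(n_samples >= 1, baseline_hazard > 0, censor_rate >= 0,
            expr_sd > 0)
  if (any(mutation_rates$rate < 0 | mutation_rates$rate > 1)) {
    stop("mutation prevalences must lie in [0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 mutation_rates = mutation_rates, delta = delta,
                 covariate_effects = covariate_effects,
                 baseline_hazard = baseline_hazard,
                 log_hr_high_expr = log_hr_high_expr,
                 censor_rate = censor_rate,
                 treatment_class = treatment_class,
                 expr_sd = expr_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic tumor cohort
#'
#' Per sample: each mutation row of the spec is drawn independently at its
#' prevalence; expression is
#' `delta * 1[WT under the hotspot model] + gamma' covariates + noise`;
#' survival time is exponential with hazard
#' `h0 * exp(beta * 1[expression > cohort median])`, censored by an
#' independent exponential time (no censoring when `censor_rate = 0`).
#' Stage is sampled uniformly from I-IV.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort`: list with `samples` (data.frame `sample, expression,
#'   age, sex, purity, stage, survival_days, event, treatment_class`),
#'   `mutations` (MAF-like data.frame `sample, gene, protein_change,
#'   driver_flag`), and `truth` (the spec parameters plus the WT indicator).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  mr <- spec$mutation_rates
  with_seed(spec$seed, {
    mut_draws <- matrix(stats::runif(n * nrow(mr)), n, nrow(mr)) <
      matrix(mr$rate, n, nrow(mr), byrow = TRUE)
    age <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, 0.5)
    purity <- stats::rnorm(n)
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
    noise <- stats::rnorm(n, sd = spec$expr_sd)
    u_event <- stats::runif(n)
    u_cens <- stats::runif(n)
  })
  mutations <- do.call(rbind, lapply(seq_len(nrow(mr)), function(j) {
    who <- which(mut_draws[, j])
    if (!length(who)) return(NULL)
    data.frame(sample = ids[who], gene = mr$gene[j],
               protein_change = mr$protein_change[j],
               driver_flag = mr$driver[j], stringsAsFactors = FALSE)
  }))
  if (is.null(mutations)) {
    mutations <- data.frame(sample = character(), gene = character(),
                            protein_change = character(),
                            driver_flag = logical())
  }
  ce <- spec$covariate_effects
  covs <- cbind(age = age, sex = sex - 0.5, purity = purity)
  lin <- drop(covs[, names(ce), drop = FALSE] %*% ce)
  wt <- !vapply(ids, function(s) {
    muts <- mutations[mutations$sample == s, , drop = FALSE]
    any(is_hotspot(muts$gene, muts$protein_change))
  }, TRUE)
  expression <- spec$delta * wt + lin + noise
  high <- expression > stats::median(expression)
  hazard <- spec$baseline_hazard * exp(spec$log_hr_high_expr * high)
  t_event <- -log(u_event) / hazard
  t_cens <- if (spec$censor_rate > 0) -log(u_cens) / spec$censor_rate else Inf
  samples <- data.frame(
    sample = ids, expression = expression, age = age, sex = sex,
    purity = purity, stage = stage,
    survival_days = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    treatment_class = spec$treatment_class, stringsAsFactors = FALSE
  )
  structure(list(samples = samples, mutations = mutations,
                 truth = list(spec = spec, wt = stats::setNames(wt, ids),
                              high = stats::setNames(high, ids))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples, %d mutation records (%s)\n",
              nrow(x$samples), nrow(x$mutations),
              x$samples$treatment_class[1]))
  invisible(x)
}
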