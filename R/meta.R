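#' Sample-size-weighted z-score meta-analysis
#'
#' Combines per-cohort z-scores with weights proportional to the square
#' root of each cohort's effective sample size. With `n+` subjects in one
#' group and `n-` in the other, the effective sample size is
#' `n_eff = n+ n- / (n+ + n-)`; weights `w_i = sqrt(n_eff_i / sum_j
#' n_eff_j)` satisfy `sum w_i^2 = 1`, so `Z_meta = sum w_i z_i` is standard
#' normal under the global null and has optimal power under equal
#' standardized effects. Any constant factor in the effective-sample-size
#' convention cancels in the normalized weights.
#'
#' @param z per-cohort z-scores.
#' @param n_plus,n_minus per-cohort group sizes (e.g. mutant/WT for
#'   expression, high/low expression for survival); all >= 1.
#' @param cohorts optional cohort labels.
#' @return a `meta_result` list: `cohorts, z, n_eff, weights, z_meta, p`.
#' @export
meta_z <- function(z, n_plus, n_minus, cohorts = NULL) {
  k <- length(z)
  stopifnot(length(n_plus) == k, length(n_minus) == k, k >= 1,
            all(n_plus >= 1), all(n_minus >= 1))
  n_eff <- n_plus * n_minus / (n_plus + n_minus)
  w <- sqrt(n_eff / sum(n_eff))
  zm <- sum(w * z)
  structure(list(cohorts = if (is.null(cohorts)) paste0("cohort", seq_len(k))
                 else cohorts,
                 z = z, n_plus = n_plus, n_minus = n_minus, n_eff = n_eff,
                 weights = w, z_meta = zm,
                 p = 2 * stats::pnorm(-abs(zm))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d cohort(s): Z_meta = %.4f, p = %.3g\n",
              length(x$z), x$z_meta, x$p))
  invisible(x)
}

#' Run the cohort panel: per-cohort analysis plus meta-analysis
#'
#' For each cohort, samples are classified under the mutation model; then
#' either (expression) the covariate-adjusted association of expression
#' with WT status is fit, or (survival) stage-excluded samples are
#' dichotomized at the cohort-wide expression median and a Firth-penalized
#' Cox model is fit within the wild-type subgroup. Cohorts are
#' meta-analyzed within each treatment stratum with square-root
#' effective-sample-size weights (group sizes: mutant/WT for expression,
#' high/low expression among analyzed WT samples for survival).
#'
#' @param cohorts named list of `cohort` objects.
#' @param model a [model_spec()].
#' @param analysis `"expression"` or `"survival"`.
#' @param covariates covariates for the expression model, or a named list
#'   (per cohort) of covariate column names for the survival model.
#' @param exclude_stage stages excluded before survival analysis.
#' @param stratify_treatment meta-analyze per `treatment_class` (default
#'   `TRUE`).
#' @return list with `per_cohort` (data.frame) and `meta` (named list of
#'   `meta_result` per stratum).
#' @export
run_cohort_panel <- function(cohorts, model,
                             analysis = c("expression", "survival"),
                             covariates = c("age", "sex", "purity", "stage"),
                             exclude_stage = "I",
                             stratify_treatment = TRUE) {
  analysis <- match.arg(analysis)
  if (!length(cohorts)) stop("no cohorts supplied")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    strat <- co$samples$treatment_class[1]
    if (analysis == "expression") {
      res <- tryCatch(
        expr_association(co, model, covariates = covariates, cohort_name = nm),
        error = function(e) stop(sprintf("cohort '%s': %s", nm, conditionMessage(e))))
      rows[[nm]] <- data.frame(cohort = nm, stratum = strat, z = res$z,
                               estimate = res$beta, se = res$se, p = res$p,
                               n_plus = res$n_mut, n_minus = res$n_wt)
    } else {
      co_f <- filter_stage(co, exclude_stage)
      grp <- dichotomize(co_f$samples$expression)
      cls <- classify_cohort(co_f, model_spec(1))
      wt <- cls == "WT"
      res <- tryCatch(
        firth_cox(co_f$samples$survival_days[wt], co_f$samples$event[wt],
                  grp[wt],
                  covariates = surv_covariates(co_f$samples[wt, , drop = FALSE],
                                               covariates, nm)),
        error = function(e) stop(sprintf("cohort '%s': %s", nm, conditionMessage(e))))
      rows[[nm]] <- data.frame(cohort = nm, stratum = strat, z = res$z,
                               estimate = res$log_hr, se = res$se, p = res$p,
                               n_plus = sum(grp[wt] == "high"),
                               n_minus = sum(grp[wt] == "low"))
    }
  }
  per_cohort <- do.call(rbind, rows)
  rownames(per_cohort) <- NULL
  strata <- if (stratify_treatment) unique(per_cohort$stratum) else "all"
  meta <- list()
  for (s in strata) {
    sub <- if (stratify_treatment) per_cohort[per_cohort$stratum == s, ] else
      per_cohort
    if (!nrow(sub)) stop(sprintf("treatment stratum '%s' has no cohorts", s))
    meta[[s]] <- meta_z(sub$z, sub$n_plus, sub$n_minus, cohorts = sub$cohort)
  }
  list(per_cohort = per_cohort, meta = meta)
}

surv_covariates <- function(samples, covariates, cohort_name) {
  if (is.list(covariates) && !is.data.frame(covariates)) {
    covariates <- covariates[[cohort_name]]
  }
  covariates <- intersect(covariates, c("age", "sex", "purity"))
  if (!length(covariates)) return(NULL)
  M <- as.matrix(samples[, covariates, drop = FALSE])
  if (!nrow(M)) NULL else M
}
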