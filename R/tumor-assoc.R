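#' Covariate-adjusted expression association with mutation status
#'
#' Ordinary least squares of expression on a wild-type indicator plus the
#' available clinical covariates (age, sex, purity, stage — stage is
#' encoded ordinally I < II < III < IV). The reported coefficient is for
#' the WT term, so a positive `beta` means higher expression in wild-type
#' tumors. Covariates missing for the whole cohort are dropped; samples
#' missing an otherwise-available covariate are dropped.
#'
#' @param cohort a `cohort`.
#' @param model a [model_spec()].
#' @param covariates character vector among
#'   `c("age", "sex", "purity", "stage")`.
#' @param assessed_genes passed to classification.
#' @param cohort_name label attached to the result.
#' @return an `expr_assoc` list: `cohort, model, beta, se, z, p, n_wt,
#'   n_mut, covariates`.
#' @export
expr_association <- function(cohort, model,
                             covariates = c("age", "sex", "purity", "stage"),
                             assessed_genes = NULL, cohort_name = "cohort") {
  cls <- classify_cohort(cohort, model, assessed_genes)
  df <- cohort$samples
  df$wt <- as.numeric(cls == "WT")
  df <- df[!is.na(cls), , drop = FALSE]
  n_wt <- sum(df$wt == 1)
  n_mut <- sum(df$wt == 0)
  if (n_wt < 2 || n_mut < 2) {
    stop(sprintf("cohort '%s', model %d: need >= 2 samples per group (WT %d, mutant %d)",
                 cohort_name, model$id, n_wt, n_mut))
  }
  used <- character()
  for (cv in covariates) {
    col <- df[[cv]]
    if (is.null(col) || all(is.na(col))) next     # unavailable for the cohort
    used <- c(used, cv)
  }
  if ("stage" %in% used) {
    df$stage <- as.numeric(factor(df$stage, levels = c("I", "II", "III", "IV")))
  }
  form <- stats::reformulate(c("wt", used), response = "expression")
  keep <- stats::complete.cases(df[, c("expression", "wt", used), drop = FALSE])
  fit <- stats::lm(form, data = df[keep, , drop = FALSE])
  co <- summary(fit)$coefficients["wt", ]
  structure(list(cohort = cohort_name, model = model$id,
                 beta = unname(co[1]), se = unname(co[2]), z = unname(co[3]),
                 p = unname(co[4]), n_wt = n_wt, n_mut = n_mut,
                 covariates = used),
            class = "expr_assoc")
}

#' Dichotomize expression at the cohort-wide median
#'
#' Labels are computed over the full cohort (never a subgroup): values
#' strictly above the median are `"high"`, values at or below are `"low"`.
#' Ties at the median go to `"low"`, which splits any odd-length
#' distinct-valued cohort into ceiling(n/2) low and floor(n/2) high.
#'
#' @param values numeric expression values (length >= 2).
#' @return character vector of `"high"`/`"low"` labels.
#' @export
dichotomize <- function(values) {
  stopifnot(length(values) >= 2)
  med <- stats::median(values)
  if (all(values == values[1])) warning("all expression values equal; everything labeled low")
  ifelse(values > med, "high", "low")
}

#' Exclude tumors by stage
#'
#' Removes samples whose stage is in the excluded set (default stage I,
#' profiled almost exclusively in cohorts of early tumors with very high
#' survival); samples with missing stage are retained.
#'
#' @param cohort a `cohort`.
#' @param exclude stages to drop (default `"I"`).
#' @return the filtered cohort.
#' @export
filter_stage <- function(cohort, exclude = "I") {
  keep <- !(cohort$samples$stage %in% exclude)
  if (!any(keep)) warning("stage filter removed every sample")
  cohort$samples <- cohort$samples[keep, , drop = FALSE]
  cohort$mutations <- cohort$mutations[
    cohort$mutations$sample %in% cohort$samples$sample, , drop = FALSE]
  cohort
}
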