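#' Conditional association from summary statistics
#'
#' COJO-style conditioning on the standardized scale: for conditioning set
#' `C` with LD block `R_CC` and cross-correlations `R_jC`,
#' `z_cond_j = (z_j - R_jC (R_CC + lambda I)^-1 z_C) /
#'             sqrt(1 - R_jC (R_CC + lambda I)^-1 R_Cj)`.
#' Variants in the conditioning set are reported as absent; variants whose
#' conditional variance is non-positive after tolerance are flagged
#' collinear and excluded. An empty conditioning set returns the marginal
#' statistics unchanged.
#'
#' @param stats a [summary_stats()].
#' @param ld LD correlation matrix aligned to `stats`.
#' @param condition_ids ids of the variants to condition on (subset of
#'   `stats$id`).
#' @param lambda ridge added to `R_CC` (default 1e-8). If `R_CC` is singular
#'   at `lambda = 0`, the ridge is applied automatically with a warning.
#' @param collinear_tol tolerance on the conditional variance (default 1e-10).
#' @return data.frame with columns `id, z_cond, p_cond`; collinear variant
#'   ids are recorded in `attr(, "collinear")`.
#' @export
conditional_z <- function(stats, ld, condition_ids = character(),
                          lambda = 1e-8, collinear_tol = 1e-10) {
  R <- align_ld(stats, ld)
  if (!length(condition_ids)) {
    out <- data.frame(id = stats$id, z_cond = stats$z,
                      p_cond = 2 * stats::pnorm(-abs(stats$z)),
                      stringsAsFactors = FALSE)
    attr(out, "collinear") <- character()
    return(out)
  }
  ci <- match(condition_ids, stats$id)
  if (anyNA(ci)) {
    stop(sprintf("conditioning variants not in summary statistics: %s",
                 paste(condition_ids[is.na(ci)], collapse = ", ")))
  }
  rest <- setdiff(seq_len(nrow(stats)), ci)
  Rcc <- R[ci, ci, drop = FALSE] + diag(lambda, length(ci))
  solve_cc <- tryCatch(solve(Rcc), error = function(e) NULL)
  if (is.null(solve_cc)) {
    warning("conditioning block singular; increasing ridge")
    solve_cc <- solve(Rcc + diag(1e-6, length(ci)))
  }
  Rjc <- R[rest, ci, drop = FALSE]
  proj <- Rjc %*% solve_cc
  num <- stats$z[rest] - drop(proj %*% stats$z[ci])
  varc <- 1 - rowSums(proj * Rjc)
  ok <- varc > collinear_tol
  out <- data.frame(id = stats$id[rest][ok],
                    z_cond = num[ok] / sqrt(varc[ok]),
                    stringsAsFactors = FALSE)
  out$p_cond <- 2 * stats::pnorm(-abs(out$z_cond))
  attr(out, "collinear") <- stats$id[rest][!ok]
  out
}
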