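#' Retain credible sets by cumulative and per-variant PIP
#'
#' Post-hoc retention filter applied after fine-mapping: only credible sets
#' whose cumulative posterior inclusion probability exceeds `cum_pip_min`
#' are kept, and within surviving sets only variants whose individual PIP
#' exceeds `var_pip_min` are kept. Both thresholds are strict.
#'
#' @param result a `finemap_result`.
#' @param cum_pip_min cumulative-PIP threshold (default 0.85).
#' @param var_pip_min per-variant PIP threshold (default 0.005).
#' @return a `finemap_result` with the filtered credible sets; PIPs are
#'   untouched.
#' @export
retain_credible_sets <- function(result, cum_pip_min = 0.85,
                                 var_pip_min = 0.005) {
  stopifnot(inherits(result, "finemap_result"))
  kept <- list()
  for (cs in result$credible_sets) {
    if (!(cs$cum_pip > cum_pip_min)) next
    pip <- result$pip[match(cs$ids, result$ids)]
    ok <- pip > var_pip_min
    if (!any(ok)) next
    cs$ids <- cs$ids[ok]
    cs$alpha <- cs$alpha[ok]
    kept[[length(kept) + 1]] <- cs
  }
  result$credible_sets <- kept
  result
}

#' Select variants by log-likelihood ratio to the lead variant
#'
#' Under the normal approximation the log-likelihood of a marginal
#' association is proportional to `z^2 / 2`, so the log-likelihood ratio of
#' variant `i` relative to the lead is `LLR_i = (z_i^2 - z_lead^2) / 2`.
#' Variants with `LLR_i >= -log(ratio)` (default ratio 1000, i.e. within
#' 1:1000 of the lead) are retained. The lead itself always has `LLR = 0`
#' and is always retained.
#'
#' @param stats a [summary_stats()].
#' @param lead_id id of the lead variant (must be present).
#' @param ratio likelihood ratio cut (default 1000).
#' @return character vector of retained variant ids, in input order.
#' @export
llr_select <- function(stats, lead_id, ratio = 1000) {
  i <- match(lead_id, stats$id)
  if (is.na(i)) stop(sprintf("lead variant '%s' not found in summary statistics", lead_id))
  llr <- (stats$z^2 - stats$z[i]^2) / 2
  stats$id[llr >= -log(ratio)]
}

#' Supplement with LD proxies of the lead variant
#'
#' Variants absent from the GWAS (e.g. indels outside the imputation panel)
#' are brought in when their LD with the lead exceeds `r2 > threshold`
#' (strict) in a reference panel. Variants already present in the summary
#' statistics are excluded — they were assessed directly.
#'
#' @param lead_id lead variant id (for provenance; not otherwise used).
#' @param proxies data.frame with columns `id` and `r2` giving reference-panel
#'   LD to the lead.
#' @param stats_ids ids already present in the summary statistics.
#' @param threshold r-squared threshold (default 0.8, strict `>`).
#' @return character vector of proxy variant ids.
#' @export
ld_supplement <- function(lead_id, proxies, stats_ids, threshold = 0.8) {
  if (is.null(proxies) || !nrow(proxies)) return(character())
  keep <- proxies$r2 > threshold & !(proxies$id %in% stats_ids)
  proxies$id[keep]
}

#' Union of credible causal variants across sources
#'
#' The locus-level credible causal variant (CCV) set is the union of (i)
#' variants in retained credible sets from any number of Bayesian
#' fine-mapping engines, (ii) the likelihood-ratio selection relative to the
#' lead, and (iii) LD proxies of the lead absent from the GWAS. Provenance
#' is tracked per source, and the output is ordered deterministically by
#' position (when known) then id; proxies without positions sort last.
#'
#' @param results list of (retained) `finemap_result` objects.
#' @param llr_set variant ids from [llr_select()].
#' @param proxy_set variant ids from [ld_supplement()].
#' @param lead_id lead variant id (always included).
#' @param positions optional named vector id -> base-pair position used for
#'   ordering.
#' @return a `ccv_set` data.frame with columns `id`, logical provenance
#'   flags `bayesian`, `llr`, `ld_proxy`, and `lead`.
#' @export
union_ccv <- function(results = list(), llr_set = character(),
                      proxy_set = character(), lead_id,
                      positions = NULL) {
  bayes <- unique(unlist(lapply(results, function(r) {
    unlist(lapply(r$credible_sets, `[[`, "ids"))
  })))
  ids <- unique(c(bayes, llr_set, proxy_set, lead_id))
  if (!length(ids)) stop("no source contributed any variant")
  out <- data.frame(
    id = ids,
    bayesian = ids %in% bayes,
    llr = ids %in% llr_set,
    ld_proxy = ids %in% proxy_set,
    lead = ids == lead_id,
    stringsAsFactors = FALSE
  )
  pos <- if (is.null(positions)) rep(NA_real_, nrow(out)) else
    unname(positions[out$id])
  ord <- order(is.na(pos), pos, out$id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ccv_set", "data.frame")
  out
}
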