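#' Priors for colocalization enumeration
#'
#' `p1` and `p2` are the per-variant prior probabilities of causality for
#' each trait alone and `p12` the prior that one variant is causal for both
#' (the colocalization prior; its tested magnitudes here are `1e-5`, the
#' stringent default, then `1e-4` and `1e-3`). A warning is issued when
#' `p12 > min(p1, p2)`.
#'
#' @param p1,p2 per-variant single-trait priors (default 1e-4).
#' @param p12 shared-causal prior (default 1e-5).
#' @return a `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  vals <- c(p1 = p1, p2 = p2, p12 = p12)
  if (any(vals <= 0 | vals >= 1)) stop("priors must lie in (0, 1)")
  if (p12 > min(p1, p2)) {
    warning("p12 exceeds min(p1, p2); shared-causal prior unusually large")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Colocalization by enumeration of single-causal configurations
#'
#' Enumerates the five hypotheses for two traits at one locus under at most
#' one causal variant per trait: H0 no association; H1/H2 one trait only;
#' H3 two distinct causal variants; H4 one shared causal variant. With
#' per-variant log approximate Bayes factors `labf1`, `labf2`, the
#' (unnormalized) hypothesis masses are
#' `H0 = 1`, `H1 = p1 sum_i ABF1_i`, `H2 = p2 sum_j ABF2_j`,
#' `H3 = p1 p2 sum_{i != j} ABF1_i ABF2_j`, `H4 = p12 sum_i ABF1_i ABF2_i`,
#' all accumulated in log space. A posterior `PP4 > 0.8` is conventionally
#' read as strong evidence for a shared causal variant, `PP4 < 0.2` as
#' evidence against.
#'
#' @param labf1,labf2 equal-length per-variant log-ABF vectors.
#' @param priors a [coloc_priors()].
#' @return a `coloc_result` list with `PP0..PP4` (summing to one), the
#'   priors used, and `n_variants`.
#' @export
coloc_enumerate <- function(labf1, labf2, priors = coloc_priors()) {
  if (length(labf1) != length(labf2)) stop("log-ABF vectors differ in length")
  m <- length(labf1)
  if (m < 1) stop("at least one variant required")
  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  l0 <- 0
  l1 <- log(priors$p1) + s1
  l2 <- log(priors$p2) + s2
  l4 <- log(priors$p12) + s12
  # sum_{i != j} = (sum_i)(sum_j) - sum_{i = j}; the cross term dominates
  # whenever m > 1, so the log1p form is stable.
  l3 <- if (m == 1) -Inf else {
    log(priors$p1) + log(priors$p2) + s1 + s2 +
      log1p(-exp(pmin(s12 - s1 - s2, 0)))
  }
  ll <- c(l0, l1, l2, l3, l4)
  pp <- softmax_inf(ll)
  structure(list(PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4],
                 PP4 = pp[5], priors = priors, n_variants = m),
            class = "coloc_result")
}

softmax_inf <- function(x) {
  m <- max(x)
  e <- ifelse(is.finite(x), exp(x - m), 0)
  e / sum(e)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> m = %d\n  PP0 %.4f | PP1 %.4f | PP2 %.4f | PP3 %.4f | PP4 %.4f\n",
              x$n_variants, x$PP0, x$PP1, x$PP2, x$PP3, x$PP4))
  invisible(x)
}

#' Per-signal colocalization of two fine-mapping results
#'
#' Mirrors the SuSiE-then-coloc construction: each retained single effect of
#' each trait carries a per-variant log-Bayes-factor vector (computed at the
#' effect's fitted prior variance); every pair of effects is colocalized by
#' [coloc_enumerate()] and the full matrix of results is returned together
#' with the maximum PP4. A result with no retained effect yields an empty
#' matrix and `max_pp4 = 0`.
#'
#' @param fm1,fm2 `finemap_result` objects exposing `lbf` matrices and
#'   credible sets (effects without a retained credible set are skipped).
#' @param priors a [coloc_priors()].
#' @return list with `pairs` (data.frame: `effect1, effect2, PP0..PP4`) and
#'   `max_pp4`.
#' @export
coloc_per_signal <- function(fm1, fm2, priors = coloc_priors()) {
  e1 <- retained_effects(fm1)
  e2 <- retained_effects(fm2)
  rows <- list()
  for (a in e1) for (b in e2) {
    cr <- coloc_enumerate(fm1$lbf[a, ], fm2$lbf[b, ], priors)
    rows[[length(rows) + 1]] <- data.frame(
      effect1 = a, effect2 = b, PP0 = cr$PP0, PP1 = cr$PP1, PP2 = cr$PP2,
      PP3 = cr$PP3, PP4 = cr$PP4)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(effect1 = integer(), effect2 = integer(), PP0 = numeric(),
               PP1 = numeric(), PP2 = numeric(), PP3 = numeric(),
               PP4 = numeric())
  list(pairs = pairs, max_pp4 = if (nrow(pairs)) max(pairs$PP4) else 0)
}

retained_effects <- function(fm) {
  if (is.null(fm$lbf) || !length(fm$credible_sets)) return(integer())
  eff <- vapply(fm$credible_sets, function(cs) {
    if (is.null(cs$effect)) NA_integer_ else as.integer(cs$effect)
  }, 1L)
  eff <- eff[!is.na(eff)]
  if (!length(eff) && nrow(fm$lbf) == 1 && length(fm$credible_sets)) eff <- 1L
  unique(eff)
}
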