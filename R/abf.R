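#' Prior for the Wakefield approximate Bayes factor
#'
#' The ABF compares `H1: beta ~ N(0, W)` against `H0: beta = 0` for a
#' single-variant association whose estimate has sampling variance `V`. With
#' standardized effects, `V` is approximately `1/n`; the default prior
#' standard deviation 0.15 is the conventional choice for a quantitative
#' trait.
#'
#' @param W prior variance of the (standardized) effect; default `0.15^2`.
#' @param V sampling variance of the effect estimate; supply `1/n` for
#'   standardized effects from a GWAS of `n` individuals.
#' @return an `abf_prior` list with elements `W` and `V`.
#' @export
abf_prior <- function(W = 0.15^2, V = 1) {
  if (W <= 0 || V <= 0) stop("W and V must be positive")
  structure(list(W = W, V = V), class = "abf_prior")
}

#' Wakefield log approximate Bayes factor
#'
#' `log ABF = 1/2 log(V / (V + W)) + 1/2 z^2 W / (V + W)`; monotone
#' increasing in `|z|`. This is the shared primitive behind single-effect
#' fine-mapping and colocalization enumeration.
#'
#' @param z association z-score(s).
#' @param prior an [abf_prior()].
#' @return log Bayes factor(s), same length as `z`.
#' @export
wakefield_log_abf <- function(z, prior = abf_prior()) {
  stopifnot(inherits(prior, "abf_prior"))
  if (!all(is.finite(z))) stop("z must be finite")
  r <- prior$W / (prior$V + prior$W)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Construct a fine-mapping result
#'
#' @param method engine label (e.g. `"susie_rss"`, `"single_effect"`).
#' @param ids variant ids.
#' @param pip per-variant posterior inclusion probabilities in `[0, 1]`.
#' @param credible_sets list of sets, each a list with `ids`, `alpha`
#'   (per-member inclusion mass), `cum_pip` (sum of member alpha), `purity`
#'   (min absolute pairwise LD among members).
#' @param alpha optional L x m matrix of per-effect inclusion vectors.
#' @param lbf optional L x m matrix of per-effect per-variant log Bayes
#'   factors (used by per-signal colocalization).
#' @param V optional per-effect prior variances.
#' @return a `finemap_result`.
#' @export
finemap_result <- function(method, ids, pip, credible_sets = list(),
                           alpha = NULL, lbf = NULL, V = NULL) {
  if (any(pip < -1e-12 | pip > 1 + 1e-12)) stop("PIPs must lie in [0, 1]")
  structure(list(method = method, ids = as.character(ids),
                 pip = pmin(pmax(pip, 0), 1),
                 credible_sets = credible_sets,
                 alpha = alpha, lbf = lbf, V = V),
            class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("<finemap_result: %s> %d variants, %d credible set(s)\n",
              x$method, length(x$ids), length(x$credible_sets)))
  for (i in seq_along(x$credible_sets)) {
    cs <- x$credible_sets[[i]]
    cat(sprintf("  CS%d: %d variant(s), cumulative PIP %.3f, purity %.3f\n",
                i, length(cs$ids), cs$cum_pip, cs$purity))
  }
  invisible(x)
}

# Smallest set of variants by descending alpha whose cumulative mass reaches
# `coverage`; ties broken by ascending variant index for determinism.
coverage_set <- function(alpha, coverage) {
  ord <- order(-alpha, seq_along(alpha))
  cum <- cumsum(alpha[ord])
  k <- which(cum >= coverage - 1e-12)[1]
  if (is.na(k)) k <- length(alpha)
  sort(ord[seq_len(k)])
}

set_purity <- function(members, R) {
  if (length(members) < 2) return(1)
  sub <- abs(R[members, members])
  min(sub[upper.tri(sub)])
}

#' Single-effect Bayesian fine-mapping
#'
#' Assumes exactly one causal variant at the locus with a uniform causal
#' prior: `PIP_i = ABF_i / sum_j ABF_j`. One credible set is built by adding
#' variants in descending PIP until the cumulative PIP reaches `coverage`.
#' This is the exhaustive single-causal enumeration and serves as the exact
#' baseline engine.
#'
#' @param stats a [summary_stats()].
#' @param prior an [abf_prior()]; by default `V = 1/n` with the standard
#'   0.15 prior sd on the standardized-effect scale.
#' @param coverage credible-set coverage (default 0.95).
#' @param ld optional LD matrix, only used to report credible-set purity.
#' @return a `finemap_result` with one credible set.
#' @export
single_effect_finemap <- function(stats, prior = NULL, coverage = 0.95,
                                  ld = NULL) {
  stopifnot(nrow(stats) >= 1)
  if (is.null(prior)) prior <- abf_prior(V = 1 / stats$n[1])
  labf <- wakefield_log_abf(stats$z, prior)
  pip <- softmax(labf)
  members <- coverage_set(pip, coverage)
  purity <- if (is.null(ld)) NA_real_ else set_purity(members, align_ld(stats, ld))
  cs <- list(ids = stats$id[members], alpha = pip[members],
             cum_pip = sum(pip[members]), purity = purity)
  finemap_result("single_effect", stats$id, pip, list(cs),
                 alpha = matrix(pip, 1), lbf = matrix(labf, 1),
                 V = prior$W)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
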