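#' Sum-of-single-effects fine-mapping from summary statistics
#'
#' Fits the RSS ("regression with summary statistics") form of the
#' sum-of-single-effects model: the vector of marginal z-scores is modeled
#' as `z ~ MVN(R b, R)` with `b = sum_l b_l` a sum of `L` single effects,
#' each placing all of its mass on one variant. Coordinate-ascent
#' variational inference cycles over effects: effect `l` sees the residual
#' z-scores after removing the other effects' posterior-mean contributions
#' through `R`, and is refit as a Bayesian single-effect regression, giving
#' a per-variant inclusion vector `alpha_l` that sums to one. The evidence
#' lower bound (ELBO) is non-decreasing across iterations and is asserted at
#' every step.
#'
#' Per-variant posterior inclusion probabilities combine across effects as
#' `PIP_i = 1 - prod_l (1 - alpha_li)`. Each effect with non-null prior
#' variance yields a credible set: the smallest set of variants by
#' descending `alpha_l` whose cumulative mass reaches `coverage`. Set purity
#' is the minimum absolute pairwise LD among members; sets with purity below
#' `min_abs_corr` are dropped (with the default `min_abs_corr = 0`, no set
#' is ever dropped for purity).
#'
#' @param stats a [summary_stats()].
#' @param ld LD correlation matrix aligned to `stats` (by id when dimnames
#'   are present, else by position).
#' @param L maximum number of single effects (default 5).
#' @param coverage credible-set coverage (default 0.95).
#' @param min_abs_corr purity threshold (default 0, i.e. keep all sets).
#' @param prior_variance initial prior variance of each effect on the
#'   z-score scale (default 50, the conventional scale-free choice).
#' @param estimate_prior_variance if `TRUE` (default), each effect's prior
#'   variance is re-optimized against its single-effect marginal likelihood
#'   every sweep, and set to zero (a null effect, excluded from credible
#'   sets) when the null fits better.
#' @param max_iter,tol iteration cap and ELBO convergence tolerance.
#' @param on_nonpsd what to do when `ld` has no Cholesky factor:
#'   `"regularize"` adds `ridge` to the diagonal (with a message), `"error"`
#'   rejects.
#' @param ridge diagonal regularization used under `"regularize"`.
#' @return a `finemap_result` with per-effect `alpha`, log-Bayes-factor
#'   matrix `lbf`, prior variances `V`, and the ELBO trace in
#'   `attr(, "elbo")`.
#' @export
susie_rss <- function(stats, ld, L = 5, coverage = 0.95, min_abs_corr = 0,
                      prior_variance = 50, estimate_prior_variance = TRUE,
                      max_iter = 200, tol = 1e-4,
                      on_nonpsd = c("regularize", "error"), ridge = 1e-8) {
  on_nonpsd <- match.arg(on_nonpsd)
  R <- align_ld(stats, ld)
  z <- stats$z
  m <- length(z)
  stopifnot(L >= 1)
  if (is.null(tryCatch(chol(R), error = function(e) NULL))) {
    if (on_nonpsd == "error") stop("LD matrix is not positive definite")
    message(sprintf("LD matrix not positive definite; adding ridge %g to diagonal", ridge))
    R <- R + diag(ridge, m)
  }

  alpha <- matrix(1 / m, L, m)
  mu <- matrix(0, L, m)
  mu2 <- matrix(0, L, m)
  lbf_var <- matrix(0, L, m)
  V <- rep(prior_variance, L)
  b_bar <- matrix(0, L, m)        # per-effect posterior mean alpha * mu
  Rb <- rep(0, m)                  # R %*% colSums(b_bar)
  yty <- sum(z^2)

  ser_loglik <- function(v, bhat) {
    if (v <= 0) return(0)
    lbf <- 0.5 * log(1 / (1 + v)) + 0.5 * bhat^2 * v / (1 + v)
    logsumexp(lbf) - log(m)
  }

  elbo <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      Rb <- Rb - drop(R %*% b_bar[l, ])
      r_l <- z - Rb                       # residual X'y for this effect
      if (estimate_prior_variance) {
        opt <- stats::optimize(function(lv) -ser_loglik(exp(lv), r_l),
                               interval = c(-15, 15))
        v_new <- exp(opt$minimum)
        V[l] <- if (ser_loglik(v_new, r_l) <= 0) 0 else v_new
      }
      v <- V[l]
      if (v <= 0) {
        lbf_var[l, ] <- 0
        alpha[l, ] <- 1 / m
        mu[l, ] <- 0
        mu2[l, ] <- 0
      } else {
        lbf_var[l, ] <- 0.5 * log(1 / (1 + v)) + 0.5 * r_l^2 * v / (1 + v)
        alpha[l, ] <- softmax(lbf_var[l, ])
        s2 <- v / (1 + v)
        mu[l, ] <- s2 * r_l
        mu2[l, ] <- s2 + mu[l, ]^2
      }
      b_bar[l, ] <- alpha[l, ] * mu[l, ]
      Rb <- Rb + drop(R %*% b_bar[l, ])
    }
    elbo <- c(elbo, susie_elbo(z, R, yty, alpha, mu, mu2, b_bar, V, m))
    if (it > 1) {
      if (elbo[it] < elbo[it - 1] - 1e-6) {
        stop(sprintf("ELBO decreased at iteration %d (%.8g -> %.8g)",
                     it, elbo[it - 1], elbo[it]))
      }
      if (abs(elbo[it] - elbo[it - 1]) < tol) break
    }
  }

  pip <- 1 - apply(1 - alpha, 2, prod)
  sets <- list()
  for (l in seq_len(L)) {
    if (V[l] <= 1e-9) next
    members <- coverage_set(alpha[l, ], coverage)
    purity <- set_purity(members, R)
    if (purity < min_abs_corr) next
    sets[[length(sets) + 1]] <- list(
      ids = stats$id[members], alpha = alpha[l, members],
      cum_pip = sum(alpha[l, members]), purity = purity, effect = l
    )
  }
  sets <- dedupe_sets(sets)
  res <- finemap_result("susie_rss", stats$id, pip, sets,
                        alpha = alpha, lbf = lbf_var, V = V)
  attr(res, "elbo") <- elbo
  res
}

# ELBO for the sufficient-statistics model with residual variance fixed at 1.
susie_elbo <- function(z, R, yty, alpha, mu, mu2, b_bar, V, m) {
  b_total <- colSums(b_bar)
  quad <- drop(b_total %*% R %*% b_total) -
    sum(vapply(seq_len(nrow(b_bar)),
               function(l) drop(b_bar[l, ] %*% R %*% b_bar[l, ]), 0)) +
    sum(alpha * mu2)                       # R_jj = 1
  eloglik <- -0.5 * (yty - 2 * sum(b_total * z) + quad) -
    0.5 * m * log(2 * pi)
  kl <- 0
  for (l in seq_len(nrow(alpha))) {
    v <- V[l]
    if (v <= 0) next
    a <- alpha[l, ]
    s2 <- v / (1 + v)
    nz <- a > 0
    kl <- kl + sum(a[nz] * (log(a[nz] * m) +
      0.5 * (log(v / s2) + (s2 + mu[l, nz]^2) / v - 1)))
  }
  eloglik - kl
}

dedupe_sets <- function(sets) {
  if (length(sets) < 2) return(sets)
  keys <- vapply(sets, function(s) paste(sort(s$ids), collapse = ","), "")
  keep <- !duplicated(keys)
  sets[keep]
}
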