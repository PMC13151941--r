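#' Specify a synthetic locus
#'
#' A locus specification bundles everything needed to simulate GWAS/QTL
#' summary statistics at a single locus: the number of variants and their
#' base-pair positions, a block partition of the variants with a per-block
#' AR(1) correlation parameter, the planted causal effects per trait
#' (standardized effect sizes on the genotype scale), and per-trait GWAS
#' sample sizes.
#'
#' @param n_variants number of variants at the locus.
#' @param positions integer vector of monotone increasing base-pair
#'   coordinates, length `n_variants`. Default: evenly spaced every 1 kb.
#' @param block_sizes integer vector partitioning the variants into LD
#'   blocks; must sum to `n_variants`. Default: one block.
#' @param rho within-block AR(1) correlation, recycled per block; each in
#'   `[0, 1)`.
#' @param causal_effects named list mapping trait label to a two-column
#'   structure of (variant index, standardized effect b), given as a list of
#'   `c(index, b)` pairs or an n x 2 matrix. Effects must satisfy `|b| < 1`.
#' @param sample_sizes named numeric vector mapping trait label to GWAS
#'   sample size (n >= 1). Names must match `causal_effects`.
#' @param seed integer seed controlling all randomness downstream.
#'
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(n_variants,
                       positions = NULL,
                       block_sizes = n_variants,
                       rho = 0.9,
                       causal_effects = list(),
                       sample_sizes = numeric(),
                       seed = 1L) {
  stopifnot(n_variants >= 1)
  if (is.null(positions)) positions <- seq_len(n_variants) * 1000L
  if (length(positions) != n_variants || any(diff(positions) <= 0)) {
    stop("positions must be monotone increasing with one entry per variant")
  }
  if (sum(block_sizes) != n_variants) {
    stop("block_sizes must sum to n_variants")
  }
  rho <- rep_len(rho, length(block_sizes))
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  causal_effects <- lapply(causal_effects, function(ce) {
    if (is.null(ce) || !length(ce)) {
      return(matrix(numeric(), ncol = 2L,
                    dimnames = list(NULL, c("index", "b"))))
    }
    ce <- matrix(unlist(ce), ncol = 2L, byrow = !is.matrix(ce))
    colnames(ce) <- c("index", "b")
    if (any(ce[, "index"] < 1 | ce[, "index"] > n_variants)) {
      stop("causal variant index out of range")
    }
    if (any(abs(ce[, "b"]) >= 1)) stop("standardized effects must satisfy |b| < 1")
    ce
  })
  if (length(sample_sizes) && any(sample_sizes < 1)) stop("sample sizes must be >= 1")
  if (length(causal_effects) &&
      !all(names(causal_effects) %in% names(sample_sizes))) {
    stop("every trait in causal_effects needs a sample size")
  }
  structure(list(
    n_variants = as.integer(n_variants),
    positions = as.integer(positions),
    block_sizes = as.integer(block_sizes),
    rho = rho,
    causal_effects = causal_effects,
    sample_sizes = sample_sizes,
    seed = as.integer(seed)
  ), class = "locus_spec")
}

#' Block-diagonal AR(1) LD matrix
#'
#' Builds the LD correlation matrix implied by a [locus_spec()]: within each
#' block, `R[i, j] = rho^|i - j|`; zero across blocks. The AR(1) structure is
#' symmetric, unit-diagonal and positive definite for `rho` in `[0, 1)`, and
#' admits closed-form entries, which makes downstream checks exact.
#'
#' @param spec a [locus_spec()].
#' @return an `ld_matrix`: the correlation matrix with variant ids as
#'   dimnames.
#' @export
make_ld <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  blocks <- mapply(function(size, r) {
    idx <- seq_len(size)
    r^abs(outer(idx, idx, "-"))
  }, spec$block_sizes, spec$rho, SIMPLIFY = FALSE)
  R <- matrix(0, spec$n_variants, spec$n_variants)
  off <- 0L
  for (B in blocks) {
    k <- nrow(B)
    R[off + seq_len(k), off + seq_len(k)] <- B
    off <- off + k
  }
  ids <- variant_ids(spec)
  dimnames(R) <- list(ids, ids)
  class(R) <- c("ld_matrix", "matrix", "array")
  R
}

variant_ids <- function(spec) sprintf("var%04d", seq_len(spec$n_variants))

#' Draw GWAS z-scores under the RSS model
#'
#' Simulates one vector of marginal association z-scores from the
#' summary-statistics likelihood `z ~ MVN(sqrt(n) * R %*% b, R)`, where `R`
#' is the LD correlation matrix, `b` the vector of true standardized effects
#' and `n` the GWAS sample size. LD both smears the mean (through `R b`) and
#' correlates the noise.
#'
#' @param ld LD correlation matrix (symmetric, unit diagonal, PSD).
#' @param b numeric vector of standardized effects aligned to `ld`.
#' @param n GWAS sample size.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric z-score vector named by the variant ids of `ld`.
#' @export
draw_zscores <- function(ld, b, n, seed = NULL) {
  m <- nrow(ld)
  stopifnot(length(b) == m, n >= 1)
  Rhalf <- psd_factor(ld)
  with_seed(seed, {
    z <- drop(sqrt(n) * ld %*% b) + drop(Rhalf %*% stats::rnorm(m))
  })
  names(z) <- rownames(ld)
  z
}

# Square-root factor of a PSD correlation matrix; Cholesky when possible,
# eigen fallback clipping eigenvalues in [-tol, 0] to zero.
psd_factor <- function(R, tol = 1e-8) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -tol) {
    stop(sprintf("matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev$values)))
  }
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
}

#' Draw genotype dosages via a Gaussian copula
#'
#' Generates `n_samples x m` dosages in `{0, 1, 2}` whose correlation is a
#' deterministic monotone transform of the target LD matrix: two latent
#' haplotype draws from `MVN(0, R)` are thresholded at the `1 - maf` normal
#' quantile and summed. Marginal allele frequencies converge to `mafs`.
#'
#' @param ld LD correlation matrix.
#' @param mafs minor-allele frequencies in `(0, 0.5]`, recycled over variants.
#' @param n_samples number of individuals.
#' @param seed integer seed.
#' @return integer dosage matrix with variant ids as column names.
#' @export
draw_genotypes <- function(ld, mafs, n_samples, seed = NULL) {
  m <- nrow(ld)
  mafs <- rep_len(mafs, m)
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  Rhalf <- psd_factor(ld)
  thr <- stats::qnorm(1 - mafs)
  with_seed(seed, {
    h1 <- matrix(stats::rnorm(n_samples * m), n_samples, m) %*% t(Rhalf)
    h2 <- matrix(stats::rnorm(n_samples * m), n_samples, m) %*% t(Rhalf)
  })
  X <- (sweep(h1, 2, thr, ">") + 0L) + (sweep(h2, 2, thr, ">") + 0L)
  colnames(X) <- rownames(ld)
  X
}

#' Simulate a locus end-to-end
#'
#' Convenience wrapper: builds the LD matrix from a [locus_spec()] and draws
#' one z-score vector per trait, recording the planted truth. The per-trait
#' seeds are derived deterministically from `spec$seed` so identical specs
#' reproduce bit-for-bit.
#'
#' @param spec a [locus_spec()].
#' @param genotypes if `TRUE`, also draw a dosage matrix (maf 0.3) and
#'   per-trait phenotypes `y = X_std b + e` for OLS cross-checks.
#' @param n_genotype_samples individuals for the dosage matrix.
#' @return a list of class `simulated_locus` with elements `ld`, `zscores`
#'   (named list per trait), `stats` (per-trait `summary_stats`), `truth`
#'   (causal index sets and effects per trait), and optionally `genotypes`
#'   and `phenotypes`.
#' @export
simulate_locus <- function(spec, genotypes = FALSE, n_genotype_samples = 5000L) {
  ld <- make_ld(spec)
  traits <- names(spec$causal_effects)
  if (length(spec$sample_sizes)) traits <- union(traits, names(spec$sample_sizes))
  zscores <- list()
  stats_l <- list()
  truth <- list()
  for (k in seq_along(traits)) {
    tr <- traits[[k]]
    b <- numeric(spec$n_variants)
    ce <- spec$causal_effects[[tr]]
    if (!is.null(ce) && nrow(ce)) b[ce[, "index"]] <- ce[, "b"]
    n <- spec$sample_sizes[[tr]]
    z <- draw_zscores(ld, b, n, seed = spec$seed + 7919L * k)
    zscores[[tr]] <- z
    stats_l[[tr]] <- summary_stats(
      id = rownames(ld), chrom = "chrSim", pos = spec$positions,
      ref = "A", alt = "G", z = z, n = n
    )
    truth[[tr]] <- list(index = if (is.null(ce)) integer() else as.integer(ce[, "index"]),
                        b = b)
  }
  out <- list(spec = spec, ld = ld, zscores = zscores, stats = stats_l,
              truth = truth)
  if (genotypes) {
    X <- draw_genotypes(ld, 0.3, n_genotype_samples, seed = spec$seed + 104729L)
    Xs <- scale(X)
    Xs[is.na(Xs)] <- 0
    phen <- list()
    for (k in seq_along(traits)) {
      tr <- traits[[k]]
      with_seed(spec$seed + 224737L * k, {
        phen[[tr]] <- drop(Xs %*% truth[[tr]]$b) +
          stats::rnorm(n_genotype_samples)
      })
    }
    out$genotypes <- X
    out$phenotypes <- phen
  }
  class(out) <- "simulated_locus"
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}
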