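# Shared fixtures built in code.

# One-block AR(1) locus with optional planted causals.
quick_locus <- function(m = 50, rho = 0.9, causal = integer(), b = 0.05,
                        n = 50000, seed = 1, traits = c("gwas")) {
  ce <- if (length(causal)) {
    stats::setNames(lapply(traits, function(t)
      lapply(causal, function(j) c(j, b))), traits)
  } else stats::setNames(vector("list", length(traits)), traits)
  locus_spec(m, block_sizes = m, rho = rho,
             causal_effects = ce,
             sample_sizes = stats::setNames(rep(n, length(traits)), traits),
             seed = seed)
}

# Independent Wakefield log-ABF via the two-normal-density route (different
# algebraic path than the package's closed-form expression).
# ratio of densities of beta_hat = z sqrt(V) under N(0, V + W) vs N(0, V);
# expressed on the z scale (the Jacobians cancel).
abf_log_density <- function(z, W, V) {
  stats::dnorm(z, 0, sqrt(1 + W / V), log = TRUE) -
    stats::dnorm(z, 0, 1, log = TRUE)
}

# Brute-force coloc: direct double loop over all single-causal
# configurations, in probability space.
coloc_brute <- function(labf1, labf2, p1, p2, p12) {
  m <- length(labf1)
  a1 <- exp(labf1); a2 <- exp(labf2)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  h4 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) h4 <- h4 + p12 * a1[i] * a2[j]
    else h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  }
  tot <- h0 + h1 + h2 + h3 + h4
  c(h0, h1, h2, h3, h4) / tot
}

# Marginal regression z-scores of phenotype y on each standardized dosage
# column.
marginal_z <- function(X, y) {
  n <- length(y)
  apply(X, 2, function(x) {
    r <- suppressWarnings(stats::cor(x, y))
    if (is.na(r)) 0 else r * sqrt(n - 2) / sqrt(1 - r^2)
  })
}

# Small synthetic chromosome with two planted enhancer-promoter pairs.
quick_annotations <- function(n_background = 0, seed = 1,
                              planted_scores = c(6.2, 7.5)) {
  cuts <- seq(500, 9500, by = 500)
  annotation_spec(
    chrom = "chrSim", length = 10000, cut_positions = cuts,
    state_intervals = data.frame(
      start = c(1200, 5200, 8100), end = c(1400, 5400, 8300),
      name = c("EnhA1", "EnhWk", "TssA"), source = "melanocyte"),
    atac_peaks = data.frame(start = 1250, end = 1350),
    promoters = data.frame(gene = c("GENE_A", "GENE_B"),
                           start = c(8050, 9050), end = c(8200, 9200)),
    planted_interactions = data.frame(
      enh_start = c(1200, 5200), enh_end = c(1400, 5400),
      gene = c("GENE_A", "GENE_B"), score = planted_scores),
    n_background = n_background, seed = seed
  )
}
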