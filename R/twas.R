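#' Summary-based expression-prediction weights
#'
#' Trains per-gene variant weights from eQTL summary statistics and LD,
#' without individual-level data. Three schemes: `top1` places an indicator
#' on the max-`|z|` variant; `topk` uses the marginal z-scores of the `k`
#' strongest variants; `ridge` solves `(R + lambda I) w = z` and rescales to
#' unit predicted-expression variance (`w' R w = 1`). The scheme is recorded
#' in the output.
#'
#' @param eqtl_stats a [summary_stats()] for the gene's cis-eQTL scan.
#' @param ld LD correlation matrix aligned to `eqtl_stats`.
#' @param method one of `"top1"`, `"topk"`, `"ridge"`.
#' @param gene gene identifier stored with the weights.
#' @param k number of variants for `topk` (default 5).
#' @param lambda ridge penalty for `ridge` (default 0.1).
#' @return an `expression_weights` list with `gene`, `ids`, `w`, `method`.
#' @export
build_weights <- function(eqtl_stats, ld, method = c("top1", "topk", "ridge"),
                          gene = "gene", k = 5, lambda = 0.1) {
  method <- match.arg(method)
  R <- align_ld(eqtl_stats, ld)
  z <- eqtl_stats$z
  m <- length(z)
  w <- numeric(m)
  if (method == "top1") {
    if (all(z == 0)) {
      warning("all z-scores are zero; top1 selects the first variant")
      j <- 1L
    } else j <- which.max(abs(z))
    w[j] <- 1
  } else if (method == "topk") {
    top <- order(-abs(z), seq_len(m))[seq_len(min(k, m))]
    w[top] <- z[top]
  } else {
    w <- drop(solve(R + diag(lambda, m), z))
    s <- drop(w %*% R %*% w)
    if (s > 0) w <- w / sqrt(s)
  }
  if (all(w == 0)) stop("degenerate weights: all zero")
  structure(list(gene = gene, ids = eqtl_stats$id, w = w, method = method),
            class = "expression_weights")
}

#' Summary-based TWAS statistic
#'
#' Association between genetically predicted expression and the GWAS trait:
#' `Z_twas = w' z / sqrt(w' R w)` with two-sided normal p-value, plus the
#' per-variant correlation between predicted expression and each variant,
#' `rho = R w / sqrt(w' R w)`.
#'
#' @param weights an [build_weights()] object (or list with `ids`, `w`).
#' @param gwas_stats a [summary_stats()] for the GWAS trait.
#' @param ld LD correlation matrix aligned to `gwas_stats`.
#' @return a `twas_result` list with `gene`, `z`, `p`, `rho`.
#' @export
twas_z <- function(weights, gwas_stats, ld) {
  R <- align_ld(gwas_stats, ld)
  w <- align_weights(weights, gwas_stats$id)
  wRw <- drop(w %*% R %*% w)
  if (wRw <= 1e-12) stop("degenerate weights: predicted expression has zero variance")
  z <- drop(w %*% gwas_stats$z) / sqrt(wRw)
  rho <- drop(R %*% w) / sqrt(wRw)
  structure(list(gene = weights$gene, z = z,
                 p = 2 * stats::pnorm(-abs(z)), rho = rho),
            class = "twas_result")
}

align_weights <- function(weights, ids) {
  w <- numeric(length(ids))
  j <- match(weights$ids, ids)
  if (anyNA(j)) stop("weight variants missing from GWAS statistics")
  w[j] <- weights$w
  w
}

#' Condition the GWAS on predicted expression of one or more genes
#'
#' Each gene enters as a pseudo-variant: its correlation with variant `j` is
#' `rho_gj = (R w_g)_j / sqrt(w_g' R w_g)`, its correlation with another
#' gene `h` is `w_g' R w_h / sqrt(w_g' R w_g * w_h' R w_h)`, and its
#' "z-score" is the gene's marginal TWAS statistic. The augmented system is
#' then passed through the standard conditional-association formula
#' ([conditional_z()]), conditioning on the pseudo-variants. Conditioning on
#' zero genes is the identity.
#'
#' @param gwas_stats a [summary_stats()].
#' @param ld LD matrix aligned to `gwas_stats`.
#' @param weights_list list of [build_weights()] objects.
#' @param lambda ridge for the conditioning block.
#' @return data.frame `id, z_cond, p_cond` over the SNPs.
#' @export
condition_gwas_on_genes <- function(gwas_stats, ld, weights_list,
                                    lambda = 1e-8) {
  if (!length(weights_list)) {
    return(conditional_z(gwas_stats, ld, character()))
  }
  aug <- augment_genes(gwas_stats, ld, weights_list)
  conditional_z(aug$stats, aug$R, aug$gene_ids, lambda = lambda)
}

augment_genes <- function(gwas_stats, ld, weights_list) {
  R <- align_ld(gwas_stats, ld)
  m <- nrow(R)
  k <- length(weights_list)
  W <- vapply(weights_list, align_weights, numeric(m), ids = gwas_stats$id)
  RW <- R %*% W                               # m x k
  sds <- sqrt(diag(crossprod(W, RW)))
  P <- sweep(RW, 2, sds, "/")                 # SNP-gene correlations
  G <- crossprod(W, RW) / tcrossprod(sds)     # gene-gene correlations
  diag(G) <- 1
  off <- abs(G[upper.tri(G)])
  if (length(off) && any(off > 1 - 1e-8)) stop("collinear gene models")
  zg <- vapply(weights_list, function(w) twas_z(w, gwas_stats, ld)$z, 0)
  gene_ids <- vapply(weights_list, function(w) paste0("gene:", w$gene), "")
  Raug <- rbind(cbind(R, P), cbind(t(P), G))
  ids <- c(gwas_stats$id, gene_ids)
  dimnames(Raug) <- list(ids, ids)
  stats_aug <- summary_stats(
    id = ids, chrom = c(gwas_stats$chrom, rep(gwas_stats$chrom[1], k)),
    pos = c(gwas_stats$pos, max(gwas_stats$pos) + seq_len(k)),
    z = c(gwas_stats$z, zg), n = gwas_stats$n[1]
  )
  list(stats = stats_aug, R = Raug, gene_ids = gene_ids)
}

#' Joint TWAS of several genes
#'
#' Solves the marginal TWAS z-scores against the gene-gene correlation
#' matrix (generalized least squares): with marginal statistics `Z` and
#' gene-gene correlation `G`, the joint statistic of gene `g` is
#' `(G^-1 Z)_g / sqrt((G^-1)_gg)`. Uncorrelated genes recover their marginal
#' statistics; collinear gene models are rejected.
#'
#' @param gwas_stats a [summary_stats()].
#' @param ld LD matrix aligned to `gwas_stats`.
#' @param weights_list list of at least two [build_weights()] objects.
#' @return data.frame `gene, z_marginal, z_joint, p_joint`.
#' @export
joint_twas <- function(gwas_stats, ld, weights_list) {
  if (length(weights_list) < 2) stop("joint model needs at least two genes")
  aug <- augment_genes(gwas_stats, ld, weights_list)
  k <- length(weights_list)
  G <- aug$R[aug$gene_ids, aug$gene_ids, drop = FALSE]
  if (abs(det(G)) < 1e-10) stop("singular gene correlation matrix")
  zg <- aug$stats$z[match(aug$gene_ids, aug$stats$id)]
  Ginv <- solve(G)
  beta <- unname(drop(Ginv %*% zg))
  zj <- beta / sqrt(unname(diag(Ginv)))
  data.frame(gene = vapply(weights_list, `[[`, "", "gene"),
             z_marginal = unname(zg), z_joint = zj,
             p_joint = 2 * stats::pnorm(-abs(zj)),
             stringsAsFactors = FALSE, row.names = NULL)
}
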