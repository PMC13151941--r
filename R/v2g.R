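#' Pad a variant position into a window
#'
#' Expands a variant (treated as a single base at `pos`, 0-based) into a
#' `[max(0, pos - pad), pos + pad + 1)` half-open window, clamped at the
#' chromosome start. The default padding of 500 bp absorbs cross-linking
#' variability and restriction-fragment boundary effects in capture-HiC.
#'
#' @param pos variant position(s), 0-based.
#' @param pad bases added on each side (default 500).
#' @return data.frame `start, end` (half-open).
#' @export
variant_window <- function(pos, pad = 500) {
  stopifnot(all(pos >= 0), pad >= 0)
  data.frame(start = pmax(0, pos - pad), end = pos + pad + 1)
}

#' Fragments overlapping a window, plus immediate neighbors
#'
#' Returns the ids of all restriction fragments overlapping the window,
#' extended by the immediate left and right neighbors of the overlapping
#' run — interactions are evaluated from both variant-overlapping and
#' adjacent fragments. At the edges of the map the missing neighbor is
#' simply absent. The result is always contiguous in fragment id.
#'
#' @param window list or data.frame with `start`, `end` (half-open).
#' @param fragments fragment map: data.frame `chrom, start, end, name` with
#'   `name` the 0-based integer fragment id, sorted and gap-free.
#' @param adjacent how many fragments to extend on each side (default 1).
#' @return integer vector of fragment ids (possibly empty, with a warning,
#'   when the window misses the map).
#' @export
fragments_for <- function(window, fragments, adjacent = 1L) {
  ov <- which(fragments$start < window$end & window$start < fragments$end)
  if (!length(ov)) {
    warning("window does not overlap the fragment map")
    return(integer())
  }
  lo <- max(1L, min(ov) - adjacent)
  hi <- min(nrow(fragments), max(ov) + adjacent)
  as.integer(fragments$name[lo:hi])
}

#' Optional coarser fragment map
#'
#' Merges every `k` consecutive fragments into one, reproducing the
#' aggregated multi-fragment resolution sometimes used to call broader
#' interactions. New ids are renumbered from 0.
#'
#' @param fragments fragment map data.frame.
#' @param k fragments per merged bin (default 4).
#' @return merged fragment map.
#' @export
merge_fragments <- function(fragments, k = 4L) {
  grp <- (seq_len(nrow(fragments)) - 1L) %/% k
  data.frame(
    chrom = tapply(fragments$chrom, grp, `[`, 1),
    start = as.vector(tapply(fragments$start, grp, min)),
    end = as.vector(tapply(fragments$end, grp, max)),
    name = sort(unique(grp)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Promoter fragments per gene
#'
#' @param promoters data.frame `chrom, start, end, name` with `name` the
#'   gene id (half-open intervals).
#' @param fragments fragment map.
#' @return named list gene -> integer fragment ids overlapping the promoter.
#' @export
promoter_fragments <- function(promoters, fragments) {
  out <- lapply(seq_len(nrow(promoters)), function(i) {
    ov <- which(fragments$start < promoters$end[i] &
                  promoters$start[i] < fragments$end)
    as.integer(fragments$name[ov])
  })
  names(out) <- promoters$name
  out
}

#' Nominate candidate target genes from chromatin interactions
#'
#' A gene is nominated when a high-confidence interaction (score strictly
#' greater than `score_min`, default 5) links any fragment of any variant's
#' fragment set to any fragment containing that gene's promoter.
#' Interactions are unordered fragment pairs; duplicate rows are
#' deduplicated keeping the maximum score.
#'
#' @param variant_frags named list variant id -> integer fragment ids (from
#'   [fragments_for()] over each variant's window).
#' @param interactions data.frame `fragA, fragB, score`.
#' @param promoter_frags named list gene -> promoter fragment ids (from
#'   [promoter_fragments()]).
#' @param score_min confidence threshold (strict `>`; default 5).
#' @return a `candidate_genes` data.frame: `gene, variants`
#'   (comma-collapsed supporting variant ids), `evidence` (always
#'   `"interaction_only"` here; see [refine_regulatory()]).
#' @export
nominate_genes <- function(variant_frags, interactions, promoter_frags,
                           score_min = 5) {
  key <- paste(pmin(interactions$fragA, interactions$fragB),
               pmax(interactions$fragA, interactions$fragB))
  score <- tapply(interactions$score, key, max)
  hi <- names(score)[score > score_min]
  pairs <- if (length(hi)) {
    do.call(rbind, lapply(strsplit(hi, " "), as.integer))
  } else matrix(integer(), ncol = 2)
  rows <- list()
  for (gene in names(promoter_frags)) {
    pf <- promoter_frags[[gene]]
    support <- character()
    for (v in names(variant_frags)) {
      vf <- variant_frags[[v]]
      linked <- (pairs[, 1] %in% vf & pairs[, 2] %in% pf) |
        (pairs[, 1] %in% pf & pairs[, 2] %in% vf)
      if (any(linked)) support <- c(support, v)
    }
    if (length(support)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene, variants = paste(support, collapse = ","),
        evidence = "interaction_only", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), variants = character(),
               evidence = character(), stringsAsFactors = FALSE)
  class(out) <- c("candidate_genes", "data.frame")
  out
}

#' Refine candidates by regulatory overlap of supporting variants
#'
#' Candidates whose supporting variants include at least one cis-regulatory
#' variant (enhancer, promoter or ATAC overlap) are upgraded to
#' `enhancer_promoter` evidence; the rest remain `interaction_only`.
#'
#' @param candidates a [nominate_genes()] result.
#' @param annotations an [annotate_variants()] result covering the
#'   supporting variants.
#' @return the candidates with updated `evidence`.
#' @export
refine_regulatory <- function(candidates, annotations) {
  if (!nrow(candidates)) return(candidates)
  reg <- annotations$id[annotations$cis_regulatory %in% TRUE]
  upgraded <- vapply(strsplit(candidates$variants, ","), function(v) {
    any(v %in% reg)
  }, TRUE)
  candidates$evidence <- ifelse(upgraded, "enhancer_promoter",
                                "interaction_only")
  candidates
}

#' Assign a methylation probe to genes
#'
#' A CpG probe is assigned to every gene for which it falls inside any
#' annotated feature (5'UTR, first exon, gene body, 3'UTR; half-open
#' intervals) or within 1,500 bp of the transcription start site
#' (inclusive, strand ignored).
#'
#' @param cpg_pos probe position (0-based, single base).
#' @param gene_models data.frame with columns `gene, feature, start, end`
#'   (feature intervals; rows with feature `"tss"` use `start` as the TSS
#'   coordinate).
#' @param tss_pad distance to the TSS that still assigns (default 1500).
#' @return character vector of gene ids (possibly empty).
#' @export
assign_probe_to_gene <- function(cpg_pos, gene_models, tss_pad = 1500) {
  hit <- logical(nrow(gene_models))
  is_tss <- gene_models$feature == "tss"
  hit[is_tss] <- abs(cpg_pos - gene_models$start[is_tss]) <= tss_pad
  hit[!is_tss] <- gene_models$start[!is_tss] <= cpg_pos &
    cpg_pos < gene_models$end[!is_tss]
  unique(gene_models$gene[hit])
}
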