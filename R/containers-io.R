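#' Per-variant summary statistics for one trait at one locus
#'
#' @param id unique variant ids.
#' @param chrom chromosome label (recycled).
#' @param pos base-pair positions.
#' @param ref,alt alleles (recycled).
#' @param z marginal association z-scores (finite).
#' @param n GWAS sample size (scalar, >= 1).
#' @return a `summary_stats` data.frame with columns
#'   `id, chrom, pos, ref, alt, z, n`.
#' @export
summary_stats <- function(id, chrom, pos, ref = "A", alt = "G", z, n) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("variant ids must be unique")
  if (!all(is.finite(z))) stop("z-scores must be finite")
  if (length(n) != 1 || n < 1) stop("n must be a scalar sample size >= 1")
  out <- data.frame(id = id, chrom = chrom, pos = as.integer(pos),
                    ref = ref, alt = alt, z = as.numeric(z), n = as.numeric(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

align_ld <- function(stats, ld) {
  ids <- rownames(ld)
  if (is.null(ids) || !all(stats$id %in% ids)) {
    if (nrow(ld) != nrow(stats)) stop("LD matrix not aligned to summary statistics")
    return(unclass_ld(ld))
  }
  unclass_ld(ld[stats$id, stats$id, drop = FALSE])
}

unclass_ld <- function(ld) {
  R <- unclass(ld)
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("LD matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("LD matrix must have unit diagonal")
  R
}

#' Read / write summary-statistics TSV
#'
#' Columns: `id, chrom, pos, ref, alt, z, n` (tab-separated, header).
#'
#' @param stats a [summary_stats()] object.
#' @param path file path.
#' @return `read_sumstats` returns a `summary_stats`; `write_sumstats`
#'   returns `path` invisibly.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  summary_stats(df$id, df$chrom, df$pos, df$ref, df$alt, df$z, df$n[1])
}

#' Read / write an LD matrix
#'
#' Whitespace-delimited square matrix; the header row carries variant ids.
#'
#' @param ld an `ld_matrix` (or plain matrix with dimnames).
#' @param path file path.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(format(unclass(ld), digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE,
                     col.names = colnames(ld))
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  R <- as.matrix(df)
  rownames(R) <- colnames(R)
  class(R) <- c("ld_matrix", "matrix", "array")
  R
}

#' Write BED-style interval tracks (0-based half-open)
#'
#' Tracks travel as data.frames with columns `chrom, start, end` plus an
#' optional `name` column (chromatin state label, gene, fragment id); exactly
#' the BED columns, so files round-trip through any BED-aware tool.
#'
#' @param track data.frame with `chrom, start, end` and optionally `name`.
#' @param path file path.
#' @export
write_bed <- function(track, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(track))
  utils::write.table(track[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  df
}

#' Write / read scored chromatin interactions
#'
#' Two dialects: BEDPE-style (`chromA,startA,endA,chromB,startB,endB,score`)
#' when a fragment map is supplied, and the compact fragment-id dialect
#' (`fragA,fragB,score`) otherwise.
#'
#' @param interactions data.frame with `fragA, fragB, score` (integer
#'   fragment ids into `fragments`).
#' @param path file path.
#' @param fragments optional fragment map data.frame
#'   (`chrom, start, end, name` with `name` the 0-based fragment id) to emit
#'   BEDPE coordinates.
#' @export
write_interactions <- function(interactions, path, fragments = NULL) {
  if (is.null(fragments)) {
    utils::write.table(interactions[, c("fragA", "fragB", "score")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    fa <- fragments[match(interactions$fragA, fragments$name), ]
    fb <- fragments[match(interactions$fragB, fragments$name), ]
    out <- data.frame(chromA = fa$chrom, startA = fa$start, endA = fa$end,
                      chromB = fb$chrom, startB = fb$start, endB = fb$end,
                      score = interactions$score)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_interactions
#' @param fragments_for_read fragment map used to translate BEDPE coordinates
#'   back to fragment ids (id of the fragment containing each anchor
#'   midpoint); `NULL` assumes the fragment-id dialect.
#' @export
read_interactions <- function(path, fragments_for_read = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(fragments_for_read)) {
    return(df[, c("fragA", "fragB", "score")])
  }
  mid_frag <- function(start, end) {
    fragment_at(floor((start + end) / 2), fragments_for_read)
  }
  data.frame(
    fragA = mapply(mid_frag, df$startA, df$endA),
    fragB = mapply(mid_frag, df$startB, df$endB),
    score = df$score
  )
}

fragment_at <- function(pos, fragments) {
  hit <- which(fragments$start <= pos & pos < fragments$end)
  if (!length(hit)) return(NA_integer_)
  as.integer(fragments$name[hit[1]])
}

#' Write / read a tumor cohort
#'
#' The cohort travels as two TSVs: a sample table
#' (`sample, expression, age, sex, purity, stage, survival_days, event,
#' treatment_class`) and a MAF-like mutation table
#' (`sample, gene, protein_change, driver_flag`).
#'
#' @param cohort a `cohort` object (see [make_cohort()]).
#' @param samples_path,mutations_path file paths.
#' @export
write_cohort <- function(cohort, samples_path, mutations_path) {
  utils::write.table(cohort$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$mutations, mutations_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(samples_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(samples_path, mutations_path) {
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  mutations <- utils::read.delim(mutations_path, stringsAsFactors = FALSE)
  structure(list(samples = samples, mutations = mutations), class = "cohort")
}

#' Read / write a fine-mapping result as TSV
#'
#' The long-format schema `variant, pip, cs_index, alpha, method` lets any
#' external fine-mapping engine feed the union rule: one row per (variant,
#' credible set) membership, `cs_index = NA` for variants outside every set.
#'
#' @param result a `finemap_result`.
#' @param path file path.
#' @export
write_finemap <- function(result, path) {
  rows <- data.frame(variant = result$ids, pip = result$pip,
                     cs_index = NA_integer_, alpha = NA_real_,
                     method = result$method)
  extra <- lapply(seq_along(result$credible_sets), function(i) {
    cs <- result$credible_sets[[i]]
    data.frame(variant = cs$ids, pip = result$pip[match(cs$ids, result$ids)],
               cs_index = i, alpha = cs$alpha, method = result$method)
  })
  rows <- rows[!rows$variant %in% unlist(lapply(result$credible_sets, `[[`, "ids")), ]
  out <- do.call(rbind, c(list(rows), extra))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_finemap
#' @export
read_finemap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$variant)
  pip <- df$pip[match(ids, df$variant)]
  cs_idx <- sort(unique(df$cs_index[!is.na(df$cs_index)]))
  sets <- lapply(cs_idx, function(i) {
    sub <- df[!is.na(df$cs_index) & df$cs_index == i, ]
    list(ids = sub$variant, alpha = sub$alpha, cum_pip = sum(sub$alpha),
         purity = NA_real_)
  })
  finemap_result(method = df$method[1], ids = ids, pip = pip,
                 credible_sets = sets)
}
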