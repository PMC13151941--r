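#' Chromatin-state to regulatory-class map
#'
#' Maps chromHMM state names to `enhancer` / `promoter` / `other`, per
#' source cell class. The default vocabulary covers the melanocyte
#' (Roadmap primary, auxiliary and imputed models) and melanoma cell-model
#' state names used for regulatory annotation of fine-mapped variants.
#' Unknown states map to `other` with a warning at lookup time.
#'
#' @param extra optional data.frame with columns `source, state, class` to
#'   append or override.
#' @return a `regulatory_class_map` data.frame (`source, state, class`).
#' @export
regulatory_class_map <- function(extra = NULL) {
  melc_enh <- c("Enh", "EnhG", "EnhBiv", "EnhG1", "EnhG2", "EnhA1", "EnhA2",
                "EnhWk", "TxEnh5", "TxEnh3", "TxEnhW", "EnhAF", "EnhW1",
                "EnhW2", "EnhAc")
  melc_prom <- c("PromU", "PromD1", "PromD2", "TssA", "PromP", "PromBiv",
                 "Tx_Reg")
  mela_enh <- c("4_EnhA", "5_EnhM", "6_EnhW", "7_TxEnhM", "7_TxEnhW",
                "9_TxWkEnhW")
  mela_prom <- c("1_TssA", "2_PromWkD", "3_TssWkP")
  map <- rbind(
    data.frame(source = "melanocyte", state = melc_enh, class = "enhancer"),
    data.frame(source = "melanocyte", state = melc_prom, class = "promoter"),
    data.frame(source = "melanoma", state = mela_enh, class = "enhancer"),
    data.frame(source = "melanoma", state = mela_prom, class = "promoter")
  )
  if (!is.null(extra)) {
    key <- paste(map$source, map$state)
    map <- rbind(map[!key %in% paste(extra$source, extra$state), ], extra)
  }
  class(map) <- c("regulatory_class_map", "data.frame")
  map
}

#' Classify a chromatin state
#'
#' @param state state name(s).
#' @param source source cell class (`"melanocyte"` or `"melanoma"`).
#' @param map a [regulatory_class_map()].
#' @return character vector in `{enhancer, promoter, other}`.
#' @export
classify_state <- function(state, source = "melanocyte",
                           map = regulatory_class_map()) {
  i <- match(paste(source, state), paste(map$source, map$state))
  out <- ifelse(is.na(i), "other", map$class[i])
  unknown <- unique(state[is.na(i)])
  if (length(unknown)) {
    warning(sprintf("unknown chromatin state(s) mapped to 'other': %s",
                    paste(unknown, collapse = ", ")))
  }
  out
}

# Convert a BED-convention (0-based half-open) interval data.frame to
# GRanges (1-based closed). All interval logic in this module funnels
# through here so the boundary convention lives in one place.
bed_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}

#' Annotate variants with regulatory evidence
#'
#' Point-in-interval tests (0-based half-open) of each variant position
#' against chromatin-state tracks (classified via the regulatory map) and
#' ATAC peak tracks. A variant is flagged `cis_regulatory` when it overlaps
#' an enhancer state, a promoter state, or an ATAC peak in any source —
#' accessibility alone suffices.
#'
#' @param variants data.frame with `id, chrom, pos` (0-based positions).
#' @param states data.frame with `chrom, start, end, name` (state label) and
#'   a `source` column (`melanocyte`/`melanoma`); a missing `source` column
#'   defaults to `melanocyte`.
#' @param atac data.frame of peaks (`chrom, start, end`), or `NULL`.
#' @param map a [regulatory_class_map()].
#' @return data.frame `id, enhancer, promoter, atac, cis_regulatory`.
#' @export
annotate_variants <- function(variants, states, atac = NULL,
                              map = regulatory_class_map()) {
  known <- unique(states$chrom)
  off <- !(variants$chrom %in% known) & length(known) > 0
  if (any(off)) {
    warning(sprintf("%d variant(s) on undeclared chromosome skipped", sum(off)))
  }
  vg <- points_to_granges(variants$chrom, variants$pos)
  out <- data.frame(id = variants$id, enhancer = FALSE, promoter = FALSE,
                    atac = FALSE, stringsAsFactors = FALSE)
  if (!is.null(states) && nrow(states)) {
    src <- if ("source" %in% names(states)) states$source else "melanocyte"
    cls <- classify_state(states$name, src, map)
    for (what in c("enhancer", "promoter")) {
      sub <- states[cls == what, , drop = FALSE]
      if (!nrow(sub)) next
      # seqlevel mismatches are handled above; silence the merge chatter
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(vg, bed_to_granges(sub)))
      out[[what]][unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  if (!is.null(atac) && nrow(atac)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(vg, bed_to_granges(atac)))
    out$atac[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  out$cis_regulatory <- out$enhancer | out$promoter | out$atac
  out$enhancer[off] <- out$promoter[off] <- out$atac[off] <-
    out$cis_regulatory[off] <- NA
  out
}
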