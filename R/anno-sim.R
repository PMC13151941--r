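#' Specify synthetic annotation and interaction tracks
#'
#' Everything needed to emulate the regulatory-annotation and capture-HiC
#' inputs on one synthetic chromosome: restriction cut positions defining
#' the fragment map, chromatin-state intervals with state labels, ATAC
#' peaks, gene promoters, planted enhancer-promoter interactions with known
#' scores, and a count of background interactions between random fragment
#' pairs.
#'
#' @param chrom chromosome label.
#' @param length chromosome length in bp.
#' @param cut_positions strictly increasing restriction-cut coordinates in
#'   `(0, length)`.
#' @param state_intervals data.frame `start, end, name` (+ optional
#'   `source`) of chromatin-state intervals (0-based half-open).
#' @param atac_peaks data.frame `start, end` of accessibility peaks.
#' @param promoters data.frame `gene, start, end`.
#' @param planted_interactions data.frame `enh_start, enh_end, gene, score`:
#'   each row connects the fragment containing the enhancer interval to the
#'   fragment containing the gene's promoter, at the given score.
#' @param n_background number of random background interactions.
#' @param background_score_range `c(min, max)` of uniform background scores.
#' @param seed integer seed.
#' @return an `annotation_spec`.
#' @export
annotation_spec <- function(chrom = "chrSim", length, cut_positions,
                            state_intervals = NULL, atac_peaks = NULL,
                            promoters = NULL, planted_interactions = NULL,
                            n_background = 0,
                            background_score_range = c(0, 5), seed = 1L) {
  cut_positions <- as.integer(cut_positions)
  if (is.unsorted(cut_positions, strictly = TRUE) ||
      any(cut_positions <= 0 | cut_positions >= length)) {
    stop("cut_positions must be strictly increasing within (0, length)")
  }
  check_iv <- function(df, what) {
    if (is.null(df) || !nrow(df)) return(invisible())
    if (any(df$start < 0 | df$end > length | df$start >= df$end)) {
      stop(sprintf("%s intervals must lie within [0, length)", what))
    }
  }
  check_iv(state_intervals, "state")
  check_iv(atac_peaks, "ATAC")
  if (!is.null(promoters) && nrow(promoters) &&
      any(promoters$start < 0 | promoters$end > length |
            promoters$start >= promoters$end)) {
    stop("promoter outside chromosome bounds")
  }
  structure(list(chrom = chrom, length = as.integer(length),
                 cut_positions = cut_positions,
                 state_intervals = state_intervals, atac_peaks = atac_peaks,
                 promoters = promoters,
                 planted_interactions = planted_interactions,
                 n_background = as.integer(n_background),
                 background_score_range = background_score_range,
                 seed = as.integer(seed)),
            class = "annotation_spec")
}

#' Generate annotation tracks with planted enhancer-promoter interactions
#'
#' Builds every input of the regulatory-annotation and variant-to-gene
#' stages from an [annotation_spec()]: the fragment map tiles `[0, length)`
#' between consecutive cut positions (fragment ids numbered from 0); each
#' planted interaction connects the fragment containing its enhancer
#' interval to the fragment containing the target gene's promoter at the
#' specified score; background interactions are drawn between random
#' distinct fragment pairs with uniform scores. The planted truth is
#' returned alongside the tracks.
#'
#' @param spec an [annotation_spec()].
#' @return list with `states`, `atac`, `fragments`, `promoters` (BED-style
#'   data.frames), `interactions` (`fragA, fragB, score`), and `truth`
#'   (data.frame `gene, enh_frag, prom_frag, score`).
#' @export
make_annotations <- function(spec) {
  stopifnot(inherits(spec, "annotation_spec"))
  bounds <- c(0L, spec$cut_positions, spec$length)
  fragments <- data.frame(
    chrom = spec$chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    name = seq_len(length(bounds) - 1L) - 1L,
    stringsAsFactors = FALSE
  )
  as_bed <- function(df, name_col = NULL) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character()))
    }
    out <- data.frame(chrom = spec$chrom, start = df$start, end = df$end,
                      stringsAsFactors = FALSE)
    if (!is.null(name_col)) out$name <- df[[name_col]]
    if ("source" %in% names(df)) out$source <- df$source
    out
  }
  states <- as_bed(spec$state_intervals, "name")
  atac <- as_bed(spec$atac_peaks)
  promoters <- as_bed(spec$promoters, "gene")
  mid_frag <- function(start, end) fragment_at(floor((start + end) / 2), fragments)
  planted <- spec$planted_interactions
  truth <- if (is.null(planted) || !nrow(planted)) {
    data.frame(gene = character(), enh_frag = integer(),
               prom_frag = integer(), score = numeric())
  } else {
    prom_idx <- match(planted$gene, spec$promoters$gene)
    if (anyNA(prom_idx)) stop("planted interaction targets an unknown gene")
    data.frame(
      gene = planted$gene,
      enh_frag = mapply(mid_frag, planted$enh_start, planted$enh_end),
      prom_frag = mapply(mid_frag, spec$promoters$start[prom_idx],
                         spec$promoters$end[prom_idx]),
      score = planted$score
    )
  }
  interactions <- data.frame(fragA = truth$enh_frag, fragB = truth$prom_frag,
                             score = truth$score)
  if (spec$n_background > 0) {
    with_seed(spec$seed, {
      fa <- sample(fragments$name, spec$n_background, replace = TRUE)
      shift <- sample(nrow(fragments) - 1L, spec$n_background, replace = TRUE)
      fb <- (fa + shift) %% nrow(fragments)
      sc <- stats::runif(spec$n_background,
                         spec$background_score_range[1],
                         spec$background_score_range[2])
    })
    interactions <- rbind(interactions,
                          data.frame(fragA = fa, fragB = fb, score = sc))
  }
  list(states = states, atac = atac, fragments = fragments,
       promoters = promoters, interactions = interactions, truth = truth)
}
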