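#' Parse a protein change string
#'
#' Splits notations like `"V600E"`, `"Q61*"` or `"G12fs"` into reference
#' residue, position and alternate. Unparseable strings are kept verbatim
#' with `NA` position.
#'
#' @param x character vector of protein changes.
#' @return data.frame `ref, pos, alt, raw`.
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^p?\\.?([A-Za-z*]+?)([0-9]+)([A-Za-z*=].*|)$", x))
  out <- data.frame(ref = NA_character_, pos = NA_integer_,
                    alt = NA_character_, raw = x, stringsAsFactors = FALSE)
  ok <- lengths(m) == 4
  out$ref[ok] <- vapply(m[ok], `[`, "", 2)
  out$pos[ok] <- as.integer(vapply(m[ok], `[`, "", 3))
  out$alt[ok] <- vapply(m[ok], `[`, "", 4)
  out
}

# Hotspot rule shared by the synthetic generator and Model 1: BRAF codon
# 600/601, NRAS codon 61/12/13 — matched by position only, any alternate.
hotspot_positions <- function() list(BRAF = c(600L, 601L),
                                     NRAS = c(61L, 12L, 13L))

is_hotspot <- function(gene, protein_change,
                       hotspots = hotspot_positions()) {
  if (!length(gene)) return(logical())
  pos <- parse_protein_change(protein_change)$pos
  unparse <- is.na(pos) & gene %in% names(hotspots)
  if (any(unparse)) {
    warning(sprintf("unparseable protein change on hotspot gene treated as non-hotspot: %s",
                    paste(unique(protein_change[unparse]), collapse = ", ")))
  }
  mapply(function(g, p) {
    !is.na(p) && g %in% names(hotspots) && p %in% hotspots[[g]]
  }, gene, pos, USE.NAMES = FALSE)
}

#' RAS-MAPK mutation-model specification
#'
#' Five nested models define the mutant subgroup: Model 1, hotspot
#' mutations only (BRAF codons 600/601; NRAS codons 61/12/13, matched by
#' position regardless of the alternate residue); Model 2, any
#' driver-flagged mutation in BRAF or NRAS; Model 3 adds KRAS and HRAS;
#' Model 4 adds NF1 (the "triple wild-type" boundary); Model 5, any
#' driver-flagged mutation in a configurable pathway gene panel (the full
#' panel of RAS-MAPK drivers is supplied by the user; a 10-gene stand-in
#' ships as the default for testing).
#'
#' @param id model number 1-5.
#' @param model5_genes gene panel for Model 5.
#' @return a `model_spec` list with `id`, `hotspots`, `genes`.
#' @export
model_spec <- function(id, model5_genes = default_model5_genes()) {
  stopifnot(id %in% 1:5)
  genes <- switch(id,
    NULL,                                         # Model 1: hotspots only
    c("BRAF", "NRAS"),
    c("BRAF", "NRAS", "KRAS", "HRAS"),
    c("BRAF", "NRAS", "KRAS", "HRAS", "NF1"),
    model5_genes)
  structure(list(id = as.integer(id), hotspots = hotspot_positions(),
                 genes = genes), class = "model_spec")
}

#' Default stand-in gene panel for Model 5
#'
#' Ten recurrently mutated RAS-MAPK pathway members, a small stand-in for
#' the full pan-cancer driver panel; supply the complete panel via
#' `model_spec(5, model5_genes = ...)` for real analyses.
#' @return character vector of gene symbols.
#' @export
default_model5_genes <- function() {
  c("BRAF", "NRAS", "KRAS", "HRAS", "NF1", "MAP2K1", "MAP2K2", "RAF1",
    "RASA2", "PTPN11")
}

#' Classify a sample as RAS-MAPK wild-type or mutant
#'
#' Model 1 calls a sample mutant when any mutation falls at a hotspot codon
#' of BRAF or NRAS. Models 2-5 call a sample mutant when any driver-flagged
#' mutation falls in the model's gene set restricted to the cohort's
#' assessed genes; samples with no qualifying mutation are wild-type over
#' the assessed genes (classification uses the sequencing data that exists,
#' so partially assessed cohorts still classify; set
#' `unassessable = "na"` to instead return `NA` for samples lacking
#' assessment of a model gene).
#'
#' @param mutations data.frame `gene, protein_change, driver_flag` for one
#'   sample (possibly empty).
#' @param model a [model_spec()].
#' @param assessed_genes genes actually sequenced in the cohort; `NULL`
#'   means all model genes were assessed.
#' @param unassessable `"wt"` (default) or `"na"`.
#' @return `"mutant"`, `"WT"`, or `NA` (unassessable).
#' @export
classify_sample <- function(mutations, model, assessed_genes = NULL,
                            unassessable = c("wt", "na")) {
  unassessable <- match.arg(unassessable)
  if (model$id == 1L) {
    mut <- nrow(mutations) > 0 &&
      any(is_hotspot(mutations$gene, mutations$protein_change,
                     model$hotspots))
    return(if (mut) "mutant" else "WT")
  }
  genes <- model$genes
  if (!is.null(assessed_genes)) genes <- intersect(genes, assessed_genes)
  mut <- nrow(mutations) > 0 &&
    any(mutations$gene %in% genes & mutations$driver_flag)
  if (mut) return("mutant")
  if (unassessable == "na" && !is.null(assessed_genes) &&
      !all(model$genes %in% assessed_genes)) return(NA_character_)
  "WT"
}

#' Classify every sample in a cohort
#'
#' @param cohort a `cohort` (see [make_cohort()] / [read_cohort()]).
#' @param model a [model_spec()].
#' @param assessed_genes,unassessable passed to [classify_sample()].
#' @return named character vector sample -> `"WT"` / `"mutant"` / `NA`.
#' @export
classify_cohort <- function(cohort, model, assessed_genes = NULL,
                            unassessable = "wt") {
  mut_by_sample <- split(cohort$mutations,
                         factor(cohort$mutations$sample,
                                levels = cohort$samples$sample))
  vapply(cohort$samples$sample, function(s) {
    classify_sample(mut_by_sample[[s]], model, assessed_genes, unassessable)
  }, "")
}
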