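test_that("chromatin states classify per the melanocytic vocabularies", {
  expect_equal(classify_state("EnhA1", "melanocyte"), "enhancer")
  expect_equal(classify_state("TssA", "melanocyte"), "promoter")
  expect_equal(classify_state("4_EnhA", "melanoma"), "enhancer")
  expect_equal(classify_state("2_PromWkD", "melanoma"), "promoter")
  expect_warning(out <- classify_state("Quies", "melanocyte"), "unknown")
  expect_equal(out, "other")
  # melanoma-only state names are not melanocyte states
  expect_warning(expect_equal(classify_state("1_TssA", "melanocyte"), "other"))
})

test_that("variant annotation uses half-open overlap and the OR rule", {
  states <- data.frame(chrom = "chr9", start = 100, end = 200,
                       name = "EnhA1", source = "melanocyte")
  atac <- data.frame(chrom = "chr9", start = 500, end = 600)
  v <- data.frame(id = c("inEnh", "atBoundary", "inPeak", "nowhere"),
                  chrom = "chr9", pos = c(150, 200, 550, 900))
  ann <- annotate_variants(v, states, atac)
  expect_true(ann$enhancer[1] && !ann$atac[1] && ann$cis_regulatory[1])
  expect_false(ann$cis_regulatory[2])        # 200 outside [100, 200)
  expect_true(!ann$enhancer[3] && ann$atac[3] && ann$cis_regulatory[3])
  expect_false(ann$cis_regulatory[4])
  expect_warning(
    off <- annotate_variants(
      data.frame(id = "x", chrom = "chrX", pos = 1), states, atac),
    "undeclared")
  expect_true(is.na(off$cis_regulatory))
})

test_that("variant windows pad and clamp correctly", {
  expect_equal(variant_window(10000), data.frame(start = 9500, end = 10501))
  expect_equal(variant_window(100), data.frame(start = 0, end = 601))
  expect_equal(variant_window(42, pad = 0), data.frame(start = 42, end = 43))
})

test_that("fragment lookup extends the overlapping run by its neighbors", {
  fr <- data.frame(chrom = "chr9", start = seq(0, 900, 100),
                   end = seq(100, 1000, 100), name = 0:9)
  # window inside fragment 7 ([700, 800))
  expect_equal(fragments_for(list(start = 720, end = 730), fr), c(6L, 7L, 8L))
  # window spanning fragments 3-4
  expect_equal(fragments_for(list(start = 350, end = 450), fr), 2:5)
  # overlapping run at the map edge
  expect_equal(fragments_for(list(start = 10, end = 20), fr), c(0L, 1L))
  expect_warning(out <- fragments_for(list(start = 5000, end = 5100), fr),
                 "fragment map")
  expect_equal(out, integer())
  # contiguity property over random windows
  set.seed(2)
  for (i in 1:25) {
    s <- sample(0:990, 1)
    ids <- fragments_for(list(start = s, end = s + sample(1:150, 1)), fr)
    expect_equal(ids, seq(min(ids), max(ids)))
  }
})

test_that("gene nomination applies the strict score rule symmetrically", {
  vf <- list(rs1 = c(3L, 4L, 5L))
  pf <- list(geneA = 10L, geneB = 12L)
  ints <- data.frame(fragA = c(4L, 12L), fragB = c(10L, 4L),
                     score = c(5.1, 5.0))
  got <- nominate_genes(vf, ints, pf)
  expect_equal(got$gene, "geneA")            # 5.1 > 5 passes, 5.0 does not
  expect_equal(got$variants, "rs1")
  # order of the pair does not matter
  flipped <- data.frame(fragA = 10L, fragB = 4L, score = 5.1)
  expect_equal(nominate_genes(vf, flipped, pf)$gene, "geneA")
  # duplicated rows keep the max score
  dup <- data.frame(fragA = c(4L, 4L), fragB = c(10L, 10L), score = c(4, 6))
  expect_equal(nominate_genes(vf, dup, pf)$gene, "geneA")
  # raising the threshold never adds candidates
  set.seed(5)
  many <- data.frame(fragA = sample(0:14, 40, TRUE),
                     fragB = sample(0:14, 40, TRUE),
                     score = runif(40, 0, 10))
  prev <- nominate_genes(vf, many, pf, score_min = 0)$gene
  for (smin in c(2, 5, 8)) {
    cur <- nominate_genes(vf, many, pf, score_min = smin)$gene
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("regulatory refinement upgrades supported candidates only", {
  cand <- data.frame(gene = c("gA", "gB"), variants = c("rs1,rs2", "rs3"),
                     evidence = "interaction_only", stringsAsFactors = FALSE)
  ann <- data.frame(id = c("rs1", "rs2", "rs3"),
                    enhancer = c(TRUE, FALSE, FALSE),
                    promoter = FALSE, atac = FALSE,
                    cis_regulatory = c(TRUE, FALSE, FALSE))
  ref <- refine_regulatory(cand, ann)
  expect_equal(ref$evidence, c("enhancer_promoter", "interaction_only"))
  expect_equal(nrow(refine_regulatory(cand[0, ], ann)), 0)
})

test_that("methylation probes assign by feature overlap or TSS distance", {
  gm <- data.frame(
    gene = c("g1", "g1", "g2"),
    feature = c("tss", "body", "body"),
    start = c(10000, 10200, 9800),
    end = c(10001, 12000, 10500))
  expect_equal(assign_probe_to_gene(10000 - 1499, gm), "g1")   # near TSS
  expect_equal(assign_probe_to_gene(10000 - 1501, gm), character())
  expect_setequal(assign_probe_to_gene(10300, gm), c("g1", "g2"))  # both bodies
})

test_that("merged fragment maps tile at coarser resolution", {
  fr <- data.frame(chrom = "chr9", start = seq(0, 900, 100),
                   end = seq(100, 1000, 100), name = 0:9)
  m4 <- merge_fragments(fr, k = 4)
  expect_equal(nrow(m4), 3)
  expect_equal(m4$start, c(0, 400, 800))
  expect_equal(m4$end, c(400, 800, 1000))
  expect_equal(m4$name, 0:2)
})

test_that("nomination recovers exactly the planted genes on clean tracks", {
  ann <- make_annotations(quick_annotations(n_background = 0))
  # variants sitting in each planted enhancer, one decoy elsewhere
  variants <- data.frame(id = c("rsA", "rsB", "rsDecoy"), chrom = "chrSim",
                         pos = c(1300, 5300, 7010))
  win <- variant_window(variants$pos)
  vf <- lapply(seq_len(nrow(variants)), function(i) {
    fragments_for(win[i, ], ann$fragments)
  })
  names(vf) <- variants$id
  pf <- promoter_fragments(ann$promoters, ann$fragments)
  cand <- nominate_genes(vf, ann$interactions, pf)
  va <- annotate_variants(variants, ann$states, ann$atac)
  cand <- refine_regulatory(cand, va)
  expect_setequal(cand$gene, ann$truth$gene)
  expect_equal(sort(cand$evidence), c("enhancer_promoter", "enhancer_promoter"))
})
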