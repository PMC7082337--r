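# CXXCH motif scanning, MHC classification, flags and cluster context.

test_that("motif scanner finds CXXCH occurrences at 0-based offsets", {
  expect_identical(scanHemeMotifs("MACAACHGG"), 2L)  # motif CAACH
  expect_identical(scanHemeMotifs("KKKKKK"), integer(0))
  # three planted non-adjacent motifs in a 60-residue sequence
  s <- paste0("MKLV", "CAACH", "GGGGGGG", "CDDCH", "LLLLLLLLLL",
              "CWWCH", "AAAAAAAAAAAAAAAAAAAAAAAA")
  expect_identical(scanHemeMotifs(s), oracleScanCXXCH(s))
  expect_length(scanHemeMotifs(s), 3L)
  # overlap: CXXCH starting where the previous H would be is still found
  s2 <- "CAACHAACH"  # offsets 0 and 4 share the C/H boundary residue? no:
  # only offset 0 matches here; oracle decides
  expect_identical(scanHemeMotifs(s2), oracleScanCXXCH(s2))
  expect_error(scanHemeMotifs("MAC1ACH"), "invalid residues")
  expect_error(scanHemeMotifs(""), "non-empty")
})

test_that("motif scanner equals the exhaustive window oracle on random
           sequences including motif-dense ones", {
  set.seed(42)
  alpha <- c("A", "C", "H", "G", "K", "L")  # C/H-rich to force motifs
  for (i in 1:500) {
    s <- paste(sample(alpha, sample(5:80, 1), replace = TRUE),
               collapse = "")
    expect_identical(scanHemeMotifs(s), oracleScanCXXCH(s))
  }
})

test_that("appending a motif never decreases the count", {
  set.seed(11)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "H", "G"), 30, replace = TRUE),
               collapse = "")
    expect_gte(length(scanHemeMotifs(paste0(s, "CAACH"))),
               length(scanHemeMotifs(s)) + 1L)
  }
})

test_that("MHC classification thresholds on motif count", {
  two <- "AAACAACHAAACAACHAAA"
  expect_identical(length(scanHemeMotifs(two)), 2L)
  expect_false(classifyMHC(two, "g1")$is_mhc)
  three <- paste0(two, "CAACH")
  expect_true(classifyMHC(three, "g2")$is_mhc)
  # giant MHC: 113 planted motifs
  set.seed(3)
  giant <- mnAOM:::.plantMotifs(113 * 7 + 20, 113)
  ann <- classifyMHC(giant$sequence, "g3")
  expect_identical(ann$heme_motif_count, 113L)
  expect_true(ann$is_mhc)
  expect_identical(as.integer(strsplit(ann$motif_positions, ",")[[1]]),
                   as.integer(giant$positions))
  # raising the threshold never adds MHCs
  expect_false(classifyMHC(three, "g4", minMotifs = 4)$is_mhc)
  expect_error(classifyMHC(three, "g5", minMotifs = 0), "minMotifs")
})

test_that("extracellular flag is inclusive OR of signal peptide and
           localization, and only for MHCs", {
  rowSP <- data.frame(signal_peptide = TRUE, localization = "unknown",
                      domains = "")
  rowNone <- data.frame(signal_peptide = FALSE,
                        localization = "cytoplasmic", domains = "")
  rowLoc <- data.frame(signal_peptide = FALSE,
                       localization = "extracellular", domains = "")
  expect_true(flagExtracellular(TRUE, rowSP))
  expect_true(flagExtracellular(TRUE, rowLoc))
  expect_false(flagExtracellular(TRUE, rowNone))
  expect_false(flagExtracellular(FALSE, rowSP))
  # gene missing from evidence: false + warning
  ev <- data.frame(gene_id = "other", signal_peptide = TRUE,
                   localization = "extracellular", domains = "")
  expect_warning(
    ann <- classifyMHC(paste0("CAACH", "CAACH", "CAACH"), "absent",
                       evidence = ev),
    "absent")
  expect_false(ann$is_extracellular_candidate)
  expect_true(ann$is_mhc)
})

test_that("S-layer fusion requires both MHC status and an S-layer domain", {
  withS <- data.frame(signal_peptide = FALSE, localization = "unknown",
                      domains = "Cytochrome_c;S-layer")
  without <- data.frame(signal_peptide = FALSE, localization = "unknown",
                        domains = "Cytochrome_c")
  expect_true(detectSlayerFusion(TRUE, withS))
  expect_false(detectSlayerFusion(TRUE, without))
  expect_false(detectSlayerFusion(FALSE, withS))
})

test_that("cluster context window counts genes on the same contig", {
  mkGenes <- function(n, mhcAt, oxrAt) {
    data.frame(gene_id = sprintf("g%02d", 1:n), contig = "c1",
               start = (1:n) * 1000, end = (1:n) * 1000 + 500,
               strand = "+",
               label = ifelse(1:n %in% oxrAt, "b-type cytochrome",
                              "hypothetical"))
  }
  ann <- data.frame(gene_id = "g01", is_mhc = TRUE,
                    cluster_context = "standalone")
  # adjacent oxidoreductase gene
  out <- annotateClusterContext(ann, mkGenes(10, 1, 2))
  expect_identical(out$cluster_context, "oxidoreductase-cluster")
  # alone on the contig
  out2 <- annotateClusterContext(ann, mkGenes(10, 1, integer(0)))
  expect_identical(out2$cluster_context, "standalone")
  # 6 genes away: outside window 5, inside window 7
  out3 <- annotateClusterContext(ann, mkGenes(10, 1, 7), window = 5)
  expect_identical(out3$cluster_context, "standalone")
  out4 <- annotateClusterContext(ann, mkGenes(10, 1, 7), window = 7)
  expect_identical(out4$cluster_context, "oxidoreductase-cluster")
  # different contig neighbours do not count
  g <- mkGenes(10, 1, 2)
  g$contig[2] <- "c2"
  expect_identical(annotateClusterContext(ann, g)$cluster_context,
                   "standalone")
  # missing coordinates: standalone with warning
  expect_warning(
    out5 <- annotateClusterContext(ann, mkGenes(10, 1, 2)[-1, ]),
    "missing coordinates")
  expect_identical(out5$cluster_context, "standalone")
})

test_that("screen recovers planted truth exactly on a synthetic genome", {
  sim <- simulateProteome(nProteins = 40, nMhc = 10,
                          hemeCounts = c(3:10, 22, 113),
                          fractionExtracellular = 0.4, nSlayer = 2,
                          nClustered = 5, seed = 17)
  rep <- screenGenome(sim$proteins, sim$evidence, sim$genes,
                      genomeId = "sim")
  ann <- annotations(rep)
  expect_identical(ann$is_mhc, sim$truth$is_mhc)
  expect_identical(ann$heme_motif_count[ann$is_mhc],
                   as.integer(sim$truth$heme_count[sim$truth$is_mhc]))
  expect_identical(ann$is_extracellular_candidate, sim$truth$extracellular)
  expect_identical(ann$is_slayer_fusion, sim$truth$slayer)
  expect_identical(ann$cluster_context[ann$is_mhc],
                   sim$truth$cluster_context[sim$truth$is_mhc])
  s <- screenSummary(rep)
  expect_identical(s$n_mhc, 10L)
  expect_identical(s$n_extracellular, 4L)
  expect_identical(s$n_slayer_fusion, 2L)
  expect_identical(s$n_oxidoreductase_cluster, 5L)
})

test_that("screen handles degenerate proteomes", {
  # cysteine-free proteome: all-zero report
  rep <- screenGenome(c(a = "MKLGAD", b = "WWWW"), genomeId = "null")
  expect_identical(screenSummary(rep)$n_mhc, 0L)
  expect_identical(sum(annotations(rep)$heme_motif_count), 0L)
  # empty proteome: empty report, not an error
  rep0 <- screenGenome(setNames(character(0), character(0)))
  expect_identical(nrow(annotations(rep0)), 0L)
  # duplicate gene ids violate the invariant
  expect_error(screenGenome(c(x = "MAAA", x = "MCCC")), "duplicate")
})
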