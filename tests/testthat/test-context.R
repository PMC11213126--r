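test_that("rank-sum position test reproduces exact small-sample p-values", {
  out <- peakPositionTest(c(1, 2, 3), c(11, 12, 13))
  expect_equal(out$p.value, 0.1)
  expect_equal(peakPositionTest(c(4, 8, 15), c(4, 8, 15))$p.value, 1)
  expect_error(peakPositionTest(numeric(0), 1:3), "nonempty")
})

test_that("context windows truncate at protein ends and score the stop", {
  # one gene, handcrafted: 30 sense codons + stop = 31 codons
  aa <- paste0("M", paste(rep("A", 29), collapse = ""), "*")
  gm <- new("GeneModelSet",
            genes = S4Vectors::DataFrame(
              gene_id = "g1", chrom = "c1", strand = "+",
              cds_start = 1L, cds_end = 93L, n_segments = 1L,
              length_codons = 31L, eligible = TRUE, reason = ""),
            aa = Biostrings::AAStringSet(c(g1 = aa)))
  # peak at codon 15: all 21 offsets inside the protein
  ctx <- extractContexts(data.frame(gene_id = "g1", codon = 15), gm)
  expect_false(anyNA(ctx))
  # peak at codon 25: offsets +6..+10 reach codons 31..35; 31 is the stop,
  # 32..35 are absent
  ctx <- extractContexts(data.frame(gene_id = "g1", codon = 25), gm)
  expect_equal(unname(ctx[1, "6"]), "*")
  expect_true(all(is.na(ctx[1, c("7", "8", "9", "10")])))
  # P-site residue lands at offset 0
  ctx <- extractContexts(data.frame(gene_id = "g1", codon = 1), gm)
  expect_equal(unname(ctx[1, "0"]), "M")
  expect_true(all(is.na(ctx[1, as.character(-10:-1)])))
  expect_error(extractContexts(data.frame(gene_id = "g1", codon = 40), gm),
               "outside")
})

test_that("the P-site residue reflects the genetic code of the peak codon", {
  cfg <- simConfig(nGenes = 20, pauseFraction = 0.5,
                   motifSpec = list("0" = "K"), seed = 51)
  sim <- simulateTranscriptome(cfg)
  pp <- plantedPauses(sim$truth)
  ctx <- extractContexts(as.data.frame(pp)[c("gene_id", "codon")],
                         sim$genes)
  expect_true(all(ctx[, "0"] == "K"))
})

test_that("context matrices count symbols per position with shrinking totals", {
  ctx <- rbind(c(NA, "K", "E"), c("M", "K", "*"), c(NA, "N", "E"))
  colnames(ctx) <- c("-1", "0", "1")
  cm <- contextMatrix(ctx)
  expect_equal(unname(contextTotals(cm)), c(1L, 3L, 3L))
  expect_equal(unname(contextCounts(cm)["K", "0"]), 2L)
  expect_equal(unname(contextCounts(cm)["*", "1"]), 1L)
  # frequencies sum to 1 over symbols wherever peaks contribute
  f <- contextFreq(cm)
  expect_equal(unname(colSums(f)), c(1, 1, 1))
})

test_that("context enrichment is null on identical matrices and antisymmetric", {
  set.seed(52)
  cfg <- simConfig(nGenes = 60, pauseFraction = 0.5, seed = 52)
  sim <- simulateTranscriptome(cfg)
  g <- as.data.frame(geneTable(sim$genes))
  rnd <- data.frame(
    gene_id = sample(g$gene_id, 80, replace = TRUE))
  rnd$codon <- vapply(rnd$gene_id, function(id) {
    L <- g$length_codons[match(id, g$gene_id)]
    sample(seq(21L, L - 20L), 1L)
  }, integer(1))
  mA <- contextMatrix(extractContexts(rnd, sim$genes))
  enr <- contextEnrichment(mA, mA)
  expect_true(all(abs(enr$p - 1) < 1e-9))
  expect_false(any(enr$significant))

  rnd2 <- rnd; rnd2$codon <- pmax(21L, rnd$codon - 3L)
  mB <- contextMatrix(extractContexts(rnd2, sim$genes))
  ab <- contextEnrichment(mA, mB)
  ba <- contextEnrichment(mB, mA)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$q, ba$q, tolerance = 1e-12)
  expect_equal(ab$log2fd, -ba$log2fd, tolerance = 1e-12)
})

test_that("cell-level Fisher p equals the hypergeometric enumeration oracle", {
  set.seed(53)
  cfg <- simConfig(nGenes = 40, pauseFraction = 0.5, seed = 53)
  sim <- simulateTranscriptome(cfg)
  g <- as.data.frame(geneTable(sim$genes))
  draw <- function(n) {
    d <- data.frame(gene_id = sample(g$gene_id, n, replace = TRUE))
    d$codon <- vapply(d$gene_id, function(id) {
      L <- g$length_codons[match(id, g$gene_id)]
      sample(seq(21L, L - 20L), 1L)
    }, integer(1))
    d
  }
  mA <- contextMatrix(extractContexts(draw(50), sim$genes))
  mB <- contextMatrix(extractContexts(draw(60), sim$genes))
  enr <- contextEnrichment(mB, mA)
  idx <- sample(nrow(enr), 40)
  pOracle <- vapply(idx, function(i)
    fisherOracle(enr$count_b[i], enr$total_b[i],
                 enr$count_a[i], enr$total_a[i]), numeric(1))
  expect_equal(enr$p[idx], pOracle, tolerance = 1e-12)
})
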