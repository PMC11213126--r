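pad <- function(n) paste(rep("ACGT", ceiling(n / 4)), collapse = "") |>
  substr(1, n)

test_that("gene eligibility rules: ATG start, introns, frame, internal stops", {
  cdsA <- "ATGAAAGAATTTCCCGGGTAA"             # M K E F P G *
  cdsC <- sub("^ATG", "GTG", cdsA)            # no annotated ATG
  cdsE <- "ATGAAAGAATTTCCCGGTA"               # length 19, not multiple of 3
  cdsF <- "ATGAAATAATTTCCCGGGTAA"             # internal stop at codon 3
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seqs <- list(
    chr1 = paste0(pad(100), cdsA, pad(100)),
    chr2 = paste0(pad(100), "ATGAAA", pad(10), "GAATTTCCCGGGTAA", pad(100)),
    chr3 = paste0(pad(100), cdsC, pad(100)),
    chr4 = paste0(pad(100), rc(cdsA), pad(100)),
    chr5 = paste0(pad(100), cdsE, pad(100)),
    chr6 = paste0(pad(100), cdsF, pad(100)))
  fa <- writeTinyGenome(seqs)
  feats <- list(
    list(chrom = "chr1", type = "CDS", start = 101, end = 121,
         strand = "+", attr = "ID=gA.cds;Parent=gA"),
    list(chrom = "chr2", type = "CDS", start = 101, end = 106,
         strand = "+", attr = "ID=gB.cds1;Parent=gB"),
    list(chrom = "chr2", type = "CDS", start = 117, end = 131,
         strand = "+", attr = "ID=gB.cds2;Parent=gB"),
    list(chrom = "chr3", type = "CDS", start = 101, end = 121,
         strand = "+", attr = "ID=gC.cds;Parent=gC"),
    list(chrom = "chr4", type = "CDS", start = 101, end = 121,
         strand = "-", attr = "ID=gD.cds;Parent=gD"),
    list(chrom = "chr5", type = "CDS", start = 101, end = 119,
         strand = "+", attr = "ID=gE.cds;Parent=gE"),
    list(chrom = "chr6", type = "CDS", start = 101, end = 121,
         strand = "+", attr = "ID=gF.cds;Parent=gF"))
  gm <- loadGenes(fa, writeTinyGff(feats))
  g <- geneTable(gm)
  expect_equal(g$eligible[match(c("gA", "gB", "gC", "gD", "gE", "gF"),
                                g$gene_id)],
               c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(g$reason[match("gB", g$gene_id)], "introns")
  expect_equal(g$reason[match("gC", g$gene_id)], "no_atg")
  expect_equal(g$reason[match("gE", g$gene_id)], "length_not_multiple_of_3")
  expect_equal(g$reason[match("gF", g$gene_id)], "internal_stop")
  # minus-strand translation equals the plus-strand one
  aa <- as.character(aaSequences(gm))
  expect_equal(aa[["gD"]], aa[["gA"]])
  expect_equal(aa[["gA"]], "MKEFPG*")
  # missing chromosome is an error
  feats[[1]]$chrom <- "chrMissing"
  expect_error(loadGenes(fa, writeTinyGff(feats)), "missing sequence")
})

test_that("P-site offsetting follows the strand convention", {
  rd <- function(strand, pos) data.frame(sample = "s", chrom = "c",
                                         pos5 = pos, strand = strand)
  expect_equal(assignPSites(rd("+", 100), offset = 12)$psite, 112)
  expect_equal(assignPSites(rd("-", 500), offset = 12)$psite, 488)
  expect_equal(assignPSites(rd("+", 77), offset = 0)$psite, 77)
  # out-of-bounds P-sites are dropped and tallied
  out <- assignPSites(rd("-", 5), offset = 12)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped"), 1)
})

test_that("P-site to codon mapping handles the ATG, flanks and exclusion edges", {
  cfg <- simConfig(nGenes = 6, cdsLengthRange = c(50, 60), seed = 21)
  sim <- simulateTranscriptome(cfg)
  g <- as.data.frame(geneTable(sim$genes))
  gp <- g[g$strand == "+", ][1, ]
  gn <- g[g$strand == "-", ][1, ]
  mk <- function(gene, psites) data.frame(
    sample = "s", chrom = gene$chrom, psite = psites,
    strand = gene$strand, count = 1L)
  # plus strand: first and third nt of ATG -> codon 1; -72 nt -> codon -24;
  # -73 nt excluded
  ps <- mk(gp, c(gp$cds_start, gp$cds_start + 2, gp$cds_start - 72,
                 gp$cds_start - 73))
  pr <- codonProfiles(ps, sim$genes)
  m <- profileMatrix(pr, gp$gene_id)
  expect_equal(unname(m["1", 1]), 2)
  expect_equal(unname(m["-24", 1]), 1)
  expect_equal(sum(m), 3)
  expect_equal(unname(pr@outOfWindow["s"]), 1)
  # minus strand mirror: biological first nt of ATG is cds_end
  ps <- mk(gn, c(gn$cds_end, gn$cds_end - 2, gn$cds_end + 72,
                 gn$cds_end + 73))
  pr <- codonProfiles(ps, sim$genes)
  m <- profileMatrix(pr, gn$gene_id)
  expect_equal(unname(m["1", 1]), 2)
  expect_equal(unname(m["-24", 1]), 1)
  expect_equal(sum(m), 3)
})

test_that("profiles are invariant under genome reverse-complementation", {
  cfg <- simConfig(nGenes = 5, depth = 3000, seed = 22)
  sim <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(sim, cfg, strains = "euploid", phases = "log")
  ps <- assignPSites(fp$reads)
  pr1 <- codonProfiles(ps, sim$genes, samples = fp$samples)

  w <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  g2 <- geneTable(sim$genes)
  newStart <- w[g2$chrom] - g2$cds_end + 1L
  newEnd <- w[g2$chrom] - g2$cds_start + 1L
  g2$cds_start <- unname(newStart); g2$cds_end <- unname(newEnd)
  g2$strand <- ifelse(g2$strand == "+", "-", "+")
  gm2 <- new("GeneModelSet", genes = g2, aa = aaSequences(sim$genes))
  ps2 <- ps
  ps2$psite <- w[ps$chrom] - ps$psite + 1L
  ps2$strand <- ifelse(ps$strand == "+", "-", "+")
  pr2 <- codonProfiles(ps2, gm2, samples = fp$samples)
  for (g in geneIds(sim$genes))
    expect_equal(profileMatrix(pr2, g), profileMatrix(pr1, g))
})

test_that("gene-body filter boundary is inclusive and joint across samples", {
  cfg <- simConfig(nGenes = 3, cdsLengthRange = c(60, 70), seed = 23)
  sim <- simulateTranscriptome(cfg)
  g <- as.data.frame(geneTable(sim$genes))[1, ]
  pos21 <- if (g$strand == "+") g$cds_start + 60 else g$cds_end - 60
  mk <- function(n, sample) data.frame(sample = sample, chrom = g$chrom,
                                       psite = pos21, strand = g$strand,
                                       count = n)
  samples <- S4Vectors::DataFrame(sample_id = c("s1", "s2"),
                                  row.names = c("s1", "s2"))
  pr <- codonProfiles(rbind(mk(50, "s1"), mk(50, "s2")), sim$genes,
                      samples = samples)
  expect_true(g$gene_id %in%
                filterGenes(pr, 50)@geneInfo$gene_id)       # 50 retained
  pr49 <- codonProfiles(rbind(mk(49, "s1"), mk(50, "s2")), sim$genes,
                        samples = samples)
  expect_error(filterGenes(pr49, 50), "filter")  # joint: fails in s1
  # passes when only s2 is required
  expect_true(g$gene_id %in%
                filterGenes(pr49, 50, samples = "s2")@geneInfo$gene_id)
})

test_that("raising the body-read threshold never adds genes", {
  cfg <- simConfig(nGenes = 30, depth = 2e4, seed = 24)
  sim <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(sim, cfg, strains = "euploid", phases = "log")
  pr <- codonProfiles(assignPSites(fp$reads), sim$genes,
                      samples = fp$samples)
  prev <- geneIds(sim$genes)
  for (thr in c(10, 50, 100, 200)) {
    kept <- tryCatch(filterGenes(pr, thr)@geneInfo$gene_id,
                     error = function(e) character(0))
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("frame fractions detect uniform placement and rotate under +1 shifts", {
  cfg <- simConfig(nGenes = 4, cdsLengthRange = c(100, 120), seed = 25)
  sim <- simulateTranscriptome(cfg)
  g <- as.data.frame(geneTable(sim$genes))
  gp <- g[g$strand == "+", ][1, ]
  set.seed(1)
  nt <- sample(seq(gp$cds_start, gp$cds_end), 3000, replace = TRUE)
  ps <- data.frame(sample = "s", chrom = gp$chrom, psite = nt,
                   strand = "+", count = 1L)
  fr <- frameReport(ps, sim$genes)
  expect_true(all(abs(fr - 1 / 3) < 0.05))
  ps1 <- ps; ps1$psite <- ps1$psite + 1L
  ps1 <- ps1[ps1$psite <= gp$cds_end, ]
  fr1 <- frameReport(ps1, sim$genes)
  frShifted <- frameReport(ps[ps$psite + 1 <= gp$cds_end, ], sim$genes)
  expect_equal(unname(fr1[1, ]),
               unname(frShifted[1, c("f2", "f0", "f1")]))
  expect_error(frameReport(ps[0, ], sim$genes), "P-sites")
})
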