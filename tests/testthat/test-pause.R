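test_that("degenerate and balanced Fisher tables give p = 1", {
  expect_equal(fisherCodonTest(5, 100, 5, 100), 1)
  expect_equal(fisherCodonTest(0, 100, 0, 100), 1)
  expect_true(is.na(fisherCodonTest(0, 0, 3, 100)))
  expect_error(fisherCodonTest(10, 5, 0, 5), "exceed")
})

test_that("Fisher p-values agree with stats::fisher.test on random tables", {
  tabs <- randomTables(200, 120, seed = 41)
  p <- fisherCodonTest(tabs$c1, tabs$b1, tabs$c2, tabs$b2)
  pref <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$c1[i], tabs$b1[i] - tabs$c1[i],
                  tabs$c2[i], tabs$b2[i] - tabs$c2[i]),
                2, 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  expect_equal(p, pref, tolerance = 1e-12)
})

test_that("Fisher p-values are invariant to row swap and column flip", {
  tabs <- randomTables(100, 80, seed = 42)
  p <- fisherCodonTest(tabs$c1, tabs$b1, tabs$c2, tabs$b2)
  pSwap <- fisherCodonTest(tabs$c2, tabs$b2, tabs$c1, tabs$b1)
  pFlip <- fisherCodonTest(tabs$b1 - tabs$c1, tabs$b1,
                           tabs$b2 - tabs$c2, tabs$b2)
  expect_equal(p, pSwap, tolerance = 1e-12)
  expect_equal(p, pFlip, tolerance = 1e-12)
})

test_that("BH adjustment matches the direct formula and handles edge cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:25) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bhNaive(p))
  }
  # q >= p always
  p <- runif(100)
  expect_true(all(bhAdjust(p) >= p - 1e-15))
})

test_that("peak calling recovers direction from truth and drops ties", {
  cfg <- simConfig(nGenes = 30, depth = 5e4, pauseFraction = 0.4, seed = 44)
  peaks <- quiescentPairPeaks(cfg)
  sim <- simulateTranscriptome(cfg)
  pp <- as.data.frame(plantedPauses(sim$truth))
  hit <- merge(as.data.frame(peaks), pp,
               by.x = c("gene_id", "codon"), by.y = c("gene_id", "codon"))
  expect_gt(nrow(hit), 0)
  # every recovered planted peak points at the aneuploid (sample_b)
  expect_true(all(hit$direction == "b_higher"))
  expect_true(all(peaks$q >= peaks$p - 1e-15))
  # direction consistent with the normalized ratio
  expect_true(all((peaks$normalized_ratio > 1) ==
                    (peaks$direction == "b_higher")))
})

test_that("alpha is validated and the tie rule drops undirected peaks", {
  cfg <- simConfig(nGenes = 5, depth = 2000, seed = 45)
  sim <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(sim, cfg, phases = "quiescent")
  pr <- codonProfiles(assignPSites(fp$reads), sim$genes,
                      samples = fp$samples)
  flt <- filterGenes(pr, 1)
  pairing <- data.frame(sample_a = "euploid_quiescent_rep1",
                        sample_b = "aneuploid_quiescent_rep1", pair = "x")
  expect_error(callPeaks(flt, pairing, alpha = 1), "alpha")
  expect_error(callPeaks(flt, pairing, alpha = 0), "alpha")
  all <- callPeaks(flt, pairing, returnAll = TRUE)
  # equal occupancy yields no direction
  ties <- all[all$occ_a == all$occ_b, ]
  expect_true(all(is.na(ties$direction)))
  expect_true(all(!ties$peak))
})

test_that("replicate combination is a direction-aware union with conflict exclusion", {
  mk <- function(pair, gene, codon, dir)
    S4Vectors::DataFrame(pair = pair, gene_id = gene, codon = codon,
                         direction = dir)
  peaks <- rbind(
    mk("r1", "gA", 10L, "b_higher"),     # rep1 only -> kept
    mk("r1", "gA", 30L, "a_higher"),
    mk("r2", "gA", 30L, "a_higher"),     # both reps same direction
    mk("r1", "gB", 5L, "b_higher"),
    mk("r2", "gB", 5L, "a_higher"),      # conflict -> excluded
    mk("r2", "gC", 7L, "a_higher"),
    mk("r2", "gC", 9L, "a_higher"))
  cmb <- combineReplicates(peaks)
  expect_equal(nrow(cmb$sites), 4)
  expect_equal(nrow(cmb$conflicts), 1)
  expect_equal(cmb$conflicts$gene_id, "gB")
  s <- cmb$summary
  expect_equal(s$n_sites[s$direction == "a_higher"], 3L)
  expect_equal(s$n_sites[s$direction == "b_higher"], 1L)
  # gC has two sites but is one transcript
  expect_equal(s$n_transcripts[s$direction == "a_higher"], 2L)
  # disjoint sets of sizes 3 and 4 combine to 7
  d1 <- mk("r1", paste0("g", 1:3), c(1L, 2L, 3L), "b_higher")
  d2 <- mk("r2", paste0("g", 4:7), c(1L, 2L, 3L, 4L), "b_higher")
  expect_equal(nrow(combineReplicates(rbind(d1, d2))$sites), 7)
})
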