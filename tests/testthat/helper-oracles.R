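# Independent reference implementations used as oracles.

# Exhaustive two-sided Fisher p for [[c1, b1-c1], [c2, b2-c2]]: enumerate the
# full hypergeometric support via lchoose and sum every table probability not
# exceeding the observed one (same relative tie tolerance as fisher.test,
# needed because mathematically equal tail masses differ in the last ulp).
fisherOracle <- function(c1, b1, c2, b2) {
  s <- c1 + c2
  ks <- max(0, s - b2):min(s, b1)
  logp <- lchoose(b1, ks) + lchoose(b2, s - ks) - lchoose(b1 + b2, s)
  p <- exp(logp)
  pObs <- p[ks == c1]
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# Naive two-loop Benjamini-Hochberg step-up.
bhNaive <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    qs[i] <- min(1, best)
  }
  out <- numeric(m)
  out[ord] <- qs
  out
}

randomTables <- function(n, maxMargin, seed) {
  set.seed(seed)
  b1 <- sample.int(maxMargin, n, replace = TRUE)
  b2 <- sample.int(maxMargin, n, replace = TRUE)
  c1 <- vapply(b1, function(b) sample.int(b + 1L, 1L) - 1L, integer(1))
  c2 <- vapply(b2, function(b) sample.int(b + 1L, 1L) - 1L, integer(1))
  data.frame(c1 = c1, b1 = b1, c2 = c2, b2 = b2)
}

# Hand-written FASTA + GFF3 for ingestion tests, bypassing the package's
# own writers.
writeTinyGenome <- function(seqs, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "g.fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  fa
}

writeTinyGff <- function(features, dir = dirname(fa), fa = NULL) {
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             vapply(features, function(f)
               paste(f$chrom, "test", f$type, f$start, f$end, ".",
                     f$strand, ".", f$attr, sep = "\t"),
               character(1)))
  writeLines(lines, gff)
  gff
}

# One euploid/aneuploid quiescent pair pipeline at a given seed; returns the
# number of peaks called (for null-calibration sweeps).
quiescentPairPeaks <- function(cfg, alpha = 0.05) {
  sim <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(sim, cfg, phases = "quiescent")
  ps <- assignPSites(fp$reads)
  pr <- codonProfiles(ps, sim$genes, samples = fp$samples)
  peaks <- lapply(seq_len(cfg@nReplicates), function(r) {
    sa <- sprintf("euploid_quiescent_rep%d", r)
    sb <- sprintf("aneuploid_quiescent_rep%d", r)
    flt <- filterGenes(pr, 50, samples = c(sa, sb))
    callPeaks(flt, data.frame(sample_a = sa, sample_b = sb,
                              pair = paste0("rep", r)), alpha = alpha)
  })
  do.call(rbind, peaks)
}
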