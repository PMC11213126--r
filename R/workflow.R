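#' @include pause.R context.R
NULL

#' Run the ribosome-profiling pipeline end to end on synthetic data
#'
#' Simulates a transcriptome and footprints under `config`, then chains the
#' full analysis: P-site assignment, codon profiling, frame QC, per-pair
#' gene-body filtering, peak calling with replicate combination per phase,
#' occupancy-trace correlations, the peak position test and the amino-acid
#' context comparison for the quiescent phase. Deterministic given the
#' config (including its seed). In all pairings `sample_a` is the euploid
#' and `sample_b` the aneuploid member, so direction `b_higher` reads
#' "aneuploid-higher".
#'
#' @param config a [RiboSimConfig-class].
#' @param alpha FDR threshold for peaks and context cells, default 0.05.
#' @param minBodyReads gene-body retention threshold, default 50.
#' @param psiteOffset P-site offset in nt, default 12.
#' @param window context half-width in codons, default 10.
#' @return list with elements `genes`, `truth`, `samples`, `frames`,
#'   `correlations`, `peaks` (per phase), `combined` (per phase),
#'   `retained` (genes passing the filter per pair), `positionTest`,
#'   `context` (enrichment table or NULL), `summary` (per-direction site
#'   and transcript tallies per phase) and `config`.
#' @export
runRiboPipeline <- function(config, alpha = 0.05, minBodyReads = 50,
                            psiteOffset = 12L, window = 10L) {
  sim <- simulateTranscriptome(config)
  fp <- simulateFootprints(sim, config, psiteOffset = psiteOffset)
  ps <- assignPSites(fp$reads, offset = psiteOffset)
  profiles <- codonProfiles(ps, sim$genes, samples = fp$samples)
  frames <- frameReport(ps, sim$genes)

  phases <- unique(fp$samples$phase)
  peaks <- list(); combined <- list(); corrs <- list()
  retained <- list(); summaries <- list()
  for (ph in phases) {
    reps <- sort(unique(fp$samples$replicate[fp$samples$phase == ph]))
    phPeaks <- list(); phCorrs <- list()
    for (r in reps) {
      sa <- fp$samples$sample_id[fp$samples$strain == "euploid" &
                                   fp$samples$phase == ph &
                                   fp$samples$replicate == r]
      sb <- fp$samples$sample_id[fp$samples$strain == "aneuploid" &
                                   fp$samples$phase == ph &
                                   fp$samples$replicate == r]
      flt <- filterGenes(profiles, minBodyReads, samples = c(sa, sb))
      retained[[paste0(ph, "_rep", r)]] <- flt@geneInfo$gene_id
      pairing <- data.frame(sample_a = sa, sample_b = sb,
                            pair = paste0(ph, "_rep", r),
                            phase = ph, replicate = r)
      phPeaks[[r]] <- callPeaks(flt, pairing, alpha = alpha)
      phCorrs[[r]] <- correlationTable(
        suppressMessages(normalizeProfiles(flt)), pairing)
    }
    pk <- do.call(rbind, phPeaks)
    peaks[[ph]] <- pk
    combined[[ph]] <- combineReplicates(pk)
    corrs[[ph]] <- do.call(rbind, phCorrs)
    summaries[[ph]] <- cbind(phase = ph, combined[[ph]]$summary)
  }
  correlations <- do.call(rbind, corrs)

  context <- NULL; positionTest <- NULL
  qs <- combined[["quiescent"]]$sites
  if (!is.null(qs)) {
    an <- qs[qs$direction == "b_higher", , drop = FALSE]
    eu <- qs[qs$direction == "a_higher", , drop = FALSE]
    if (nrow(an) && nrow(eu)) {
      positionTest <- peakPositionTest(an$codon, eu$codon)
      mAn <- contextMatrix(extractContexts(an, sim$genes, window))
      mEu <- contextMatrix(extractContexts(eu, sim$genes, window))
      context <- contextEnrichment(mAn, mEu, alpha = alpha)
    }
  }

  list(genes = sim$genes, truth = sim$truth, samples = fp$samples,
       frames = frames, correlations = correlations, peaks = peaks,
       combined = combined, retained = retained,
       positionTest = positionTest, context = context,
       summary = do.call(rbind, summaries), config = config)
}

#' Score a pipeline run against its simulation truth
#'
#' Parameter-recovery metrics: sensitivity of pause detection (planted
#' pauses recovered among the combined quiescent aneuploid-higher sites,
#' restricted to planted genes that passed the read filter in at least one
#' replicate pair), the realized false-direction rate among recovered
#' planted sites, the count of called sites that were never planted, and --
#' when the run produced a context comparison -- how many of the planted
#' motif cells were recovered as significantly enriched.
#'
#' @param truth the [SimTruth-class] the data were simulated under.
#' @param result the matching [runRiboPipeline()] result.
#' @return list of recovery metrics (all computed, `NA` where undefined,
#'   e.g. sensitivity under a null simulation with no planted pauses).
#' @export
recoveryReport <- function(truth, result) {
  if (!identical(truth@seed, result$truth@seed))
    stop("truth and result come from different runs (seed mismatch)")
  sites <- result$combined[["quiescent"]]$sites
  called <- paste(sites$gene_id, sites$codon)
  calledDir <- setNames(sites$direction, called)

  pp <- truth@pauses
  filtered <- unique(unlist(result$retained[grep("^quiescent",
                                                 names(result$retained))]))
  out <- list()
  if (nrow(pp)) {
    assayable <- pp$gene_id %in% filtered
    key <- paste(pp$gene_id, pp$codon)[assayable]
    found <- key %in% called
    rightDir <- found & calledDir[key] == "b_higher"
    out$n_planted <- nrow(pp)
    out$n_assayable <- sum(assayable)
    out$sensitivity <- if (any(assayable)) mean(rightDir) else NA_real_
    out$direction_errors <- sum(found & !rightDir)
    out$false_sites <- sum(!(called %in% paste(pp$gene_id, pp$codon)) &
                             calledDir == "b_higher")
  } else {
    out$n_planted <- 0L
    out$sensitivity <- NA_real_
    out$direction_errors <- 0L
    out$false_sites <- length(called)
  }

  if (!is.null(result$context) && length(truth@motifSpec)) {
    expCells <- do.call(rbind, lapply(names(truth@motifSpec), function(o)
      data.frame(symbol = truth@motifSpec[[o]],
                 position = as.integer(o))))
    ctx <- result$context
    sigPos <- ctx[ctx$significant & ctx$log2fd > 0, , drop = FALSE]
    hit <- paste(expCells$symbol, expCells$position) %in%
      paste(sigPos$symbol, sigPos$position)
    out$motif_cells_expected <- nrow(expCells)
    out$motif_cells_recovered <- sum(hit)
    out$motif_cells_extra_positive <-
      sum(!(paste(sigPos$symbol, sigPos$position) %in%
              paste(expCells$symbol, expCells$position)))
  }
  out
}
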