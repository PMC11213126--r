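#' @include sim-transcriptome.R
NULL

#' Simulate ribosome-footprint read starts
#'
#' Draws per-gene footprint totals from a negative binomial around
#' `depth * relExpr`, places them multinomially over the gene's codons with
#' weight 1 everywhere except planted pause codons -- which receive weight
#' `amplitude` only in samples matching the pause's enhanced strain and phase
#' -- and emits read 5' ends such that 5' + 12 nt is the first nucleotide of
#' the occupied codon (all reads frame 0). Rows with identical coordinates
#' are aggregated in a `count` column.
#'
#' @param sim result of [simulateTranscriptome()].
#' @param config the same [RiboSimConfig-class] used for the transcriptome.
#' @param strains,phases condition labels; samples are every combination of
#'   strain, phase and replicate `1..nReplicates`.
#' @param psiteOffset nt from the read 5' end to the P-site (default 12).
#' @return list with `reads` (data.frame: `sample`, `chrom`, `pos5`,
#'   `strand`, `read_length`, `count`), `samples`
#'   ([S4Vectors::DataFrame]: `sample_id`, `strain`, `phase`, `replicate`)
#'   and `truth` (the input truth, unchanged).
#' @examples
#' cfg <- simConfig(nGenes = 10, depth = 2000, seed = 3)
#' fp <- simulateFootprints(simulateTranscriptome(cfg), cfg)
#' head(fp$reads)
#' @export
simulateFootprints <- function(sim, config,
                               strains = c("euploid", "aneuploid"),
                               phases = c("log", "quiescent"),
                               psiteOffset = 12L) {
  stopifnot(is(config, "RiboSimConfig"))
  truth <- sim$truth
  g <- sim$genes@genes
  if (nrow(truth@pauses) &&
      !all(truth@pauses$gene_id %in% g$gene_id))
    stop("truth references unknown gene(s): ",
         paste(setdiff(truth@pauses$gene_id, g$gene_id), collapse = ", "))
  set.seed(subSeed(config, "footprints"))

  samples <- expand.grid(replicate = seq_len(config@nReplicates),
                         phase = phases, strain = strains,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_rep%d", samples$strain,
                               samples$phase, samples$replicate)
  sampleDF <- S4Vectors::DataFrame(samples[c("sample_id", "strain",
                                             "phase", "replicate")])
  rownames(sampleDF) <- sampleDF$sample_id

  relExpr <- truth@relExpr[g$gene_id]
  ## hoist gene/pause columns out of the S4 containers before the hot loop
  gid <- g$gene_id; chromG <- g$chrom; strandG <- g$strand
  cdsStartG <- g$cds_start; cdsEndG <- g$cds_end; lenG <- g$length_codons
  pauseIdx <- match(gid, truth@pauses$gene_id)
  pCodon <- truth@pauses$codon; pAmp <- truth@pauses$amplitude
  pStrain <- truth@pauses$enhanced_strain
  pPhase <- truth@pauses$enhanced_phase

  out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    mu <- config@depth * relExpr
    totals <- if (config@dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
    else stats::rpois(length(mu), mu)
    chromV <- posV <- cntV <- strandV <- vector("list", length(gid))
    for (i in seq_along(gid)) {
      if (totals[i] == 0L) next
      L <- lenG[i]
      w <- rep(1, L)
      pi <- pauseIdx[i]
      if (!is.na(pi) && pStrain[pi] == samples$strain[s] &&
          pPhase[pi] == samples$phase[s])
        w[pCodon[pi]] <- pAmp[pi]
      cnt <- as.integer(stats::rmultinom(1, totals[i], w))
      nz <- which(cnt > 0L)
      pos5 <- if (strandG[i] == "+")
        cdsStartG[i] + 3L * (nz - 1L) - psiteOffset
      else
        cdsEndG[i] - 3L * (nz - 1L) + psiteOffset
      chromV[[i]] <- rep(chromG[i], length(nz))
      posV[[i]] <- pos5
      cntV[[i]] <- cnt[nz]
      strandV[[i]] <- rep(strandG[i], length(nz))
    }
    out[[s]] <- data.frame(
      sample = samples$sample_id[s],
      chrom = unlist(chromV), pos5 = unlist(posV),
      strand = unlist(strandV),
      read_length = config@readLength,
      count = unlist(cntV))
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  list(reads = reads, samples = sampleDF, truth = truth)
}

#' Write a read-start table
#'
#' Tab-delimited with columns `sample`, `chrom`, `pos5`, `strand`,
#' `read_length`, `count` (identical read starts aggregated).
#'
#' @param reads the `reads` element of [simulateFootprints()].
#' @param file output path.
#' @export
writeReadStarts <- function(reads, file) {
  utils::write.table(reads, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a read-start table written by [writeReadStarts()]
#'
#' A missing `count` column is treated as one read per row.
#'
#' @param file path to a tab-delimited read-start table.
#' @export
readReadStarts <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos5", "strand")
  if (!all(need %in% colnames(x)))
    stop("read-start table must have columns: ",
         paste(need, collapse = ", "))
  if (is.null(x$count)) x$count <- 1L
  x
}
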