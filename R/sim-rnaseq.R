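#' @include simConfig.R
NULL

#' Simulate spike-anchored bulk RNA-seq counts
#'
#' Emulates libraries in which a fixed number of *Sz. pombe* cells is mixed
#' into every sample before extraction: spike-gene per-cell expression is
#' constant across samples, while a designated silenced subset of target
#' genes has its per-cell expression multiplied by the timepoint's silencing
#' factor. Library depth varies per sample, so only spike-anchored
#' normalization recovers per-cell fold changes. Replicate-to-replicate
#' biological noise is gamma-distributed with the configured overdispersion.
#'
#' @param config a [RiboSimConfig-class]; relevant fields `nGenes` (target
#'   genes), `nSpikeGenes`, `spikeFraction`, `silencedFraction`,
#'   `silencingFactors` (named per timepoint; the first timepoint is the
#'   reference), `rnaseqDepth`, `rnaseqDispersion`, `rnaseqReplicates`.
#' @return list with `counts` (integer matrix, genes x samples), `species`
#'   (named `"target"`/`"spike"` per gene), `samples`
#'   ([S4Vectors::DataFrame]: `sample_id`, `timepoint`, `replicate`) and
#'   `truth` ([SimTruth-class] with silencing factors and the silenced set).
#' @examples
#' rs <- simulateRnaSeqSpike(simConfig(nGenes = 50, rnaseqDepth = 1e5,
#'                                     seed = 2))
#' rs$counts[1:3, ]
#' @export
simulateRnaSeqSpike <- function(config) {
  stopifnot(is(config, "RiboSimConfig"))
  set.seed(subSeed(config, "rnaseq"))
  nT <- config@nGenes
  nS <- config@nSpikeGenes
  targets <- sprintf("t%04d", seq_len(nT))
  spikes <- sprintf("spike%02d", seq_len(nS))
  species <- setNames(rep(c("target", "spike"), c(nT, nS)),
                      c(targets, spikes))

  exprT <- stats::rlnorm(nT, 0, 0.5)
  exprS <- stats::rlnorm(nS, 0, 0.3)
  ## scale spikes to the configured share of the log-phase mRNA pool
  exprS <- exprS * config@spikeFraction * sum(exprT) /
    ((1 - config@spikeFraction) * sum(exprS))

  nSil <- round(config@silencedFraction * nT)
  silenced <- if (nSil > 0) sort(sample(targets, nSil)) else character(0)

  tps <- names(config@silencingFactors)
  grid <- expand.grid(replicate = seq_len(config@rnaseqReplicates),
                      timepoint = tps, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_rep%d", grid$timepoint, grid$replicate)

  counts <- matrix(0L, nT + nS, nrow(grid),
                   dimnames = list(c(targets, spikes), grid$sample_id))
  phi <- config@rnaseqDispersion
  for (j in seq_len(nrow(grid))) {
    fac <- config@silencingFactors[[grid$timepoint[j]]]
    abundance <- c(exprT * ifelse(targets %in% silenced, fac, 1), exprS)
    if (phi > 0)
      abundance <- abundance *
        stats::rgamma(length(abundance), shape = 1 / phi, rate = 1 / phi)
    depth <- round(config@rnaseqDepth * stats::runif(1, 0.7, 1.3))
    counts[, j] <- as.integer(stats::rmultinom(1, depth, abundance))
  }

  sampleDF <- S4Vectors::DataFrame(grid[c("sample_id", "timepoint",
                                          "replicate")])
  rownames(sampleDF) <- sampleDF$sample_id
  truth <- new("SimTruth",
               silencingFactors = S4Vectors::DataFrame(
                 sample = grid$sample_id, timepoint = grid$timepoint,
                 factor = as.numeric(
                   config@silencingFactors[grid$timepoint])),
               silencedGenes = silenced, spikeGenes = spikes,
               seed = config@seed)
  list(counts = counts, species = species, samples = sampleDF,
       truth = truth)
}

#' Write a genes x samples count table
#'
#' Tab-delimited, header row, first column `gene_id`, optional second column
#' `species` tagging spike-in genes.
#'
#' @param counts integer matrix, genes x samples.
#' @param file output path.
#' @param species optional named vector of `"target"`/`"spike"` per gene.
#' @export
writeCountTable <- function(counts, file, species = NULL) {
  df <- data.frame(gene_id = rownames(counts), check.names = FALSE)
  if (!is.null(species)) df$species <- species[rownames(counts)]
  df <- cbind(df, as.data.frame(counts))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a count table written by [writeCountTable()]
#'
#' @param file path.
#' @return list with `counts` (integer matrix) and `species` (or NULL).
#' @export
readCountTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("first column must be gene_id")
  species <- NULL
  dat <- df[-1]
  if (identical(colnames(dat)[1], "species")) {
    species <- setNames(dat$species, df$gene_id)
    dat <- dat[-1]
  }
  counts <- as.matrix(dat)
  rownames(counts) <- df$gene_id
  list(counts = counts, species = species)
}
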