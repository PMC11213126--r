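#' @include AllClasses.R
NULL

#' Simulation configuration
#'
#' One configuration object drives all three synthetic-data generators
#' ([simulateTranscriptome()] / [simulateFootprints()],
#' [simulateRnaSeqSpike()] and [simulateScreen()]). Identical configurations
#' (including `seed`) produce bit-identical outputs.
#'
#' @slot nGenes number of protein-coding genes to simulate.
#' @slot cdsLengthRange min/max CDS length in codons (including the stop).
#' @slot nReplicates replicates per condition for the footprint simulation.
#' @slot depth expected footprints per ribosome-profiling sample.
#' @slot pauseFraction fraction of genes given a condition-specific pause.
#' @slot pauseAmplitude multiplicative occupancy factor at the pause codon in
#'   the enhanced condition (>= 1).
#' @slot motifSpec list mapping P-site-relative offset (as character, "0" =
#'   P-site, "1" = A-site) to the residues allowed at planted pause codons.
#' @slot dispersion negative-binomial overdispersion of per-gene footprint
#'   totals.
#' @slot exprSdLog sdlog of log-normal per-gene relative expression; the
#'   default 0 gives every gene equal expected coverage, keeping the
#'   baseline the simplest null for calibration and recovery (set > 0 to
#'   probe robustness to expression spread).
#' @slot readLength simulated footprint length in nt (analysis-neutral).
#' @slot flankNt random genomic sequence flanking each CDS on its contig.
#' @slot rnaseqDepth,rnaseqDispersion,spikeFraction,nSpikeGenes,
#'   silencedFraction,silencingFactors bulk RNA-seq generator: mean library
#'   depth, biological overdispersion between replicates, fraction of the
#'   log-phase mRNA pool contributed by spike-ins, number of spike genes,
#'   fraction of target genes subject to silencing, and the named per-cell
#'   mRNA retention factor per timepoint (1 = log-phase level).
#' @slot rnaseqReplicates replicates per timepoint for the RNA-seq generator.
#' @slot nBarcodes,screenDepth,screenReplicates,screenDispersion barcode
#'   screen generator: pool complexity, reads per sample, replicate cultures,
#'   and between-replicate overdispersion.
#' @slot fitnessEffects DataFrame (`gene`, `fitness_euploid`,
#'   `fitness_aneuploid`, `expected_class`) of per-gene growth-rate deltas
#'   per day; zero rows means "plant the default scenario".
#' @slot seed integer RNG seed.
#'
#' @aliases RiboSimConfig-class
#' @exportClass RiboSimConfig
setClass("RiboSimConfig",
  representation(nGenes = "integer", cdsLengthRange = "integer",
                 nReplicates = "integer", depth = "numeric",
                 pauseFraction = "numeric", pauseAmplitude = "numeric",
                 motifSpec = "list", dispersion = "numeric",
                 exprSdLog = "numeric", readLength = "integer",
                 flankNt = "integer",
                 rnaseqDepth = "numeric", rnaseqDispersion = "numeric",
                 spikeFraction = "numeric", nSpikeGenes = "integer",
                 silencedFraction = "numeric", silencingFactors = "numeric",
                 rnaseqReplicates = "integer",
                 nBarcodes = "integer", screenDepth = "numeric",
                 screenReplicates = "integer", screenDispersion = "numeric",
                 fitnessEffects = "DataFrame", seed = "integer"))

setValidity("RiboSimConfig", function(object) {
  if (object@nGenes < 1L) return("nGenes must be >= 1")
  if (length(object@cdsLengthRange) != 2L ||
      any(object@cdsLengthRange < 25L))
    return("cdsLengthRange must be two values >= 25 codons")
  if (object@cdsLengthRange[1] > object@cdsLengthRange[2])
    return("cdsLengthRange must be (min, max)")
  if (object@pauseAmplitude < 1) return("pauseAmplitude must be >= 1")
  if (object@pauseFraction < 0 || object@pauseFraction > 1)
    return("pauseFraction must lie in [0, 1]")
  if (object@depth <= 0 || object@rnaseqDepth <= 0 ||
      object@screenDepth <= 0)
    return("depths must be positive")
  if (object@dispersion < 0 || object@rnaseqDispersion < 0 ||
      object@screenDispersion < 0)
    return("dispersions must be >= 0")
  if (object@nSpikeGenes < 10L)
    return("at least 10 spike genes are required")
  if (length(object@silencingFactors) < 2L ||
      is.null(names(object@silencingFactors)))
    return("silencingFactors must be a named vector over >= 2 timepoints")
  if (any(object@silencingFactors <= 0))
    return("silencingFactors must be positive")
  if (length(object@motifSpec)) {
    offs <- suppressWarnings(as.integer(names(object@motifSpec)))
    if (anyNA(offs) || any(abs(offs) > 10))
      return("motifSpec offsets must be integers in -10..10")
    res <- unlist(object@motifSpec)
    if (!all(res %in% setdiff(AA_SYMBOLS, "*")))
      return("motifSpec residues must be standard amino acids")
  }
  if (is.na(object@seed)) return("seed is required")
  TRUE
})

#' Build a simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 200 genes of 90-180 codons, 2 replicates of {euploid, aneuploid} x
#' {log, quiescent} at 1e5 footprints per sample, a 10x pause planted in 30%
#' of genes (aneuploid + quiescent only) carrying lysine/asparagine at the
#' P-site and glutamate at the A-site; RNA-seq libraries with ~3% constant
#' per-cell spike-ins and 512-fold silencing of the silenced subset at the
#' quiescent timepoint; and a 1000-barcode pool read at 1e6 depth in
#' triplicate, with late-benefit (f = 0.1/day) and early+late (f = 0.3/day)
#' genes planted in the aneuploid background.
#'
#' @param nGenes,cdsLengthRange,nReplicates,depth,pauseFraction,
#'   pauseAmplitude,motifSpec,dispersion,exprSdLog,readLength,flankNt see
#'   [RiboSimConfig-class].
#' @param rnaseqDepth,rnaseqDispersion,spikeFraction,nSpikeGenes,
#'   silencedFraction,silencingFactors,rnaseqReplicates RNA-seq generator
#'   settings.
#' @param nBarcodes,screenDepth,screenReplicates,screenDispersion,
#'   fitnessEffects screen generator settings; `fitnessEffects = NULL` plants
#'   the default scenario.
#' @param seed integer RNG seed.
#' @return a validated [RiboSimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 20, depth = 1e4, seed = 1)
#' @export
simConfig <- function(nGenes = 200, cdsLengthRange = c(90, 180),
                      nReplicates = 2, depth = 1e5,
                      pauseFraction = 0.3, pauseAmplitude = 10,
                      motifSpec = list("0" = c("K", "N"), "1" = "E"),
                      dispersion = 0.1, exprSdLog = 0,
                      readLength = 28, flankNt = 100,
                      rnaseqDepth = 1e6, rnaseqDispersion = 0.01,
                      spikeFraction = 0.03, nSpikeGenes = 12,
                      silencedFraction = 0.6,
                      silencingFactors = c(log = 1, quiescent = 1 / 512),
                      rnaseqReplicates = 2,
                      nBarcodes = 1000, screenDepth = 1e6,
                      screenReplicates = 3, screenDispersion = 0.002,
                      fitnessEffects = NULL, seed = 1) {
  if (is.null(fitnessEffects))
    fitnessEffects <- S4Vectors::DataFrame()
  else
    fitnessEffects <- S4Vectors::DataFrame(fitnessEffects)
  new("RiboSimConfig",
      nGenes = as.integer(nGenes),
      cdsLengthRange = as.integer(cdsLengthRange),
      nReplicates = as.integer(nReplicates),
      depth = as.numeric(depth),
      pauseFraction = as.numeric(pauseFraction),
      pauseAmplitude = as.numeric(pauseAmplitude),
      motifSpec = as.list(motifSpec),
      dispersion = as.numeric(dispersion),
      exprSdLog = as.numeric(exprSdLog),
      readLength = as.integer(readLength),
      flankNt = as.integer(flankNt),
      rnaseqDepth = as.numeric(rnaseqDepth),
      rnaseqDispersion = as.numeric(rnaseqDispersion),
      spikeFraction = as.numeric(spikeFraction),
      nSpikeGenes = as.integer(nSpikeGenes),
      silencedFraction = as.numeric(silencedFraction),
      silencingFactors = silencingFactors,
      rnaseqReplicates = as.integer(rnaseqReplicates),
      nBarcodes = as.integer(nBarcodes),
      screenDepth = as.numeric(screenDepth),
      screenReplicates = as.integer(screenReplicates),
      screenDispersion = as.numeric(screenDispersion),
      fitnessEffects = fitnessEffects,
      seed = as.integer(seed))
}

#' @export
setMethod("show", "RiboSimConfig", function(object) {
  cat("RiboSimConfig: ", object@nGenes, " genes (",
      object@cdsLengthRange[1], "-", object@cdsLengthRange[2],
      " codons), depth ", format(object@depth, scientific = TRUE),
      ", pause ", object@pauseAmplitude, "x in ",
      round(100 * object@pauseFraction), "% of genes, seed ",
      object@seed, "\n", sep = "")
})

## deterministic sub-seeds so the generators can be called in any order
subSeed <- function(config, stream) {
  offsets <- c(transcriptome = 11L, footprints = 23L, rnaseq = 37L,
               screen = 53L)
  (config@seed + offsets[[stream]]) %% .Machine$integer.max
}
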