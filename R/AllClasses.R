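#' @include riboPause-package.R
NULL

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Gene models with eligibility flags
#'
#' Container for protein-coding gene models: genomic CDS coordinates, amino
#' acid sequences (including the terminal stop, written `*`), codon lengths
#' and the eligibility flags used throughout the ribosome-profiling analyses.
#' A gene is eligible when its CDS is a single segment (no introns), starts
#' with ATG, has length divisible by three and contains no internal stop;
#' ineligible genes are retained but flagged, with the reason recorded.
#'
#' @slot genes A [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `chrom`, `strand`, `cds_start`, `cds_end` (1-based inclusive genomic
#'   coordinates of the CDS span), `n_segments`, `length_codons` (codons
#'   including the stop codon), `eligible`, `reason`.
#' @slot aa Named [Biostrings::AAStringSet] of translations for genes whose
#'   sequence could be extracted; the last residue of an eligible gene is `*`.
#'
#' @aliases GeneModelSet-class
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(genes = "DataFrame", aa = "AAStringSet"))

setValidity("GeneModelSet", function(object) {
  need <- c("gene_id", "chrom", "strand", "cds_start", "cds_end",
            "n_segments", "length_codons", "eligible", "reason")
  miss <- setdiff(need, colnames(object@genes))
  if (length(miss))
    return(paste("missing gene columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@genes$gene_id))
    return("duplicated gene_id")
  if (!all(object@genes$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  TRUE
})

#' @describeIn GeneModelSet-class number of genes
#' @param x,object a `GeneModelSet`
#' @export
setMethod("length", "GeneModelSet", function(x) nrow(x@genes))

#' @export
setMethod("show", "GeneModelSet", function(object) {
  g <- object@genes
  cat("GeneModelSet with", nrow(g), "genes (",
      sum(g$eligible), "eligible )\n")
  if (nrow(g)) {
    cat("  codon lengths:", min(g$length_codons), "-",
        max(g$length_codons), "(incl. stop)\n")
    bad <- table(g$reason[!g$eligible])
    if (length(bad))
      cat("  ineligible:", paste(names(bad), bad, sep = "=", collapse = ", "),
          "\n")
  }
})

#' @describeIn GeneModelSet-class gene identifiers
#' @export
geneIds <- function(x) x@genes$gene_id

#' @describeIn GeneModelSet-class per-gene annotation table
#' @export
geneTable <- function(x) x@genes

#' @describeIn GeneModelSet-class translated amino-acid sequences
#' @export
aaSequences <- function(x) x@aa

#' @describeIn GeneModelSet-class subset to the eligible genes
#' @export
eligibleGenes <- function(x) {
  keep <- x@genes$eligible
  new("GeneModelSet", genes = x@genes[keep, , drop = FALSE],
      aa = x@aa[intersect(names(x@aa), x@genes$gene_id[keep])])
}

## ---------------------------------------------------------------------------

#' Codon-resolution footprint count profiles
#'
#' Per-gene, per-sample integer counts of ribosome P-sites at codon
#' resolution, spanning 24 codons upstream of the ATG (codon -24, i.e. -72 nt)
#' through 20 codons downstream of the stop (codon L+20, +60 nt). Codon 1 is
#' the ATG; upstream codons are numbered -24..-1 (there is no codon 0), so
#' each profile has L + 44 entries for a gene of L codons. The interior
#' window (gene body) is codons 21..L-20.
#'
#' @slot counts Named list (by gene) of integer matrices, codons x samples;
#'   rownames are codon indices, colnames sample identifiers.
#' @slot geneInfo [S4Vectors::DataFrame] with `gene_id`, `length_codons`,
#'   `chrom`, `strand`, `cds_start`, `cds_end`.
#' @slot samples [S4Vectors::DataFrame] of per-sample metadata; rownames are
#'   sample identifiers.
#' @slot flankUp,flankDown flank widths in codons (24 and 20 by default).
#' @slot edge codons trimmed from each CDS end to form the interior window.
#' @slot outOfWindow per-sample tally of P-sites that fell on an assayed
#'   gene's chromosome but outside every gene window.
#' @slot normalized logical; `FALSE` for raw counts.
#'
#' @aliases CodonProfileSet-class
#' @exportClass CodonProfileSet
setClass("CodonProfileSet",
  representation(counts = "list", geneInfo = "DataFrame",
                 samples = "DataFrame", flankUp = "integer",
                 flankDown = "integer", edge = "integer",
                 outOfWindow = "numeric", normalized = "logical"),
  prototype(flankUp = 24L, flankDown = 20L, edge = 20L,
            outOfWindow = numeric(0), normalized = FALSE))

setValidity("CodonProfileSet", function(object) {
  if (!identical(sort(names(object@counts)),
                 sort(object@geneInfo$gene_id)))
    return("counts list names must match geneInfo$gene_id")
  ns <- nrow(object@samples)
  for (gid in names(object@counts)) {
    m <- object@counts[[gid]]
    L <- object@geneInfo$length_codons[match(gid, object@geneInfo$gene_id)]
    if (nrow(m) != L + object@flankUp + object@flankDown)
      return(sprintf("gene %s: profile has %d rows, expected %d",
                     gid, nrow(m), L + object@flankUp + object@flankDown))
    if (ncol(m) != ns)
      return(sprintf("gene %s: %d sample columns, expected %d",
                     gid, ncol(m), ns))
    if (!object@normalized && any(m < 0))
      return(sprintf("gene %s: negative counts", gid))
  }
  TRUE
})

#' @export
setMethod("show", "CodonProfileSet", function(object) {
  cat(if (object@normalized) "Normalized" else "Raw",
      "CodonProfileSet:", length(object@counts), "genes x",
      nrow(object@samples), "samples\n")
  cat("  window: -", object@flankUp, " .. L+", object@flankDown,
      " codons; interior: ", object@edge + 1L, "..L-", object@edge,
      "\n", sep = "")
  if (nrow(object@samples))
    cat("  samples:", paste(head(rownames(object@samples), 6),
                            collapse = ", "),
        if (nrow(object@samples) > 6) "..." else "", "\n")
})

#' @describeIn CodonProfileSet-class number of genes held
#' @param x,object a `CodonProfileSet`
#' @export
setMethod("length", "CodonProfileSet", function(x) length(x@counts))

#' Sample metadata of a profile set
#' @param x a `CodonProfileSet`
#' @return a [S4Vectors::DataFrame], rownames are sample identifiers.
#' @export
sampleData <- function(x) x@samples

#' Per-gene profile matrix
#'
#' @param x a `CodonProfileSet`
#' @param gene gene identifier
#' @return the codons x samples matrix for one gene; rownames are codon
#'   indices (`-24..-1`, `1..L+20`).
#' @export
profileMatrix <- function(x, gene) {
  m <- x@counts[[gene]]
  if (is.null(m)) stop("gene not in profile set: ", gene)
  m
}

#' Row indices of the interior window (codons 21..L-20) of a gene profile
#' @param x a `CodonProfileSet`
#' @param gene gene identifier
#' @export
interiorRows <- function(x, gene) {
  L <- x@geneInfo$length_codons[match(gene, x@geneInfo$gene_id)]
  if (is.na(L)) stop("gene not in profile set: ", gene)
  lo <- x@edge + 1L
  hi <- L - x@edge
  if (hi < lo) return(integer(0))
  ## rows are -flankUp..-1 then 1..L+flankDown
  x@flankUp + seq(lo, hi)
}

#' Gene-body totals
#'
#' Sum of counts over the interior window (codons 21..L-20) for every gene
#' and sample; this is the "reads per gene body" quantity behind the >= 50
#' read retention filter.
#'
#' @param x a `CodonProfileSet`
#' @return numeric matrix, genes x samples.
#' @export
bodyTotals <- function(x) {
  ids <- x@geneInfo$gene_id
  out <- matrix(0, length(ids), nrow(x@samples),
                dimnames = list(ids, rownames(x@samples)))
  for (gid in ids) {
    rows <- interiorRows(x, gid)
    if (length(rows))
      out[gid, ] <- colSums(x@counts[[gid]][rows, , drop = FALSE])
  }
  out
}

## ---------------------------------------------------------------------------

#' Amino-acid context matrix around pause sites
#'
#' Counts of each amino acid (plus the stop symbol `*`) at every position
#' -10..+10 relative to the P-site codon of a set of pause sites (offset 0 is
#' the P-site residue, +1 the A-site). Window positions falling outside the
#' protein contribute to neither counts nor totals, so `totals` can shrink
#' near the ends while frequencies still sum to one over contributing peaks.
#'
#' @slot counts integer matrix, 21 symbols x positions.
#' @slot totals integer vector of contributing peaks per position.
#' @slot nPeaks number of peaks scored.
#' @slot window half-width of the context window (codons).
#'
#' @aliases ContextMatrix-class
#' @exportClass ContextMatrix
setClass("ContextMatrix",
  representation(counts = "matrix", totals = "integer", nPeaks = "integer",
                 window = "integer"))

setValidity("ContextMatrix", function(object) {
  if (!identical(rownames(object@counts), AA_SYMBOLS))
    return("rownames must be the 20 amino acids plus '*'")
  if (length(object@totals) != ncol(object@counts))
    return("totals length must equal number of positions")
  if (any(colSums(object@counts) != object@totals))
    return("column sums must equal totals")
  if (any(object@counts > rep(object@totals, each = nrow(object@counts))))
    return("counts cannot exceed totals")
  TRUE
})

#' @export
setMethod("show", "ContextMatrix", function(object) {
  cat("ContextMatrix:", object@nPeaks, "peaks, positions",
      colnames(object@counts)[1], "..",
      colnames(object@counts)[ncol(object@counts)],
      "(0 = P-site, +1 = A-site)\n")
})

#' @describeIn ContextMatrix-class symbol x position count matrix
#' @param x a `ContextMatrix`
#' @export
contextCounts <- function(x) x@counts

#' @describeIn ContextMatrix-class peaks contributing per position
#' @export
contextTotals <- function(x) x@totals

#' @describeIn ContextMatrix-class symbol frequencies (counts / totals)
#' @export
contextFreq <- function(x) {
  sweep(x@counts, 2, pmax(x@totals, 1L), "/")
}

## ---------------------------------------------------------------------------

#' Simulation ground truth
#'
#' Record of everything a synthetic dataset planted, sufficient for
#' parameter-recovery scoring without re-reading the generator inputs:
#' planted pause sites and their local residue context, per-gene relative
#' expression, per-sample silencing factors and the silenced gene subset,
#' and per-gene fitness effects for the barcode screen.
#'
#' @slot pauses DataFrame: `gene_id`, `codon`, `amplitude`,
#'   `enhanced_strain`, `enhanced_phase`, plus `context` (residues -10..+10).
#' @slot motifSpec list mapping offset (as character, "0" = P-site) to the
#'   allowed residues planted there.
#' @slot relExpr named numeric, per-gene relative expression.
#' @slot silencingFactors DataFrame: `sample`, `timepoint`, `factor`.
#' @slot silencedGenes,spikeGenes character vectors.
#' @slot fitness DataFrame: `gene`, `fitness_euploid`, `fitness_aneuploid`,
#'   `expected_class`.
#' @slot seed integer seed the generator ran under.
#'
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
  representation(pauses = "DataFrame", motifSpec = "list",
                 relExpr = "numeric", silencingFactors = "DataFrame",
                 silencedGenes = "character", spikeGenes = "character",
                 fitness = "DataFrame", seed = "integer"),
  prototype(pauses = S4Vectors::DataFrame(), motifSpec = list(),
            relExpr = numeric(0), silencingFactors = S4Vectors::DataFrame(),
            silencedGenes = character(0), spikeGenes = character(0),
            fitness = S4Vectors::DataFrame(), seed = NA_integer_))

#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth (seed ", object@seed, "):\n", sep = "")
  if (nrow(object@pauses))
    cat("  planted pauses:", nrow(object@pauses), "\n")
  if (length(object@silencedGenes))
    cat("  silenced genes:", length(object@silencedGenes), "\n")
  if (nrow(object@fitness))
    cat("  fitness effects:", sum(object@fitness$fitness_aneuploid != 0 |
                                  object@fitness$fitness_euploid != 0),
        "non-neutral genes\n")
})

#' @describeIn SimTruth-class planted pause table
#' @param x a `SimTruth`
#' @export
plantedPauses <- function(x) x@pauses

#' @describeIn SimTruth-class planted fitness-effect table
#' @export
plantedFitness <- function(x) x@fitness
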