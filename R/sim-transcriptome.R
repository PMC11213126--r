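#' @include simConfig.R
NULL

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS  <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

codonsForResidue <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

#' Simulate a synthetic transcriptome with planted stall motifs
#'
#' Generates `nGenes` intron-less protein-coding genes, each on its own
#' contig with random flanking sequence, on a random strand. Every CDS starts
#' with ATG, contains no internal stop and ends with a stop codon. A fraction
#' of genes receives one planted pause site at an interior codon (21..L-20);
#' the residues around a planted pause are rewritten to honour `motifSpec`
#' (the amino acid is fixed by the motif, the codon drawn uniformly among its
#' synonymous codons). Per-gene relative expression is drawn log-normally and
#' recorded in the truth object.
#'
#' @param config a [RiboSimConfig-class] from [simConfig()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   ([GeneModelSet-class]), `annotation` (a [GenomicRanges::GRanges] of gene
#'   and CDS features) and `truth` ([SimTruth-class]).
#' @seealso [writeTranscriptome()] to serialize as FASTA + GFF3.
#' @examples
#' sim <- simulateTranscriptome(simConfig(nGenes = 5, seed = 7))
#' sim$genes
#' @export
simulateTranscriptome <- function(config) {
  stopifnot(is(config, "RiboSimConfig"))
  set.seed(subSeed(config, "transcriptome"))
  n <- config@nGenes
  gids <- sprintf("g%04d", seq_len(n))
  lenRange <- seq(config@cdsLengthRange[1], config@cdsLengthRange[2])
  lens <- lenRange[sample.int(length(lenRange), n, replace = TRUE)]
  strands <- sample(c("+", "-"), n, replace = TRUE)

  ## codon sequences: ATG + sense codons + stop
  codons <- lapply(lens, function(L) {
    c("ATG", sample(SENSE_CODONS, L - 2L, replace = TRUE),
      sample(STOP_CODONS, 1L))
  })
  names(codons) <- gids

  ## plant pauses with motif residues
  nPause <- round(config@pauseFraction * n)
  if (nPause > 0 && config@cdsLengthRange[1] < 41L)
    stop("pause planting needs CDSs of >= 41 codons so the interior ",
         "window 21..L-20 is nonempty")
  pauseGenes <- if (nPause > 0) sort(sample(gids, nPause)) else character(0)
  offsets <- as.integer(names(config@motifSpec))
  pauseCodon <- integer(0)
  for (gid in pauseGenes) {
    L <- lens[match(gid, gids)]
    pc <- sample(seq(21L, L - 20L), 1L)
    pauseCodon <- c(pauseCodon, pc)
    for (k in seq_along(offsets)) {
      aa <- sample(config@motifSpec[[k]], 1L)
      codons[[gid]][pc + offsets[k]] <- sample(codonsForResidue(aa), 1L)
    }
  }

  ## assemble contigs
  flank <- config@flankNt
  cdsStr <- vapply(codons, paste, character(1), collapse = "")
  cdsSet <- Biostrings::DNAStringSet(cdsStr)
  aaChar <- as.character(Biostrings::translate(cdsSet,
                                               no.init.codon = TRUE))
  genomicCds <- cdsStr
  minus <- strands == "-"
  if (any(minus))
    genomicCds[minus] <- as.character(
      Biostrings::reverseComplement(cdsSet[minus]))
  flanks <- matrix(sample(c("A", "C", "G", "T"), 2L * n * flank,
                          replace = TRUE), nrow = 2L * n)
  flankStr <- apply(flanks, 1, paste, collapse = "")
  contigs <- paste0(flankStr[seq_len(n)], genomicCds,
                    flankStr[n + seq_len(n)])
  cdsStart <- rep(flank + 1L, n)
  cdsEnd <- flank + 3L * lens
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- paste0("ctg_", gids)

  genes <- S4Vectors::DataFrame(
    gene_id = gids, chrom = paste0("ctg_", gids), strand = strands,
    cds_start = cdsStart, cds_end = cdsEnd, n_segments = 1L,
    length_codons = as.integer(lens), eligible = TRUE, reason = "")
  aa <- Biostrings::AAStringSet(aaChar)
  names(aa) <- gids
  gms <- new("GeneModelSet", genes = genes, aa = aa)

  relExpr <- stats::rlnorm(n, 0, config@exprSdLog)
  relExpr <- relExpr / sum(relExpr)
  names(relExpr) <- gids

  pauses <- S4Vectors::DataFrame(
    gene_id = pauseGenes,
    codon = pauseCodon,
    amplitude = rep(config@pauseAmplitude, length(pauseGenes)),
    enhanced_strain = rep("aneuploid", length(pauseGenes)),
    enhanced_phase = rep("quiescent", length(pauseGenes)))
  if (nrow(pauses)) {
    ctx <- t(vapply(seq_len(nrow(pauses)), function(i) {
      s <- strsplit(aaChar[match(pauses$gene_id[i], gids)], "")[[1]]
      pos <- pauses$codon[i] + (-10:10)
      ifelse(pos >= 1 & pos <= length(s), s[pmax(pos, 1)], NA_character_)
    }, character(21)))
    colnames(ctx) <- as.character(-10:10)
    pauses$context <- I(apply(ctx, 1, paste, collapse = ""))
  }
  truth <- new("SimTruth", pauses = pauses, motifSpec = config@motifSpec,
               relExpr = relExpr, seed = config@seed)

  gr <- GenomicRanges::GRanges(
    seqnames = rep(genes$chrom, 2),
    ranges = IRanges::IRanges(start = rep(cdsStart, 2),
                              end = rep(cdsEnd, 2)),
    strand = rep(strands, 2),
    type = rep(c("gene", "CDS"), each = n),
    phase = rep(c(NA_integer_, 0L), each = n),
    ID = c(gids, paste0(gids, ".cds")),
    Parent = c(rep(NA_character_, n), gids))

  list(genome = genome, genes = gms, annotation = gr, truth = truth)
}

#' Write a simulated transcriptome as FASTA + GFF3
#'
#' @param sim result of [simulateTranscriptome()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths of the FASTA and GFF3 files written.
#' @export
writeTranscriptome <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(sim$genome, fa)
  rtracklayer::export(sim$annotation, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Write simulation ground truth as plain-text tables
#'
#' One tab-delimited file per truth component (planted pauses, relative
#' expression, silencing factors, fitness effects), prefixed `truth_`.
#'
#' @param truth a [SimTruth-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSimTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, paste0("truth_", name, ".tsv"))
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  if (nrow(truth@pauses)) paths <- c(paths, wt(truth@pauses, "pauses"))
  if (length(truth@relExpr))
    paths <- c(paths, wt(data.frame(gene_id = names(truth@relExpr),
                                    rel_expr = truth@relExpr), "rel_expr"))
  if (nrow(truth@silencingFactors))
    paths <- c(paths, wt(truth@silencingFactors, "silencing"))
  if (length(truth@silencedGenes))
    paths <- c(paths, wt(data.frame(gene_id = truth@silencedGenes),
                         "silenced_genes"))
  if (nrow(truth@fitness)) paths <- c(paths, wt(truth@fitness, "fitness"))
  invisible(paths)
}
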