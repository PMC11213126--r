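#' @include AllClasses.R
NULL

#' Load gene models from FASTA + GFF3
#'
#' Reads a genome and its annotation, groups CDS features into genes and
#' flags each gene's eligibility for codon-level analysis. Genes whose CDS
#' has more than one segment (introns), does not begin with ATG, has length
#' not divisible by three, or contains an internal stop are retained but
#' marked ineligible with the reason recorded; they are excluded downstream.
#' Translations (standard genetic code, terminal stop as `*`) are computed
#' for every single-segment gene of valid length.
#'
#' @param fasta path to the genome FASTA (or a [Biostrings::DNAStringSet]).
#' @param gff3 path to a GFF3 file with CDS features (or a
#'   [GenomicRanges::GRanges] with `type` and `ID`/`Parent` columns).
#' @return a [GeneModelSet-class].
#' @examples
#' sim <- simulateTranscriptome(simConfig(nGenes = 4, seed = 11))
#' d <- tempfile(); paths <- writeTranscriptome(sim, d)
#' loadGenes(paths["fasta"], paths["gff3"])
#' @export
loadGenes <- function(fasta, gff3) {
  genome <- if (is(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- if (is(gff3, "GRanges")) gff3 else rtracklayer::import(gff3)
  cds <- ann[tolower(as.character(ann$type)) == "cds"]
  if (!length(cds)) stop("no CDS features in annotation")

  key <- rep(NA_character_, length(cds))
  if (!is.null(cds$Parent)) {
    p <- as(cds$Parent, "CharacterList")
    has <- S4Vectors::elementNROWS(p) > 0
    key[has] <- vapply(p[has], `[`, character(1), 1L)
  }
  if (anyNA(key) && !is.null(cds$ID)) key[is.na(key)] <- cds$ID[is.na(key)]
  if (anyNA(key)) stop("CDS features lack Parent and ID attributes")
  key <- sub("\\.cds$", "", key)

  ord <- order(key, GenomicRanges::start(cds))
  cds <- cds[ord]; key <- key[ord]
  gids <- unique(key)

  n <- length(gids)
  chrom <- character(n); strand <- character(n)
  s1 <- integer(n); s2 <- integer(n); nseg <- integer(n)
  lenC <- integer(n); eligible <- logical(n); reason <- character(n)
  aaList <- setNames(rep(NA_character_, n), gids)

  for (i in seq_len(n)) {
    seg <- cds[key == gids[i]]
    chrom[i] <- as.character(GenomicRanges::seqnames(seg))[1]
    strand[i] <- as.character(GenomicRanges::strand(seg))[1]
    s1[i] <- min(GenomicRanges::start(seg))
    s2[i] <- max(GenomicRanges::end(seg))
    nseg[i] <- length(seg)
    totalLen <- sum(GenomicRanges::end(seg) - GenomicRanges::start(seg) + 1L)
    lenC[i] <- totalLen %/% 3L
    if (!chrom[i] %in% names(genome))
      stop("missing sequence for chromosome: ", chrom[i])
    if (nseg[i] > 1L) { reason[i] <- "introns"; next }
    if (totalLen %% 3L != 0L) { reason[i] <- "length_not_multiple_of_3"; next }
    seq <- Biostrings::subseq(genome[[chrom[i]]], s1[i], s2[i])
    if (strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    if (as.character(Biostrings::subseq(seq, 1L, 3L)) != "ATG") {
      reason[i] <- "no_atg"
      aaList[i] <- as.character(Biostrings::translate(
        seq, no.init.codon = TRUE, if.fuzzy.codon = "X"))
      next
    }
    aa <- as.character(Biostrings::translate(seq, no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
    aaList[i] <- aa
    if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) {
      reason[i] <- "internal_stop"; next
    }
    eligible[i] <- TRUE
  }

  genes <- S4Vectors::DataFrame(
    gene_id = gids, chrom = chrom, strand = strand,
    cds_start = s1, cds_end = s2, n_segments = nseg,
    length_codons = lenC, eligible = eligible, reason = reason)
  aaOk <- !is.na(aaList)
  aa <- Biostrings::AAStringSet(aaList[aaOk])
  new("GeneModelSet", genes = genes, aa = aa)
}

#' Assign ribosome P-sites from read 5' ends
#'
#' Applies the fixed P-site offset: on the plus strand the P-site is
#' `pos5 + offset`, on the minus strand `pos5 - offset` (`pos5` is the
#' biological 5' end in genomic coordinates). A single offset is used
#' regardless of read length.
#'
#' @param reads data.frame with columns `sample`, `chrom`, `pos5`, `strand`
#'   and optionally `count` (defaults to 1 per row).
#' @param offset nt from the 5' end to the P-site; default 12.
#' @param chromLengths optional named vector of chromosome lengths; P-sites
#'   outside `[1, length]` are dropped and tallied in the `"dropped"`
#'   attribute of the result.
#' @return the input with a `psite` column added (and out-of-bounds records
#'   removed).
#' @examples
#' assignPSites(data.frame(sample = "s", chrom = "c", pos5 = 100,
#'                         strand = "+"), offset = 12)$psite  # 112
#' @export
assignPSites <- function(reads, offset = 12L, chromLengths = NULL) {
  stopifnot(all(c("sample", "chrom", "pos5", "strand") %in% colnames(reads)))
  if (is.null(reads$count)) reads$count <- 1L
  reads$psite <- ifelse(reads$strand == "+",
                        reads$pos5 + offset, reads$pos5 - offset)
  dropped <- 0L
  bad <- reads$psite < 1L
  if (!is.null(chromLengths))
    bad <- bad | reads$psite > chromLengths[reads$chrom]
  if (any(bad)) {
    dropped <- sum(reads$count[bad])
    reads <- reads[!bad, , drop = FALSE]
  }
  attr(reads, "dropped") <- dropped
  reads
}

#' Build codon-resolution count profiles
#'
#' Sums P-sites per codon for every eligible gene, over the window from
#' `flankUpNt` (72 nt = 24 codons) upstream of the ATG to `flankDownNt`
#' (60 nt = 20 codons) downstream of the stop. The codon index of a P-site
#' is its strand-aware nucleotide offset from the ATG divided by three:
#' all three nucleotides of the ATG map to codon 1, nt -1..-3 to codon -1,
#' nt -72..-70 to codon -24. P-sites outside every gene window are excluded
#' silently and tallied per sample.
#'
#' @param psites data.frame from [assignPSites()].
#' @param genes a [GeneModelSet-class]; only eligible genes are profiled.
#' @param flankUpNt,flankDownNt flank widths in nt (multiples of 3).
#' @param samples optional [S4Vectors::DataFrame] of sample metadata
#'   (rownames = sample ids) fixing the sample set and order.
#' @param edgeCodons codons trimmed from each CDS end to form the interior
#'   window used for gene-body totals and normalization (default 20).
#' @return a [CodonProfileSet-class].
#' @export
codonProfiles <- function(psites, genes, flankUpNt = 72L, flankDownNt = 60L,
                          samples = NULL, edgeCodons = 20L) {
  if (flankUpNt %% 3L || flankDownNt %% 3L)
    stop("flank widths must be multiples of 3 nt")
  fu <- as.integer(flankUpNt %/% 3L)
  fd <- as.integer(flankDownNt %/% 3L)
  gm <- eligibleGenes(genes)
  g <- gm@genes
  if (!nrow(g)) stop("no eligible genes")
  if (is.null(psites$count)) psites$count <- 1L

  if (is.null(samples)) {
    sids <- sort(unique(psites$sample))
    samples <- S4Vectors::DataFrame(sample_id = sids)
    rownames(samples) <- sids
  }
  sids <- rownames(samples)
  sIdx <- match(psites$sample, sids)
  if (anyNA(sIdx)) stop("psites contain samples absent from `samples`")

  plus <- g$strand == "+"
  winGR <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(
      start = ifelse(plus, g$cds_start - flankUpNt,
                     g$cds_start - flankDownNt),
      end = ifelse(plus, g$cds_end + flankDownNt,
                   g$cds_end + flankUpNt)),
    strand = g$strand)
  pGR <- GenomicRanges::GRanges(
    seqnames = psites$chrom,
    ranges = IRanges::IRanges(start = psites$psite, width = 1L),
    strand = psites$strand)
  hits <- GenomicRanges::findOverlaps(pGR, winGR)

  counts <- vector("list", nrow(g))
  names(counts) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    L <- g$length_codons[i]
    m <- matrix(0L, L + fu + fd, length(sids),
                dimnames = list(c(seq(-fu, -1L), seq(1L, L + fd)), sids))
    counts[[i]] <- m
  }

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- ifelse(g$strand[sh] == "+",
              psites$psite[qh] - g$cds_start[sh],
              g$cds_end[sh] - psites$psite[qh])
  idx0 <- floor(d / 3)
  codon <- ifelse(idx0 >= 0, idx0 + 1L, idx0)
  row <- ifelse(codon < 0, codon + fu + 1L, codon + fu)
  bySubject <- split(seq_along(sh), sh)
  for (nm in names(bySubject)) {
    i <- as.integer(nm)
    sel <- bySubject[[nm]]
    m <- counts[[i]]
    key <- (sIdx[qh[sel]] - 1L) * nrow(m) + row[sel]
    agg <- rowsum(psites$count[qh[sel]], key)
    m[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    counts[[i]] <- m
  }

  inWindow <- logical(nrow(psites))
  inWindow[qh] <- TRUE
  oow <- vapply(seq_along(sids), function(s)
    sum(psites$count[!inWindow & sIdx == s]), numeric(1))
  names(oow) <- sids

  new("CodonProfileSet", counts = counts,
      geneInfo = g[, c("gene_id", "length_codons", "chrom", "strand",
                       "cds_start", "cds_end")],
      samples = samples, flankUp = fu, flankDown = fd,
      edge = as.integer(edgeCodons), outOfWindow = oow,
      normalized = FALSE)
}

#' Retain genes with enough gene-body reads
#'
#' Keeps gene profiles whose interior-window total is at least
#' `minBodyReads` (inclusive) in *every* sample listed in `samples`; a gene
#' enters a paired comparison only if it passes in all members of that
#' comparison.
#'
#' @param x a [CodonProfileSet-class].
#' @param minBodyReads retention threshold, default 50.
#' @param samples sample ids the filter must hold in (default: all).
#' @return the filtered `CodonProfileSet`.
#' @export
filterGenes <- function(x, minBodyReads = 50, samples = NULL) {
  bt <- bodyTotals(x)
  if (is.null(samples)) samples <- colnames(bt)
  miss <- setdiff(samples, colnames(bt))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  keep <- rownames(bt)[rowSums(bt[, samples, drop = FALSE] >=
                                 minBodyReads) == length(samples)]
  if (!length(keep))
    stop("no genes pass the ", minBodyReads,
         "-read gene-body filter; lower the threshold or sequence deeper")
  new("CodonProfileSet", counts = x@counts[keep],
      geneInfo = x@geneInfo[match(keep, x@geneInfo$gene_id), , drop = FALSE],
      samples = x@samples, flankUp = x@flankUp, flankDown = x@flankDown,
      edge = x@edge, outOfWindow = x@outOfWindow, normalized = x@normalized)
}

#' Reading-frame QC report
#'
#' Fraction of in-CDS P-sites in each frame relative to the ATG, per sample.
#' Frame 0 is the first nucleotide of a codon; correctly offset footprint
#' data should be almost entirely frame 0.
#'
#' @param psites data.frame from [assignPSites()].
#' @param genes a [GeneModelSet-class].
#' @return numeric matrix, samples x frames `f0`,`f1`,`f2`; rows sum to 1.
#' @export
frameReport <- function(psites, genes) {
  g <- eligibleGenes(genes)@genes
  if (is.null(psites$count)) psites$count <- 1L
  cdsGR <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$cds_start, end = g$cds_end),
    strand = g$strand)
  pGR <- GenomicRanges::GRanges(
    seqnames = psites$chrom,
    ranges = IRanges::IRanges(start = psites$psite, width = 1L),
    strand = psites$strand)
  hits <- GenomicRanges::findOverlaps(pGR, cdsGR)
  if (!length(hits)) stop("no P-sites fall inside a CDS")
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  frame <- ifelse(g$strand[sh] == "+",
                  (psites$psite[qh] - g$cds_start[sh]) %% 3L,
                  (g$cds_end[sh] - psites$psite[qh]) %% 3L)
  sids <- sort(unique(psites$sample))
  out <- matrix(0, length(sids), 3,
                dimnames = list(sids, c("f0", "f1", "f2")))
  tab <- rowsum(psites$count[qh],
                paste(psites$sample[qh], frame, sep = "\r"))
  kk <- do.call(rbind, strsplit(rownames(tab), "\r"))
  out[cbind(kk[, 1], c("f0", "f1", "f2")[as.integer(kk[, 2]) + 1L])] <-
    tab[, 1]
  sweep(out, 1, rowSums(out), "/")
}
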