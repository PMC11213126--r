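#' @include AllClasses.R
NULL

#' Wilcoxon rank-sum test on peak positions
#'
#' Two-sided rank-sum comparison of the codon indices of two peak sets,
#' used to ask whether one set of differential pauses sits closer to the
#' start codon than the other. Exact p-values are used where
#' [stats::wilcox.test()] provides them (small samples without ties).
#'
#' @param positionsA,positionsB codon indices of the two peak sets; both
#'   must be nonempty.
#' @return list with `statistic` (rank-sum W), `p.value`, `medianA`,
#'   `medianB`, `nA`, `nB`.
#' @examples
#' peakPositionTest(c(1, 2, 3), c(11, 12, 13))$p.value  # exact: 0.1
#' @export
peakPositionTest <- function(positionsA, positionsB) {
  if (!length(positionsA) || !length(positionsB))
    stop("both peak sets must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(positionsA, positionsB,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       medianA = stats::median(positionsA),
       medianB = stats::median(positionsB),
       nA = length(positionsA), nB = length(positionsB))
}

#' Extract amino-acid context windows around peaks
#'
#' For each peak, returns the residues at offsets `-window..+window` from
#' the P-site codon (offset 0 = the P-site residue itself, +1 = the A-site).
#' The stop codon is a scorable symbol (`*`); offsets falling before residue
#' 1 or beyond the stop are `NA` and are excluded from position totals when
#' the matrix is built.
#'
#' @param sites DataFrame/data.frame with `gene_id` and `codon` (e.g. the
#'   `sites` element of [combineReplicates()]).
#' @param genes a [GeneModelSet-class] providing the translations.
#' @param window half-width in codons, default 10.
#' @return character matrix, peaks x offsets (colnames `-window..window`).
#' @export
extractContexts <- function(sites, genes, window = 10L) {
  aa <- genes@aa
  miss <- setdiff(unique(sites$gene_id), names(aa))
  if (length(miss))
    stop("no translation for gene(s): ", paste(miss, collapse = ", "))
  offs <- seq(-window, window)
  out <- matrix(NA_character_, nrow(sites), length(offs),
                dimnames = list(NULL, as.character(offs)))
  seqs <- strsplit(as.character(aa), "")
  names(seqs) <- names(aa)
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$gene_id[i]]]
    if (sites$codon[i] < 1L || sites$codon[i] > length(s))
      stop("peak at codon ", sites$codon[i], " lies outside protein ",
           sites$gene_id[i])
    pos <- sites$codon[i] + offs
    keep <- pos >= 1L & pos <= length(s)
    out[i, keep] <- s[pos[keep]]
  }
  out
}

#' Build an amino-acid context matrix
#'
#' Tallies each of the 21 symbols (20 amino acids + stop) at every offset of
#' a set of context windows. The frequency of a symbol at a position is its
#' count divided by the number of peaks scored there; truncated windows
#' shrink the totals rather than contributing padding.
#'
#' @param contexts character matrix from [extractContexts()].
#' @return a [ContextMatrix-class].
#' @export
contextMatrix <- function(contexts) {
  counts <- vapply(seq_len(ncol(contexts)), function(j) {
    tab <- table(factor(contexts[, j], levels = AA_SYMBOLS))
    as.integer(tab)
  }, integer(length(AA_SYMBOLS)))
  dimnames(counts) <- list(AA_SYMBOLS, colnames(contexts))
  new("ContextMatrix", counts = counts,
      totals = as.integer(colSums(counts)),
      nPeaks = nrow(contexts),
      window = as.integer((ncol(contexts) - 1L) / 2L))
}

#' Per-cell enrichment between two context matrices
#'
#' Compares symbol counts against position totals between two peak sets
#' (e.g. aneuploid-higher versus euploid-higher) with a two-sided Fisher
#' exact test per cell, adjusts across all cells jointly with
#' Benjamini-Hochberg, and reports the log2 fold difference in frequency.
#' Cells at positions with a zero total in either matrix are skipped. Where
#' a frequency is zero, the reported (never the tested) fold difference uses
#' a Haldane-Anscombe +0.5 on all four counts.
#'
#' @param matrixB,matrixA [ContextMatrix-class] objects built with the same
#'   window; `log2fd > 0` means enriched in `matrixB`.
#' @param alpha FDR threshold for the significance mask, default 0.05.
#' @return [S4Vectors::DataFrame] with one row per tested cell: `symbol`,
#'   `position`, counts and totals for both sets, `freq_b`, `freq_a`,
#'   `log2fd`, `p`, `q`, `significant`, and `log2fd_masked` (`log2fd` where
#'   significant, else `NA`).
#' @seealso [enrichmentMatrix()] for a heat-map-ready symbols x positions
#'   matrix.
#' @export
contextEnrichment <- function(matrixB, matrixA, alpha = 0.05) {
  stopifnot(is(matrixB, "ContextMatrix"), is(matrixA, "ContextMatrix"))
  if (!identical(colnames(matrixB@counts), colnames(matrixA@counts)))
    stop("matrices were built with different windows")
  pos <- colnames(matrixB@counts)
  grid <- expand.grid(symbol = AA_SYMBOLS, position = pos,
                      stringsAsFactors = FALSE)
  cb <- matrixB@counts[cbind(grid$symbol, grid$position)]
  ca <- matrixA@counts[cbind(grid$symbol, grid$position)]
  tb <- matrixB@totals[match(grid$position, pos)]
  ta <- matrixA@totals[match(grid$position, pos)]
  keep <- tb > 0L & ta > 0L
  grid <- grid[keep, ]; cb <- cb[keep]; ca <- ca[keep]
  tb <- tb[keep]; ta <- ta[keep]

  p <- .fisher2x2(cb, tb, ca, ta)
  q <- bhAdjust(p)
  fb <- cb / tb; fa <- ca / ta
  log2fd <- log2(fb / fa)
  zero <- fb == 0 | fa == 0
  log2fd[zero] <- log2(((cb[zero] + 0.5) / (tb[zero] + 0.5)) /
                         ((ca[zero] + 0.5) / (ta[zero] + 0.5)))
  sig <- q < alpha
  res <- S4Vectors::DataFrame(
    symbol = grid$symbol, position = as.integer(grid$position),
    count_b = cb, total_b = tb, count_a = ca, total_a = ta,
    freq_b = fb, freq_a = fa, log2fd = log2fd, p = p, q = q,
    significant = sig,
    log2fd_masked = ifelse(sig, log2fd, NA_real_))
  S4Vectors::metadata(res) <- list(alpha = alpha, n_cells = nrow(res))
  res
}

#' Heat-map-ready enrichment matrix
#'
#' Reshapes a [contextEnrichment()] result into a symbols x positions matrix
#' of masked log2 fold differences (`NA` where not significant or skipped).
#'
#' @param enrichment result of [contextEnrichment()].
#' @export
enrichmentMatrix <- function(enrichment) {
  pos <- sort(unique(enrichment$position))
  m <- matrix(NA_real_, length(AA_SYMBOLS), length(pos),
              dimnames = list(AA_SYMBOLS, as.character(pos)))
  m[cbind(enrichment$symbol, as.character(enrichment$position))] <-
    enrichment$log2fd_masked
  m
}
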