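#' @include AllClasses.R
NULL

#' Spike-in slope normalization
#'
#' Anchors every sample to the constant-per-cell spike-in genes: the
#' reference profile is the geometric mean of spike counts across samples,
#' each sample's scale factor is the through-origin least-squares slope of
#' its spike counts against that reference, and normalized counts are
#' `counts / factor`. After normalization the spike slope of every sample
#' against the reference is 1, so target-gene changes are on a per-cell
#' scale.
#'
#' @param counts integer matrix, genes x samples.
#' @param species named vector tagging each gene `"target"` or `"spike"`.
#' @return list with `factors` (per-sample slopes), `normalized` (numeric
#'   matrix) and `reference` (spike-gene reference profile).
#' @export
spikeScale <- function(counts, species) {
  spikes <- names(species)[species == "spike"]
  spikes <- intersect(spikes, rownames(counts))
  if (length(spikes) < 2L) stop("need >= 2 spike genes in the count table")
  sm <- counts[spikes, , drop = FALSE]
  if (any(colSums(sm) == 0))
    stop("sample(s) with zero spike counts: ",
         paste(colnames(sm)[colSums(sm) == 0], collapse = ", "))
  ref <- exp(rowMeans(log(sm)))  # zero anywhere -> ref 0, gene drops out
  ref[!is.finite(ref)] <- 0
  if (all(ref == 0)) stop("every spike gene has a zero count somewhere")
  factors <- apply(sm, 2, function(y) sum(ref * y) / sum(ref^2))
  normalized <- sweep(counts, 2, factors, "/")
  list(factors = factors, normalized = normalized, reference = ref)
}

#' Log2 fold changes between sample groups
#'
#' Mean normalized count per group with a pseudocount guard, on whatever
#' scale `normalized` is on (typically the per-cell scale from
#' [spikeScale()]).
#'
#' @param normalized numeric matrix, genes x samples.
#' @param groupA,groupB column names of the two groups; the fold change is
#'   B over A.
#' @param pseudocount added to both group means, default 0.5.
#' @return named numeric vector of `log2(meanB + pc) - log2(meanA + pc)`.
#' @export
foldChangeTable <- function(normalized, groupA, groupB, pseudocount = 0.5) {
  ma <- rowMeans(normalized[, groupA, drop = FALSE])
  mb <- rowMeans(normalized[, groupB, drop = FALSE])
  log2((mb + pseudocount) / (ma + pseudocount))
}

#' Method-of-moments common dispersion
#'
#' Median across genes of the per-gene moment estimate
#' `(variance - mean) / mean^2` on counts scaled to a common library size,
#' floored at zero. Groups with fewer than two samples are ignored.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups list of character vectors of column names, one per group.
#' @param sizes effective library sizes (default: column sums).
#' @return a single nonnegative dispersion estimate.
#' @export
estimateDispersion <- function(counts, groups, sizes = NULL) {
  if (is.null(sizes)) sizes <- colSums(counts)
  M <- exp(mean(log(sizes)))
  adj <- sweep(counts, 2, M / sizes, "*")
  phis <- numeric(0)
  for (g in groups) {
    if (length(g) < 2L) next
    m <- adj[, g, drop = FALSE]
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ok <- mu > 1
    phis <- c(phis, (v[ok] - mu[ok]) / mu[ok]^2)
  }
  if (!length(phis)) return(0)
  max(0, stats::median(phis))
}

nbTailProbs <- function(s, nA, nB, phi) {
  k <- 0:s
  m <- s / (nA + nB)
  if (phi > 0) {
    la <- stats::dnbinom(k, size = nA / phi, mu = nA * m, log = TRUE)
    lb <- stats::dnbinom(s - k, size = nB / phi, mu = nB * m, log = TRUE)
  } else {
    la <- stats::dpois(k, nA * m, log = TRUE)
    lb <- stats::dpois(s - k, nB * m, log = TRUE)
  }
  w <- la + lb
  w <- exp(w - max(w))
  w / sum(w)
}

#' Exact negative-binomial test between two sample groups
#'
#' Conditional two-group exact test on counts rescaled to a common library
#' size: group sums are modelled as negative binomial with a common
#' dispersion, the first group's sum is tested against its conditional
#' distribution given the two-group total, and the two-sided p-value doubles
#' the smaller tail (capped at 1). With `dispersion = 0` this reduces to the
#' exact conditional Poisson (binomial) test. Calibration, not numerical
#' agreement with any particular DE tool, is the design goal.
#'
#' @param countsA,countsB integer matrices (genes x samples) or vectors for
#'   single-sample groups; row order must match.
#' @param sizes effective library sizes for the columns of `countsA`
#'   followed by those of `countsB` (default: column sums).
#' @param dispersion common NB dispersion (>= 0).
#' @return numeric vector of two-sided p-values, named by gene.
#' @export
nbExactTest <- function(countsA, countsB, sizes = NULL, dispersion = 0) {
  if (is.null(dim(countsA))) countsA <- cbind(countsA)
  if (is.null(dim(countsB))) countsB <- cbind(countsB)
  if (nrow(countsA) != nrow(countsB))
    stop("countsA and countsB must have the same genes")
  if (dispersion < 0) stop("dispersion must be >= 0")
  nA <- ncol(countsA); nB <- ncol(countsB)
  if (is.null(sizes)) sizes <- c(colSums(countsA), colSums(countsB))
  if (length(sizes) != nA + nB)
    stop("sizes must cover every sample of both groups")
  M <- exp(mean(log(sizes)))
  adjA <- round(sweep(countsA, 2, M / sizes[seq_len(nA)], "*"))
  adjB <- round(sweep(countsB, 2, M / sizes[nA + seq_len(nB)], "*"))
  kA <- rowSums(adjA); kB <- rowSums(adjB)
  p <- numeric(length(kA))
  for (i in seq_along(kA)) {
    s <- kA[i] + kB[i]
    if (s == 0) { p[i] <- 1; next }
    w <- nbTailProbs(s, nA, nB, dispersion)
    obs <- kA[i]
    pLow <- sum(w[seq_len(obs + 1)])
    pHigh <- sum(w[(obs + 1):(s + 1)])
    p[i] <- min(1, 2 * min(pLow, pHigh))
  }
  names(p) <- rownames(countsA)
  p
}

#' Group-versus-group differential test table
#'
#' Convenience wrapper: rescales to a common library size, computes log2
#' fold changes (B over A) and [nbExactTest()] p-values with BH-adjusted
#' q-values. Dispersion defaults to the method-of-moments estimate pooled
#' over both groups.
#'
#' @param counts integer matrix, genes x samples.
#' @param groupA,groupB column names of the two groups.
#' @param sizes effective library sizes for all columns of `counts`
#'   (default: column sums); e.g. the `factors` from [spikeScale()] times a
#'   constant.
#' @param dispersion common NB dispersion; `NULL` to estimate.
#' @return [S4Vectors::DataFrame]: `gene`, `log2FC`, `p`, `q`.
#' @export
nbDiffTest <- function(counts, groupA, groupB, sizes = NULL,
                       dispersion = NULL) {
  miss <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  if (is.null(sizes)) sizes <- colSums(counts)
  if (is.null(names(sizes))) names(sizes) <- colnames(counts)
  if (is.null(dispersion))
    dispersion <- estimateDispersion(counts, list(groupA, groupB),
                                     sizes[colnames(counts)])
  norm <- sweep(counts, 2, sizes[colnames(counts)] /
                  exp(mean(log(sizes))), "/")
  p <- nbExactTest(counts[, groupA, drop = FALSE],
                   counts[, groupB, drop = FALSE],
                   sizes = sizes[c(groupA, groupB)],
                   dispersion = dispersion)
  S4Vectors::DataFrame(
    gene = rownames(counts),
    log2FC = unname(foldChangeTable(norm, groupA, groupB)),
    p = unname(p), q = unname(bhAdjust(p)))
}

#' Genes failing quiescent transcriptome silencing in every aneuploid
#'
#' Implements the repression-defect gene-set rule: a gene qualifies when it
#' is significantly repressed in the euploid strain (q < alpha and
#' log2FC < 0, in any supplied quiescent-versus-log contrast) *and*, for
#' every aneuploid, is significantly higher than euploid (q < alpha and
#' log2FC > 0) in at least one timepoint.
#'
#' @param euVsLog a [nbDiffTest()]-style table (or list of them, one per
#'   quiescent timepoint) for euploid quiescent versus log.
#' @param anVsEu named list, one entry per aneuploid, each a table or list
#'   of per-timepoint tables for that aneuploid versus euploid.
#' @param alpha FDR threshold, default 0.05.
#' @return sorted character vector of qualifying genes.
#' @export
repressionDefectSet <- function(euVsLog, anVsEu, alpha = 0.05) {
  asList <- function(x) if (is.data.frame(x) || is(x, "DataFrame"))
    list(x) else x
  euVsLog <- asList(euVsLog)
  if (!length(euVsLog)) stop("missing contrast: euploid versus log")
  if (!length(anVsEu)) stop("missing contrast: aneuploid versus euploid")
  repressed <- Reduce(union, lapply(euVsLog, function(d)
    d$gene[!is.na(d$q) & d$q < alpha & d$log2FC < 0]))
  higherInAll <- NULL
  for (an in names(anVsEu)) {
    tabs <- asList(anVsEu[[an]])
    if (!length(tabs))
      stop("missing contrast: ", an, " versus euploid")
    up <- Reduce(union, lapply(tabs, function(d)
      d$gene[!is.na(d$q) & d$q < alpha & d$log2FC > 0]))
    higherInAll <- if (is.null(higherInAll)) up
                   else intersect(higherInAll, up)
  }
  sort(intersect(repressed, higherInAll))
}

#' Count deeply repressed genes
#'
#' Genes whose spike-normalized log2 fold change is at or below
#' `-log2(foldThreshold)`; with the default 256, a gene must be more than
#' 256-fold below its reference level.
#'
#' @param log2fc named numeric vector of log2 fold changes (quiescent over
#'   log), or a table with `gene` and `log2FC` columns.
#' @param foldThreshold repression depth on the linear scale, default 256.
#' @return list with `count`, `genes` and `threshold_log2`.
#' @export
deepRepressionCount <- function(log2fc, foldThreshold = 256) {
  if (!is.numeric(log2fc)) {
    v <- log2fc$log2FC
    names(v) <- log2fc$gene
    log2fc <- v
  }
  thr <- -log2(foldThreshold)
  genes <- names(log2fc)[!is.na(log2fc) & log2fc <= thr]
  list(count = length(genes), genes = genes, threshold_log2 = thr)
}
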