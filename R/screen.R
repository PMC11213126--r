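#' @include silencing.R
NULL

#' Trimmed-mean-of-M (TMM) normalization factors
#'
#' Between-sample scaling factors from trimmed log-ratios of counts: the
#' reference is the sample whose 75th-percentile count rate is closest to
#' the mean such rate; for every sample, barcodes present in both it and the
#' reference contribute an M-value (log2 count ratio versus the reference)
#' and an A-value (average log2 count), the most extreme 30% of M and 5% of
#' A are trimmed two-sidedly, and the factor is the precision-weighted mean
#' of the remaining M-values. Factors are geometrically centred so their
#' product is 1.
#'
#' Factors are on the absolute count scale -- a sample sequenced twice as
#' deeply with no differential barcodes gets twice the factor -- so
#' `counts / factor` is directly comparable across samples and the factor
#' itself serves as the effective library size.
#'
#' @param counts integer matrix, genes/barcodes x samples; >= 2 samples with
#'   nonzero totals.
#' @param trimM,trimA two-sided trim fractions, defaults 0.3 and 0.05.
#' @return named numeric vector of factors with product 1.
#' @export
tmmFactors <- function(counts, trimM = 0.3, trimA = 0.05) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, 0.75)
  refIdx <- which.min(abs(uq - mean(uq)))
  r <- counts[, refIdx]; lr <- lib[refIdx]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- as.numeric(counts[, j]); ly <- lib[j]
    keep <- y > 0 & r > 0
    y <- y[keep]; rr <- as.numeric(r[keep])
    M <- log2(y / rr)
    A <- 0.5 * log2(y * rr)
    w <- 1 / ((ly - y) / (ly * y) + (lr - rr) / (lr * rr))
    loM <- stats::quantile(M, trimM); hiM <- stats::quantile(M, 1 - trimM)
    loA <- stats::quantile(A, trimA); hiA <- stats::quantile(A, 1 - trimA)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) return(1)
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Barcode enrichment versus the starting pool
#'
#' Scores the change in TMM-normalized relative barcode abundance between
#' the starting pool and a later timepoint: log2 fold change of
#' factor-adjusted abundance, an exact negative-binomial p-value
#' ([nbExactTest()]) with the pool as one group and the replicate cultures
#' as the other, and BH q-values across genes. Barcodes absent from the
#' pool cannot be scored and are flagged.
#'
#' @param poolCounts named vector (or 1-column matrix) of starting-pool
#'   counts.
#' @param dayCounts matrix of counts at the timepoint, barcodes x
#'   replicates; rownames must match `poolCounts`.
#' @param dispersion common NB dispersion; `NULL` to estimate from the
#'   replicates.
#' @param factors optional TMM factors for `cbind(pool, day)`; computed if
#'   missing.
#' @return [S4Vectors::DataFrame]: `gene`, `log2FC`, `p`, `q`,
#'   `in_pool`; rows absent from the pool have `NA` statistics.
#' @export
enrichmentTest <- function(poolCounts, dayCounts, dispersion = NULL,
                           factors = NULL) {
  if (is.null(dim(poolCounts))) poolCounts <- cbind(pool = poolCounts)
  stopifnot(nrow(poolCounts) == nrow(dayCounts))
  all <- cbind(poolCounts, dayCounts)
  if (is.null(factors)) factors <- tmmFactors(all)
  ## absolute-scale TMM factors: the factor is the effective library size
  ## (up to a constant)
  sizes <- factors * exp(mean(log(colSums(all))))
  inPool <- poolCounts[, 1] > 0
  if (is.null(dispersion)) {
    dispersion <- if (ncol(dayCounts) >= 2)
      estimateDispersion(dayCounts, list(colnames(dayCounts)),
                         sizes[-1]) else 0
  }
  norm <- sweep(all, 2, sizes / exp(mean(log(sizes))), "/")
  p <- nbExactTest(poolCounts, dayCounts, sizes = sizes,
                   dispersion = dispersion)
  lfc <- foldChangeTable(norm, colnames(all)[1], colnames(dayCounts))
  p[!inPool] <- NA_real_
  lfc[!inPool] <- NA_real_
  S4Vectors::DataFrame(gene = rownames(all), log2FC = unname(lfc),
                       p = unname(p), q = unname(bhAdjust(p)),
                       in_pool = unname(inPool))
}

#' Two-stage screen hit selection and day-1/day-28 classification
#'
#' A gene is a hit when its day-28 enrichment over the starting pool in the
#' aneuploid background is significantly positive (q < alpha, log2FC > 0)
#' *and* its average day-28 enrichment exceeds the euploid's by at least
#' `log2(fold)`. Hits are partitioned into `day1_and_day28` (also
#' significantly positive at day 1 in the aneuploid) and `day28_only`.
#'
#' @param resAn,resEu named lists with elements `day1` and `day28`, each an
#'   [enrichmentTest()] table, for the aneuploid and euploid backgrounds.
#' @param alpha FDR threshold (both timepoints), default 0.05.
#' @param fold minimum aneuploid-over-euploid day-28 abundance ratio,
#'   default 2 (i.e. a log2 difference of at least 1).
#' @return [S4Vectors::DataFrame]: `gene`, `log2FC_day1_an`,
#'   `log2FC_day28_an`, `q_day1_an`, `q_day28_an`, `log2FC_day28_eu`,
#'   `delta_vs_euploid`, `class` in {`not_hit`, `day28_only`,
#'   `day1_and_day28`}.
#' @export
classifyHits <- function(resAn, resEu, alpha = 0.05, fold = 2) {
  for (nm in c("day1", "day28")) {
    if (is.null(resAn[[nm]])) stop("missing aneuploid timepoint: ", nm)
    if (is.null(resEu[[nm]])) stop("missing euploid timepoint: ", nm)
  }
  genes <- resAn$day28$gene
  a1 <- resAn$day1[match(genes, resAn$day1$gene), ]
  a28 <- resAn$day28
  e28 <- resEu$day28[match(genes, resEu$day28$gene), ]
  delta <- a28$log2FC - e28$log2FC
  hit <- !is.na(a28$q) & a28$q < alpha & a28$log2FC > 0 &
    !is.na(delta) & delta >= log2(fold)
  day1pos <- !is.na(a1$q) & a1$q < alpha & a1$log2FC > 0
  cls <- ifelse(!hit, "not_hit",
                ifelse(day1pos, "day1_and_day28", "day28_only"))
  S4Vectors::DataFrame(
    gene = genes,
    log2FC_day1_an = a1$log2FC, log2FC_day28_an = a28$log2FC,
    q_day1_an = a1$q, q_day28_an = a28$q,
    log2FC_day28_eu = e28$log2FC, delta_vs_euploid = delta,
    class = cls)
}

#' Score a simulated screen end to end
#'
#' Runs [enrichmentTest()] for both backgrounds and timepoints of a
#' [simulateScreen()] result and classifies hits with [classifyHits()].
#'
#' @param sc result of [simulateScreen()].
#' @param alpha,fold passed to [classifyHits()].
#' @param dispersion passed to [enrichmentTest()]; `NULL` to estimate.
#' @return list with `results` (per background, per timepoint enrichment
#'   tables) and `hits` (the classification table).
#' @export
scoreScreen <- function(sc, alpha = 0.05, fold = 2, dispersion = NULL) {
  s <- sc$samples
  res <- list()
  for (bg in unique(s$background)) {
    pool <- sc$counts[, s$sample_id[s$background == bg &
                                      s$timepoint == "pool"], drop = FALSE]
    res[[bg]] <- list()
    for (tp in c("day1", "day28")) {
      day <- sc$counts[, s$sample_id[s$background == bg &
                                       s$timepoint == tp], drop = FALSE]
      res[[bg]][[tp]] <- enrichmentTest(pool, day, dispersion = dispersion)
    }
  }
  list(results = res,
       hits = classifyHits(res$aneuploid, res$euploid,
                           alpha = alpha, fold = fold))
}
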