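#' @include AllClasses.R
NULL

#' Two-sided Fisher exact test for codon versus gene-body counts
#'
#' Tests the 2x2 table `[[c1, body1 - c1], [c2, body2 - c2]]` -- reads at a
#' codon against the rest of that gene's interior reads, in two conditions.
#' The two-sided p-value sums, over the hypergeometric support, every table
#' probability not exceeding that of the observed table. Vectorized over
#' tables; a zero body total yields `NA` (such genes fail the read filter
#' upstream).
#'
#' @param c1,body1 codon and gene-body counts in condition 1.
#' @param c2,body2 same for condition 2.
#' @return numeric vector of two-sided p-values in `[0, 1]`.
#' @examples
#' fisherCodonTest(5, 100, 5, 100)  # identical margins: p = 1
#' @export
fisherCodonTest <- function(c1, body1, c2, body2) {
  n <- max(length(c1), length(body1), length(c2), length(body2))
  c1 <- rep_len(as.integer(c1), n); body1 <- rep_len(as.integer(body1), n)
  c2 <- rep_len(as.integer(c2), n); body2 <- rep_len(as.integer(body2), n)
  if (any(c1 > body1, na.rm = TRUE) || any(c2 > body2, na.rm = TRUE))
    stop("codon counts cannot exceed gene-body counts")
  .fisher2x2(c1, body1, c2, body2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: `q(i) = min over j >= i of m * p(j) / j`
#' on the sorted p-values. `NA`s are propagated.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential ribosome pause sites between paired samples
#'
#' For every retained gene and interior codon, compares raw codon counts to
#' gene-body counts between the two conditions of a replicate pair with
#' [fisherCodonTest()], applies [bhAdjust()] across all tested codons of all
#' genes within that pair, and calls peaks at `q < alpha`. Direction is
#' assigned from pseudocount-normalized occupancy (condition with the larger
#' occupancy at the codon); peaks with exactly tied occupancy have no
#' defensible direction and are dropped (tallied in
#' `metadata()$ties_dropped`). Raw counts enter the test; occupancy is used
#' only for direction.
#'
#' @param x a filtered [CodonProfileSet-class] of raw counts; apply
#'   [filterGenes()] jointly over the samples of each pair first.
#' @param pairing data.frame with columns `sample_a`, `sample_b` (e.g.
#'   euploid and aneuploid members of one replicate pair) and `pair` (label);
#'   any further columns are carried through.
#' @param alpha FDR threshold in (0, 1), default 0.05.
#' @param returnAll if `TRUE`, return every tested codon with a `peak`
#'   column; otherwise only the called peaks.
#' @return a [S4Vectors::DataFrame] with columns `pair`, `gene_id`, `codon`,
#'   `count_a`, `body_a`, `count_b`, `body_b`, `occ_a`, `occ_b`,
#'   `normalized_ratio` (occ_b / occ_a), `p`, `q`, `direction`
#'   (`"a_higher"`/`"b_higher"`); `metadata()` records `alpha`, `n_tests`
#'   and `ties_dropped`.
#' @export
callPeaks <- function(x, pairing, alpha = 0.05, returnAll = FALSE) {
  stopifnot(is(x, "CodonProfileSet"), !x@normalized)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!all(c("sample_a", "sample_b", "pair") %in% colnames(pairing)))
    stop("pairing needs columns sample_a, sample_b, pair")
  ids <- x@geneInfo$gene_id
  lens <- x@geneInfo$length_codons
  nInt <- pmax(lens - 2L * x@edge, 0L)
  if (any(nInt == 0L))
    stop("gene(s) without an interior window; filter them out first")
  extra <- setdiff(colnames(pairing), c("sample_a", "sample_b", "pair"))
  rowsByGene <- lapply(seq_along(ids),
                       function(k) x@flankUp + seq(x@edge + 1L,
                                                   lens[k] - x@edge))
  out <- vector("list", nrow(pairing))
  for (pr in seq_len(nrow(pairing))) {
    sa <- pairing$sample_a[pr]; sb <- pairing$sample_b[pr]
    caL <- cbL <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      cm <- x@counts[[ids[k]]]
      caL[[k]] <- cm[rowsByGene[[k]], sa]
      cbL[[k]] <- cm[rowsByGene[[k]], sb]
    }
    ca <- unlist(caL, use.names = FALSE)
    cb <- unlist(cbL, use.names = FALSE)
    bodyA <- rep(vapply(caL, sum, numeric(1)), nInt)
    bodyB <- rep(vapply(cbL, sum, numeric(1)), nInt)
    ## pseudocounted occupancy, identical to normalizeProfiles() at
    ## interior codons: (c + 1) / (body + n_interior)
    tab <- data.frame(
      gene_id = rep(ids, nInt),
      codon = unlist(lapply(seq_along(ids),
                            function(k) seq(x@edge + 1L,
                                            lens[k] - x@edge)),
                     use.names = FALSE),
      count_a = ca, body_a = bodyA, count_b = cb, body_b = bodyB,
      occ_a = (ca + 1) / (bodyA + rep(nInt, nInt)),
      occ_b = (cb + 1) / (bodyB + rep(nInt, nInt)))
    tab$p <- .fisher2x2(tab$count_a, tab$body_a, tab$count_b, tab$body_b)
    tab$q <- bhAdjust(tab$p)
    tab$normalized_ratio <- tab$occ_b / tab$occ_a
    tab$direction <- ifelse(tab$occ_b > tab$occ_a, "b_higher",
                            ifelse(tab$occ_b < tab$occ_a, "a_higher",
                                   NA_character_))
    sig <- !is.na(tab$q) & tab$q < alpha
    tie <- sig & is.na(tab$direction)
    tab$peak <- sig & !is.na(tab$direction)
    res <- S4Vectors::DataFrame(pair = pairing$pair[pr], tab)
    for (cn in extra) res[[cn]] <- pairing[[cn]][pr]
    S4Vectors::metadata(res) <- list(alpha = alpha, n_tests = nrow(tab),
                                     ties_dropped = sum(tie))
    out[[pr]] <- res
  }
  res <- do.call(rbind, out)
  S4Vectors::metadata(res) <- list(
    alpha = alpha,
    n_tests = sum(vapply(out, function(o)
      S4Vectors::metadata(o)$n_tests, numeric(1))),
    ties_dropped = sum(vapply(out, function(o)
      S4Vectors::metadata(o)$ties_dropped, numeric(1))))
  if (returnAll) res else {
    peaks <- res[res$peak, , drop = FALSE]
    S4Vectors::metadata(peaks) <- S4Vectors::metadata(res)
    peaks
  }
}

#' Combine peak calls across replicates
#'
#' Takes the union of significant codons over replicate pairs, per
#' direction. A codon called in opposite directions in different replicates
#' has no coherent assignment and is excluded (returned in `conflicts`).
#' Reports the number of sites and of distinct transcripts per direction.
#'
#' @param peaks a peak table from [callPeaks()] covering >= 1 replicate
#'   pairs of the same condition contrast.
#' @return list with `sites` (DataFrame: `gene_id`, `codon`, `direction`,
#'   `n_replicates`), `summary` (data.frame: `direction`, `n_sites`,
#'   `n_transcripts`) and `conflicts` (DataFrame of excluded sites).
#' @export
combineReplicates <- function(peaks) {
  key <- paste(peaks$gene_id, peaks$codon, sep = "\r")
  dirByKey <- split(peaks$direction, key)
  geneByKey <- vapply(strsplit(names(dirByKey), "\r"), `[`, character(1), 1)
  codonByKey <- as.integer(vapply(strsplit(names(dirByKey), "\r"),
                                  `[`, character(1), 2))
  nDir <- vapply(dirByKey, function(d) length(unique(d)), integer(1))
  ok <- nDir == 1L
  sites <- S4Vectors::DataFrame(
    gene_id = geneByKey[ok], codon = codonByKey[ok],
    direction = vapply(dirByKey[ok], `[`, character(1), 1),
    n_replicates = lengths(dirByKey[ok]))
  sites <- sites[order(sites$gene_id, sites$codon), , drop = FALSE]
  rownames(sites) <- NULL
  conflicts <- S4Vectors::DataFrame(
    gene_id = geneByKey[!ok], codon = codonByKey[!ok])
  dirs <- c("a_higher", "b_higher")
  summary <- data.frame(
    direction = dirs,
    n_sites = vapply(dirs, function(d)
      sum(sites$direction == d), integer(1)),
    n_transcripts = vapply(dirs, function(d)
      length(unique(sites$gene_id[sites$direction == d])), integer(1)),
    row.names = NULL)
  list(sites = sites, summary = summary, conflicts = conflicts)
}
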