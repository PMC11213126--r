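#' @include AllClasses.R
NULL

#' Normalize codon profiles to gene-body-relative occupancy
#'
#' Adds one pseudocount to every codon and divides by the pseudocounted sum
#' over the interior window (codons 21..L-20), so interior occupancy sums to
#' exactly 1 for every gene and sample; flanking codons share the interior
#' denominator. Genes whose interior window is empty (fewer than 41 codons)
#' are excluded with a message.
#'
#' @param x a [CodonProfileSet-class] of raw counts.
#' @param pseudocount added to every codon before normalization (default 1).
#' @return a [CodonProfileSet-class] with `normalized = TRUE` and numeric
#'   occupancy matrices.
#' @export
normalizeProfiles <- function(x, pseudocount = 1) {
  stopifnot(is(x, "CodonProfileSet"), !x@normalized)
  ids <- x@geneInfo$gene_id
  empty <- vapply(ids, function(g) length(interiorRows(x, g)) == 0L,
                  logical(1))
  if (any(empty)) {
    message("excluding ", sum(empty),
            " gene(s) with an empty interior window (< ",
            2L * x@edge + 1L, " codons)")
    ids <- ids[!empty]
  }
  if (!length(ids)) stop("no genes with a nonempty interior window")
  occ <- vector("list", length(ids))
  names(occ) <- ids
  for (g in ids) {
    m <- x@counts[[g]] + pseudocount
    denom <- colSums(m[interiorRows(x, g), , drop = FALSE])
    occ[[g]] <- sweep(m, 2, denom, "/")
  }
  new("CodonProfileSet", counts = occ,
      geneInfo = x@geneInfo[match(ids, x@geneInfo$gene_id), , drop = FALSE],
      samples = x@samples, flankUp = x@flankUp, flankDown = x@flankDown,
      edge = x@edge, outOfWindow = x@outOfWindow, normalized = TRUE)
}

#' Uncentered Pearson correlation (cosine similarity)
#'
#' `sum(a*b) / (||a|| ||b||)`: the Pearson correlation computed without mean
#' centering, i.e. the cosine of the angle between the two occupancy traces.
#' Scale-invariant; returns `NA` if either vector has zero norm.
#'
#' @param a,b numeric vectors of equal length.
#' @export
uncenteredCorrelation <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Per-gene occupancy-trace correlations across a condition pairing
#'
#' For every gene and every row of `pairing`, computes the uncentered
#' Pearson correlation between the two samples' occupancy over the interior
#' window (flanks excluded, since their denominator comes from a different
#' region). Both samples must be columns of `x`.
#'
#' @param x a normalized [CodonProfileSet-class] (see [normalizeProfiles()]).
#' @param pairing data.frame with columns `sample_a` and `sample_b`; any
#'   additional columns (e.g. `replicate`, `phase`) are carried through.
#' @return a [S4Vectors::DataFrame] with one row per (gene, pair):
#'   `gene_id`, the pairing columns, and `correlation`.
#' @export
correlationTable <- function(x, pairing) {
  stopifnot(is(x, "CodonProfileSet"), x@normalized,
            all(c("sample_a", "sample_b") %in% colnames(pairing)))
  sids <- rownames(x@samples)
  bad <- setdiff(c(pairing$sample_a, pairing$sample_b), sids)
  if (length(bad))
    stop("unmatched sample(s) in pairing: ", paste(bad, collapse = ", "))
  ids <- x@geneInfo$gene_id
  res <- vector("list", nrow(pairing))
  for (p in seq_len(nrow(pairing))) {
    r <- vapply(ids, function(g) {
      m <- x@counts[[g]][interiorRows(x, g), , drop = FALSE]
      uncenteredCorrelation(m[, pairing$sample_a[p]],
                            m[, pairing$sample_b[p]])
    }, numeric(1))
    block <- S4Vectors::DataFrame(gene_id = ids)
    for (cn in colnames(pairing)) block[[cn]] <- pairing[[cn]][p]
    block$correlation <- unname(r)
    res[[p]] <- block
  }
  do.call(rbind, res)
}
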