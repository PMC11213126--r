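#' @include simConfig.R
NULL

defaultFitnessEffects <- function(config, barcodes) {
  ## planted scenario: aneuploid-specific late benefit (quiescence survival
  ## only: no outgrowth advantage, strong by day 28), aneuploid-specific
  ## early+late benefit, and a background-shared benefit that the 2-fold
  ## aneuploid-vs-euploid rule must reject.  Effect sizes sit above the 4x
  ## day-28 detectability bound.
  z <- setNames(numeric(length(barcodes)), barcodes)
  fEuE <- fEuL <- fAnE <- fAnL <- z
  cls <- setNames(rep("not_hit", length(barcodes)), barcodes)
  pick <- sample(barcodes, 25)
  late <- pick[1:12]; both <- pick[13:20]; shared <- pick[21:25]
  fAnL[late] <- 0.1                    # survival benefit only
  cls[late] <- "day28_only"
  fAnE[both] <- 0.3; fAnL[both] <- 0.3 # constant growth-rate delta
  cls[both] <- "day1_and_day28"
  fAnE[shared] <- 0.2; fAnL[shared] <- 0.2
  fEuE[shared] <- 0.2; fEuL[shared] <- 0.2  # equal benefit: not_hit
  S4Vectors::DataFrame(gene = barcodes,
                       fitness_euploid_early = fEuE,
                       fitness_euploid_late = fEuL,
                       fitness_aneuploid_early = fAnE,
                       fitness_aneuploid_late = fAnL,
                       expected_class = cls)
}

## per-gene log-abundance increment at day t for one background; constant
## fitness f has early == late and reduces to a0 * exp(f * t)
fitnessAt <- function(fit, bg, t) {
  early <- fit[[paste0("fitness_", bg, "_early")]]
  late <- fit[[paste0("fitness_", bg, "_late")]]
  if (is.null(early)) early <- late <- fit[[paste0("fitness_", bg)]]
  if (is.null(early)) stop("fitnessEffects lacks columns for ", bg)
  early * pmin(t, 1) + late * pmax(t - 1, 0)
}

#' Simulate a pooled barcode fitness screen
#'
#' Relative barcode abundance evolves as `a(t) = a(0) * exp(f * t)` with
#' per-gene growth-rate deltas `f` per background (day 1 is t = 1, day 28 is
#' t = 28). `f` may differ between the outgrowth phase (t <= 1) and the
#' quiescence-survival phase (t > 1) -- columns `fitness_<bg>_early` /
#' `fitness_<bg>_late`; a single `fitness_<bg>` column applies to both
#' phases and recovers the constant-rate model exactly. Counts are sampled
#' multinomially at the configured depth, so each sample's counts sum
#' exactly to it; replicate cultures add gamma noise with the configured
#' overdispersion. With no `fitnessEffects` in the config, a default
#' scenario is planted (see [simConfig()]) and recorded in the truth object
#' together with each gene's expected classification.
#'
#' @param config a [RiboSimConfig-class].
#' @param backgrounds strain backgrounds screened in parallel pools.
#' @return list with `counts` (integer matrix, barcodes x samples), `samples`
#'   ([S4Vectors::DataFrame]: `sample_id`, `background`, `timepoint` in
#'   {pool, day1, day28}, `replicate`) and `truth` ([SimTruth-class]).
#' @examples
#' sc <- simulateScreen(simConfig(nBarcodes = 100, screenDepth = 1e5,
#'                                seed = 4))
#' head(sc$truth@fitness[sc$truth@fitness$expected_class != "not_hit", ])
#' @export
simulateScreen <- function(config, backgrounds = c("euploid", "aneuploid")) {
  stopifnot(is(config, "RiboSimConfig"))
  set.seed(subSeed(config, "screen"))
  barcodes <- sprintf("b%04d", seq_len(config@nBarcodes))
  fit <- if (nrow(config@fitnessEffects)) config@fitnessEffects
         else defaultFitnessEffects(config, barcodes)
  if (!all(barcodes %in% fit$gene))
    stop("fitnessEffects must cover every barcode")

  a0 <- stats::rlnorm(length(barcodes), 0, 0.3)
  names(a0) <- barcodes
  phi <- config@screenDispersion
  depth <- round(config@screenDepth)

  draw <- function(abundance) {
    if (phi > 0)
      abundance <- abundance *
        stats::rgamma(length(abundance), shape = 1 / phi, rate = 1 / phi)
    as.integer(stats::rmultinom(1, depth, abundance))
  }

  cols <- list(); meta <- list()
  for (bg in backgrounds) {
    id <- paste0(bg, "_pool")
    cols[[id]] <- draw(a0)
    meta[[id]] <- c(bg, "pool", 1L)
    for (tpName in c("day1", "day28")) {
      tp <- c(day1 = 1, day28 = 28)[[tpName]]
      logInc <- setNames(fitnessAt(fit, bg, tp), fit$gene)[barcodes]
      a <- a0 * exp(logInc)
      for (r in seq_len(config@screenReplicates)) {
        id <- sprintf("%s_%s_rep%d", bg, tpName, r)
        cols[[id]] <- draw(a)
        meta[[id]] <- c(bg, tpName, r)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- barcodes
  m <- do.call(rbind, meta)
  sampleDF <- S4Vectors::DataFrame(
    sample_id = names(cols), background = m[, 1], timepoint = m[, 2],
    replicate = as.integer(m[, 3]))
  rownames(sampleDF) <- sampleDF$sample_id

  truth <- new("SimTruth", fitness = fit, seed = config@seed)
  list(counts = counts, samples = sampleDF, truth = truth)
}
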