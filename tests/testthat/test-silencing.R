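test_that("spike factors are through-origin slopes against the geometric-mean reference", {
  base <- c(100, 200, 400, 800, 50, 150, 300, 600, 120, 240, 480, 960)
  scale <- c(1, 1, 1 / 3, 3)  # geometric mean 1
  counts <- outer(base, scale)
  rownames(counts) <- paste0("spike", seq_along(base))
  colnames(counts) <- paste0("s", 1:4)
  species <- setNames(rep("spike", length(base)), rownames(counts))
  sc <- spikeScale(counts, species)
  expect_equal(unname(sc$factors), scale, tolerance = 1e-12)
  # normalized spike slope against the reference is exactly 1
  for (j in 1:4) {
    slope <- sum(sc$reference * sc$normalized[, j]) / sum(sc$reference^2)
    expect_equal(slope, 1, tolerance = 1e-12)
  }
  # identical samples give unit factors
  same <- outer(base, rep(1, 3))
  rownames(same) <- rownames(counts); colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(spikeScale(same, species)$factors), rep(1, 3))
  # pure rescaling: within-sample gene ratios unchanged
  expect_equal(sc$normalized[1, ] / sc$normalized[2, ],
               counts[1, ] / counts[2, ])
  bad <- counts; bad[, 2] <- 0
  expect_error(spikeScale(bad, species), "zero spike")
})

test_that("NB exact test: symmetry, identity, and the Poisson/binomial limit", {
  set.seed(61)
  a <- matrix(rpois(40, 50), 20, 2)
  rownames(a) <- paste0("g", 1:20)
  expect_true(all(nbExactTest(a, a, dispersion = 0.1) == 1))
  b <- matrix(rpois(40, 70), 20, 2)
  rownames(b) <- rownames(a)
  expect_equal(nbExactTest(a, b, dispersion = 0.2),
               nbExactTest(b, a, dispersion = 0.2), tolerance = 1e-12)
  expect_error(nbExactTest(a, b, dispersion = -1), "dispersion")

  # dispersion 0 at matched library sizes = exact conditional binomial test
  y1 <- rpois(30, 40); y2 <- rpois(30, 40)
  names(y1) <- names(y2) <- paste0("g", 1:30)
  p <- nbExactTest(y1, y2, sizes = c(1, 1), dispersion = 0)
  pBinom <- vapply(seq_along(y1), function(i) {
    s <- y1[i] + y2[i]
    if (s == 0) return(1)
    d <- dbinom(0:s, s, 0.5)
    lo <- sum(d[seq_len(y1[i] + 1)])
    hi <- sum(d[(y1[i] + 1):(s + 1)])
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  expect_equal(unname(p), pBinom, tolerance = 1e-12)
})

test_that("NB exact test is calibrated on null overdispersed data", {
  set.seed(62)
  n <- 4000
  mu <- 100
  phi <- 0.1
  a <- matrix(rnbinom(2 * n, mu = mu, size = 1 / phi), n, 2)
  b <- matrix(rnbinom(2 * n, mu = mu, size = 1 / phi), n, 2)
  rownames(a) <- rownames(b) <- paste0("g", seq_len(n))
  p <- nbExactTest(a, b, sizes = rep(1, 4), dispersion = phi)
  expect_lte(mean(p < 0.05), 0.06)
  expect_lte(mean(p < 0.01), 0.015)
})

test_that("moment dispersion estimates recover the simulated value", {
  set.seed(63)
  n <- 3000
  phi <- 0.08
  m <- matrix(rnbinom(4 * n, mu = 200, size = 1 / phi), n, 4)
  rownames(m) <- paste0("g", seq_len(n))
  colnames(m) <- paste0("s", 1:4)
  est <- estimateDispersion(m, list(colnames(m)), sizes = rep(1, 4))
  expect_gt(est, phi * 0.6)
  expect_lt(est, phi * 1.6)
})

test_that("repression-defect set logic follows the all-aneuploids rule", {
  tab <- function(genes, lfc, q) S4Vectors::DataFrame(
    gene = genes, log2FC = lfc, p = q, q = q)
  genes <- c("g1", "g2", "g3", "g4")
  eu <- tab(genes, c(-3, -3, -3, +2), c(0.001, 0.001, 0.001, 0.001))
  up <- function(g3q) list(
    an1 = tab(genes, c(2, 2, 2, 2), c(0.001, 0.001, 0.001, 0.001)),
    an2 = tab(genes, c(2, 2, 2, 2), c(0.001, 0.001, 0.001, 0.001)),
    an3 = tab(genes, c(2, 2, 2, 2), c(0.001, 0.001, 0.001, 0.001)),
    an4 = tab(genes, c(2, 2, -1, 2), c(0.001, 0.001, g3q, 0.001)))
  # g1,g2 pass; g3 fails in aneuploid 4; g4 is not repressed in euploid
  expect_equal(repressionDefectSet(eu, up(0.5)), c("g1", "g2"))
  # monotone in alpha: smaller alpha never adds genes
  s1 <- repressionDefectSet(eu, up(0.04), alpha = 0.05)
  s2 <- repressionDefectSet(eu, up(0.04), alpha = 0.01)
  expect_true(all(s2 %in% s1))
  expect_error(repressionDefectSet(eu, list()), "missing contrast")
  # multiple timepoints: any qualifying timepoint suffices
  an1 <- list(tab(genes, c(0, 0, 0, 0), rep(0.9, 4)),
              tab(genes, c(2, 2, 2, 2), rep(0.001, 4)))
  got <- repressionDefectSet(eu, list(an1 = an1))
  expect_equal(got, c("g1", "g2", "g3"))
})

test_that("deep repression counting applies the strict 256-fold boundary", {
  lfc <- c(gA = -8.1, gB = -7.9, gC = -8, gD = -12, gE = 0)
  out <- deepRepressionCount(lfc)
  expect_equal(sort(out$genes), c("gA", "gC", "gD"))
  expect_equal(out$count, 3)
  expect_equal(out$threshold_log2, -8)
})
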