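test_that("two populations fixed for different alleles give F_ST = 1", {
  des <- oneRegionDesign(2, 1, 1)
  g <- makeGenotypes(list(
    P1 = replicate(5, list(c(1L, 1L)), simplify = FALSE),
    P2 = replicate(5, list(c(2L, 2L)), simplify = FALSE)
  ), des)
  res <- amovaHierarchical(g)
  expect_equal(fStatistics(res)[["F_ST"]], 1, tolerance = 1e-12)
})

test_that("identical heterozygotes everywhere give zero differentiation", {
  des <- toyDesign(2, 2, 1, 1)
  mk <- function() replicate(6, list(c(1L, 2L)), simplify = FALSE)
  g <- makeGenotypes(list(A1 = mk(), A2 = mk(), B1 = mk(), B2 = mk()), des)
  res <- amovaHierarchical(g)
  # unbiased among-group components are <= 0 (retained unclamped in sums);
  # the reported F statistics are clamped to zero
  expect_lte(res@components[["a"]], 1e-12)
  expect_lte(res@components[["b"]], 1e-12)
  expect_gt(res@components[["c"]], 0)
  expect_lte(res@fUnclamped[["F_ST"]], 1e-12)
  expect_equal(fStatistics(res)[["F_ST"]], 0, tolerance = 1e-12)
})

test_that("components equal the brute-force pairwise-distance oracle", {
  set.seed(14)
  for (i in 1:25) {
    gt <- randomToyGenotypes(withMissing = (i %% 2 == 0))
    res <- try(amovaHierarchical(gt), silent = TRUE)
    oracle <- bruteAmovaComponents(gt)
    if (inherits(res, "try-error")) {
      expect_true(all(oracle == 0))  # no usable variation
      next
    }
    expect_equal(unname(res@components), unname(oracle), tolerance = 1e-10)
  }
})

test_that("indices are invariant to row order and allele relabelling", {
  gt <- simulateGenotypes(toyDesign(2, 3), nLoci = 3, nAlleles = 5,
                          individualsPerPopulation = 8, seed = 6)
  f0 <- fStatistics(amovaHierarchical(gt))
  d <- as.data.frame(gt)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  gt2 <- GenotypeTable(d2, studyDesign(gt), loci = lociNames(gt))
  expect_equal(fStatistics(amovaHierarchical(gt2)), f0, tolerance = 1e-12)
  # bijective allele relabelling applied to every column of one locus
  perm <- c(9L, 8L, 7L, 6L, 5L)  # code k -> perm[k]
  d3 <- d
  for (s in 1:2) {
    col <- paste0("L1.", s)
    d3[[col]] <- ifelse(d3[[col]] == 0, 0L, perm[d3[[col]]])
  }
  gt3 <- GenotypeTable(d3, studyDesign(gt), loci = lociNames(gt))
  expect_equal(fStatistics(amovaHierarchical(gt3)), f0, tolerance = 1e-12)
})

test_that("with one region F_SR collapses to the two-level F_ST", {
  des <- oneRegionDesign(6, 1, 1)
  gt <- simulateGenotypes(des, nLoci = 3, nAlleles = 4, thetaRT = 0,
                          thetaSR = 0.3, individualsPerPopulation = 10, seed = 7)
  res <- amovaHierarchical(gt)
  expect_true(is.na(fStatistics(res)[["F_RT"]]))
  expect_equal(res@fUnclamped[["F_SR"]], twoLevelFst(gt), tolerance = 1e-10)
  expect_equal(fStatistics(res)[["F_ST"]], fStatistics(res)[["F_SR"]])
})

test_that("degenerate genotype tables are rejected", {
  des <- toyDesign(2, 1, 1, 1)  # one population per region
  g <- makeGenotypes(list(
    A1 = replicate(3, list(c(1L, 2L)), simplify = FALSE),
    B1 = replicate(3, list(c(1L, 2L)), simplify = FALSE)
  ), des)
  expect_error(amovaHierarchical(g), "single population")
  # monomorphic at every locus
  des2 <- oneRegionDesign(2, 1, 1)
  g2 <- makeGenotypes(list(
    P1 = replicate(3, list(c(1L, 1L)), simplify = FALSE),
    P2 = replicate(3, list(c(1L, 1L)), simplify = FALSE)
  ), des2)
  expect_error(amovaHierarchical(g2), "no variation")
  # a population with zero scored copies anywhere
  g3 <- makeGenotypes(list(
    P1 = replicate(3, list(c(1L, 2L)), simplify = FALSE),
    P2 = replicate(3, list(c(0L, 0L)), simplify = FALSE)
  ), des2)
  expect_error(amovaHierarchical(g3), "0 scored copies")
})
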