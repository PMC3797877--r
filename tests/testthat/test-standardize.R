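test_that("fully differentiated populations have F' = 1 and G'_ST = 1", {
  des <- toyDesign(2, 2, 1, 1)
  # every population monomorphic for its own allele: H_S = 0, no sharing
  g <- makeGenotypes(list(
    A1 = replicate(4, list(c(1L, 1L)), simplify = FALSE),
    A2 = replicate(4, list(c(2L, 2L)), simplify = FALSE),
    B1 = replicate(4, list(c(3L, 3L)), simplify = FALSE),
    B2 = replicate(4, list(c(4L, 4L)), simplify = FALSE)
  ), des)
  # region-level standardization is undefined here (populations share no
  # alleles even within regions, so regions explain nothing beyond them)
  expect_warning(std <- standardizeIndices(g), "F_RT")
  expect_true(is.na(std@fPrime[["F_RT"]]))
  expect_equal(std@fPrime[["F_ST"]], 1, tolerance = 1e-12)
  expect_equal(std@fPrime[["F_SR"]], 1, tolerance = 1e-12)
  expect_equal(std@gst, 1, tolerance = 1e-12)
  expect_equal(std@gstPrime, 1, tolerance = 1e-12)
  expect_equal(std@hS, 0)
})

test_that("standardized indices dominate their raw counterparts", {
  set.seed(20)
  for (i in 1:20) {
    gt <- simulateGenotypes(toyDesign(2, 3), nLoci = 2, nAlleles = 4,
                            thetaRT = stats::runif(1, 0, 0.3),
                            thetaSR = stats::runif(1, 0.05, 0.5),
                            individualsPerPopulation = 10, seed = NULL)
    raw <- amovaHierarchical(gt)
    std <- standardizeIndices(gt, raw)
    for (nm in c("F_RT", "F_SR", "F_ST")) {
      f <- fStatistics(raw)[[nm]]
      expect_gte(std@fPrime[[nm]] + 1e-10, f)
    }
  }
})

test_that("standardization matches an explicit recode-then-recompute oracle", {
  gt <- simulateGenotypes(toyDesign(2, 3), nLoci = 3, nAlleles = 5,
                          individualsPerPopulation = 12, seed = 17)
  raw <- amovaHierarchical(gt)
  std <- standardizeIndices(gt, raw)
  # oracle: relabel allele codes in the data itself, rerun the AMOVA
  maxPop <- amovaHierarchical(recodeGenotypes(gt, "population"))
  maxReg <- amovaHierarchical(recodeGenotypes(gt, "region"))
  expect_equal(std@fPrime[["F_ST"]],
               fStatistics(raw)[["F_ST"]] / fStatistics(maxPop)[["F_ST"]],
               tolerance = 1e-10)
  expect_equal(std@fPrime[["F_SR"]],
               fStatistics(raw)[["F_SR"]] / fStatistics(maxPop)[["F_SR"]],
               tolerance = 1e-10)
  expect_equal(std@fPrime[["F_RT"]],
               fStatistics(raw)[["F_RT"]] / fStatistics(maxReg)[["F_RT"]],
               tolerance = 1e-10)
})

test_that("weak regional but strong local drift orders F'_RT below F'_SR", {
  set.seed(30)
  hits <- replicate(40, {
    gt <- simulateGenotypes(nLoci = 5, nAlleles = 8, thetaRT = 0.1,
                            thetaSR = 0.4, individualsPerPopulation = 20,
                            seed = NULL)
    std <- standardizeIndices(gt)
    std@fPrime[["F_RT"]] < std@fPrime[["F_SR"]]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("G'_ST uses the closed-form Hedrick standardization", {
  gt <- simulateGenotypes(toyDesign(2, 2), nLoci = 2, nAlleles = 4,
                          individualsPerPopulation = 10, seed = 5)
  std <- standardizeIndices(gt)
  s <- 4  # populations
  expected <- std@gst * (s - 1 + std@hS) / ((s - 1) * (1 - std@hS))
  expect_equal(std@gstPrime, min(expected, 1), tolerance = 1e-12)
  expect_gte(std@gstPrime, std@gst)
})
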