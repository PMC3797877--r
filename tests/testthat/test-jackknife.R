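# mean of population means: a linear statistic whose jackknife SE has the
# closed form sd(population means) / sqrt(n)
meanOfPopMeans <- function(x) {
  d <- as.data.frame(x)
  mean(tapply(d$trait, d$population, mean))
}

test_that("the jackknife is exact for the mean of population means", {
  set.seed(12)
  for (i in 1:100) {
    nPops <- sample(5:12, 1)
    des <- oneRegionDesign(nPops, 2, 2)
    ph <- simulatePhenotypes(des, sigma2 = c(region = 0, population = 2,
                                             family = 0.5, residual = 1),
                             seed = NULL)
    ci <- jackknifePopulations(ph, meanOfPopMeans, range = NULL, name = "mean")
    d <- as.data.frame(ph)
    pm <- tapply(d$trait, d$population, mean)
    expect_equal(ci@se, stats::sd(pm) / sqrt(nPops), tolerance = 1e-12)
    expect_equal(ci@center, mean(pm), tolerance = 1e-12)
  }
})

test_that("a constant estimator yields a point interval", {
  ph <- simulatePhenotypes(toyDesign(2, 2), seed = 1)
  ci <- jackknifePopulations(ph, function(x) 0.4, name = "const")
  expect_equal(ci@se, 0)
  expect_equal(ci@lower, 0.4)
  expect_equal(ci@upper, 0.4)
})

test_that("failing delete-one subsets are skipped, too many failures abort", {
  des <- oneRegionDesign(10, 2, 2)
  ph <- simulatePhenotypes(des, seed = 2)
  # estimator that fails when P1 has been removed
  fragile <- function(x) {
    if (!"P1" %in% as.data.frame(x)$population) stop("boom")
    meanOfPopMeans(x)
  }
  expect_warning(ci <- jackknifePopulations(ph, fragile, range = NULL), "skipped")
  expect_equal(ci@nFailed, 1L)
  expect_equal(ci@nPopulations, 9L)
  # more than 20% failures is an error
  broken <- function(x) {
    if (any(c("P1", "P2", "P3") %in% setdiff(paste0("P", 1:10),
                                             as.data.frame(x)$population))) stop("boom")
    meanOfPopMeans(x)
  }
  expect_error(suppressWarnings(jackknifePopulations(ph, broken, range = NULL)),
               "20%")
})

test_that("intervals are clamped to the index's natural range", {
  des <- oneRegionDesign(8, 2, 2)
  gt <- simulateGenotypes(des, nLoci = 3, nAlleles = 4, thetaRT = 0,
                          thetaSR = 0.02, individualsPerPopulation = 8, seed = 3)
  est <- function(g) fStatistics(amovaHierarchical(g))[["F_SR"]]
  ci <- jackknifePopulations(gt, est, name = "F_SR")
  expect_gte(ci@lower, 0)
  expect_lte(ci@upper, 1)
})
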