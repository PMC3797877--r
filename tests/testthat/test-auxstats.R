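test_that("population means weight families equally regardless of size", {
  des <- StudyDesign(data.frame(population = c("P1", "P2", "P3"), region = "A",
                                elevation = c(1, 2, 3)), 2, 2)
  d <- data.frame(
    plant = paste0("x", 1:103),
    region = "A",
    population = c(rep("P1", 100), "P2", "P2", "P3"),
    family = c(rep("f1", 1), rep("f2", 99), "f1", "f1", "f1"),
    treatment = "control", diameter = 3,
    y = c(0, rep(10, 99), 4, 6, 7)
  )
  ph <- PhenotypeTable(d, des, traits = "y")
  pm <- populationMeans(ph, "y")
  # families (sizes 1 and 99) have means 0 and 10: unweighted mean is 5
  expect_equal(unname(pm[["P1"]]), 5)
  # one family per population: population mean equals the family mean
  expect_equal(unname(pm[["P2"]]), 5)
  expect_equal(unname(pm[["P3"]]), 7)
})

test_that("elevation correlations match the t-distribution oracle", {
  des <- campanulaDesign()
  elev <- elevations(des)
  # exactly proportional values: r = 1
  expect_equal(correlateElevation(2 * elev, des)$r, 1, tolerance = 1e-12)
  # constant values: zero variance error
  expect_error(correlateElevation(stats::setNames(rep(1, 21), names(elev)), des),
               "zero variance")
  # random values: p equals the two-sided t transformation of r
  set.seed(10)
  vals <- stats::setNames(0.9 * scale(elev)[, 1] + stats::rnorm(21, 0, 0.4),
                          names(elev))
  res <- correlateElevation(vals, des)
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tstat), res$n - 2), tolerance = 1e-12)
  # invariance under affine rescaling of elevation
  des2 <- StudyDesign(transform(populations(des), elevation = 3 * elevation + 100),
                      6, 8)
  expect_equal(correlateElevation(vals, des2)$r, res$r, tolerance = 1e-12)
})

test_that("Holm adjustment matches the step-down hand computation", {
  expect_equal(holmAdjust(0.03), 0.03)
  expect_equal(holmAdjust(rep(0.01, 8)), rep(0.08, 8))
  expect_equal(holmAdjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  # permutation invariance
  p <- c(0.04, 0.001, 0.02)
  expect_equal(holmAdjust(p), c(0.04, 0.003, 0.04))
  # monotone in rank and never below the raw p
  set.seed(2)
  pr <- stats::runif(10)
  adj <- holmAdjust(pr)
  expect_true(all(adj >= pr))
  expect_error(holmAdjust(c(0.5, 0)), "0, 1")
  expect_error(holmAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("the G statistic follows its closed form", {
  # observed = expected: G = 0, p = 1
  res0 <- gTest(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p.value, 1)
  # diagonal 2x2 table: G = 40 ln 2, df = 1
  res <- gTest(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 40 * log(2), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # independence mode is symmetric under transposition
  m <- matrix(c(12, 3, 7, 9, 4, 11), 2)
  expect_equal(gTest(m)$statistic, gTest(t(m))$statistic, tolerance = 1e-12)
  # goodness of fit against given expected counts
  gof <- gTest(c(10, 10, 20), expected = c(0.25, 0.25, 0.5))
  expect_equal(gof$df, 2)
  expect_equal(gof$statistic, 0, tolerance = 1e-12)
  # impossible expectations and negative counts are errors
  expect_error(gTest(c(3, 1), expected = c(1, 0)), "expected")
  expect_error(gTest(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("power transforms behave on boundary inputs", {
  expect_equal(as.numeric(powerTransform(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(as.numeric(powerTransform(0, 0.62)), 0)
  expect_equal(as.numeric(powerTransform(8, 0.331)), exp(0.331 * log(8)),
               tolerance = 1e-12)
  expect_error(powerTransform(-1, 0.5), "non-negative")
})
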