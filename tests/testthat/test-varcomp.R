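test_that("balanced toy data match the classical EMS solution exactly", {
  des <- toyDesign(2, 2, 2, 4)  # 2 control plants per family after the split
  ph <- simulatePhenotypes(des, sigma2 = c(region = 2, population = 1,
                                           family = 1, residual = 1),
                           treatmentEffect = 0, seed = 42)
  d <- as.data.frame(ph)
  d <- d[d$treatment == "control", ]
  d$y <- d$trait
  oracle <- balancedNestedVC(d)
  vc <- varComponents(estimateAnova(ph, "trait"))
  expect_equal(unname(vc), unname(pmax(oracle, 0)), tolerance = 1e-10)
})

test_that("a constant trait yields all-zero components", {
  des <- toyDesign(2, 2, 2, 2)
  ph <- simulatePhenotypes(des, sigma2 = c(region = 0, population = 0,
                                           family = 0, residual = 0),
                           treatmentEffect = 0, seed = 1)
  for (est in list(estimateAnova, estimateReml)) {
    vc <- est(ph, "trait")
    expect_equal(unname(varComponents(vc)), rep(0, 4))
  }
})

test_that("components are scale-equivariant and shift-invariant", {
  ph <- simulatePhenotypes(toyDesign(3, 3, 3, 4), seed = 9, treatmentEffect = 0)
  base <- varComponents(estimateAnova(ph, "trait"))
  d <- as.data.frame(ph)
  for (k in c(0.5, 3)) {
    d2 <- d; d2$trait <- k * d2$trait
    ph2 <- PhenotypeTable(d2, studyDesign(ph), traits = "trait")
    expect_equal(varComponents(estimateAnova(ph2, "trait")), k^2 * base,
                 tolerance = 1e-10)
  }
  d3 <- d; d3$trait <- d3$trait + 100
  ph3 <- PhenotypeTable(d3, studyDesign(ph), traits = "trait")
  expect_equal(varComponents(estimateAnova(ph3, "trait")), base, tolerance = 1e-8)
})

test_that("ANOVA and REML agree on balanced data with interior estimates", {
  ph <- simulatePhenotypes(balancedDesign(),
                           sigma2 = c(region = 2, population = 1,
                                      family = 1, residual = 4), seed = 11)
  a <- estimateAnova(ph, "trait")
  expect_length(a@truncated, 0)  # interior
  r <- estimateReml(ph, "trait")
  expect_equal(varComponents(a), varComponents(r), tolerance = 1e-6)
})

test_that("degenerate nesting is rejected with the level named", {
  des1 <- StudyDesign(data.frame(population = c("P1", "P2"),
                                 region = c("A", "B"), elevation = c(1, 2)), 2, 2)
  ph <- simulatePhenotypes(des1, seed = 1)
  expect_error(estimateAnova(ph, "trait"), "population")
  expect_error(estimateAnova(simulatePhenotypes(oneRegionDesign(4, 2, 2), seed = 1),
                             "trait"), "region")
})

test_that("covariate pre-adjustment removes exactly the fitted linear effect", {
  des <- toyDesign(2, 3, 3, 4)
  # slope 0: adjustment changes nothing beyond fit noise
  ph <- simulatePhenotypes(des, slope = 0, seed = 21)
  adj <- adjustCovariate(ph, "trait")
  r <- stats::cor(as.data.frame(ph)$trait, as.data.frame(adj)$trait)
  expect_gt(r, 0.99)
  # trait exactly 2 * covariate: adjusted trait is constant at the grand mean
  d <- as.data.frame(ph)
  d$lin <- 2 * d$diameter
  ph2 <- PhenotypeTable(d, des, traits = c("trait", "lin"))
  adj2 <- adjustCovariate(ph2, "lin")
  expect_equal(stats::var(as.data.frame(adj2)$lin), 0, tolerance = 1e-20)
  expect_equal(unique(round(as.data.frame(adj2)$lin, 9)),
               round(mean(d$lin), 9))
  # known slope 1.5 is recovered and the residual scale preserved
  set.seed(8)
  d$known <- 5 + 1.5 * d$diameter + stats::rnorm(nrow(d), 0, 0.5)
  fit <- stats::lm(known ~ diameter, data = d)
  expect_equal(unname(stats::coef(fit)[2]), 1.5, tolerance = 0.1)
  ph3 <- PhenotypeTable(d, des, traits = "known")
  adj3 <- adjustCovariate(ph3, "known")
  expect_equal(stats::var(as.data.frame(adj3)$known), 0.25, tolerance = 0.05)
  # constant covariate is an error
  d$diameter <- 3
  ph4 <- PhenotypeTable(d, des, traits = "known")
  expect_error(adjustCovariate(ph4, "known"), "constant covariate")
})

test_that("unbalanced data still give finite nonnegative estimates", {
  ph <- simulatePhenotypes(toyDesign(3, 3, 3, 6), seed = 33, treatmentEffect = 0)
  d <- as.data.frame(ph)
  set.seed(33)
  d <- d[-sample(nrow(d), round(0.2 * nrow(d))), ]  # delete 20% of rows
  ph2 <- PhenotypeTable(d, studyDesign(ph), traits = "trait")
  for (est in list(estimateAnova, estimateReml)) {
    vc <- varComponents(est(ph2, "trait", treatment = "all"))
    expect_true(all(is.finite(vc)))
    expect_true(all(vc >= 0))
  }
})
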