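test_that("identical parameters and seed reproduce identical tables", {
  a <- simulatePhenotypes(seed = 11)
  b <- simulatePhenotypes(seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  g1 <- simulateGenotypes(seed = 11)
  g2 <- simulateGenotypes(seed = 11)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("degenerate phenotype settings collapse as the model predicts", {
  des <- toyDesign(2, 2, 2, 4)
  # all variances 0, slope 0, no treatment effect: one constant value
  ph <- simulatePhenotypes(des, sigma2 = c(region = 0, population = 0,
                                           family = 0, residual = 0),
                           slope = 0, treatmentEffect = 0, grandMean = 5,
                           seed = 1)
  expect_equal(unique(as.data.frame(ph)$trait), 5)
  # region variance only: family means separate between, not within, regions
  ph2 <- simulatePhenotypes(campanulaDesign(),
                            sigma2 = c(region = 1, population = 0,
                                       family = 0, residual = 1e-8),
                            treatmentEffect = 0, seed = 2)
  d <- as.data.frame(ph2)
  fm <- tapply(d$trait, d$family, mean)
  freg <- tapply(d$region, d$family, function(r) r[1])
  withinVar <- mean(tapply(fm, freg, stats::var))
  betweenVar <- stats::var(tapply(fm, freg, mean))
  expect_lt(withinVar, 1e-6)
  expect_gt(betweenVar, 0.01)
})

test_that("family means decompose into their generating effects when noise vanishes", {
  des <- toyDesign(2, 2, 3, 4)
  ph <- simulatePhenotypes(des, sigma2 = c(region = 2, population = 1,
                                           family = 1, residual = 1e-12),
                           treatmentEffect = 0, grandMean = 10, seed = 5)
  eff <- attr(ph, "effects")
  d <- as.data.frame(ph)
  fm <- tapply(d$trait, d$family, mean)
  for (f in names(fm)) {
    rows <- d[d$family == f, ][1, ]
    expected <- 10 + eff$region[[rows$region]] + eff$population[[rows$population]] +
      eff$family[[f]]
    expect_equal(unname(fm[[f]]), expected, tolerance = 1e-4)
  }
})

test_that("simulated allele frequencies live on the simplex", {
  gt <- simulateGenotypes(nLoci = 4, nAlleles = 6, seed = 3)
  fr <- attr(gt, "frequencies")
  for (loc in names(fr)) {
    vecs <- c(list(fr[[loc]]$ancestral), fr[[loc]]$region, fr[[loc]]$population)
    for (v in vecs) {
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-12)
    }
  }
})

test_that("zero differentiation targets copy frequencies down the hierarchy", {
  des <- oneRegionDesign(21, 1, 1)
  gt <- simulateGenotypes(campanulaDesign(), nLoci = 10, nAlleles = 8,
                          thetaRT = 0, thetaSR = 0,
                          individualsPerPopulation = 30, seed = 4)
  fr <- attr(gt, "frequencies")
  for (loc in names(fr)) {
    for (p in fr[[loc]]$population) {
      expect_identical(p, fr[[loc]]$ancestral)
    }
  }
  # estimated multi-locus F_ST stays near zero
  un <- amovaHierarchical(gt)@fUnclamped[["F_ST"]]
  expect_lt(abs(un), 0.02)
})

test_that("phenology censuses follow their region's stage probabilities", {
  des <- toyDesign(2, 2)
  stages <- c("rosette", "bolting", "flowering", "ripening")
  # all mass on rosette
  pr <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), stages))
  cnt <- simulatePhenology(des, pr, 25, seed = 1)
  expect_true(all(cnt$rosette == 25))
  expect_true(all(cnt[c("bolting", "flowering", "ripening")] == 0))
  # disjoint stages in the two regions: G test p-value is tiny
  pr2 <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), stages))
  cnt2 <- simulatePhenology(des, pr2, 30, seed = 1)
  g <- phenologyGTests(cnt2)
  expect_lt(g$p[g$scope == "among_regions"], 1e-10)
  # probability rows must sum to one
  pr2[1, 1] <- 0.5
  expect_error(simulatePhenology(des, pr2, 30), "simplex")
})
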