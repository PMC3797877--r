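#' @include AllClasses.R
NULL

# harmonic mean (unweighted-means effective coefficient)
.hmean <- function(x) length(x) / sum(1 / x)

# subset a phenotype table to a treatment group and drop rows with a
# missing trait value; returns a plain data.frame with factors prepared
.vcData <- function(x, trait, treatment) {
  d <- x@data
  if (!trait %in% x@traits) stop("unknown trait: ", trait)
  treatment <- match.arg(treatment, c("control", "clipped", "all"))
  if (treatment != "all") d <- d[d$treatment == treatment, , drop = FALSE]
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  if (nrow(d) == 0) stop("no usable rows for trait '", trait, "'")
  d$.y <- d[[trait]]
  d$.pop <- paste(d$region, d$population, sep = "/")
  d$.fam <- paste(d$.pop, d$family, sep = "/")
  d
}

.checkNesting <- function(d) {
  if (length(unique(d$region)) < 2) stop("degenerate nesting at level 'region': >= 2 regions required")
  popsPerReg <- tapply(d$.pop, d$region, function(p) length(unique(p)))
  if (all(popsPerReg < 2)) stop("degenerate nesting at level 'population': every region has a single population")
  famsPerPop <- tapply(d$.fam, d$.pop, function(f) length(unique(f)))
  if (all(famsPerPop < 2)) stop("degenerate nesting at level 'family': every population has a single family")
}

#' Pre-adjust a trait for the initial-size covariate
#'
#' Replaces the trait by the residuals of an ordinary least-squares fit of
#' trait on covariate plus the trait grand mean, so the trait scale is
#' preserved while initial-size effects are removed. Rows missing the
#' trait or the covariate are set to `NA` in the adjusted column and
#' counted in a message.
#'
#' @param x a [PhenotypeTable-class].
#' @param trait trait column to adjust.
#' @param covariate covariate column (default the initial rosette
#'   diameter, `"diameter"`).
#' @return a [PhenotypeTable-class] with the trait column replaced by its
#'   adjusted values.
#' @export
adjustCovariate <- function(x, trait, covariate = "diameter") {
  stopifnot(methods::is(x, "PhenotypeTable"))
  d <- x@data
  if (!trait %in% names(d)) stop("unknown trait: ", trait)
  if (!covariate %in% names(d)) stop("unknown covariate: ", covariate)
  use <- !is.na(d[[trait]]) & !is.na(d[[covariate]])
  if (sum(use) < 3) stop("fewer than 3 usable rows for covariate adjustment")
  cv <- d[[covariate]][use]
  if (stats::var(cv) == 0) stop("constant covariate: adjustment undefined")
  y <- d[[trait]][use]
  fit <- stats::lm(y ~ cv)
  adj <- rep(NA_real_, nrow(d))
  adj[use] <- stats::residuals(fit) + mean(y)
  dropped <- nrow(d) - sum(use)
  if (dropped > 0) message(dropped, " row(s) without trait or covariate left NA")
  d[[trait]] <- adj
  methods::new("PhenotypeTable", data = d, traits = x@traits, design = x@design)
}

#' @describeIn estimateAnova Method-of-moments solution equating observed
#'   nested mean squares to their expected-mean-square expressions, with
#'   unweighted-means (harmonic-mean) coefficients for unbalanced data.
#'   Negative solutions are truncated to 0 and flagged. For balanced data
#'   this reproduces the classical nested ANOVA estimator exactly.
#' @param treatment which treatment subset to analyse: `"control"`
#'   (default, the convention for Q-index estimation), `"clipped"` or
#'   `"all"`.
setMethod("estimateAnova", "PhenotypeTable", function(x, trait, treatment = "control") {
  d <- .vcData(x, trait, treatment)
  if (stats::var(d$.y) == 0) {
    return(methods::new("VarianceComponents", trait = trait,
      components = c(region = 0, population = 0, family = 0, residual = 0),
      method = "anova", nPlants = nrow(d), truncated = character()))
  }
  .checkNesting(d)
  famMean <- tapply(d$.y, d$.fam, mean)
  famSize <- tapply(d$.y, d$.fam, length)
  famPop <- tapply(d$.pop, d$.fam, function(p) p[1])
  N <- nrow(d); Fam <- length(famMean)
  # residual: pooled within-family mean square
  ssWithin <- sum((d$.y - famMean[d$.fam])^2)
  dfWithin <- N - Fam
  if (dfWithin < 1) stop("degenerate nesting at level 'plant': one plant per family everywhere")
  msE <- ssWithin / dfWithin

  popMean <- tapply(famMean, famPop, mean)          # unweighted over families
  famPerPop <- tapply(famMean, famPop, length)
  popReg <- vapply(strsplit(names(popMean), "/"), `[`, character(1), 1)
  P <- length(popMean); R <- length(unique(popReg))
  regMean <- tapply(popMean, popReg, mean)          # unweighted over populations
  popPerReg <- tapply(popMean, popReg, length)
  grand <- mean(regMean)

  mh <- .hmean(famSize)       # plants per family
  fh <- .hmean(famPerPop)     # families per population
  ph <- .hmean(popPerReg)     # populations per region

  ssF <- sum((famMean - popMean[famPop])^2); dfF <- Fam - P
  ssP <- sum((popMean - regMean[popReg])^2); dfP <- P - R
  ssR <- sum((regMean - grand)^2); dfR <- R - 1
  if (dfF < 1 || dfP < 1 || dfR < 1) stop("insufficient replication to separate all levels")

  # expected mean squares on unweighted means:
  #   E[ssF/dfF] = s2F + s2e/mh
  #   E[ssP/dfP] = s2P + s2F/fh + s2e/(fh*mh)
  #   E[ssR/dfR] = s2R + s2P/ph + s2F/(ph*fh) + s2e/(ph*fh*mh)
  s2e <- msE
  s2F <- ssF / dfF - s2e / mh
  s2P <- ssP / dfP - s2F / fh - s2e / (fh * mh)
  s2R <- ssR / dfR - s2P / ph - s2F / (ph * fh) - s2e / (ph * fh * mh)

  raw <- c(region = s2R, population = s2P, family = s2F, residual = s2e)
  truncated <- names(raw)[raw < 0]
  comp <- pmax(raw, 0)
  methods::new("VarianceComponents", trait = trait, components = comp,
               method = "anova", nPlants = N, truncated = truncated)
})

#' @describeIn estimateReml REML fit of the Gaussian nested random model
#'   `trait ~ 1 + (1|region) + (1|region:population) + (1|family)` via
#'   `lme4::lmer`, the recommended method for unbalanced real data.
#'   Nonnegativity is enforced by the fitter; components estimated on the
#'   boundary (0) are flagged as truncated.
#' @param treatment which treatment subset to analyse (see
#'   [estimateAnova()]).
setMethod("estimateReml", "PhenotypeTable", function(x, trait, treatment = "control") {
  d <- .vcData(x, trait, treatment)
  if (stats::var(d$.y) == 0) {
    return(methods::new("VarianceComponents", trait = trait,
      components = c(region = 0, population = 0, family = 0, residual = 0),
      method = "reml", nPlants = nrow(d), truncated = character()))
  }
  .checkNesting(d)
  d$regF <- factor(d$region); d$popF <- factor(d$.pop); d$famF <- factor(d$.fam)
  fit <- tryCatch(
    lme4::lmer(.y ~ 1 + (1 | regF) + (1 | popF) + (1 | famF), data = d, REML = TRUE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           optCtrl = list(rhoend = 1e-12),
                                           calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    error = function(e) stop("REML fit failed to converge: ", conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) != 1) stop("REML fit returned no component for ", g)
    v
  }
  comp <- c(region = getv("regF"), population = getv("popF"),
            family = getv("famF"), residual = getv("Residual"))
  truncated <- names(comp)[comp < 1e-12 & names(comp) != "residual"]
  methods::new("VarianceComponents", trait = trait, components = comp,
               method = "reml", nPlants = nrow(d), truncated = truncated)
})
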