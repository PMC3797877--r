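#' @include AllClasses.R
NULL

# Dirichlet sampler; alpha may contain zeros (those categories get mass 0).
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # all shapes zero cannot happen for a valid simplex centre, but guard
    g <- rep(1, length(alpha)); s <- length(alpha)
  }
  g / s
}

#' Simulate common-garden phenotypes under the nested random model
#'
#' Generates one trait per plant as
#' `grand mean + region effect + population effect + family effect +
#'  slope * (covariate - covariate mean) + treatment effect * [clipped] +
#'  residual`, each random effect drawn independently Gaussian with its
#' stated variance and resampled per level unit. Both treatment halves are
#' generated for every seed family (plants per family split as evenly as
#' possible between control and clipped). The initial rosette diameter
#' covariate is Gaussian, floored at 0.
#'
#' @param design a [StudyDesign-class]; defaults to [campanulaDesign()].
#' @param sigma2 named numeric vector of true variance components
#'   `c(region=, population=, family=, residual=)`, trait units squared.
#'   All must be `>= 0` and `residual > 0` unless exactly 0 is wanted for a
#'   degenerate check.
#' @param grandMean trait grand mean.
#' @param slope covariate effect on the trait (trait units per cm).
#' @param covariateMean,covariateSD Gaussian parameters of the initial
#'   rosette diameter (cm).
#' @param treatmentEffect additive effect applied to clipped plants.
#' @param traitName name of the simulated trait column.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [PhenotypeTable-class] with attribute `"effects"` holding the
#'   generating region/population/family effects (ground truth sidecar).
#' @examples
#' ph <- simulatePhenotypes(seed = 1)
#' ph
#' @export
simulatePhenotypes <- function(design = campanulaDesign(),
                               sigma2 = c(region = 2, population = 1,
                                          family = 1, residual = 4),
                               grandMean = 10, slope = 0,
                               covariateMean = 3, covariateSD = 1,
                               treatmentEffect = -2,
                               traitName = "trait", seed = NULL) {
  stopifnot(all(c("region", "population", "family", "residual") %in% names(sigma2)))
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dp <- design@populations
  regs <- unique(dp$region)
  nf <- design@familiesPerPopulation
  np <- design@plantsPerFamily
  regEff <- stats::setNames(stats::rnorm(length(regs), 0, sqrt(sigma2[["region"]])), regs)
  popEff <- stats::setNames(stats::rnorm(nrow(dp), 0, sqrt(sigma2[["population"]])), dp$population)
  famIDs <- paste(rep(dp$population, each = nf), rep(seq_len(nf), nrow(dp)), sep = "_F")
  famEff <- stats::setNames(stats::rnorm(length(famIDs), 0, sqrt(sigma2[["family"]])), famIDs)

  rows <- expand.grid(plantIdx = seq_len(np), famIdx = seq_len(nf),
                      popIdx = seq_len(nrow(dp)), KEEP.OUT.ATTRS = FALSE)
  pop <- dp$population[rows$popIdx]
  fam <- paste(pop, rows$famIdx, sep = "_F")
  reg <- dp$region[rows$popIdx]
  # split each family as evenly as possible into the two treatment halves
  treatment <- ifelse(rows$plantIdx <= ceiling(np / 2), "control", "clipped")
  n <- nrow(rows)
  covariate <- pmax(0, stats::rnorm(n, covariateMean, covariateSD))
  value <- grandMean + regEff[reg] + popEff[pop] + famEff[fam] +
    slope * (covariate - covariateMean) +
    treatmentEffect * (treatment == "clipped") +
    stats::rnorm(n, 0, sqrt(sigma2[["residual"]]))
  d <- data.frame(
    plant = sprintf("%s_P%02d", fam, rows$plantIdx),
    region = reg, population = pop, family = fam,
    treatment = treatment, diameter = covariate,
    value = unname(value), stringsAsFactors = FALSE
  )
  names(d)[names(d) == "value"] <- traitName
  out <- PhenotypeTable(d, design, traits = traitName)
  attr(out, "effects") <- list(region = regEff, population = popEff, family = famEff,
                               sigma2 = sigma2, grandMean = grandMean)
  out
}

#' Simulate codominant genotypes under a hierarchical Dirichlet drift model
#'
#' Per locus, ancestral allele frequencies are drawn from a symmetric
#' Dirichlet; region frequencies from a Dirichlet centred on the ancestral
#' vector with concentration `(1 - thetaRT) / thetaRT` (so the expected
#' region-level fixation index is `thetaRT`; `thetaRT = 0` copies the
#' ancestral frequencies exactly); population frequencies likewise from a
#' Dirichlet centred on their region with concentration
#' `(1 - thetaSR) / thetaSR`. Individual genotypes are two independent
#' allele draws per locus (Hardy-Weinberg within population). The
#' Dirichlet moment identity E(F) = 1/(1 + c) links the target theta to the
#' realized differentiation.
#'
#' @param design a [StudyDesign-class].
#' @param nLoci number of microsatellite loci.
#' @param nAlleles alleles per locus (>= 2).
#' @param thetaRT,thetaSR target differentiation among regions and among
#'   populations within regions, each in [0, 1).
#' @param ancestralConcentration symmetric Dirichlet parameter for the
#'   ancestral frequencies (> 0; 1 = uniform on the simplex).
#' @param individualsPerPopulation diploid individuals sampled per
#'   population.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [GenotypeTable-class] with attribute `"frequencies"` (the
#'   generating ancestral/region/population frequency vectors per locus).
#' @examples
#' gt <- simulateGenotypes(seed = 1)
#' gt
#' @export
simulateGenotypes <- function(design = campanulaDesign(), nLoci = 5L,
                              nAlleles = 8L, thetaRT = 0.1, thetaSR = 0.4,
                              ancestralConcentration = 1,
                              individualsPerPopulation = 30L, seed = NULL) {
  stopifnot(nLoci >= 1, nAlleles >= 2, individualsPerPopulation >= 1,
            ancestralConcentration > 0)
  if (thetaRT < 0 || thetaRT >= 1 || thetaSR < 0 || thetaSR >= 1) {
    stop("theta levels must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  dp <- design@populations
  regs <- unique(dp$region)
  cRT <- if (thetaRT > 0) (1 - thetaRT) / thetaRT else Inf
  cSR <- if (thetaSR > 0) (1 - thetaSR) / thetaSR else Inf
  nInd <- as.integer(individualsPerPopulation)
  freqs <- vector("list", nLoci)
  alleleMat <- array(0L, dim = c(nrow(dp) * nInd, 2L, nLoci))
  for (l in seq_len(nLoci)) {
    p0 <- .rdirichlet(rep(ancestralConcentration, nAlleles))
    pReg <- lapply(regs, function(r) if (is.finite(cRT)) .rdirichlet(p0 * cRT) else p0)
    names(pReg) <- regs
    pPop <- lapply(seq_len(nrow(dp)), function(i) {
      pr <- pReg[[dp$region[i]]]
      if (is.finite(cSR)) .rdirichlet(pr * cSR) else pr
    })
    names(pPop) <- dp$population
    freqs[[l]] <- list(ancestral = p0, region = pReg, population = pPop)
    for (i in seq_len(nrow(dp))) {
      idx <- (i - 1L) * nInd + seq_len(nInd)
      alleleMat[idx, 1L, l] <- sample.int(nAlleles, nInd, replace = TRUE, prob = pPop[[i]])
      alleleMat[idx, 2L, l] <- sample.int(nAlleles, nInd, replace = TRUE, prob = pPop[[i]])
    }
  }
  loci <- paste0("L", seq_len(nLoci))
  d <- data.frame(
    individual = sprintf("%s_I%03d", rep(dp$population, each = nInd),
                         rep(seq_len(nInd), nrow(dp))),
    region = rep(dp$region, each = nInd),
    population = rep(dp$population, each = nInd),
    stringsAsFactors = FALSE
  )
  for (l in seq_len(nLoci)) {
    d[[paste0(loci[l], ".1")]] <- alleleMat[, 1L, l]
    d[[paste0(loci[l], ".2")]] <- alleleMat[, 2L, l]
  }
  out <- GenotypeTable(d, design, loci = loci)
  names(freqs) <- loci
  attr(out, "frequencies") <- freqs
  out
}

#' Simulate phenological-stage censuses
#'
#' Draws, for every population, a multinomial sample of plants over the
#' phenological stages using its region's stage-probability vector.
#'
#' @param design a [StudyDesign-class].
#' @param stageProbs numeric matrix of per-region stage probabilities: one
#'   row per region (rownames = region ids), one column per stage
#'   (default stages: rosette, bolting, flowering, ripening). Rows must sum
#'   to 1.
#' @param nPerPopulation plants censused per population.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return `data.frame` with columns `population`, `region` and one count
#'   column per stage.
#' @examples
#' pr <- matrix(0.25, 4, 4, dimnames = list(c("WA", "CSA", "CAA", "SEA"),
#'   c("rosette", "bolting", "flowering", "ripening")))
#' simulatePhenology(campanulaDesign(), pr, 40, seed = 1)
#' @export
simulatePhenology <- function(design, stageProbs, nPerPopulation, seed = NULL) {
  stopifnot(is.matrix(stageProbs), !is.null(rownames(stageProbs)))
  if (any(abs(rowSums(stageProbs) - 1) > 1e-8) || any(stageProbs < 0)) {
    stop("each region's stage probabilities must be a simplex (sum to 1, >= 0)")
  }
  dp <- design@populations
  miss <- setdiff(unique(dp$region), rownames(stageProbs))
  if (length(miss)) stop("stageProbs missing region(s): ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  stages <- colnames(stageProbs)
  if (is.null(stages)) stages <- c("rosette", "bolting", "flowering", "ripening")
  counts <- t(vapply(seq_len(nrow(dp)), function(i) {
    as.integer(stats::rmultinom(1, nPerPopulation, stageProbs[dp$region[i], ]))
  }, integer(ncol(stageProbs))))
  out <- data.frame(population = dp$population, region = dp$region,
                    stringsAsFactors = FALSE)
  out[stages] <- as.data.frame(counts)
  out
}
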