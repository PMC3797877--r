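#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# StudyDesign
# ---------------------------------------------------------------------------

#' Hierarchical sampling design of a common-garden phylogeography study
#'
#' A `StudyDesign` records the region/population hierarchy, the elevation of
#' each population of origin (m a.s.l.), optional coordinates, and the
#' nominal number of seed families per population and plants per family.
#' Every data object in the package carries a design, and all readers
#' validate labels against it.
#'
#' @slot populations `data.frame` with columns `population`, `region`,
#'   `elevation`, `longitude`, `latitude`; one row per population.
#' @slot familiesPerPopulation integer, nominal seed families per population.
#' @slot plantsPerFamily integer, nominal plants per seed family.
#'
#' @seealso [StudyDesign()], [campanulaDesign()]
#' @export
setClass("StudyDesign",
  slots = c(
    populations = "data.frame",
    familiesPerPopulation = "integer",
    plantsPerFamily = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  p <- object@populations
  msgs <- character()
  need <- c("population", "region", "elevation", "longitude", "latitude")
  if (!all(need %in% names(p))) {
    return(paste("populations must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(p$population)) {
    msgs <- c(msgs, "duplicated population identifiers (each population maps to exactly one region)")
  }
  if (nrow(p) == 0) msgs <- c(msgs, "at least one population required")
  if (!is.numeric(p$elevation) || any(!is.finite(p$elevation)) || any(p$elevation < 0)) {
    msgs <- c(msgs, "elevations must be finite and >= 0")
  }
  if (length(object@familiesPerPopulation) != 1 || object@familiesPerPopulation < 1) {
    msgs <- c(msgs, "familiesPerPopulation must be a single count >= 1")
  }
  if (length(object@plantsPerFamily) != 1 || object@plantsPerFamily < 1) {
    msgs <- c(msgs, "plantsPerFamily must be a single count >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StudyDesign
#'
#' @param populations `data.frame` with at least columns `population`,
#'   `region` and `elevation`; `longitude`/`latitude` filled with `NA` when
#'   absent (coordinates are stored but never used in computation).
#' @param familiesPerPopulation nominal seed families per population.
#' @param plantsPerFamily nominal plants per seed family.
#' @return a validated [StudyDesign-class] object.
#' @examples
#' d <- StudyDesign(data.frame(
#'   population = c("P1", "P2", "P3", "P4"),
#'   region = c("A", "A", "B", "B"),
#'   elevation = c(1400, 1600, 1800, 2000)
#' ), familiesPerPopulation = 2, plantsPerFamily = 4)
#' nPopulations(d)
#' @export
StudyDesign <- function(populations, familiesPerPopulation = 6L, plantsPerFamily = 8L) {
  populations <- as.data.frame(populations)
  for (col in c("longitude", "latitude")) {
    if (is.null(populations[[col]])) populations[[col]] <- NA_real_
  }
  populations$population <- as.character(populations$population)
  populations$region <- as.character(populations$region)
  populations$elevation <- as.numeric(populations$elevation)
  rownames(populations) <- NULL
  methods::new("StudyDesign",
    populations = populations[, c("population", "region", "elevation", "longitude", "latitude")],
    familiesPerPopulation = as.integer(familiesPerPopulation),
    plantsPerFamily = as.integer(plantsPerFamily)
  )
}

#' @rdname populations
setMethod("populations", "StudyDesign", function(x) x@populations)

#' @rdname populations
setMethod("regions", "StudyDesign", function(x) unique(x@populations$region))

#' @rdname populations
setMethod("nPopulations", "StudyDesign", function(x) nrow(x@populations))

#' @rdname populations
setMethod("elevations", "StudyDesign", function(x) {
  stats::setNames(x@populations$elevation, x@populations$population)
})

setMethod("show", "StudyDesign", function(object) {
  p <- object@populations
  cat("StudyDesign:", nrow(p), "populations in", length(unique(p$region)), "regions\n")
  cat("  populations per region:",
      paste(sprintf("%s=%d", names(table(p$region)), table(p$region)), collapse = ", "), "\n")
  cat("  nominal families/population:", object@familiesPerPopulation,
      "| plants/family:", object@plantsPerFamily, "\n")
  cat("  elevation range:", min(p$elevation), "-", max(p$elevation), "m a.s.l.\n")
})

# internal: map population -> region
.popRegion <- function(design) {
  stats::setNames(design@populations$region, design@populations$population)
}

# internal: design restricted to a population subset
.subsetDesign <- function(design, keep) {
  p <- design@populations[design@populations$population %in% keep, , drop = FALSE]
  rownames(p) <- NULL
  methods::new("StudyDesign",
    populations = p,
    familiesPerPopulation = design@familiesPerPopulation,
    plantsPerFamily = design@plantsPerFamily
  )
}

# ---------------------------------------------------------------------------
# PhenotypeTable
# ---------------------------------------------------------------------------

#' Per-plant common-garden phenotype measurements
#'
#' One row per plant with its origin labels (`region`, `population`,
#' `family`), the clipping-treatment label (`control` or `clipped`), the
#' initial rosette diameter covariate (`diameter`, cm), and one numeric
#' column per trait. Missing trait values are `NA`, never silent zeroes.
#'
#' @slot data `data.frame` with columns `plant`, `region`, `population`,
#'   `family`, `treatment`, `diameter` plus one numeric column per trait.
#' @slot traits character vector naming the trait columns.
#' @slot design the [StudyDesign-class] the labels were validated against.
#'
#' @seealso [PhenotypeTable()], [readPhenotypes()], [simulatePhenotypes()]
#' @export
setClass("PhenotypeTable",
  slots = c(data = "data.frame", traits = "character", design = "StudyDesign")
)

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("plant", "region", "population", "family", "treatment", "diameter")
  if (!all(need %in% names(d))) {
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(object@traits %in% names(d))) {
    return("all trait names must be data columns")
  }
  dp <- object@design@populations
  bad <- setdiff(unique(d$population), dp$population)
  if (length(bad)) {
    msgs <- c(msgs, paste("population(s) not in design:", paste(bad, collapse = ", ")))
  }
  if (nrow(d)) {
    pr <- stats::setNames(dp$region, dp$population)
    mism <- d$region != pr[d$population]
    if (any(mism, na.rm = TRUE)) {
      msgs <- c(msgs, "region labels inconsistent with design for some rows")
    }
    if (!all(d$treatment %in% c("control", "clipped"))) {
      msgs <- c(msgs, "treatment must be 'control' or 'clipped' for every row")
    }
  }
  for (tr in object@traits) {
    if (!is.numeric(d[[tr]])) msgs <- c(msgs, paste0("trait '", tr, "' is not numeric"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhenotypeTable
#'
#' @param data `data.frame` with the label columns `plant`, `region`,
#'   `population`, `family`, `treatment`, `diameter` and numeric trait
#'   columns.
#' @param design a [StudyDesign-class]; labels are validated against it.
#' @param traits names of the trait columns; defaults to every column after
#'   the six label columns.
#' @return a validated [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(data, design, traits = NULL) {
  data <- as.data.frame(data)
  lab <- c("plant", "region", "population", "family", "treatment", "diameter")
  if (is.null(traits)) traits <- setdiff(names(data), lab)
  for (col in c("plant", "region", "population", "family", "treatment")) {
    if (!is.null(data[[col]])) data[[col]] <- as.character(data[[col]])
  }
  rownames(data) <- NULL
  methods::new("PhenotypeTable", data = data, traits = as.character(traits), design = design)
}

#' @rdname traitNames
setMethod("traitNames", "PhenotypeTable", function(x) x@traits)

#' @rdname studyDesign
setMethod("studyDesign", "PhenotypeTable", function(x) x@design)

#' @rdname populations
setMethod("regions", "PhenotypeTable", function(x) regions(x@design))

#' @rdname populations
setMethod("nPopulations", "PhenotypeTable", function(x) length(unique(x@data$population)))

#' Coerce package data objects to data.frame
#'
#' @param x a [PhenotypeTable-class] or [GenotypeTable-class].
#' @param ... unused.
#' @return the underlying `data.frame`.
#' @export
as.data.frame.PhenotypeTable <- function(x, ...) x@data

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", nrow(object@data), "plants,",
      length(unique(object@data$population)), "populations,",
      length(object@traits), "trait(s)\n")
  if (length(object@traits)) cat("  traits:", paste(object@traits, collapse = ", "), "\n")
  tab <- table(object@data$treatment)
  if (length(tab)) cat("  treatment:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname subsetPopulations
setMethod("subsetPopulations", "PhenotypeTable", function(x, keep) {
  d <- x@data[x@data$population %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  methods::new("PhenotypeTable", data = d, traits = x@traits,
               design = .subsetDesign(x@design, keep))
})

# ---------------------------------------------------------------------------
# GenotypeTable
# ---------------------------------------------------------------------------

#' Codominant microsatellite genotypes
#'
#' One row per individual with `region` and `population` labels and two
#' integer allele-code columns per locus (`<locus>.1`, `<locus>.2`), the
#' GenAlEx codominant convention. Allele code 0 marks a missing copy; a
#' locus is missing for an individual iff both copies are 0.
#'
#' @slot data `data.frame` with columns `individual`, `region`,
#'   `population`, then two integer columns per locus.
#' @slot loci character vector of locus names.
#' @slot design the [StudyDesign-class] the labels were validated against.
#'
#' @seealso [GenotypeTable()], [readGenotypes()], [simulateGenotypes()]
#' @export
setClass("GenotypeTable",
  slots = c(data = "data.frame", loci = "character", design = "StudyDesign")
)

setValidity("GenotypeTable", function(object) {
  d <- object@data
  msgs <- character()
  if (!all(c("individual", "region", "population") %in% names(d))) {
    return("data must have columns individual, region, population")
  }
  if (length(object@loci) < 1) return("at least one locus required")
  cols <- as.vector(rbind(paste0(object@loci, ".1"), paste0(object@loci, ".2")))
  if (!all(cols %in% names(d))) {
    return("each locus needs two allele columns '<locus>.1' and '<locus>.2'")
  }
  bad <- setdiff(unique(d$population), object@design@populations$population)
  if (length(bad)) {
    msgs <- c(msgs, paste("population(s) not in design:", paste(bad, collapse = ", ")))
  }
  for (cc in cols) {
    v <- d[[cc]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE) || any(v != floor(v), na.rm = TRUE)) {
      msgs <- c(msgs, paste0("allele column '", cc, "' must hold non-negative integer codes"))
    }
  }
  # missing convention: both copies 0, never just one
  for (loc in object@loci) {
    a <- d[[paste0(loc, ".1")]]; b <- d[[paste0(loc, ".2")]]
    if (any(xor(a == 0, b == 0), na.rm = TRUE)) {
      msgs <- c(msgs, paste0("locus '", loc, "': one allele copy 0 with the other scored (missing means both 0)"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeTable
#'
#' @param data `data.frame` with `individual`, `region`, `population` and
#'   two integer allele columns per locus named `<locus>.1` / `<locus>.2`.
#' @param design a [StudyDesign-class].
#' @param loci locus names; inferred from column names when `NULL`.
#' @return a validated [GenotypeTable-class].
#' @export
GenotypeTable <- function(data, design, loci = NULL) {
  data <- as.data.frame(data)
  for (col in c("individual", "region", "population")) {
    if (!is.null(data[[col]])) data[[col]] <- as.character(data[[col]])
  }
  if (is.null(loci)) {
    ac <- setdiff(names(data), c("individual", "region", "population"))
    loci <- unique(sub("\\.[12]$", "", ac))
  }
  rownames(data) <- NULL
  methods::new("GenotypeTable", data = data, loci = as.character(loci), design = design)
}

#' @rdname lociNames
setMethod("lociNames", "GenotypeTable", function(x) x@loci)

#' @rdname lociNames
setMethod("nLoci", "GenotypeTable", function(x) length(x@loci))

#' @rdname studyDesign
setMethod("studyDesign", "GenotypeTable", function(x) x@design)

#' @rdname populations
setMethod("nPopulations", "GenotypeTable", function(x) length(unique(x@data$population)))

#' @rdname populations
setMethod("regions", "GenotypeTable", function(x) regions(x@design))

#' @rdname as.data.frame.PhenotypeTable
#' @export
as.data.frame.GenotypeTable <- function(x, ...) x@data

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object@data), "individuals,",
      length(unique(object@data$population)), "populations,",
      length(object@loci), "loci\n")
  miss <- vapply(object@loci, function(loc) {
    mean(object@data[[paste0(loc, ".1")]] == 0)
  }, numeric(1))
  cat("  per-locus missingness:",
      paste(sprintf("%s=%.1f%%", object@loci, 100 * miss), collapse = ", "), "\n")
})

#' @rdname subsetPopulations
setMethod("subsetPopulations", "GenotypeTable", function(x, keep) {
  d <- x@data[x@data$population %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  methods::new("GenotypeTable", data = d, loci = x@loci,
               design = .subsetDesign(x@design, keep))
})

#' @rdname alleleCounts
setMethod("alleleCounts", "GenotypeTable", function(x) {
  d <- x@data
  pops <- unique(d$population)
  out <- lapply(x@loci, function(loc) {
    a <- c(d[[paste0(loc, ".1")]], d[[paste0(loc, ".2")]])
    p <- factor(rep(d$population, 2), levels = pops)
    ok <- a != 0
    if (!any(ok)) {
      m <- matrix(0L, nrow = length(pops), ncol = 0, dimnames = list(pops, NULL))
      return(m)
    }
    tab <- table(p[ok], factor(a[ok]))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
    m
  })
  names(out) <- x@loci
  out
})

# ---------------------------------------------------------------------------
# VarianceComponents
# ---------------------------------------------------------------------------

#' Nested random-model variance components for one trait
#'
#' Components of the Gaussian nested random model
#' `trait = mu + region + population(region) + family(population) + error`,
#' reported after truncating negative method-of-moments solutions at zero
#' (truncated levels are flagged).
#'
#' @slot trait trait name.
#' @slot components named numeric vector
#'   (`region`, `population`, `family`, `residual`), variances in trait
#'   units squared.
#' @slot method `"anova"` or `"reml"`.
#' @slot nPlants number of plants used.
#' @slot truncated names of levels whose raw estimate was negative and was
#'   truncated to zero.
#'
#' @export
setClass("VarianceComponents",
  slots = c(trait = "character", components = "numeric", method = "character",
            nPlants = "integer", truncated = "character")
)

setValidity("VarianceComponents", function(object) {
  lv <- c("region", "population", "family", "residual")
  if (!identical(names(object@components), lv)) {
    return("components must be named region, population, family, residual")
  }
  if (any(object@components < 0)) return("reported components must be >= 0")
  TRUE
})

#' @rdname varComponents
setMethod("varComponents", "VarianceComponents", function(x) x@components)

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents ('%s', %s, n = %d plants)\n",
              object@trait, object@method, object@nPlants))
  print(round(object@components, 6))
  if (length(object@truncated)) {
    cat("  truncated to 0:", paste(object@truncated, collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# AmovaResult and StandardizedIndices
# ---------------------------------------------------------------------------

#' Hierarchical AMOVA result
#'
#' Variance components of the three-level AMOVA on allele-identity
#' distances: `a` among regions, `b` among populations within regions, `c`
#' within populations. Components are summed over loci before the F
#' statistics are formed. F statistics are clamped to [0, 1] for
#' reporting; the unclamped values are retained.
#'
#' @slot components named numeric (`a`, `b`, `c`), summed over loci.
#' @slot fStat named numeric (`F_RT`, `F_SR`, `F_ST`), clamped to [0, 1].
#' @slot fUnclamped the same ratios before clamping.
#' @slot perLocus `data.frame` of per-locus components and coefficients.
#' @slot nLoci loci used.
#' @slot copies named numeric, scored allele copies per population (summed
#'   over loci).
#'
#' @export
setClass("AmovaResult",
  slots = c(components = "numeric", fStat = "numeric", fUnclamped = "numeric",
            perLocus = "data.frame", nLoci = "integer", copies = "numeric")
)

#' @rdname varComponents
setMethod("varComponents", "AmovaResult", function(x) x@components)

#' @rdname varComponents
setMethod("fStatistics", "AmovaResult", function(x) x@fStat)

setMethod("show", "AmovaResult", function(object) {
  cat("Hierarchical AMOVA (", object@nLoci, "loci )\n")
  cat("  components (summed over loci):\n")
  print(round(object@components, 6))
  cat("  F statistics:\n")
  print(round(object@fStat, 6))
})

#' Standardized differentiation indices
#'
#' F' indices obtained by dividing each raw AMOVA F statistic by its
#' maximum attainable value given the observed within-population structure
#' (computed by allele recoding), plus Hedrick's standardized G'_ST.
#'
#' @slot fPrime named numeric (`F_RT`, `F_SR`, `F_ST`) in [0, 1].
#' @slot fMax the recoded-data maxima used as denominators.
#' @slot gst multi-locus Nei G_ST.
#' @slot gstPrime Hedrick's G'_ST.
#' @slot hS mean within-population gene diversity (across loci).
#' @slot hT total gene diversity (across loci).
#'
#' @export
setClass("StandardizedIndices",
  slots = c(fPrime = "numeric", fMax = "numeric", gst = "numeric",
            gstPrime = "numeric", hS = "numeric", hT = "numeric")
)

setMethod("show", "StandardizedIndices", function(object) {
  cat("Standardized differentiation indices\n")
  print(round(object@fPrime, 6))
  cat(sprintf("  G_ST = %.6f, G'_ST = %.6f (H_S = %.4f, H_T = %.4f)\n",
              object@gst, object@gstPrime, object@hS, object@hT))
})

# ---------------------------------------------------------------------------
# IndexCI
# ---------------------------------------------------------------------------

#' A differentiation index with a jackknife confidence interval
#'
#' Point estimate plus delete-one-population jackknife standard error and
#' normal-approximation confidence interval, clamped to the index's natural
#' range. Objects can also be built directly from published estimates and
#' interval bounds via [IndexCI()] for worked-example classification.
#'
#' @slot name index name (e.g. `"Q_RT"`, `"F'_SR"`).
#' @slot estimate point estimate on the full data.
#' @slot se jackknife standard error (`NA` for externally supplied CIs).
#' @slot center jackknife bias-corrected centre (mean pseudovalue).
#' @slot lower,upper confidence bounds.
#' @slot nPopulations populations contributing delete-one replicates.
#' @slot nFailed delete-one replicates skipped because the estimator failed.
#'
#' @export
setClass("IndexCI",
  slots = c(name = "character", estimate = "numeric", se = "numeric",
            center = "numeric", lower = "numeric", upper = "numeric",
            nPopulations = "integer", nFailed = "integer")
)

setValidity("IndexCI", function(object) {
  if (length(object@lower) == 1 && length(object@upper) == 1 &&
      is.finite(object@lower) && is.finite(object@upper) &&
      object@lower > object@upper) {
    return("lower bound exceeds upper bound")
  }
  TRUE
})

#' Construct an IndexCI (e.g. from published values)
#'
#' @param name index name.
#' @param estimate point estimate.
#' @param lower,upper confidence bounds.
#' @param se standard error, if known.
#' @param center bias-corrected centre; defaults to `estimate`.
#' @param nPopulations,nFailed jackknife bookkeeping, if applicable.
#' @return an [IndexCI-class] object.
#' @examples
#' IndexCI("Q_RT", 0.371, 0.355, 0.387)
#' @export
IndexCI <- function(name, estimate, lower, upper, se = NA_real_,
                    center = estimate, nPopulations = NA_integer_,
                    nFailed = 0L) {
  methods::new("IndexCI", name = name, estimate = as.numeric(estimate),
               se = as.numeric(se), center = as.numeric(center),
               lower = as.numeric(lower), upper = as.numeric(upper),
               nPopulations = as.integer(nPopulations), nFailed = as.integer(nFailed))
}

setMethod("show", "IndexCI", function(object) {
  cat(sprintf("%s = %.3f (%.3f-%.3f)", object@name, object@estimate,
              object@lower, object@upper))
  if (is.finite(object@se)) cat(sprintf(" [jackknife SE %.4f, n = %d pops]",
                                        object@se, object@nPopulations))
  cat("\n")
})
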