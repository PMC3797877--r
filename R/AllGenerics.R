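#' @include AllGenerics.R
NULL

#' Population table of a study design or data object
#'
#' @param x a [StudyDesign-class], [PhenotypeTable-class] or
#'   [GenotypeTable-class] object.
#' @return For `populations()`, a `data.frame` with one row per population
#'   (columns `population`, `region`, `elevation`, `longitude`, `latitude`);
#'   for `regions()`, the character vector of region identifiers; for
#'   `nPopulations()`, an integer count; for `elevations()`, a named numeric
#'   vector of elevations (m a.s.l.) indexed by population.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname populations
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname populations
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))

#' @rdname populations
#' @export
setGeneric("elevations", function(x) standardGeneric("elevations"))

#' Study design of a data object
#'
#' @param x a [PhenotypeTable-class] or [GenotypeTable-class] object.
#' @return a [StudyDesign-class] object.
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))

#' Restrict a data object to a subset of populations
#'
#' Drops all rows (and design entries) belonging to populations outside
#' `keep`. Used internally by the delete-one-population jackknife and
#' available for sensitivity analyses.
#'
#' @param x a [PhenotypeTable-class] or [GenotypeTable-class] object.
#' @param keep character vector of population identifiers to retain.
#' @return an object of the same class restricted to `keep`.
#' @export
setGeneric("subsetPopulations", function(x, keep) standardGeneric("subsetPopulations"))

#' Trait columns of a phenotype table
#' @param x a [PhenotypeTable-class] object.
#' @return character vector of trait names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Locus names of a genotype table
#' @param x a [GenotypeTable-class] object.
#' @return character vector of locus names (`lociNames`) or their count
#'   (`nLoci`).
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname lociNames
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Per-locus allele count matrices
#'
#' Tabulates, for each locus, the number of scored allele copies per
#' population and allele code (missing copies, code 0, are excluded).
#'
#' @param x a [GenotypeTable-class] object.
#' @return named list (one element per locus) of integer matrices with one
#'   row per population and one column per observed allele code.
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' Nested variance-component estimation (ANOVA method of moments)
#'
#' @param x a [PhenotypeTable-class] object.
#' @param trait name of the trait column to analyse.
#' @param ... further arguments (`treatment`, see methods).
#' @return a [VarianceComponents-class] object.
#' @export
setGeneric("estimateAnova", function(x, trait, ...) standardGeneric("estimateAnova"))

#' Nested variance-component estimation (REML)
#'
#' @inheritParams estimateAnova
#' @return a [VarianceComponents-class] object.
#' @export
setGeneric("estimateReml", function(x, trait, ...) standardGeneric("estimateReml"))

#' Hierarchical AMOVA on codominant genotypes
#'
#' @param x a [GenotypeTable-class] object.
#' @param ... unused.
#' @return an [AmovaResult-class] object.
#' @export
setGeneric("amovaHierarchical", function(x, ...) standardGeneric("amovaHierarchical"))

#' Accessors for variance components and F statistics
#'
#' @param x a [VarianceComponents-class] or [AmovaResult-class] object.
#' @return `varComponents()` returns the named numeric vector of variance
#'   components; `fStatistics()` the named vector of (clamped) F statistics.
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname varComponents
#' @export
setGeneric("fStatistics", function(x) standardGeneric("fStatistics"))
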