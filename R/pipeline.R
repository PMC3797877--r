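#' @include AllClasses.R
NULL

#' Simulate a complete design-matched study dataset
#'
#' Generates phenotypes, genotypes and a phenology census under the
#' package's default study conditions: the 4-region / 21-population /
#' 6-family / 8-plant design, three Gaussian traits with region-heavy
#' (`height`), population-heavy (`leafRatio`) and strongly regional
#' (`biomass`) variance-component settings, microsatellite genotypes with
#' weak among-region (`thetaRT = 0.1`) and strong within-region
#' (`thetaSR = 0.4`) drift, and a late-season census in which the
#' south-eastern region flowers late while the others are ripening.
#'
#' @param seed integer seed driving all randomness.
#' @param design a [StudyDesign-class].
#' @return list with elements `phenotypes` ([PhenotypeTable-class] with 3
#'   traits), `genotypes` ([GenotypeTable-class]), `phenology`
#'   (`data.frame`) and `truth` (the generating parameters).
#' @examples
#' st <- simulateStudy(seed = 1)
#' st$phenotypes
#' @export
simulateStudy <- function(seed, design = campanulaDesign()) {
  set.seed(seed)
  sig <- list(
    height = c(region = 2, population = 0.5, family = 1, residual = 4),
    leafRatio = c(region = 0.1, population = 1, family = 1, residual = 4),
    biomass = c(region = 4, population = 0.3, family = 1, residual = 4)
  )
  tabs <- lapply(names(sig), function(tr) {
    simulatePhenotypes(design, sigma2 = sig[[tr]], traitName = tr, seed = NULL)
  })
  d <- as.data.frame(tabs[[1]])
  for (i in 2:length(tabs)) d[[names(sig)[i]]] <- as.data.frame(tabs[[i]])[[names(sig)[i]]]
  pheno <- PhenotypeTable(d, design, traits = names(sig))
  geno <- simulateGenotypes(design, nLoci = 5L, nAlleles = 8L, thetaRT = 0.1,
                            thetaSR = 0.4, individualsPerPopulation = 30L,
                            seed = NULL)
  stages <- c("rosette", "bolting", "flowering", "ripening")
  probs <- rbind(
    WA  = c(0.05, 0.10, 0.25, 0.60),
    CSA = c(0.05, 0.10, 0.25, 0.60),
    CAA = c(0.05, 0.10, 0.25, 0.60),
    SEA = c(0.05, 0.05, 0.80, 0.10)
  )
  colnames(probs) <- stages
  regs <- unique(design@populations$region)
  if (!all(regs %in% rownames(probs))) {
    probs <- matrix(1 / length(stages), length(regs), length(stages),
                    dimnames = list(regs, stages))
  }
  phenology <- simulatePhenology(design, probs[regs, , drop = FALSE],
                                 nPerPopulation = 40, seed = NULL)
  list(phenotypes = pheno, genotypes = geno, phenology = phenology,
       truth = list(sigma2 = sig, thetaRT = 0.1, thetaSR = 0.4, seed = seed))
}

# Q-index estimator factory used for jackknifing
.qEstimator <- function(trait, which = c("Q_RT", "Q_SR"), structure, convention,
                        treatment) {
  which <- match.arg(which)
  function(p) {
    vc <- estimateAnova(p, trait, treatment = treatment)
    computeQ(vc, structure = structure, convention = convention)[[which]]
  }
}

# F'-index estimator factory used for jackknifing
.fEstimator <- function(which = c("F_RT", "F_SR", "F_ST")) {
  which <- match.arg(which)
  function(g) standardizeIndices(g)@fPrime[[which]]
}

#' Run the full past-selection and local-adaptation analysis
#'
#' For every trait: estimates nested variance components on the chosen
#' treatment subset (optionally pre-adjusted for the initial-size
#' covariate), converts them to Q_RT / Q_SR, and attaches
#' delete-one-population jackknife CIs. On the genotypes: hierarchical
#' AMOVA, standardized F' indices with jackknife CIs, and G'_ST. Each
#' trait and level is then classified as under diversifying, unifying or
#' no detectable selection by CI comparison, Q_RT is compared against
#' Q_SR, trait-elevation correlations (two-stage population means) are
#' Holm-corrected, and phenology tables (if given) are G-tested.
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param genotypes a [GenotypeTable-class].
#' @param phenology optional phenology count `data.frame` (see
#'   [simulatePhenology()]).
#' @param traits traits to analyse; default all.
#' @param structure,convention passed to [computeQ()].
#' @param treatment treatment subset for Q analyses (default
#'   `"control"`: unclipped plants only).
#' @param covariate name of a covariate column to pre-adjust traits for,
#'   or `NULL` (default) to skip adjustment.
#' @param z CI multiplier (1.96 = 95%).
#' @param outDir if non-`NULL`, results are written there via
#'   [writeResults()] (byte-identical on rerun with identical inputs).
#' @param seed optional integer recorded in the manifest (the pipeline
#'   itself is deterministic given its inputs).
#' @return named list of result `data.frame`s: `variance_components`,
#'   `q_indices`, `molecular_indices`, `selection_calls`, `correlations`,
#'   `g_tests` (when phenology given).
#' @examples
#' \donttest{
#' st <- simulateStudy(seed = 7)
#' res <- runPipeline(st$phenotypes, st$genotypes, st$phenology)
#' res$selection_calls
#' }
#' @export
runPipeline <- function(phenotypes, genotypes, phenology = NULL,
                        traits = traitNames(phenotypes),
                        structure = "half_sib", convention = "total_within",
                        treatment = "control", covariate = NULL,
                        z = 1.96, outDir = NULL, seed = NULL) {
  stopifnot(methods::is(phenotypes, "PhenotypeTable"),
            methods::is(genotypes, "GenotypeTable"))
  altConvention <- setdiff(c("total_within", "pooled"), convention)

  vcRows <- list(); qRows <- list()
  for (tr in traits) {
    ph <- if (is.null(covariate)) phenotypes else adjustCovariate(phenotypes, tr, covariate)
    vc <- estimateAnova(ph, tr, treatment = treatment)
    cmp <- varComponents(vc)
    vcRows[[tr]] <- data.frame(trait = tr, method = vc@method,
      n_plants = vc@nPlants, sigma2_region = cmp[["region"]],
      sigma2_population = cmp[["population"]], sigma2_family = cmp[["family"]],
      sigma2_residual = cmp[["residual"]],
      truncated = paste(vc@truncated, collapse = ";"), stringsAsFactors = FALSE)
    q <- computeQ(vc, structure = structure, convention = convention)
    qAlt <- computeQ(vc, structure = structure, convention = altConvention)
    jkRT <- jackknifePopulations(ph,
      .qEstimator(tr, "Q_RT", structure, convention, treatment),
      z = z, name = paste0("Q_RT(", tr, ")"))
    jkSR <- jackknifePopulations(ph,
      .qEstimator(tr, "Q_SR", structure, convention, treatment),
      z = z, name = paste0("Q_SR(", tr, ")"))
    qRows[[tr]] <- data.frame(trait = tr,
      q_rt = q$Q_RT, q_rt_lower = jkRT@lower, q_rt_upper = jkRT@upper,
      q_sr = q$Q_SR, q_sr_lower = jkSR@lower, q_sr_upper = jkSR@upper,
      q_rt_alt_convention = qAlt$Q_RT, convention = convention,
      k = q$k, stringsAsFactors = FALSE)
  }
  vcTab <- do.call(rbind, vcRows); rownames(vcTab) <- NULL
  qTab <- do.call(rbind, qRows); rownames(qTab) <- NULL

  raw <- amovaHierarchical(genotypes)
  std <- standardizeIndices(genotypes, raw)
  jkFRT <- jackknifePopulations(genotypes, .fEstimator("F_RT"), z = z, name = "F'_RT")
  jkFSR <- jackknifePopulations(genotypes, .fEstimator("F_SR"), z = z, name = "F'_SR")
  mol <- data.frame(
    index = c("F_RT", "F_SR", "F_ST", "F_prime_RT", "F_prime_SR", "F_prime_ST",
              "G_ST", "G_prime_ST"),
    estimate = c(fStatistics(raw)[["F_RT"]], fStatistics(raw)[["F_SR"]],
                 fStatistics(raw)[["F_ST"]], std@fPrime[["F_RT"]],
                 std@fPrime[["F_SR"]], std@fPrime[["F_ST"]], std@gst,
                 std@gstPrime),
    lower = c(NA, NA, NA, jkFRT@lower, jkFSR@lower, NA, NA, NA),
    upper = c(NA, NA, NA, jkFRT@upper, jkFSR@upper, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  calls <- selectionCalls(qTab,
    fRT = IndexCI("F'_RT", std@fPrime[["F_RT"]], jkFRT@lower, jkFRT@upper),
    fSR = IndexCI("F'_SR", std@fPrime[["F_SR"]], jkFSR@lower, jkFSR@upper))

  corRows <- lapply(traits, function(tr) {
    pm <- tryCatch(suppressWarnings(populationMeans(phenotypes, tr, treatment)),
                   error = function(e) NULL)
    if (is.null(pm)) return(NULL)
    ct <- tryCatch(correlateElevation(pm, phenotypes@design),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    data.frame(trait = tr, n = ct$n, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  corTab <- do.call(rbind, corRows)
  if (!is.null(corTab) && nrow(corTab)) {
    corTab$p_holm <- holmAdjust(corTab$p)
    rownames(corTab) <- NULL
  }

  out <- list(variance_components = vcTab, q_indices = qTab,
              molecular_indices = mol, selection_calls = calls,
              correlations = corTab)
  if (!is.null(phenology)) out$g_tests <- phenologyGTests(phenology)
  if (!is.null(outDir)) {
    cfg <- list(traits = traits, structure = structure, convention = convention,
                treatment = treatment, covariate = covariate, z = z)
    writeResults(out, outDir, config = cfg, seed = seed)
  }
  out
}
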