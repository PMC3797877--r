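#' @include AllClasses.R
NULL

#' Within-population additive genetic variance from the family component
#'
#' Seed-family variance estimates a fraction of the additive genetic
#' variance that depends on the relatedness structure within families:
#' `V_A = k * sigma2_family` with `k = 4` for half sibs (open-pollinated
#' maternal families of an outcrosser, the default), `k = 2` for full
#' sibs, and `k = 1` when the family component is read as broad-sense
#' genetic variance.
#'
#' @param vc a [VarianceComponents-class] object.
#' @param structure `"half_sib"`, `"full_sib"` or `"broad_sense"`.
#' @return the within-population additive variance (numeric scalar).
#' @examples
#' vc <- new("VarianceComponents", trait = "t",
#'   components = c(region = 1, population = 1, family = 0.25, residual = 4),
#'   method = "anova", nPlants = 100L, truncated = character())
#' additiveWithin(vc, "half_sib")
#' @export
additiveWithin <- function(vc, structure = c("half_sib", "full_sib", "broad_sense")) {
  stopifnot(methods::is(vc, "VarianceComponents"))
  structure <- match.arg(structure)
  k <- c(half_sib = 4, full_sib = 2, broad_sense = 1)[[structure]]
  k * vc@components[["family"]]
}

#' Hierarchical quantitative-trait differentiation indices Q_RT and Q_SR
#'
#' Converts nested variance components into the hierarchical analogues of
#' Q_ST: `Q_RT` measures trait differentiation among phylogeographic
#' regions, `Q_SR` among populations within regions. With
#' `V_A = additiveWithin(vc, structure)`:
#'
#' * convention `"total_within"` (default):
#'   `Q_RT = s2_region / (s2_region + 2 * (s2_population + V_A))`,
#'   treating all genetic variance below the region level as the
#'   within-group term;
#' * convention `"pooled"`:
#'   `Q_RT = s2_region / (s2_region + 2 * V_A)`.
#'
#' Both conventions share
#' `Q_SR = s2_population / (s2_population + 2 * V_A)`. The residual
#' component never enters any index. Because the appropriate `Q_RT`
#' denominator is a modelling choice, [runPipeline()] reports both
#' conventions side by side.
#'
#' @param vc a [VarianceComponents-class] object.
#' @param structure family relatedness structure, see [additiveWithin()].
#' @param convention `"total_within"` or `"pooled"`.
#' @return one-row `data.frame` with columns `trait`, `Q_RT`, `Q_SR`,
#'   `k`, `convention`.
#' @examples
#' vc <- new("VarianceComponents", trait = "height",
#'   components = c(region = 1, population = 1, family = 0.25, residual = 4),
#'   method = "anova", nPlants = 100L, truncated = character())
#' computeQ(vc)  # Q_RT = 0.2, Q_SR = 1/3
#' @export
computeQ <- function(vc, structure = c("half_sib", "full_sib", "broad_sense"),
                     convention = c("total_within", "pooled")) {
  stopifnot(methods::is(vc, "VarianceComponents"))
  structure <- match.arg(structure)
  convention <- match.arg(convention)
  va <- additiveWithin(vc, structure)
  s2r <- vc@components[["region"]]
  s2p <- vc@components[["population"]]
  denRT <- if (convention == "total_within") s2r + 2 * (s2p + va) else s2r + 2 * va
  denSR <- s2p + 2 * va
  if (denRT == 0 || denSR == 0) stop("index undefined for constant trait (zero denominator)")
  data.frame(trait = vc@trait,
             Q_RT = unname(s2r / denRT),
             Q_SR = unname(s2p / denSR),
             k = c(half_sib = 4, full_sib = 2, broad_sense = 1)[[structure]],
             convention = convention,
             stringsAsFactors = FALSE)
}
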