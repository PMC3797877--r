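#' @include AllClasses.R
NULL

#' Published differentiation estimates from a Campanula thyrsoides
#' common-garden study
#'
#' Reference point estimates and 95% jackknife confidence intervals of the
#' hierarchical differentiation indices reported for an Alpine
#' *Campanula thyrsoides* common-garden study (7 phenotypic traits, four
#' phylogeographic regions, 21 populations), together with the published
#' selection calls. Used as a worked example: feeding these intervals to
#' [classifySelection()] and [compareLevels()] reproduces every published
#' call.
#'
#' @return list with two `data.frame`s:
#' \describe{
#'   \item{quantitative}{per-trait `q_rt`, `q_sr` estimates with CI bounds
#'     and the published calls (`published_call_rt`, `published_call_sr`,
#'     `published_level_comparison`).}
#'   \item{molecular}{estimates (and CIs where published) of `F_prime_RT`,
#'     `F_prime_SR`, `F_prime_ST` and `G_prime_ST`.}
#' }
#' @examples
#' ref <- campanulaIndices()
#' ref$molecular
#' @export
campanulaIndices <- function() {
  qf <- system.file("extdata", "campanula_reference_indices.csv",
                    package = "hierQF", mustWork = TRUE)
  mf <- system.file("extdata", "campanula_molecular_indices.csv",
                    package = "hierQF", mustWork = TRUE)
  list(
    quantitative = utils::read.csv(qf, stringsAsFactors = FALSE),
    molecular = utils::read.csv(mf, stringsAsFactors = FALSE)
  )
}
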