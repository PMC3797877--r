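#' @include AllClasses.R
NULL

#' The 21-population, four-region Campanula thyrsoides sampling design
#'
#' Returns the hierarchical design used throughout the package examples and
#' the synthetic-data defaults: 21 populations split 6/5/4/6 over the four
#' Alpine phylogeographic regions WA (Western Alps and Jura), CSA (Central
#' Swiss Alps), CAA (Central Austrian Alps) and SEA (South-eastern Alps),
#' with 6 open-pollinated seed families per population and 8 plants per
#' family. Elevations are synthetic but span the species' elevational
#' distribution (sub-alpine 1400-2200 m for WA/CSA/CAA, colline/montane
#' 1000-1500 m for SEA); coordinates are rough region-ordered placeholders
#' and are never used in computation.
#'
#' @return a [StudyDesign-class] with 21 populations in 4 regions.
#' @examples
#' campanulaDesign()
#' @export
campanulaDesign <- function() {
  pops <- data.frame(
    population = c(paste0("WA", 1:6), paste0("CSA", 1:5),
                   paste0("CAA", 1:4), paste0("SEA", 1:6)),
    region = c(rep("WA", 6), rep("CSA", 5), rep("CAA", 4), rep("SEA", 6)),
    elevation = c(
      1450, 1620, 1780, 1930, 2080, 2210,   # WA
      1520, 1680, 1840, 1990, 2140,         # CSA
      1580, 1760, 1900, 2050,               # CAA
      1020, 1110, 1230, 1340, 1430, 1510    # SEA
    ),
    longitude = c(
      6.1, 6.4, 6.8, 7.1, 7.3, 7.5,
      7.9, 8.2, 8.5, 8.8, 9.1,
      9.6, 10.1, 10.6, 11.1,
      12.0, 12.4, 12.9, 13.4, 13.9, 14.3
    ),
    latitude = c(
      44.3, 44.8, 45.2, 45.6, 46.0, 46.4,
      46.2, 46.4, 46.6, 46.7, 46.8,
      46.7, 46.6, 46.5, 46.4,
      46.3, 46.2, 46.1, 46.0, 45.9, 45.8
    )
  )
  StudyDesign(pops, familiesPerPopulation = 6L, plantsPerFamily = 8L)
}
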