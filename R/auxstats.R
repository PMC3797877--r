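#' @include AllClasses.R
NULL

#' Two-stage population means (plants -> family means -> population mean)
#'
#' Population-averaged trait values computed from seed-family means:
#' plant values are first averaged within family, then family means are
#' averaged (unweighted, regardless of family size) within population.
#' Families with no data are excluded; populations with no family having
#' data are dropped with a warning.
#'
#' @param x a [PhenotypeTable-class].
#' @param trait trait column.
#' @param treatment `"control"` (default), `"clipped"` or `"all"`.
#' @return named numeric vector of population means.
#' @export
populationMeans <- function(x, trait, treatment = "control") {
  stopifnot(methods::is(x, "PhenotypeTable"))
  if (!trait %in% names(x@data)) stop("unknown trait: ", trait)
  treatment <- match.arg(treatment, c("control", "clipped", "all"))
  d <- x@data
  if (treatment != "all") d <- d[d$treatment == treatment, , drop = FALSE]
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  if (nrow(d) == 0) stop("empty subset for trait '", trait, "'")
  key <- paste(d$population, d$family, sep = "\r")
  famMean <- tapply(d[[trait]], key, mean)
  famPop <- vapply(strsplit(names(famMean), "\r", fixed = TRUE), `[`, character(1), 1)
  popMean <- tapply(famMean, famPop, mean)
  dropped <- setdiff(unique(x@data$population), names(popMean))
  if (length(dropped)) {
    warning("population(s) with no data excluded: ", paste(dropped, collapse = ", "))
  }
  out <- as.numeric(popMean)
  names(out) <- names(popMean)
  out
}

#' Pearson correlation between population trait means and elevation
#'
#' Tests whether a population-averaged trait varies with the elevation of
#' population origin (a proxy for elevation-related environmental
#' variables). The two-sided p-value comes from the t transformation of r
#' with n - 2 degrees of freedom.
#'
#' @param popMeans named numeric vector of population means (names =
#'   population ids), e.g. from [populationMeans()].
#' @param design a [StudyDesign-class] providing elevations.
#' @param subset optional character vector restricting to a population
#'   subset (e.g. one subspecies).
#' @return one-row `data.frame` with columns `n`, `r`, `p`.
#' @export
correlateElevation <- function(popMeans, design, subset = NULL) {
  elev <- elevations(design)
  pops <- intersect(names(popMeans), names(elev))
  if (!is.null(subset)) pops <- intersect(pops, subset)
  if (length(pops) < 3) stop("need >= 3 populations with trait means and elevations")
  x <- popMeans[pops]; e <- elev[pops]
  if (stats::var(x) == 0 || stats::var(e) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, e, method = "pearson", alternative = "two.sided")
  data.frame(n = length(pops), r = unname(ct$estimate), p = ct$p.value)
}

#' Sequential Holm-Bonferroni adjustment
#'
#' Step-down adjustment: with the m p-values sorted ascending,
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))`, returned in the
#' original order (delegates to `stats::p.adjust(method = "holm")`).
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' holmAdjust(c(0.001, 0.02, 0.04))  # 0.003, 0.04, 0.04
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Likelihood-ratio G test on count tables
#'
#' `G = 2 * sum(O * ln(O / E))` over cells with observed counts > 0,
#' referred to the upper chi-square tail. In independence mode (a matrix
#' of observed counts) the expected counts come from the row/column
#' margins and `df = (rows - 1) * (cols - 1)`; in goodness-of-fit mode the
#' expected counts (or probabilities) are supplied and
#' `df = cells - 1 - constraints`. Cells with expected 0 and observed 0
#' are dropped; expected 0 with observed > 0 is an error. No Williams or
#' Yates correction is applied by default.
#'
#' @param observed matrix (independence) or vector (goodness of fit) of
#'   non-negative counts.
#' @param expected expected counts or probabilities (goodness-of-fit mode
#'   only; rescaled to `sum(observed)`).
#' @param constraints number of parameters estimated from the data
#'   (goodness-of-fit df correction).
#' @param williams apply the Williams continuity correction
#'   (`G / (1 + (cells^2 - 1) / (6 * n * df))`).
#' @return list with elements `statistic` (G), `df` and `p.value`.
#' @examples
#' gTest(matrix(c(10, 0, 0, 10), 2))  # G = 40 * log(2)
#' @export
gTest <- function(observed, expected = NULL, constraints = 0, williams = FALSE) {
  if (any(observed < 0)) stop("negative counts")
  if (is.matrix(observed) && is.null(expected)) {
    n <- sum(observed)
    if (n == 0) stop("empty table")
    E <- outer(rowSums(observed), colSums(observed)) / n
    df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  } else {
    if (is.null(expected)) stop("goodness-of-fit mode needs expected counts")
    if (length(expected) != length(observed)) stop("observed/expected length mismatch")
    if (any(expected < 0)) stop("negative expected counts")
    E <- expected * sum(observed) / sum(expected)
    df <- length(observed) - 1 - constraints
  }
  O <- as.vector(observed); E <- as.vector(E)
  if (any(E == 0 & O > 0)) stop("expected count 0 with observed > 0")
  keep <- !(E == 0 & O == 0)
  O <- O[keep]; E <- E[keep]
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  if (df < 1) stop("no degrees of freedom")
  if (williams) {
    q <- 1 + (length(O)^2 - 1) / (6 * sum(O) * df)
    G <- G / q
  }
  list(statistic = G, df = df, p.value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' G tests on phenological-state censuses
#'
#' Runs the among-regions test (region totals x stages) and one
#' populations-within-region test per region on a phenology count table as
#' produced by [simulatePhenology()].
#'
#' @param counts `data.frame` with columns `population`, `region` and one
#'   count column per stage.
#' @return `data.frame` with columns `scope`, `G`, `df`, `p` (first row
#'   `among_regions`, then `within_<region>` rows; regions whose table has
#'   no degrees of freedom, e.g. a single population, are skipped).
#' @export
phenologyGTests <- function(counts) {
  stopifnot(all(c("population", "region") %in% names(counts)))
  stages <- setdiff(names(counts), c("population", "region"))
  m <- as.matrix(counts[stages])
  regTot <- rowsum(m, counts$region)
  keep <- colSums(regTot) > 0
  res <- gTest(regTot[, keep, drop = FALSE])
  out <- data.frame(scope = "among_regions", G = res$statistic, df = res$df,
                    p = res$p.value, stringsAsFactors = FALSE)
  for (r in unique(counts$region)) {
    sub <- m[counts$region == r, , drop = FALSE]
    if (nrow(sub) < 2) next
    keep <- colSums(sub) > 0
    if (sum(keep) < 2) next
    res <- gTest(sub[, keep, drop = FALSE])
    out <- rbind(out, data.frame(scope = paste0("within_", r), G = res$statistic,
                                 df = res$df, p = res$p.value,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Elementwise power transform
#'
#' Normalising transform for right-skewed non-negative traits (counts,
#' biomass): `x^exponent`. Canonical exponents used for the worked
#' example traits: 0.656 (number of leaves), 0.620 (number of flowers),
#' 0.331 (above-ground biomass).
#'
#' @param x non-negative numeric values.
#' @param exponent power exponent (> 0).
#' @return transformed values with attribute `"exponent"`.
#' @export
powerTransform <- function(x, exponent) {
  if (any(x < 0, na.rm = TRUE)) stop("power transform needs non-negative input")
  stopifnot(is.numeric(exponent), length(exponent) == 1, exponent > 0)
  out <- x^exponent
  attr(out, "exponent") <- exponent
  out
}
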