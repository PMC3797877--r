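#' @include amova.R
NULL

# Relabel alleles so that no two recoding units (populations or regions)
# share an allele code, preserving within-unit genotype structure. Counts
# are sufficient statistics for identity-distance AMOVA, so recoding acts
# on the count matrix: each unit's observed alleles move to their own
# column block.
.recodeCounts <- function(m, groups) {
  units <- unique(groups)
  blocks <- lapply(units, function(u) {
    sub <- m[groups == u, , drop = FALSE]
    keep <- colSums(sub) > 0
    sub <- sub[, keep, drop = FALSE]
    full <- matrix(0L, nrow = nrow(m), ncol = ncol(sub))
    full[groups == u, ] <- sub
    full
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(m)
  colnames(out) <- if (ncol(out)) paste0("rc", seq_len(ncol(out))) else NULL
  out
}

# multi-locus Nei G_ST and Hedrick's G'_ST from count matrices
.gstFromCounts <- function(countsList, nPops) {
  hs <- ht <- numeric(0)
  for (m in countsList) {
    ni <- rowSums(m)
    m <- m[ni > 0, , drop = FALSE]
    ni <- ni[ni > 0]
    if (nrow(m) < 2 || ncol(m) == 0) next
    p <- m / ni
    hs <- c(hs, mean(1 - rowSums(p^2)))
    pbar <- colMeans(p)                       # unweighted across populations
    ht <- c(ht, 1 - sum(pbar^2))
  }
  if (!length(ht) || mean(ht) == 0) stop("no variation: G_ST undefined")
  hS <- mean(hs); hT <- mean(ht)
  gst <- (hT - hS) / hT
  s <- nPops
  gstPrime <- if (hS >= 1) NA_real_ else gst * (s - 1 + hS) / ((s - 1) * (1 - hS))
  list(gst = gst, gstPrime = min(gstPrime, 1), hS = hS, hT = hT)
}

#' Standardized differentiation indices F'_RT, F'_SR, F'_ST and G'_ST
#'
#' Each raw AMOVA F statistic is divided by the maximum value it could
#' attain given the observed within-population diversity. The maxima are
#' obtained by relabelling alleles so that no two recoding units share an
#' allele code and rerunning the AMOVA: for `F'_ST` and `F'_SR` the
#' recoding unit is the population; for `F'_RT` it is the region
#' (populations within a region keep shared codes, so only among-region
#' sharing is removed). Hedrick's `G'_ST` is computed in closed form from
#' multi-locus `G_ST` and the mean within-population gene diversity `H_S`
#' over `s` populations as `G'_ST = G_ST * (s - 1 + H_S) /
#' ((s - 1) * (1 - H_S))`.
#'
#' @param x the [GenotypeTable-class] the raw AMOVA was computed on.
#' @param raw an [AmovaResult-class] from [amovaHierarchical()]; computed
#'   from `x` when `NULL`.
#' @return a [StandardizedIndices-class] object. A level whose recoded
#'   maximum is 0 (possible only when within-population variation is
#'   absent and the raw index is itself 0) is reported as `NA` with a
#'   warning; if every level is undefined an error is raised.
#' @examples
#' gt <- simulateGenotypes(seed = 1)
#' standardizeIndices(gt)
#' @export
standardizeIndices <- function(x, raw = NULL) {
  stopifnot(methods::is(x, "GenotypeTable"))
  if (is.null(raw)) raw <- amovaHierarchical(x)
  stopifnot(methods::is(raw, "AmovaResult"))
  counts <- alleleCounts(x)
  pops <- unique(x@data$population)
  pr <- .popRegion(x@design)[pops]
  G <- length(unique(pr))

  popRecoded <- lapply(counts, function(m) .recodeCounts(m, rownames(m)))
  maxPop <- .amovaCore(popRecoded, pr)
  fMax <- c(F_RT = NA_real_, F_SR = maxPop@fStat[["F_SR"]],
            F_ST = maxPop@fStat[["F_ST"]])
  if (G >= 2) {
    regRecoded <- lapply(counts, function(m) .recodeCounts(m, unname(pr[rownames(m)])))
    maxReg <- .amovaCore(regRecoded, pr)
    fMax[["F_RT"]] <- maxReg@fStat[["F_RT"]]
  }
  fPrime <- c(F_RT = NA_real_, F_SR = NA_real_, F_ST = NA_real_)
  for (nm in names(fPrime)) {
    f <- raw@fStat[[nm]]
    if (is.na(f)) next
    if (is.na(fMax[[nm]]) || fMax[[nm]] == 0) {
      # attainable only when within-population variation is absent and the
      # raw index is itself 0; the level carries no standardizable signal
      warning("standardization undefined for ", nm, " (recoded maximum is 0)")
      next
    }
    fPrime[[nm]] <- min(f / fMax[[nm]], 1)
  }
  if (all(is.na(fPrime))) stop("standardization undefined at every level")
  g <- .gstFromCounts(counts, nPops = length(pops))
  methods::new("StandardizedIndices", fPrime = fPrime, fMax = fMax,
               gst = g$gst, gstPrime = g$gstPrime, hS = g$hS, hT = g$hT)
}
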