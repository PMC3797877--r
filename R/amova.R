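#' @include AllClasses.R
NULL

# sum of squares of a set of allele copies given allele counts ck:
# with 0/1 identity distance, SS = (n - sum(ck^2)/n) / 2
.ssIdentity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  (n - sum(counts^2) / n) / 2
}

# Three-level AMOVA components for one locus from a population x allele
# count matrix and a population -> region map. Returns NULL when the
# locus carries no usable information (monomorphic after deletion, or
# fewer than 2 populations scored).
.amovaLocus <- function(m, popRegion) {
  ni <- rowSums(m)
  m <- m[ni > 0, , drop = FALSE]
  ni <- ni[ni > 0]
  if (nrow(m) < 2) return(NULL)
  ck <- colSums(m)
  if (sum(ck > 0) < 2) return(NULL)             # monomorphic after deletion
  g <- popRegion[rownames(m)]
  G <- length(unique(g)); I <- nrow(m); N <- sum(ni)
  Ng <- tapply(ni, g, sum)

  ssWP <- sum(apply(m, 1, .ssIdentity))
  ssWG <- sum(vapply(unique(g), function(r) {
    .ssIdentity(colSums(m[g == r, , drop = FALSE]))
  }, numeric(1)))
  ssTot <- .ssIdentity(ck)
  ssAP <- ssWG - ssWP                            # among pops within regions
  ssAG <- ssTot - ssWG                           # among regions

  dfWP <- N - I; dfAP <- I - G; dfAG <- G - 1
  if (dfWP < 1) return(NULL)
  sumNi2overNg <- sum(tapply(ni^2, g, sum) / Ng)

  msWP <- ssWP / dfWP
  c0 <- msWP
  if (dfAP >= 1) {
    nPrime <- (N - sumNi2overNg) / dfAP
    b0 <- (ssAP / dfAP - c0) / nPrime
  } else {
    nPrime <- NA_real_; b0 <- NA_real_
  }
  if (dfAG >= 1) {
    nDPrime <- (sumNi2overNg - sum(ni^2) / N) / dfAG
    nTPrime <- (N - sum(Ng^2) / N) / dfAG
    a0 <- (ssAG / dfAG - c0 - nDPrime * b0) / nTPrime
  } else {
    nDPrime <- NA_real_; nTPrime <- NA_real_; a0 <- 0
  }
  list(a = a0, b = b0, c = c0,
       ss = c(amongRegions = ssAG, amongPops = ssAP, withinPops = ssWP),
       coef = c(nPrime = nPrime, nDPrime = nDPrime, nTPrime = nTPrime),
       copies = stats::setNames(ni, rownames(m)))
}

# Full AMOVA from per-locus count matrices; shared by the raw analysis and
# the recoded (standardization) analysis.
.amovaCore <- function(countsList, popRegion) {
  pops <- names(popRegion)
  G <- length(unique(popRegion))
  perLocus <- lapply(countsList, .amovaLocus, popRegion = popRegion)
  used <- !vapply(perLocus, is.null, logical(1))
  if (!any(used)) stop("no variation: every locus is monomorphic or unscorable")
  pl <- perLocus[used]
  comp <- c(
    a = sum(vapply(pl, `[[`, numeric(1), "a")),
    b = sum(vapply(pl, `[[`, numeric(1), "b")),
    c = sum(vapply(pl, `[[`, numeric(1), "c"))
  )
  tot <- comp[["a"]] + comp[["b"]] + comp[["c"]]
  fUn <- c(
    F_RT = if (G >= 2) comp[["a"]] / tot else NA_real_,
    F_SR = comp[["b"]] / (comp[["b"]] + comp[["c"]]),
    F_ST = if (G >= 2) (comp[["a"]] + comp[["b"]]) / tot
           else comp[["b"]] / (comp[["b"]] + comp[["c"]])
  )
  fCl <- pmin(pmax(fUn, 0), 1)
  copies <- stats::setNames(numeric(length(pops)), pops)
  for (x in pl) copies[names(x$copies)] <- copies[names(x$copies)] + x$copies
  perLocusDf <- do.call(rbind, lapply(names(pl), function(nm) {
    x <- pl[[nm]]
    data.frame(locus = nm, sigma_a = x$a, sigma_b = x$b, sigma_c = x$c,
               ss_among_regions = x$ss[["amongRegions"]],
               ss_among_pops = x$ss[["amongPops"]],
               ss_within_pops = x$ss[["withinPops"]],
               n_prime = x$coef[["nPrime"]], n_dprime = x$coef[["nDPrime"]],
               n_tprime = x$coef[["nTPrime"]], stringsAsFactors = FALSE)
  }))
  methods::new("AmovaResult", components = comp, fStat = fCl, fUnclamped = fUn,
               perLocus = perLocusDf, nLoci = sum(used), copies = copies)
}

#' @describeIn amovaHierarchical Three-level AMOVA (among regions / among
#'   populations within regions / within populations) treating each diploid
#'   individual as two allele copies with the 0/1 allele-identity distance.
#'   Variance components are solved per locus from the expected-mean-square
#'   equations with sample-size coefficients accommodating unequal
#'   population and region sizes, then summed over loci before the F
#'   statistics `F_RT = a/(a+b+c)`, `F_SR = b/(b+c)`,
#'   `F_ST = (a+b)/(a+b+c)` are formed. Missing copies are excluded per
#'   locus with coefficients recomputed. Single-region tables are allowed
#'   for two-level analyses (`F_RT` is `NA` and `F_ST` collapses to the
#'   two-level `F_SR`).
setMethod("amovaHierarchical", "GenotypeTable", function(x, ...) {
  counts <- alleleCounts(x)
  pops <- unique(x@data$population)
  if (length(pops) < 2) stop("at least 2 populations required")
  scored <- Reduce(`+`, lapply(counts, function(m) {
    rowSums(m)[pops] -> v; v[is.na(v)] <- 0; v
  }))
  if (any(scored == 0)) {
    stop("population(s) with 0 scored copies at every locus: ",
         paste(pops[scored == 0], collapse = ", "))
  }
  pr <- .popRegion(x@design)[pops]
  G <- length(unique(pr))
  if (G >= 2 && length(pops) == G) {
    stop("each region holds a single population: within-region component inestimable")
  }
  poly <- any(vapply(counts, function(m) sum(colSums(m) > 0) >= 2, logical(1)))
  if (!poly) stop("no variation: all loci monomorphic")
  .amovaCore(counts, pr)
})
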