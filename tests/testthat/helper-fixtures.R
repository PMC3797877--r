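# Shared fixtures and independent oracles used across the test files.

# a small nested design: nRegions x popsPerRegion x families x plants
toyDesign <- function(nRegions = 2, popsPerRegion = 2, families = 2, plants = 2) {
  regs <- LETTERS[seq_len(nRegions)]
  pops <- as.vector(t(outer(regs, seq_len(popsPerRegion), paste0)))
  StudyDesign(
    data.frame(population = pops,
               region = rep(regs, each = popsPerRegion),
               elevation = seq(1000, 2000, length.out = length(pops))),
    familiesPerPopulation = families, plantsPerFamily = plants
  )
}

# single-region design (two-level analyses)
oneRegionDesign <- function(nPops = 21, families = 6, plants = 8) {
  StudyDesign(
    data.frame(population = paste0("P", seq_len(nPops)), region = "R1",
               elevation = seq(1000, 2000, length.out = nPops)),
    familiesPerPopulation = families, plantsPerFamily = plants
  )
}

# fully balanced multi-region design (ANOVA == REML territory)
balancedDesign <- function(nRegions = 4, popsPerRegion = 5, families = 6, plants = 8) {
  toyDesign(nRegions, popsPerRegion, families, plants)
}

# hand-built genotype table from a list: pops -> list of individuals ->
# list of loci -> c(a1, a2)
makeGenotypes <- function(genolist, design) {
  rows <- list()
  for (pop in names(genolist)) {
    reg <- populations(design)$region[populations(design)$population == pop]
    for (i in seq_along(genolist[[pop]])) {
      ind <- genolist[[pop]][[i]]
      row <- data.frame(individual = paste0(pop, "_", i), region = reg,
                        population = pop, stringsAsFactors = FALSE)
      for (l in seq_along(ind)) {
        row[[paste0("L", l, ".1")]] <- ind[[l]][1]
        row[[paste0("L", l, ".2")]] <- ind[[l]][2]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  GenotypeTable(do.call(rbind, rows), design)
}

# random toy genotype table: <= 4 populations (2 regions), <= 8 individuals
# per population, <= 3 loci, optional missing genotypes
randomToyGenotypes <- function(withMissing = TRUE) {
  nPops <- sample(2:4, 1)
  regs <- if (nPops == 2) rep("A", 2) else c("A", "A", rep("B", nPops - 2))
  des <- StudyDesign(
    data.frame(population = paste0("P", seq_len(nPops)),
               region = regs,
               elevation = seq(1200, 1800, length.out = nPops)),
    familiesPerPopulation = 1, plantsPerFamily = 1
  )
  nLoci <- sample(1:3, 1)
  genolist <- lapply(seq_len(nPops), function(p) {
    nInd <- sample(3:8, 1)
    lapply(seq_len(nInd), function(i) {
      lapply(seq_len(nLoci), function(l) {
        if (withMissing && stats::runif(1) < 0.1) c(0L, 0L)
        else sample(1:4, 2, replace = TRUE)
      })
    })
  })
  names(genolist) <- paste0("P", seq_len(nPops))
  makeGenotypes(genolist, des)
}

# ---------------------------------------------------------------------------
# Independent AMOVA oracle: sums of squares from explicit pairwise
# allele-identity distances (SS of a set = sum of pairwise distances / n),
# EMS coefficients from explicit per-group loops.
# ---------------------------------------------------------------------------
bruteAmovaComponents <- function(gt) {
  d <- as.data.frame(gt)
  tot <- c(a = 0, b = 0, c = 0)
  for (loc in lociNames(gt)) {
    al <- c(d[[paste0(loc, ".1")]], d[[paste0(loc, ".2")]])
    pop <- rep(d$population, 2); reg <- rep(d$region, 2)
    keep <- al != 0
    al <- al[keep]; pop <- pop[keep]; reg <- reg[keep]
    # drop populations with no scored copies at this locus
    if (length(al) == 0 || length(unique(al)) < 2) next
    if (length(unique(pop)) < 2) next
    ssOf <- function(idx) {
      a <- al[idx]; m <- length(a)
      if (m < 2) return(0)
      s <- 0
      for (j in seq_len(m - 1)) for (k in (j + 1):m) s <- s + as.numeric(a[j] != a[k])
      s / m
    }
    N <- length(al)
    pops <- unique(pop); regsHere <- unique(reg)
    I <- length(pops); G <- length(regsHere)
    ssTot <- ssOf(seq_len(N))
    ssWG <- sum(vapply(regsHere, function(r) ssOf(which(reg == r)), numeric(1)))
    ssWP <- sum(vapply(pops, function(p) ssOf(which(pop == p)), numeric(1)))
    ssAG <- ssTot - ssWG
    ssAP <- ssWG - ssWP
    ni <- vapply(pops, function(p) sum(pop == p), numeric(1))
    Ng <- vapply(regsHere, function(r) sum(reg == r), numeric(1))
    popReg <- vapply(pops, function(p) reg[which(pop == p)[1]], character(1))
    if (N - I < 1) next
    cc <- ssWP / (N - I)
    sumNi2Ng <- 0
    for (r in regsHere) {
      nir <- ni[popReg == r]
      sumNi2Ng <- sumNi2Ng + sum(nir^2) / sum(nir)
    }
    if (I - G >= 1) {
      nP <- (N - sumNi2Ng) / (I - G)
      bb <- (ssAP / (I - G) - cc) / nP
    } else next
    if (G - 1 >= 1) {
      nDP <- (sumNi2Ng - sum(ni^2) / N) / (G - 1)
      nTP <- (N - sum(Ng^2) / N) / (G - 1)
      aa <- (ssAG / (G - 1) - cc - nDP * bb) / nTP
    } else aa <- 0
    tot <- tot + c(a = aa, b = bb, c = cc)
  }
  tot
}

# direct two-level AMOVA F_ST (populations as the only grouping), used for
# the one-region collapse check
twoLevelFst <- function(gt) {
  d <- as.data.frame(gt)
  b <- 0; c0 <- 0
  for (loc in lociNames(gt)) {
    al <- c(d[[paste0(loc, ".1")]], d[[paste0(loc, ".2")]])
    pop <- rep(d$population, 2)
    keep <- al != 0
    al <- al[keep]; pop <- pop[keep]
    if (length(al) == 0 || length(unique(al)) < 2 || length(unique(pop)) < 2) next
    ssOf <- function(idx) {
      a <- al[idx]; m <- length(a)
      if (m < 2) return(0)
      s <- 0
      for (j in seq_len(m - 1)) for (k in (j + 1):m) s <- s + as.numeric(a[j] != a[k])
      s / m
    }
    N <- length(al); pops <- unique(pop); I <- length(pops)
    ssTot <- ssOf(seq_len(N))
    ssWP <- sum(vapply(pops, function(p) ssOf(which(pop == p)), numeric(1)))
    ssAP <- ssTot - ssWP
    ni <- vapply(pops, function(p) sum(pop == p), numeric(1))
    nc <- (N - sum(ni^2) / N) / (I - 1)
    msW <- ssWP / (N - I)
    b <- b + (ssAP / (I - 1) - msW) / nc
    c0 <- c0 + msW
  }
  b / (b + c0)
}

# explicit data-level allele recoding (offset per unit) used as the
# standardization oracle: relabels allele codes so units share none
recodeGenotypes <- function(gt, level = c("population", "region")) {
  level <- match.arg(level)
  d <- as.data.frame(gt)
  unit <- if (level == "population") d$population else d$region
  uu <- unique(unit)
  offset <- stats::setNames((seq_along(uu) - 1) * 10000L, uu)
  for (loc in lociNames(gt)) {
    for (s in 1:2) {
      col <- paste0(loc, ".", s)
      v <- d[[col]]
      d[[col]] <- ifelse(v == 0, 0L, as.integer(v + offset[unit]))
    }
  }
  GenotypeTable(d, studyDesign(gt), loci = lociNames(gt))
}

# classical balanced nested ANOVA estimator (spreadsheet-style EMS), the
# independent oracle for estimateAnova on balanced data
balancedNestedVC <- function(df) {
  stopifnot(!is.null(df$y))
  fam <- paste(df$region, df$population, df$family)
  popf <- paste(df$region, df$population)
  famMean <- tapply(df$y, fam, mean)
  famPop <- tapply(popf, fam, function(x) x[1])
  popMean <- tapply(famMean, famPop, mean)
  popReg <- vapply(strsplit(names(popMean), " "), `[`, character(1), 1)
  regMean <- tapply(popMean, popReg, mean)
  grand <- mean(regMean)
  n <- tapply(df$y, fam, length)[1]
  f <- table(famPop)[1]
  p <- table(popReg)[1]
  N <- nrow(df); Fn <- length(famMean); P <- length(popMean); R <- length(regMean)
  msE <- sum((df$y - famMean[fam])^2) / (N - Fn)
  msF <- n * sum((famMean - popMean[famPop])^2) / (Fn - P)
  msP <- n * f * sum((popMean - regMean[popReg])^2) / (P - R)
  msR <- n * f * p * sum((regMean - grand)^2) / (R - 1)
  s2e <- msE
  s2f <- (msF - msE) / n
  s2p <- (msP - msF) / (n * f)
  s2r <- (msR - msP) / (n * f * p)
  c(region = unname(s2r), population = unname(s2p),
    family = unname(s2f), residual = unname(s2e))
}
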