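# Independent oracles and panel builders shared across the suite.

# Brute-force EHH: enumerate every pair of carrier chromosomes and count
# the pairs identical at every site between core and target (inclusive).
oracleEhh <- function(mat, coreSite, coreAllele, targetSite) {
  carriers <- which(mat[, coreSite] == coreAllele)
  span <- seq(min(coreSite, targetSite), max(coreSite, targetSite))
  same <- 0L; total <- 0L
  for (i in seq_along(carriers)) {
    for (j in seq_len(i - 1L)) {
      total <- total + 1L
      if (all(mat[carriers[i], span] == mat[carriers[j], span]))
        same <- same + 1L
    }
  }
  same / total
}

# Random polarized panel whose first site is guaranteed to segregate with
# at least two carriers of each allele.
randomPanel <- function(nChrom, nSites) {
  repeat {
    mat <- matrix(rbinom(nChrom * nSites, 1L, runif(1, 0.2, 0.8)),
                  nChrom, nSites)
    if (all(colSums(mat) >= 2L & colSums(mat) <= nChrom - 2L)) break
  }
  HaplotypeMatrix(mat, positions = sort(sample.int(1e6, nSites)))
}

# Minimal independent single-population coalescent with the
# one-mutation-per-tree convention (uniform on realized branch lengths).
# Returns the derived-allele count of the sample; deliberately naive and
# separate from the package's simulator.
rCoalDerivedCount <- function(n, N) {
  size <- as.list(rep(1L, n))       # leaves under each active lineage
  birth <- rep(0, n)
  t <- 0
  lens <- c(); subtends <- c()
  k <- n
  while (k > 1L) {
    t <- t + rexp(1L, rate = choose(k, 2) / (2 * N))
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    lens <- c(lens, t - birth[i], t - birth[j])
    subtends <- c(subtends, size[[i]], size[[j]])
    size[[i]] <- size[[i]] + size[[j]]
    birth[i] <- t
    size[[j]] <- NULL
    birth <- birth[-j]
    k <- k - 1L
  }
  subtends[sample.int(length(lens), 1L, prob = lens)]
}

# type-7 (linear interpolation) quantile, written independently of
# stats::quantile for cross-checking
oracleQuantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# neutral score set for iHS standardization: panels without selection,
# cores restricted to well-populated frequency bins
neutralScoreSet <- function(nPanels = 50L, bins = 5L, minPerBin = 5L) {
  scores <- list()
  for (i in seq_len(nPanels)) {
    scen <- sweepScenario(populationSize = 150L, nSites = 21L,
                          selectionCoefficient = 0, targetFrequency = 0.5,
                          sampleChromosomes = 100L)
    hap <- simulatePanel(scen)
    scores <- c(scores, ihsScan(hap, minCarriers = 10L))
  }
  f <- vapply(scores, function(r) r@derivedFrequency, numeric(1))
  b <- pmin(pmax(ceiling(f * bins), 1L), bins)
  full <- as.integer(names(which(table(b) >= minPerBin)))
  scores[b %in% full]
}
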