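## Synthetic inputs: forward-simulated haplotype panels (neutral or with a
## recent partial sweep at a focal site) and multi-population
## allele-frequency tables with regional structure.

#' Scenario for a synthetic haplotype panel
#'
#' Parameters of the forward Wright-Fisher panel generator
#' ([simulatePanel()]). Defaults emulate the geometry of the empirical
#' window the selection statistics were designed around: ~30 SNPs spread
#' over ~510 kb with the focal site centered.
#'
#' @param populationSize diploid population size N (2N chromosomes evolve).
#' @param nSites number of SNP columns, focal site included.
#' @param spanBp physical span of the panel in bp (default 510000).
#' @param focalSite column index of the selected/focal site (default
#'   center).
#' @param selectionCoefficient additive selection coefficient s on the
#'   focal derived allele (0 = neutral panel).
#' @param recombinationPerBp per-generation, per-bp crossover probability
#'   between adjacent sites (default 1e-8, a human-typical average).
#' @param targetFrequency the focal derived allele's required sample-path
#'   frequency: the trajectory is re-drawn until it first reaches this
#'   value (conditioning on establishment).
#' @param sampleChromosomes chromosomes drawn (without replacement) from
#'   the final generation.
#' @param maxGenerations cap per trajectory attempt.
#' @param maxTries trajectory re-draw cap; exceeding it is an error.
#' @return a list with class `"sweepScenario"`.
#' @export
sweepScenario <- function(populationSize = 200L, nSites = 31L,
                          spanBp = 510000L, focalSite = NULL,
                          selectionCoefficient = 0,
                          recombinationPerBp = 1e-8,
                          targetFrequency = 0.6,
                          sampleChromosomes = 100L,
                          maxGenerations = 5000L, maxTries = 10000L) {
  if (is.null(focalSite)) focalSite <- (nSites + 1L) %/% 2L
  stopifnot(populationSize >= 2L, nSites >= 2L, spanBp >= nSites,
            focalSite >= 1L, focalSite <= nSites,
            selectionCoefficient >= 0, recombinationPerBp >= 0,
            targetFrequency > 0, targetFrequency < 1,
            sampleChromosomes >= 2L,
            sampleChromosomes <= 2L * populationSize)
  structure(list(populationSize = as.integer(populationSize),
                 nSites = as.integer(nSites), spanBp = as.integer(spanBp),
                 focalSite = as.integer(focalSite),
                 selectionCoefficient = selectionCoefficient,
                 recombinationPerBp = recombinationPerBp,
                 targetFrequency = targetFrequency,
                 sampleChromosomes = as.integer(sampleChromosomes),
                 maxGenerations = as.integer(maxGenerations),
                 maxTries = as.integer(maxTries)),
            class = "sweepScenario")
}

## neutral standing variation: derived count of a segregating site drawn
## from the fixed-S neutral frequency spectrum P(i) proportional to 1/i
.sfsCounts <- function(nSites, n2) {
  i <- seq_len(n2 - 1L)
  sample(i, nSites, replace = TRUE, prob = 1 / i)
}

#' Raw Wright-Fisher focal-allele trajectory
#'
#' One unconditioned trajectory of a derived-allele count under additive
#' selection (genotype fitnesses 1, 1 + s/2, 1 + s), run until absorption
#' or `maxGenerations`. Used for fixation-probability and sojourn-time
#' checks of the forward machinery.
#'
#' @param n2 chromosomes (2N).
#' @param s additive selection coefficient.
#' @param initCount starting derived count (default 1, a new mutation).
#' @param nReps replicates.
#' @param maxGenerations generation cap.
#' @return integer vector of final counts (0 = lost, n2 = fixed).
#' @export
wrightFisherFate <- function(n2, s = 0, initCount = 1L, nReps = 1L,
                             maxGenerations = 100000L) {
  cpp_wf_fate(as.integer(nReps), as.integer(n2), s, as.integer(initCount),
              as.integer(maxGenerations))
}

#' Conditioned focal-allele trajectory
#'
#' Wright-Fisher trajectory from one copy, re-drawn until the derived count
#' first reaches `targetFrequency * 2N` before loss.
#'
#' @inheritParams wrightFisherFate
#' @param targetFrequency required frequency.
#' @param maxTries re-draw cap; an informative error reports the caps when
#'   exceeded.
#' @return integer vector of per-generation derived counts, ending at the
#'   first generation at or above target.
#' @export
wrightFisherTrajectory <- function(n2, s = 0, targetFrequency = 0.6,
                                   initCount = 1L, maxGenerations = 5000L,
                                   maxTries = 10000L) {
  cpp_wf_trajectory(as.integer(n2), s, as.integer(initCount),
                    as.integer(ceiling(targetFrequency * n2)),
                    as.integer(maxGenerations), as.integer(maxTries))
}

#' Simulate a phased haplotype panel with or without a partial sweep
#'
#' Discrete-generation forward simulation. The focal derived allele follows
#' a Wright-Fisher trajectory under additive selection, conditioned on
#' first reaching `targetFrequency` (trajectories that lose the allele are
#' re-drawn). Flanking sites start as standing neutral variation (derived
#' counts from the neutral fixed-S spectrum, alleles assigned to random
#' chromosomes) and evolve neutrally, linked to the focal site with
#' per-generation crossover probability proportional to inter-site
#' distance. With `selectionCoefficient = 0` the panel is a neutral
#' control; with zero recombination every carrier of the focal derived
#' allele shares the founding flanking haplotype, so its EHH is 1
#' everywhere.
#'
#' Positions are uniform draws over `spanBp` with the focal site centered.
#' Monomorphic flanking sites in the drawn sample are retained (they carry
#' no haplotype information but keep the window geometry); the focal site
#' always segregates.
#'
#' @param scenario a [sweepScenario()].
#' @param seed integer seed (`set.seed()`), or `NULL` to continue the
#'   current stream.
#' @return a [HaplotypeMatrix-class] of `sampleChromosomes` phased
#'   chromosomes.
#' @export
simulatePanel <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sweepScenario"))
  if (!is.null(seed)) set.seed(seed)
  n2 <- 2L * scenario$populationSize
  S <- scenario$nSites
  traj <- cpp_wf_trajectory(n2, scenario$selectionCoefficient, 1L,
                            as.integer(ceiling(scenario$targetFrequency * n2)),
                            scenario$maxGenerations, scenario$maxTries)
  # positions: uniform draws over the span, focal site at the center bp,
  # with focalSite - 1 flanking sites placed 5' and the rest 3'
  center <- as.numeric(scenario$spanBp %/% 2L)
  nLeft <- scenario$focalSite - 1L
  nRight <- S - scenario$focalSite
  positions <- sort(c(sample.int(center - 1L, nLeft),
                      center + sample.int(scenario$spanBp - center, nRight),
                      center))
  focalIdx <- scenario$focalSite
  # gen-0 population: one focal copy in row 1, flanks as standing variation
  init <- matrix(0L, n2, S)
  init[1L, focalIdx] <- 1L
  counts <- .sfsCounts(S - 1L, n2)
  k <- 0L
  for (j in setdiff(seq_len(S), focalIdx)) {
    k <- k + 1L
    init[sample.int(n2, counts[k]), j] <- 1L
  }
  recProb <- pmin(1, scenario$recombinationPerBp * diff(positions))
  pop <- cpp_wf_panel(init, traj, focalIdx - 1L, recProb)
  rows <- sample.int(n2, scenario$sampleChromosomes)
  HaplotypeMatrix(pop[rows, , drop = FALSE],
                  positions = positions,
                  siteIds = ifelse(seq_len(S) == focalIdx, "focal",
                                   paste0("s", seq_len(S))),
                  samplePopulations = rep("synthetic", length(rows)))
}

#' Simulate a multi-population allele-frequency table
#'
#' Per region, draws population frequencies from a beta distribution
#' centered on the regional mean, then binomial derived counts at each
#' population's chromosome count. `dispersion` is the beta intraclass
#' correlation rho in [0, 1): the beta shapes are
#' `mean * (1 - rho) / rho` and `(1 - mean) * (1 - rho) / rho`, so
#' `dispersion = 0` pins every population's expected frequency to the
#' regional mean. Chromosome counts are drawn uniformly (in even numbers,
#' diploid samples) from `chromosomesRange`; setting the lower bound below
#' 8 produces populations under the default 4-genotype inclusion
#' threshold, for exercising [filterPopulations()].
#'
#' @param regions data.frame with columns `region`, `n_populations`,
#'   `mean_frequency`, `dispersion`.
#' @param chromosomesRange length-2 integer range of per-population
#'   chromosome counts (2n).
#' @param seed integer seed, or `NULL`.
#' @return a validated population table (see [validatePopulationTable()]).
#' @examples
#' regions <- data.frame(region = c("Asia", "America"), n_populations = 5,
#'                       mean_frequency = c(0.48, 0.76), dispersion = 0.05)
#' tab <- simulateFrequencyTable(regions, seed = 1)
#' poolByRegion(tab)
#' @export
simulateFrequencyTable <- function(regions, chromosomesRange = c(10L, 60L),
                                   seed = NULL) {
  needed <- c("region", "n_populations", "mean_frequency", "dispersion")
  missing <- setdiff(needed, names(regions))
  if (length(missing))
    stop("'regions' is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(all(regions$mean_frequency >= 0 & regions$mean_frequency <= 1),
            all(regions$dispersion >= 0 & regions$dispersion < 1),
            length(chromosomesRange) == 2L)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    nPop <- regions$n_populations[i]
    m <- regions$mean_frequency[i]
    rho <- regions$dispersion[i]
    f <- if (rho == 0) rep(m, nPop) else {
      kappa <- (1 - rho) / rho
      rbeta(nPop, m * kappa, (1 - m) * kappa)
    }
    n2 <- 2L * sample(seq(ceiling(chromosomesRange[1] / 2),
                          floor(chromosomesRange[2] / 2)),
                      nPop, replace = TRUE)
    rows[[i]] <- data.frame(
      population = sprintf("%s_pop%02d", regions$region[i], seq_len(nPop)),
      region = regions$region[i],
      chromosomes = as.integer(n2),
      derived_count = rbinom(nPop, n2, f)
    )
  }
  validatePopulationTable(do.call(rbind, rows))
}
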