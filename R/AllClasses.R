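#' @useDynLib haplodrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats quantile rbinom rbeta pnorm setNames runif sd
#' @importFrom utils read.delim write.table combn packageVersion
NULL

#' Phased haplotype panel around a candidate locus
#'
#' A phased, fully polarized biallelic haplotype panel: one row per sampled
#' chromosome, one column per SNP, entries 0 (ancestral) / 1 (derived).
#' Physical positions are 1-based base pairs and strictly increasing.
#' This is the substrate for the extended haplotype homozygosity family of
#' selection statistics ([ehhAt()], [ehhCurve()], [rehhAt()], [ihs()]).
#'
#' @slot alleles integer matrix, chromosomes x sites, entries in \{0, 1\}.
#' @slot positions numeric, physical positions in bp, strictly increasing,
#'   one per site.
#' @slot siteIds character, one label per site (e.g. rs numbers).
#' @slot samplePopulations character, one population label per chromosome.
#'
#' @seealso [HaplotypeMatrix()] for the validating constructor,
#'   [readVcfHaplotypes()] and [readHaplotypePanel()] for file input,
#'   [simulatePanel()] for synthetic panels.
#' @export
setClass("HaplotypeMatrix",
  representation(
    alleles = "matrix",
    positions = "numeric",
    siteIds = "character",
    samplePopulations = "character"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  a <- object@alleles
  msgs <- character()
  if (!is.numeric(a) && !is.integer(a))
    msgs <- c(msgs, "'alleles' must be a numeric 0/1 matrix")
  else if (!all(a %in% c(0L, 1L)))
    msgs <- c(msgs, "'alleles' entries must all be 0 (ancestral) or 1 (derived)")
  if (length(object@positions) != ncol(a))
    msgs <- c(msgs, "length(positions) must equal the number of sites (columns)")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msgs <- c(msgs, "'positions' must be strictly increasing")
  if (length(object@siteIds) != ncol(a))
    msgs <- c(msgs, "length(siteIds) must equal the number of sites")
  if (length(object@samplePopulations) != nrow(a))
    msgs <- c(msgs, "length(samplePopulations) must equal the number of chromosomes (rows)")
  if (length(msgs)) msgs else TRUE
})

#' Extended haplotype homozygosity decay curve
#'
#' EHH evaluated at every flanking SNP on both sides of a core SNP, for the
#' chromosomes carrying one core allele. Distances are signed physical bp
#' (5' negative, 3' positive) and the curve is anchored at (0, 1).
#'
#' @slot coreSite integer, column index of the core SNP.
#' @slot coreAllele integer, 0 (ancestral) or 1 (derived) core allele.
#' @slot carrierCount integer, number of chromosomes carrying the core allele.
#' @slot distance numeric, signed distance in bp of each evaluated site.
#' @slot ehh numeric, EHH value in [0, 1] at each distance.
#'
#' @seealso [ehhCurve()]
#' @export
setClass("EHHCurve",
  representation(
    coreSite = "integer",
    coreAllele = "integer",
    carrierCount = "integer",
    distance = "numeric",
    ehh = "numeric"
  )
)

setValidity("EHHCurve", function(object) {
  msgs <- character()
  if (length(object@distance) != length(object@ehh))
    msgs <- c(msgs, "'distance' and 'ehh' must have equal length")
  if (any(object@ehh < 0 | object@ehh > 1))
    msgs <- c(msgs, "'ehh' values must lie in [0, 1]")
  at0 <- object@ehh[object@distance == 0]
  if (length(at0) != 1L || abs(at0 - 1) > 1e-12)
    msgs <- c(msgs, "the curve must contain exactly one anchor point (0, 1)")
  for (sgn in c(-1, 1)) {
    side <- object@distance * sgn > 0
    if (any(side)) {
      e <- object@ehh[side][order(abs(object@distance[side]))]
      if (any(diff(e) > 1e-12))
        msgs <- c(msgs, "EHH must be non-increasing with |distance| on each side")
    }
  }
  if (object@carrierCount < 2L)
    msgs <- c(msgs, "'carrierCount' must be at least 2")
  if (length(msgs)) msgs else TRUE
})

#' Integrated haplotype score at one core SNP
#'
#' iHH per allele is the trapezoidal integral of that allele's EHH decay
#' curve over physical distance (units bp x EHH), truncated on each side at
#' the first site where EHH falls below the truncation level. The
#' unstandardized score is ln(iHH_ancestral / iHH_derived): negative values
#' mean longer haplotype homozygosity around the derived allele.
#' Standardization (within derived-frequency bins of a reference score set)
#' fills `ihsStandardized` and `pValue`; both are NA until then.
#'
#' @slot coreSite integer, core SNP column index.
#' @slot ihhAncestral,ihhDerived numeric, integrated EHH per allele (bp).
#' @slot ihsUnstandardized numeric, ln(iHH_A / iHH_D).
#' @slot ihsStandardized numeric, bin-standardized score (NA if not standardized).
#' @slot pValue numeric, two-sided Gaussian tail p for the standardized score.
#' @slot derivedFrequency numeric, sample frequency of the derived core allele.
#' @slot frequencyBin integer, index of the standardization bin (NA before).
#' @slot edgeTruncated logical length 2 (5', 3'): TRUE when integration ran
#'   into the panel edge before reaching the truncation level.
#'
#' @seealso [ihs()], [standardizeIhs()]
#' @export
setClass("IHSResult",
  representation(
    coreSite = "integer",
    ihhAncestral = "numeric",
    ihhDerived = "numeric",
    ihsUnstandardized = "numeric",
    ihsStandardized = "numeric",
    pValue = "numeric",
    derivedFrequency = "numeric",
    frequencyBin = "integer",
    edgeTruncated = "logical"
  )
)

setValidity("IHSResult", function(object) {
  msgs <- character()
  if (object@ihhAncestral < 0 || object@ihhDerived < 0)
    msgs <- c(msgs, "integrated EHH values must be non-negative")
  if (object@ihhAncestral > 0 && object@ihhDerived > 0) {
    expect <- log(object@ihhAncestral / object@ihhDerived)
    if (abs(expect - object@ihsUnstandardized) > 1e-8)
      msgs <- c(msgs, "'ihsUnstandardized' must equal ln(ihhAncestral/ihhDerived)")
  }
  if (!is.na(object@derivedFrequency) &&
      (object@derivedFrequency <= 0 || object@derivedFrequency >= 1))
    msgs <- c(msgs, "'derivedFrequency' must lie in (0, 1): the core must segregate")
  if (length(object@edgeTruncated) != 2L)
    msgs <- c(msgs, "'edgeTruncated' must have length 2 (5' and 3')")
  if (length(msgs)) msgs else TRUE
})

#' Closed-form expected age of a neutral derived allele
#'
#' Stores the frequency-based expectation E(t1) = [-2p/(1-p)] ln(p) in units
#' of 2N generations together with its conversion to generations and years.
#' A point estimate only: the estimator carries no uncertainty.
#'
#' @slot p numeric, derived-allele frequency used, in (0, 1).
#' @slot t2N numeric, expected age in units of 2N generations, in (0, 2).
#' @slot effectiveSize numeric, effective population size N.
#' @slot generationYears numeric, years per generation.
#' @slot generations numeric, t2N * 2N.
#' @slot years numeric, generations * generationYears.
#' @slot pointEstimateOnly logical, always TRUE (no interval is computed).
#'
#' @seealso [alleleAge()]
#' @export
setClass("AgeEstimate",
  representation(
    p = "numeric",
    t2N = "numeric",
    effectiveSize = "numeric",
    generationYears = "numeric",
    generations = "numeric",
    years = "numeric",
    pointEstimateOnly = "logical"
  )
)

setValidity("AgeEstimate", function(object) {
  msgs <- character()
  if (object@p <= 0 || object@p >= 1)
    msgs <- c(msgs, "'p' must lie strictly inside (0, 1)")
  else {
    expect <- (-2 * object@p / (1 - object@p)) * log(object@p)
    if (abs(expect - object@t2N) > 1e-10)
      msgs <- c(msgs, "'t2N' must equal [-2p/(1-p)] ln(p) at the stored p")
    if (object@t2N <= 0 || object@t2N >= 2)
      msgs <- c(msgs, "'t2N' must lie in (0, 2) for segregating p")
  }
  if (abs(object@generations - object@t2N * 2 * object@effectiveSize) > 1e-6)
    msgs <- c(msgs, "'generations' must equal t2N * 2N")
  if (abs(object@years - object@generations * object@generationYears) > 1e-6)
    msgs <- c(msgs, "'years' must equal generations * generationYears")
  if (length(msgs)) msgs else TRUE
})

#' Demographic model of an Asia/America continental split
#'
#' A fully resolved piecewise demography for the structured-coalescent
#' simulator. Five model families are supported:
#' \describe{
#'   \item{A}{split at T2 into two derived populations of equal size;}
#'   \item{B}{as A, but the American population is bottlenecked to a
#'     constant 0.15 of the Asian size;}
#'   \item{C}{American population founded at 0.06 of the Asian size at the
#'     split, growing exponentially to 0.15 at present;}
#'   \item{D}{B plus continental substructure (demes with migration)
#'     arising at T1 < T2;}
#'   \item{E}{C plus the same substructure.}
#' }
#' Times are generations before present; sizes are effective chromosome-pair
#' counts (N). The ancestral population has the Asian size.
#'
#' @slot modelId character, one of "A".."E".
#' @slot splitGenerations numeric, T2, the Asia/America split.
#' @slot structureGenerations numeric, T1, onset of substructure (NA for A-C).
#' @slot asiaDemes,americaDemes integer, deme counts under substructure.
#' @slot asiaN numeric, Asian effective size (constant).
#' @slot americaNPresent numeric, American effective size at present.
#' @slot americaNAtSplit numeric, American effective size at T2.
#' @slot growth logical, TRUE for exponential American growth (C, E).
#' @slot topology character, "island", "stepping_stone" or "none".
#' @slot migrationFraction numeric, per-generation migrant fraction per deme.
#' @slot circumarctic logical, dedicated Asian-American deme pair exchanging
#'   migrants while isolated from their own continents.
#' @slot circumarcticRate numeric, per-generation rate of that exchange.
#' @slot ancestralN numeric, ancestral population size (= asiaN).
#'
#' @seealso [buildModel()], [simulateSnps()], [runModel()]
#' @export
setClass("DemographicModel",
  representation(
    modelId = "character",
    splitGenerations = "numeric",
    structureGenerations = "numeric",
    asiaDemes = "integer",
    americaDemes = "integer",
    asiaN = "numeric",
    americaNPresent = "numeric",
    americaNAtSplit = "numeric",
    growth = "logical",
    topology = "character",
    migrationFraction = "numeric",
    circumarctic = "logical",
    circumarcticRate = "numeric",
    ancestralN = "numeric"
  )
)

setValidity("DemographicModel", function(object) {
  msgs <- character()
  if (!object@modelId %in% c("A", "B", "C", "D", "E"))
    msgs <- c(msgs, "'modelId' must be one of A, B, C, D, E")
  if (object@splitGenerations <= 0)
    msgs <- c(msgs, "'splitGenerations' (T2) must be positive")
  structured <- object@modelId %in% c("D", "E")
  if (structured) {
    if (is.na(object@structureGenerations))
      msgs <- c(msgs, "models D/E require 'structureGenerations' (T1)")
    else if (object@structureGenerations > object@splitGenerations)
      msgs <- c(msgs, "T1 (structure onset) must not exceed T2 (split)")
    if (!object@topology %in% c("island", "stepping_stone"))
      msgs <- c(msgs, "models D/E require topology 'island' or 'stepping_stone'")
  } else {
    if (!is.na(object@structureGenerations))
      msgs <- c(msgs, sprintf("model %s takes no T1 (substructure only in D/E)",
                              object@modelId))
    if (object@topology != "none")
      msgs <- c(msgs, sprintf("model %s takes no migration topology", object@modelId))
    if (object@circumarctic)
      msgs <- c(msgs, "circumarctic gene flow requires substructure (models D/E)")
  }
  if (object@growth) {
    if (object@americaNAtSplit >= object@americaNPresent)
      msgs <- c(msgs, "growth requires americaNAtSplit < americaNPresent")
  } else if (object@americaNAtSplit != object@americaNPresent) {
    msgs <- c(msgs, "without growth the American size must be constant")
  }
  if (any(c(object@asiaN, object@americaNPresent, object@americaNAtSplit,
            object@ancestralN) <= 0))
    msgs <- c(msgs, "all effective sizes must be positive")
  if (object@migrationFraction < 0 || object@migrationFraction > 1)
    msgs <- c(msgs, "'migrationFraction' must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' One model variant's simulated SNP replicates and exceedance statistic
#'
#' Per-replicate continental derived-allele frequencies under one resolved
#' demographic model, their (unsigned by default) differentials, and the
#' proportion of replicates whose differential is at least the threshold.
#'
#' @slot model the [DemographicModel-class] simulated.
#' @slot nSnps integer, number of replicate SNPs.
#' @slot asiaFrequency,americaFrequency numeric, pooled per-continent
#'   derived-allele frequency per replicate.
#' @slot differential numeric, per-replicate frequency differential.
#' @slot signed logical, whether `differential` kept the America - Asia sign.
#' @slot threshold numeric, exceedance threshold on the unsigned differential.
#' @slot exceedanceProportion numeric, fraction of replicates with unsigned
#'   differential >= threshold.
#' @slot seed integer, the seed the replicates were drawn under.
#'
#' @seealso [simulateSnps()], [runModel()]
#' @export
setClass("SimResult",
  representation(
    model = "DemographicModel",
    nSnps = "integer",
    asiaFrequency = "numeric",
    americaFrequency = "numeric",
    differential = "numeric",
    signed = "logical",
    threshold = "numeric",
    exceedanceProportion = "numeric",
    seed = "integer"
  )
)

setValidity("SimResult", function(object) {
  msgs <- character()
  n <- object@nSnps
  if (length(object@asiaFrequency) != n || length(object@americaFrequency) != n ||
      length(object@differential) != n)
    msgs <- c(msgs, "frequency and differential vectors must have length nSnps")
  f <- c(object@asiaFrequency, object@americaFrequency)
  if (any(f < 0 | f > 1))
    msgs <- c(msgs, "frequencies must lie in [0, 1]")
  tot <- object@asiaFrequency + object@americaFrequency
  if (any(tot == 0) || any(object@asiaFrequency == 1 & object@americaFrequency == 1))
    msgs <- c(msgs, "every replicate must segregate in the combined sample")
  exc <- mean(abs(object@differential) >= object@threshold)
  if (abs(exc - object@exceedanceProportion) > 1e-12)
    msgs <- c(msgs, "'exceedanceProportion' must equal the recomputed exceedance")
  if (length(msgs)) msgs else TRUE
})

#' Distribution summary of allele-frequency differentials
#'
#' Five-number summary and threshold exceedance of a set of (unsigned)
#' allele-frequency differentials, e.g. one per SNP between two continental
#' groups. Quantiles use the linear-interpolation convention (type 7),
#' recorded in `quantileType`; exceedance counts values >= threshold.
#'
#' @slot values numeric, the differentials, each in [0, 1].
#' @slot minimum,q1,median,q3,maximum numeric, the five-number summary.
#' @slot threshold numeric, exceedance threshold.
#' @slot exceedanceFraction numeric, fraction of values >= threshold.
#' @slot quantileType integer, the stats::quantile() type used.
#'
#' @seealso [differentialDistribution()]
#' @export
setClass("DifferentialSummary",
  representation(
    values = "numeric",
    minimum = "numeric",
    q1 = "numeric",
    median = "numeric",
    q3 = "numeric",
    maximum = "numeric",
    threshold = "numeric",
    exceedanceFraction = "numeric",
    quantileType = "integer"
  )
)

setValidity("DifferentialSummary", function(object) {
  msgs <- character()
  if (length(object@values) == 0L)
    msgs <- c(msgs, "'values' must be non-empty")
  if (any(object@values < 0 | object@values > 1))
    msgs <- c(msgs, "'values' must lie in [0, 1]")
  q <- c(object@minimum, object@q1, object@median, object@q3, object@maximum)
  if (any(diff(q) < -1e-12))
    msgs <- c(msgs, "quantiles must be ordered min <= q1 <= median <= q3 <= max")
  exc <- mean(object@values >= object@threshold)
  if (abs(exc - object@exceedanceFraction) > 1e-12)
    msgs <- c(msgs, "'exceedanceFraction' must equal (# values >= threshold)/n")
  if (length(msgs)) msgs else TRUE
})
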