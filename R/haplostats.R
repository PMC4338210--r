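## Extended haplotype homozygosity statistics on phased panels.
##
## Homozygosity uses unbiased pair counting: for n carrier chromosomes
## partitioned into extended-haplotype groups of sizes n_h,
##   EHH = sum_h C(n_h, 2) / C(n, 2),
## i.e. the probability that two carriers drawn without replacement are
## identical over the whole span between core and target site.

.pairHomozygosity <- function(keys) {
  n <- length(keys)
  cnt <- tabulate(match(keys, unique(keys)))
  sum(choose(cnt, 2)) / choose(n, 2)
}

## group carriers (row indices) by their allele vector over columns spanCols
.spanKeys <- function(hap, rows, spanCols) {
  a <- hap@alleles[rows, spanCols, drop = FALSE]
  do.call(paste0, as.data.frame(a))
}

.carrierRows <- function(hap, coreSite, coreAllele) {
  which(hap@alleles[, coreSite] == coreAllele)
}

.checkCore <- function(hap, coreSite, coreAllele) {
  if (coreSite < 1L || coreSite > nSites(hap))
    stop("core site index out of range", call. = FALSE)
  if (!coreAllele %in% c(0L, 1L))
    stop("'coreAllele' must be 0 (ancestral) or 1 (derived)", call. = FALSE)
}

#' Extended haplotype homozygosity at one target site
#'
#' EHH of the chromosomes carrying `coreAllele` at `coreSite`, evaluated
#' over the span from the core to `targetSite` inclusive: the probability
#' that two randomly chosen carrier chromosomes are identical at every site
#' in between. Computed by exact pair counting
#' \eqn{\sum_h \binom{n_h}{2} / \binom{n}{2}} over extended-haplotype
#' groups.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param coreSite core SNP column index.
#' @param coreAllele 0 (ancestral) or 1 (derived).
#' @param targetSite target SNP column index (may equal `coreSite`, giving 1).
#' @return EHH value in [0, 1].
#' @examples
#' hap <- HaplotypeMatrix(rbind(c(1, 0), c(1, 0), c(1, 1), c(0, 1)),
#'                        positions = c(100, 200))
#' ehhAt(hap, coreSite = 1, coreAllele = 1, targetSite = 2)
#' @export
ehhAt <- function(hap, coreSite, coreAllele, targetSite) {
  .checkCore(hap, coreSite, coreAllele)
  if (targetSite < 1L || targetSite > nSites(hap))
    stop("target site index out of range", call. = FALSE)
  rows <- .carrierRows(hap, coreSite, coreAllele)
  if (length(rows) < 2L)
    stop(sprintf("EHH undefined: only %d chromosome(s) carry allele %d at site %d",
                 length(rows), coreAllele, coreSite), call. = FALSE)
  span <- seq(min(coreSite, targetSite), max(coreSite, targetSite))
  .pairHomozygosity(.spanKeys(hap, rows, span))
}

#' EHH decay curve around a core SNP
#'
#' [ehhAt()] evaluated at every flanking SNP on both sides of the core,
#' with signed distances (5' negative, 3' positive) and the (0, 1) anchor.
#' The curve is non-increasing in |distance| on each side by construction:
#' extending the span can only refine the haplotype grouping.
#'
#' @inheritParams ehhAt
#' @return an [EHHCurve-class] object.
#' @export
ehhCurve <- function(hap, coreSite, coreAllele) {
  .checkCore(hap, coreSite, coreAllele)
  rows <- .carrierRows(hap, coreSite, coreAllele)
  if (length(rows) < 2L)
    stop(sprintf("EHH undefined: only %d chromosome(s) carry allele %d at site %d",
                 length(rows), coreAllele, coreSite), call. = FALSE)
  # incremental outward walk: extending the span refines the haplotype
  # grouping, so each side costs O(sites x carriers) overall and the curve
  # is non-increasing by construction (agrees exactly with ehhAt per site)
  S <- nSites(hap)
  ehh <- numeric(S)
  ehh[coreSite] <- 1
  for (dir in c(1L, -1L)) {
    keys <- rep("", length(rows))
    s <- coreSite + dir
    while (s >= 1L && s <= S) {
      keys <- paste0(keys, hap@alleles[rows, s])
      ehh[s] <- .pairHomozygosity(keys)
      s <- s + dir
    }
  }
  new("EHHCurve",
      coreSite = as.integer(coreSite),
      coreAllele = as.integer(coreAllele),
      carrierCount = length(rows),
      distance = hap@positions - hap@positions[coreSite],
      ehh = ehh)
}

setMethod("show", "EHHCurve", function(object) {
  side5 <- sum(object@distance < 0)
  side3 <- sum(object@distance > 0)
  cat(sprintf("EHHCurve: core site %d, %s allele, %d carriers\n",
              object@coreSite,
              if (object@coreAllele == 1L) "derived" else "ancestral",
              object@carrierCount))
  cat(sprintf("  %d sites 5' / %d sites 3'; EHH at far flanks: %.3f / %.3f\n",
              side5, side3,
              if (side5) object@ehh[which.min(object@distance)] else NA,
              if (side3) object@ehh[which.max(object@distance)] else NA))
})

#' @rdname ehhCurve
#' @param x an `EHHCurve`.
#' @return `as.data.frame()` returns columns `distance_bp` and `ehh`,
#'   ordered by distance.
#' @param row.names,optional,... passed on conventions, ignored.
#' @export
as.data.frame.EHHCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  o <- order(x@distance)
  data.frame(distance_bp = x@distance[o], ehh = x@ehh[o])
}

#' Relative EHH at one target site
#'
#' Ratio of the EHH of the chromosomes carrying the tested core allele to
#' the EHH of all remaining chromosomes pooled (grouped by extended
#' haplotype over the same span). Values well above 1 at long range suggest
#' a sweep on the tested allele. The core is the single SNP's allele: all
#' non-carriers form the comparison class.
#'
#' @inheritParams ehhAt
#' @return non-negative ratio; `Inf` (with a warning) when the comparison
#'   class has EHH 0 at the target.
#' @export
rehhAt <- function(hap, coreSite, coreAllele, targetSite) {
  .checkCore(hap, coreSite, coreAllele)
  tested <- .carrierRows(hap, coreSite, coreAllele)
  others <- setdiff(seq_len(nChromosomes(hap)), tested)
  if (length(tested) < 2L || length(others) < 2L)
    stop("REHH needs at least 2 carriers and 2 non-carriers of the core allele",
         call. = FALSE)
  span <- seq(min(coreSite, targetSite), max(coreSite, targetSite))
  num <- .pairHomozygosity(.spanKeys(hap, tested, span))
  den <- .pairHomozygosity(.spanKeys(hap, others, span))
  if (den == 0) {
    warning("EHH of the comparison class is 0 at the target; REHH is infinite",
            call. = FALSE)
    return(Inf)
  }
  num / den
}

## trapezoidal integral of an EHH curve on one side of the core, truncated
## at the first site where EHH < truncation (that site's trapezoid is the
## last one included); returns the integral and whether the panel edge was
## hit before truncation.
.integrateSide <- function(distance, ehh, truncation) {
  o <- order(abs(distance))
  d <- abs(distance[o]); e <- ehh[o]
  area <- 0
  edge <- TRUE
  if (length(d) >= 2L) {
    for (i in 2:length(d)) {
      area <- area + (d[i] - d[i - 1]) * (e[i] + e[i - 1]) / 2
      if (e[i] < truncation) { edge <- FALSE; break }
    }
  }
  list(area = area, edge = edge)
}

## iHH for one allele from its full curve: sum of both sides
.ihhFromCurve <- function(curve, truncation) {
  left <- curve@distance <= 0
  right <- curve@distance >= 0
  l <- .integrateSide(curve@distance[left], curve@ehh[left], truncation)
  r <- .integrateSide(curve@distance[right], curve@ehh[right], truncation)
  list(ihh = l$area + r$area, edge = c(l$edge, r$edge))
}

#' Integrated haplotype score at a core SNP
#'
#' Computes the EHH decay curve for each core allele, integrates each over
#' physical distance with the trapezoid rule (truncating each side at the
#' first site where EHH drops below `truncation`; if that never happens the
#' integration runs to the panel edge and the result is flagged
#' edge-truncated), and returns
#' \eqn{\mathrm{iHS} = \ln(\mathrm{iHH}_A / \mathrm{iHH}_D)}.
#' Negative scores mean longer haplotype homozygosity around the derived
#' allele — the signature of a recent partial sweep on it.
#'
#' Raw iHS depends strongly on the derived-allele frequency, so scores are
#' compared after standardization within derived-frequency bins of a
#' reference (usually genome-wide or neutral-simulation) score set: pass
#' such a set as `standardization` or use [standardizeIhs()] on a list of
#' results. Significance is the two-sided Gaussian tail
#' `2 * pnorm(-|z|)` of the standardized score.
#'
#' @inheritParams ehhAt
#' @param truncation EHH level below which integration stops (default 0.05).
#' @param standardization optional list of [IHSResult-class] objects used as
#'   the standardization reference; when supplied the returned score is
#'   standardized against it.
#' @param bins number of equal-width derived-frequency bins on [0, 1] for
#'   standardization (default 20).
#' @return an [IHSResult-class] object.
#' @export
ihs <- function(hap, coreSite, truncation = 0.05, standardization = NULL,
                bins = 20L) {
  .checkCore(hap, coreSite, 1L)
  nDer <- sum(hap@alleles[, coreSite] == 1L)
  nTot <- nChromosomes(hap)
  if (nDer < 2L || nTot - nDer < 2L)
    stop(sprintf("iHS needs >= 2 carriers of each allele at the core (derived: %d, ancestral: %d)",
                 nDer, nTot - nDer), call. = FALSE)
  curveA <- ehhCurve(hap, coreSite, 0L)
  curveD <- ehhCurve(hap, coreSite, 1L)
  a <- .ihhFromCurve(curveA, truncation)
  d <- .ihhFromCurve(curveD, truncation)
  if (a$ihh == 0 || d$ihh == 0)
    stop("iHS undefined: integrated EHH is zero for one allele ",
         "(no flanking sites before truncation)", call. = FALSE)
  res <- new("IHSResult",
             coreSite = as.integer(coreSite),
             ihhAncestral = a$ihh, ihhDerived = d$ihh,
             ihsUnstandardized = log(a$ihh / d$ihh),
             ihsStandardized = NA_real_, pValue = NA_real_,
             derivedFrequency = nDer / nTot,
             frequencyBin = NA_integer_,
             edgeTruncated = a$edge | d$edge)
  if (!is.null(standardization))
    res <- standardizeIhs(list(res), bins = bins,
                          reference = standardization)[[1L]]
  res
}

#' iHS at every eligible core SNP of a panel
#'
#' Convenience scan: [ihs()] at each site where both alleles have at least
#' `minCarriers` carriers; sites where the score is undefined are skipped.
#'
#' @inheritParams ihs
#' @param minCarriers minimum carriers of each allele (default 2).
#' @return list of [IHSResult-class] (unstandardized).
#' @export
ihsScan <- function(hap, truncation = 0.05, minCarriers = 2L) {
  out <- list()
  for (s in seq_len(nSites(hap))) {
    nDer <- sum(hap@alleles[, s] == 1L)
    if (nDer < minCarriers || nChromosomes(hap) - nDer < minCarriers) next
    r <- tryCatch(ihs(hap, s, truncation = truncation), error = function(e) NULL)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  out
}

#' Standardize a set of iHS scores within derived-frequency bins
#'
#' Within each of `bins` equal-width derived-frequency bins on [0, 1],
#' subtracts the bin mean and divides by the bin standard deviation of the
#' unstandardized scores, then attaches the two-sided Gaussian p-value.
#' Standardizing a set against itself leaves each occupied bin with mean 0
#' and SD 1. A bin occupied by fewer than two scores has no usable SD and
#' is a configuration error naming the bin (use fewer bins or more scores).
#'
#' @param results list of [IHSResult-class] objects.
#' @param bins number of equal-width frequency bins (default 20).
#' @param reference list of [IHSResult-class] supplying the bin means and
#'   SDs; by default `results` standardizes against itself.
#' @return `results` with `ihsStandardized`, `pValue` and `frequencyBin`
#'   filled in.
#' @export
standardizeIhs <- function(results, bins = 20L, reference = results) {
  stopifnot(length(results) >= 1L, length(reference) >= 2L, bins >= 1L)
  .bin <- function(res) {
    f <- vapply(res, slot, numeric(1), "derivedFrequency")
    pmin(pmax(ceiling(f * bins), 1L), as.integer(bins))
  }
  refBin <- .bin(reference)
  refU <- vapply(reference, slot, numeric(1), "ihsUnstandardized")
  bin <- .bin(results)
  for (b in unique(bin)) {
    idx <- refBin == b
    if (sum(idx) < 2L)
      stop(sprintf("standardization bin %d (frequencies (%.3f, %.3f]) holds %d reference score(s); cannot estimate its spread",
                   b, (b - 1) / bins, b / bins, sum(idx)), call. = FALSE)
    if (stats::sd(refU[idx]) == 0)
      stop(sprintf("standardization bin %d has zero score variance", b),
           call. = FALSE)
  }
  mu <- tapply(refU, refBin, mean)
  sdv <- tapply(refU, refBin, stats::sd)
  u <- vapply(results, slot, numeric(1), "ihsUnstandardized")
  z <- (u - mu[as.character(bin)]) / sdv[as.character(bin)]
  for (i in seq_along(results)) {
    results[[i]]@ihsStandardized <- unname(z[i])
    results[[i]]@pValue <- 2 * pnorm(-abs(z[i]))
    results[[i]]@frequencyBin <- as.integer(bin[i])
  }
  results
}

setMethod("show", "IHSResult", function(object) {
  cat(sprintf("IHSResult: core site %d (derived frequency %.3f)\n",
              object@coreSite, object@derivedFrequency))
  cat(sprintf("  iHH ancestral %.1f bp | iHH derived %.1f bp | unstandardized iHS %.4f\n",
              object@ihhAncestral, object@ihhDerived,
              object@ihsUnstandardized))
  if (!is.na(object@ihsStandardized))
    cat(sprintf("  standardized iHS %.4f (bin %d), p = %.4g\n",
                object@ihsStandardized, object@frequencyBin, object@pValue))
  else
    cat("  not standardized (supply a reference score set)\n")
  if (any(object@edgeTruncated))
    cat("  note: integration hit the panel edge before the truncation level\n")
})

#' Tabulate iHS results
#'
#' @param results list of [IHSResult-class].
#' @param hap optional [HaplotypeMatrix-class] supplying site ids/positions.
#' @return data.frame, one row per result.
#' @export
ihsTable <- function(results, hap = NULL) {
  tab <- data.frame(
    core_site = vapply(results, slot, integer(1), "coreSite"),
    derived_frequency = vapply(results, slot, numeric(1), "derivedFrequency"),
    ihh_ancestral = vapply(results, slot, numeric(1), "ihhAncestral"),
    ihh_derived = vapply(results, slot, numeric(1), "ihhDerived"),
    ihs_unstandardized = vapply(results, slot, numeric(1), "ihsUnstandardized"),
    ihs_standardized = vapply(results, slot, numeric(1), "ihsStandardized"),
    p_value = vapply(results, slot, numeric(1), "pValue"),
    edge_truncated = vapply(results, function(r) any(r@edgeTruncated), logical(1))
  )
  if (!is.null(hap)) {
    tab$site_id <- hap@siteIds[tab$core_site]
    tab$position_bp <- hap@positions[tab$core_site]
  }
  tab
}
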