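## Per-population allele-frequency tables, regional pooling and
## frequency-differential summaries.
##
## A population table is a plain data.frame with columns
##   population   character, sample label
##   region       character, geographical group label
##   chromosomes  integer, counted chromosomes (2n)
##   derived_count integer, derived-allele chromosomes, 0 <= count <= 2n
## `validatePopulationTable()` enforces the invariants; all popdata
## functions validate on entry and return tables in the same shape.

#' Validate a per-population allele-frequency table
#'
#' Checks the column contract and per-row invariants
#' (`0 <= derived_count <= chromosomes`, `chromosomes >= 1`) and returns the
#' table with an added `frequency` column. Violations are reported with the
#' offending population named.
#'
#' @param samples data.frame with columns `population`, `region`,
#'   `chromosomes`, `derived_count`.
#' @return the validated data.frame with a `frequency` column.
#' @export
validatePopulationTable <- function(samples) {
  needed <- c("population", "region", "chromosomes", "derived_count")
  missing <- setdiff(needed, names(samples))
  if (length(missing))
    stop("population table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  samples$chromosomes <- as.integer(samples$chromosomes)
  samples$derived_count <- as.integer(samples$derived_count)
  bad <- which(is.na(samples$chromosomes) | samples$chromosomes < 1L)
  if (length(bad))
    stop("invalid chromosome count (2n) for population(s): ",
         paste(samples$population[bad], collapse = ", "), call. = FALSE)
  bad <- which(is.na(samples$derived_count) | samples$derived_count < 0L |
               samples$derived_count > samples$chromosomes)
  if (length(bad))
    stop("derived_count outside [0, chromosomes] for population(s): ",
         paste(samples$population[bad], collapse = ", "), call. = FALSE)
  samples$frequency <- samples$derived_count / samples$chromosomes
  rownames(samples) <- NULL
  samples
}

#' Read a per-population allele-frequency table from TSV
#'
#' Tab-separated with a header. The count dialect carries columns
#' `population region chromosomes derived_count`; the frequency dialect
#' replaces `derived_count` with `frequency`, converted to a count by
#' rounding `frequency * chromosomes` to the nearest integer (the count-based
#' data model is universal downstream). Rows violating the invariants are
#' rejected with the population named.
#'
#' @param path path to the TSV file.
#' @param dialect `"count"` or `"frequency"`.
#' @return validated population data.frame (see [validatePopulationTable()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("population\tregion\tchromosomes\tderived_count",
#'              "YRI\tAfrica\t226\t21"), tf)
#' readFrequencyTable(tf)
#' @export
readFrequencyTable <- function(path, dialect = c("count", "frequency")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  base <- c("population", "region", "chromosomes")
  value <- if (dialect == "count") "derived_count" else "frequency"
  missing <- setdiff(c(base, value), names(tab))
  if (length(missing))
    stop(sprintf("malformed frequency table '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  if (dialect == "frequency") {
    f <- as.numeric(tab$frequency)
    bad <- which(is.na(f) | f < 0 | f > 1)
    if (length(bad))
      stop("frequency outside [0, 1] for population(s): ",
           paste(tab$population[bad], collapse = ", "), call. = FALSE)
    tab$derived_count <- as.integer(round(f * as.numeric(tab$chromosomes)))
  }
  validatePopulationTable(tab[c(base, "derived_count")])
}

#' Filter populations by sample size and an exclusion list
#'
#' Drops populations with fewer than `minGenotypes` diploid genotyped
#' individuals (i.e. `chromosomes < 2 * minGenotypes`) and any population
#' named in `exclusions`. Order is preserved; each removal is reported via
#' `message()` with its reason.
#'
#' @param samples population data.frame.
#' @param minGenotypes minimum diploid genotypes to retain (default 4, i.e.
#'   at least 8 chromosomes).
#' @param exclusions character vector of population names to drop
#'   unconditionally (e.g. known recent admixture).
#' @return the filtered data.frame (possibly empty).
#' @export
filterPopulations <- function(samples, minGenotypes = 4L,
                              exclusions = character()) {
  stopifnot(minGenotypes >= 1L)
  samples <- validatePopulationTable(samples)
  small <- samples$chromosomes < 2L * minGenotypes
  excluded <- samples$population %in% exclusions
  for (i in which(small & !excluded))
    message(sprintf("removing '%s': %d genotypes < minimum %d",
                    samples$population[i], samples$chromosomes[i] %/% 2L,
                    minGenotypes))
  for (i in which(excluded))
    message(sprintf("removing '%s': on the exclusion list",
                    samples$population[i]))
  samples[!(small | excluded), , drop = FALSE]
}

#' Merge same-name populations within a region
#'
#' Population samples sharing both name and region (e.g. one ethnic group
#' sampled at two localities by the same study) are collapsed into a single
#' record with summed chromosomes and summed derived counts. Identical names
#' in *different* regions are left unmerged with a warning.
#'
#' @param samples population data.frame.
#' @return data.frame with merged records, first-occurrence order.
#' @export
mergeSameName <- function(samples) {
  samples <- validatePopulationTable(samples)
  crossRegion <- unique(samples$population[duplicated(samples$population) |
                                             duplicated(samples$population, fromLast = TRUE)])
  for (nm in crossRegion) {
    regs <- unique(samples$region[samples$population == nm])
    if (length(regs) > 1L)
      warning(sprintf("population '%s' appears in multiple regions (%s); not merged across regions",
                      nm, paste(regs, collapse = ", ")), call. = FALSE)
  }
  key <- paste(samples$population, samples$region, sep = "\r")
  first <- !duplicated(key)
  merged <- samples[first, c("population", "region"), drop = FALSE]
  merged$chromosomes <- as.integer(rowsum(samples$chromosomes, key,
                                          reorder = FALSE))
  merged$derived_count <- as.integer(rowsum(samples$derived_count, key,
                                            reorder = FALSE))
  validatePopulationTable(merged)
}

#' Pool populations into regional groups
#'
#' Chromosome-count-weighted pooling: per region, the pooled frequency is
#' the ratio of summed derived counts to summed chromosomes, which is
#' exactly the frequency computed from the raw counts of the pooled sample.
#'
#' @param samples population data.frame; every row must carry a region.
#' @return data.frame with one row per region (first-occurrence order) and
#'   columns `region`, `total_chromosomes`, `derived_count`,
#'   `pooled_frequency`, `member_count`.
#' @examples
#' tab <- data.frame(population = c("p1", "p2"), region = "R",
#'                   chromosomes = c(10L, 30L), derived_count = c(2L, 12L))
#' poolByRegion(tab)  # pooled 14/40 = 0.35
#' @export
poolByRegion <- function(samples) {
  samples <- validatePopulationTable(samples)
  if (nrow(samples) == 0L) stop("cannot pool an empty table", call. = FALSE)
  if (any(is.na(samples$region) | samples$region == ""))
    stop("every population needs a region label before pooling", call. = FALSE)
  region <- unique(samples$region)
  idx <- match(samples$region, region)
  data.frame(
    region = region,
    total_chromosomes = as.integer(rowsum(samples$chromosomes, idx, reorder = FALSE)),
    derived_count = as.integer(rowsum(samples$derived_count, idx, reorder = FALSE)),
    pooled_frequency = as.numeric(rowsum(samples$derived_count, idx, reorder = FALSE) /
                                    rowsum(samples$chromosomes, idx, reorder = FALSE)),
    member_count = as.integer(tabulate(idx)),
    stringsAsFactors = FALSE
  )
}

#' Allele-frequency differential between two groups
#'
#' The workhorse contrast statistic: `|f1 - f2|`, or the signed `f1 - f2`
#' when `signed = TRUE`.
#'
#' @param f1,f2 allele frequencies in [0, 1]; vectorized.
#' @param signed keep the sign of `f1 - f2`?
#' @return numeric differential(s); in [0, 1] when unsigned.
#' @examples
#' frequencyDifferential(0.764, 0.477)  # 0.287, rounding to 0.29
#' @export
frequencyDifferential <- function(f1, f2, signed = FALSE) {
  if (any(f1 < 0 | f1 > 1, na.rm = FALSE) || any(f2 < 0 | f2 > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  d <- f1 - f2
  if (signed) d else abs(d)
}

#' Summarize a distribution of allele-frequency differentials
#'
#' Computes the five-number summary (linear-interpolation quantiles,
#' `stats::quantile()` type 7) of unsigned differentials and the exceedance
#' fraction: the proportion of differentials at least as large as
#' `threshold` (comparison is `>=`).
#'
#' @param pairs either a numeric vector of unsigned differentials, or a
#'   two-column matrix / data.frame of frequency pairs from which unsigned
#'   differentials are taken.
#' @param threshold exceedance threshold (default 0.29, the continental
#'   contrast observed for the focal polymorphism).
#' @return a [DifferentialSummary-class] object.
#' @examples
#' differentialDistribution(c(0.1, 0.2, 0.3, 0.4), threshold = 0.29)
#' @export
differentialDistribution <- function(pairs, threshold = 0.29) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    if (ncol(pairs) != 2L)
      stop("'pairs' must have exactly two frequency columns", call. = FALSE)
    pairs <- as.matrix(pairs)
    values <- frequencyDifferential(as.numeric(pairs[, 1]),
                                    as.numeric(pairs[, 2]))
  } else {
    values <- abs(as.numeric(pairs))
  }
  if (length(values) == 0L)
    stop("cannot summarize an empty differential list", call. = FALSE)
  q <- unname(quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7L))
  new("DifferentialSummary",
      values = values,
      minimum = q[1], q1 = q[2], median = q[3], q3 = q[4], maximum = q[5],
      threshold = threshold,
      exceedanceFraction = mean(values >= threshold),
      quantileType = 7L)
}

#' @rdname differentialDistribution
#' @param x a `DifferentialSummary`.
#' @export
setGeneric("exceedanceFraction", function(x) standardGeneric("exceedanceFraction"))

#' @rdname differentialDistribution
#' @export
setMethod("exceedanceFraction", "DifferentialSummary", function(x)
  x@exceedanceFraction)

#' @rdname differentialDistribution
#' @export
setMethod("exceedanceFraction", "SimResult", function(x)
  x@exceedanceProportion)

setMethod("show", "DifferentialSummary", function(object) {
  cat(sprintf("DifferentialSummary over %d differentials\n",
              length(object@values)))
  cat(sprintf("  min %.3f | Q1 %.3f | median %.3f | Q3 %.3f | max %.3f\n",
              object@minimum, object@q1, object@median, object@q3,
              object@maximum))
  cat(sprintf("  exceedance: %.1f%% of values >= %.3f\n",
              100 * object@exceedanceFraction, object@threshold))
})

#' Write regional pools or a differential summary as annotated TSV
#'
#' Output carries a `# metadata` comment block (settings and, for
#' summaries, the threshold and quantile convention) followed by a
#' tab-separated table, so every file can be traced to the computation that
#' produced it.
#'
#' @param pools data.frame from [poolByRegion()].
#' @param path output file.
#' @param metadata named character vector of extra `key: value` lines.
#' @return `path`, invisibly.
#' @export
writeRegionalPools <- function(pools, path, metadata = character()) {
  writeAnnotatedTsv(pools, path,
                    c(type = "regional-pools", pooling = "chromosome-count-weighted",
                      metadata))
}

#' @rdname writeRegionalPools
#' @param summary a [DifferentialSummary-class] object.
#' @export
writeDifferentialSummary <- function(summary, path, metadata = character()) {
  stopifnot(is(summary, "DifferentialSummary"))
  tab <- data.frame(
    statistic = c("minimum", "q1", "median", "q3", "maximum",
                  "exceedance_fraction"),
    value = formatC(c(summary@minimum, summary@q1, summary@median, summary@q3,
                      summary@maximum, summary@exceedanceFraction),
                    format = "g", digits = 15)
  )
  writeAnnotatedTsv(tab, path,
                    c(type = "differential-summary",
                      threshold = formatC(summary@threshold, format = "g"),
                      quantile_convention = sprintf("linear interpolation (type %d)",
                                                    summary@quantileType),
                      n_values = as.character(length(summary@values)),
                      metadata))
}
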