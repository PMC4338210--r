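#' Construct a phased haplotype panel
#'
#' Validating constructor for [HaplotypeMatrix-class]. Alleles must already
#' be polarized: 0 is the ancestral state, 1 the derived state.
#'
#' @param alleles chromosomes x sites matrix of 0/1.
#' @param positions physical positions in bp, strictly increasing, one per
#'   site (1-based physical coordinates).
#' @param siteIds optional site labels; defaults to `site1..siteS`.
#' @param samplePopulations optional per-chromosome population labels;
#'   defaults to `"pop1"` for all chromosomes.
#'
#' @return a [HaplotypeMatrix-class] object.
#' @examples
#' hap <- HaplotypeMatrix(rbind(c(0, 1, 0), c(0, 1, 1), c(1, 0, 0)),
#'                        positions = c(100, 200, 350))
#' nChromosomes(hap)
#' @export
HaplotypeMatrix <- function(alleles, positions,
                            siteIds = paste0("site", seq_len(ncol(alleles))),
                            samplePopulations = rep("pop1", nrow(alleles))) {
  storage.mode(alleles) <- "integer"
  new("HaplotypeMatrix",
      alleles = alleles,
      positions = as.numeric(positions),
      siteIds = as.character(siteIds),
      samplePopulations = as.character(samplePopulations))
}

#' @rdname HaplotypeMatrix
#' @param object,x a `HaplotypeMatrix`.
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("alleles", "HaplotypeMatrix", function(x) x@alleles)

#' @rdname HaplotypeMatrix
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("positions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname HaplotypeMatrix
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("siteIds", "HaplotypeMatrix", function(x) x@siteIds)

#' @rdname HaplotypeMatrix
#' @export
setGeneric("samplePopulations", function(x) standardGeneric("samplePopulations"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("samplePopulations", "HaplotypeMatrix", function(x) x@samplePopulations)

#' @rdname HaplotypeMatrix
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("nChromosomes", "HaplotypeMatrix", function(x) nrow(x@alleles))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) ncol(x@alleles))

#' @rdname HaplotypeMatrix
#' @param site site index.
#' @export
setGeneric("derivedFrequency", function(x, site) standardGeneric("derivedFrequency"))

#' @rdname HaplotypeMatrix
#' @export
setMethod("derivedFrequency", "HaplotypeMatrix", function(x, site) {
  mean(x@alleles[, site])
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d chromosomes x %d sites\n",
              nrow(object@alleles), ncol(object@alleles)))
  cat(sprintf("  span: %s-%s bp (%.0f kb)\n",
              format(min(object@positions), big.mark = ","),
              format(max(object@positions), big.mark = ","),
              diff(range(object@positions)) / 1e3))
  pops <- table(object@samplePopulations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
})

#' Subset a haplotype panel
#'
#' @param x a [HaplotypeMatrix-class].
#' @param i chromosome (row) indices.
#' @param j site (column) indices; must keep positions strictly increasing.
#' @param ... ignored.
#' @param drop ignored; the result is always a `HaplotypeMatrix`.
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@alleles))
  if (missing(j)) j <- seq_len(ncol(x@alleles))
  HaplotypeMatrix(x@alleles[i, j, drop = FALSE],
                  positions = x@positions[j],
                  siteIds = x@siteIds[j],
                  samplePopulations = x@samplePopulations[i])
})
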