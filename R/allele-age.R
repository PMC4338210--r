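#' Expected age of a neutral derived allele from its frequency
#'
#' For a segregating neutral allele currently at frequency `p`, the expected
#' age (time since the mutation arose) is
#' \deqn{E(t_1) = \frac{-2p}{1-p}\,\ln p}
#' in units of 2N generations. This is the classical frequency-based
#' moment estimator for a neutral allele in a constant-size population; it
#' assumes no selection on the locus and no population structure. The value
#' is converted to generations (`t2N * 2N`) and calendar years.
#'
#' `t2N` is strictly increasing in `p` on (0, 1): a common derived allele is
#' in expectation older than a rare one. Its limits are 0 as `p -> 0` and 2
#' (i.e. 4N generations) as `p -> 1`.
#'
#' This is a point estimate only; no uncertainty is propagated.
#'
#' @param p derived-allele frequency, strictly inside (0, 1). The allele
#'   must segregate: the formula has no meaning for fixed or absent alleles.
#' @param N effective population size (default 6000, a conservative
#'   long-term human estimate predating recent growth).
#' @param generationYears years per generation (default 25).
#' @return an [AgeEstimate-class] object.
#' @examples
#' alleleAge(0.5)                # t2N = 2 ln 2, ~16,636 generations
#' alleleAge(0.093)              # pooled African frequency of a stop-gain allele
#' @export
alleleAge <- function(p, N = 6000, generationYears = 25) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single frequency strictly inside (0, 1): ",
         "the estimator applies to a segregating allele only", call. = FALSE)
  stopifnot(N > 0, generationYears > 0)
  t2N <- (-2 * p / (1 - p)) * log(p)
  generations <- t2N * 2 * N
  new("AgeEstimate",
      p = p, t2N = t2N,
      effectiveSize = as.numeric(N),
      generationYears = as.numeric(generationYears),
      generations = generations,
      years = generations * generationYears,
      pointEstimateOnly = TRUE)
}

setMethod("show", "AgeEstimate", function(object) {
  cat("Neutral derived-allele age estimate (point estimate only)\n")
  cat(sprintf("  p (derived frequency) : %.4g\n", object@p))
  cat(sprintf("  E(t1) in 2N units     : %.4f\n", object@t2N))
  cat(sprintf("  N = %s, %g years/generation\n",
              format(object@effectiveSize, big.mark = ","),
              object@generationYears))
  cat(sprintf("  age: %s generations  ~  %s years\n",
              format(round(object@generations), big.mark = ","),
              format(round(object@years), big.mark = ",")))
})
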