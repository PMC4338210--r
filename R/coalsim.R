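## Structured-coalescent simulation of the five Asia/America demographic
## models and the allele-frequency-differential exceedance statistic.

.SPLIT_TIMES <- c(1001, 740, 500)      # T2 choices, generations
.STRUCTURE_TIMES <- c(295, 195, 75)    # T1 choices, generations (D/E)

#' Build a resolved demographic model
#'
#' Resolves one of the five model families (see
#' [DemographicModel-class]) into a fully parameterized demography.
#' Size conventions: the Asian population is constant at `asiaN` (9000 by
#' default) in every model and equals the ancestral size; model A gives
#' America that same size; models B/D bottleneck America to a constant
#' `0.15 * asiaN`; models C/E found America at `0.06 * asiaN` and grow it
#' exponentially to `0.15 * asiaN` at present, with rate
#' `alpha = ln(present/founding) / T2`. Substructure (D/E) splits each
#' continental size equally across its demes.
#'
#' @param modelId one of `"A".."E"`.
#' @param splitGenerations T2, the Asia/America split in generations before
#'   present (the study grid is 1001, 740, 500).
#' @param structureGenerations T1, onset of continental substructure
#'   (required for D/E; grid 295, 195, 75; must not exceed T2).
#' @param topology `"island"` or `"stepping_stone"` (required for D/E).
#' @param circumarctic add a dedicated Asian-American deme pair exchanging
#'   migrants at `circumarcticRate` while isolated from their own
#'   continents (D/E only).
#' @param asiaDemes,americaDemes deme counts under substructure
#'   (defaults 25 and 18).
#' @param asiaN Asian effective size (default 9000).
#' @param migrationFraction per-generation migrant fraction of each deme
#'   (default 0.05).
#' @param circumarcticRate per-generation circumarctic exchange rate
#'   (default 0.0022).
#' @return a validated [DemographicModel-class].
#' @examples
#' buildModel("B", 740)                        # America constant at 1350
#' buildModel("C", 500)                        # 540 growing to 1350
#' buildModel("D", 1001, 295, "island", circumarctic = TRUE)
#' @export
buildModel <- function(modelId, splitGenerations,
                       structureGenerations = NULL, topology = NULL,
                       circumarctic = FALSE,
                       asiaDemes = 25L, americaDemes = 18L,
                       asiaN = 9000, migrationFraction = 0.05,
                       circumarcticRate = 0.0022) {
  modelId <- match.arg(modelId, c("A", "B", "C", "D", "E"))
  structured <- modelId %in% c("D", "E")
  if (structured && (is.null(structureGenerations) || is.null(topology)))
    stop(sprintf("model %s requires 'structureGenerations' (T1) and a migration topology",
                 modelId), call. = FALSE)
  if (!structured && (!is.null(structureGenerations) || !is.null(topology) ||
                      circumarctic))
    stop(sprintf("model %s has no substructure: T1, topology and circumarctic flow do not apply",
                 modelId), call. = FALSE)
  growth <- modelId %in% c("C", "E")
  americaNPresent <- switch(modelId, A = asiaN, 0.15 * asiaN)
  americaNAtSplit <- if (growth) 0.06 * asiaN else americaNPresent
  new("DemographicModel",
      modelId = modelId,
      splitGenerations = as.numeric(splitGenerations),
      structureGenerations = if (structured) as.numeric(structureGenerations) else NA_real_,
      asiaDemes = as.integer(asiaDemes),
      americaDemes = as.integer(americaDemes),
      asiaN = as.numeric(asiaN),
      americaNPresent = americaNPresent,
      americaNAtSplit = americaNAtSplit,
      growth = growth,
      topology = if (structured) match.arg(topology, c("island", "stepping_stone")) else "none",
      migrationFraction = migrationFraction,
      circumarctic = isTRUE(circumarctic),
      circumarcticRate = circumarcticRate,
      ancestralN = as.numeric(asiaN))
}

#' @rdname buildModel
#' @param object,x a `DemographicModel`.
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname buildModel
#' @details `growthRate()` returns the exponential growth rate
#'   `ln(americaNPresent / americaNAtSplit) / splitGenerations` (0 without
#'   growth).
#' @export
setMethod("growthRate", "DemographicModel", function(x) {
  if (!x@growth) return(0)
  log(x@americaNPresent / x@americaNAtSplit) / x@splitGenerations
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel %s: split T2 = %g generations\n",
              object@modelId, object@splitGenerations))
  cat(sprintf("  Asia N = %g constant; America N = %g at split -> %g at present%s\n",
              object@asiaN, object@americaNAtSplit, object@americaNPresent,
              if (object@growth)
                sprintf(" (exponential, alpha = %.5f/generation)", growthRate(object))
              else ""))
  if (!is.na(object@structureGenerations))
    cat(sprintf("  substructure from T1 = %g: %d + %d demes, %s migration %.3g%s\n",
                object@structureGenerations, object@asiaDemes,
                object@americaDemes, object@topology,
                object@migrationFraction,
                if (object@circumarctic)
                  sprintf(", circumarctic pair at %.4g", object@circumarcticRate)
                else ""))
  else
    cat("  panmictic continents (no substructure)\n")
})

#' Sampling configuration for the coalescent simulator
#'
#' How many chromosomes are sampled per deme on each continent. The default
#' of 8 chromosomes (4 diploid genotypes) per deme mirrors the minimum
#' sample size used for including an empirical population, giving 200 Asian
#' and 144 American chromosomes with the default deme counts.
#'
#' @param chromosomesPerAsianDeme,chromosomesPerAmericanDeme chromosomes
#'   sampled per deme.
#' @return a list with class `"sampleConfig"`.
#' @export
sampleConfig <- function(chromosomesPerAsianDeme = 8L,
                         chromosomesPerAmericanDeme = 8L) {
  stopifnot(chromosomesPerAsianDeme >= 1L, chromosomesPerAmericanDeme >= 1L)
  structure(list(asia = as.integer(chromosomesPerAsianDeme),
                 america = as.integer(chromosomesPerAmericanDeme)),
            class = "sampleConfig")
}

.simArgs <- function(model, sample, minPerContinent = 2L) {
  sAsia <- rep(sample$asia, model@asiaDemes)
  sAmer <- rep(sample$america, model@americaDemes)
  if (sum(sAsia) < minPerContinent || sum(sAmer) < minPerContinent)
    stop("need at least ", minPerContinent,
         " sampled chromosomes per continent", call. = FALSE)
  list(samplesAsia = sAsia, samplesAmerica = sAmer,
       T1 = if (is.na(model@structureGenerations)) 0 else model@structureGenerations,
       T2 = model@splitGenerations,
       asiaN = model@asiaN, amerNPresent = model@americaNPresent,
       alpha = growthRate(model), ancestralN = model@ancestralN,
       topology = match(model@topology, c("none", "island", "stepping_stone")) - 1L,
       circumarctic = model@circumarctic,
       migFrac = model@migrationFraction, circRate = model@circumarcticRate)
}

#' Simulate single-SNP replicates under a demographic model
#'
#' Runs the structured coalescent backward from the sampled chromosomes:
#' within-deme pairwise coalescence at rate `choose(k,2) / (2 N_deme(t))`
#' per generation; backward migration per the model topology; at T1 the
#' demes of each continent merge into one panmictic population; at T2 the
#' continents merge into the ancestral population. After the genealogy
#' coalesces, exactly one mutation is placed uniformly at random on the
#' total branch length (single-segregating-site convention), so every
#' replicate SNP segregates in the combined sample. Waiting times are exact
#' exponentials, with closed-form time rescaling through the American
#' growth epoch.
#'
#' @param model a [DemographicModel-class] from [buildModel()].
#' @param sample a [sampleConfig()].
#' @param nSnps number of replicate SNPs.
#' @param seed integer seed (applied via `set.seed()`; all randomness in
#'   the simulator flows through R's RNG). `NULL` continues the current
#'   RNG stream.
#' @param threshold exceedance threshold on the unsigned differential
#'   (default 0.29).
#' @param signed keep the America - Asia sign in the stored differentials?
#'   (Exceedance always uses the unsigned value.)
#' @return a [SimResult-class] object.
#' @examples
#' r <- simulateSnps(buildModel("A", 500), sampleConfig(), nSnps = 50, seed = 1)
#' exceedanceFraction(r)
#' @export
simulateSnps <- function(model, sample = sampleConfig(), nSnps = 1000L,
                         seed = NULL, threshold = 0.29, signed = FALSE) {
  stopifnot(is(model, "DemographicModel"), nSnps >= 1L)
  validObject(model)
  if (!is.null(seed)) set.seed(seed)
  a <- .simArgs(model, sample)
  counts <- cpp_simulate_snps(as.integer(nSnps),
                              a$samplesAsia, a$samplesAmerica,
                              a$T1, a$T2, a$asiaN, a$amerNPresent,
                              a$alpha, a$ancestralN, a$topology,
                              a$circumarctic, a$migFrac, a$circRate)
  fAsia <- counts[, 1] / sum(a$samplesAsia)
  fAmer <- counts[, 2] / sum(a$samplesAmerica)
  diffs <- frequencyDifferential(fAmer, fAsia, signed = signed)
  new("SimResult",
      model = model, nSnps = as.integer(nSnps),
      asiaFrequency = fAsia, americaFrequency = fAmer,
      differential = diffs, signed = isTRUE(signed),
      threshold = threshold,
      exceedanceProportion = mean(abs(diffs) >= threshold),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: model %s, T2 = %g, %d SNPs (seed %s)\n",
              object@model@modelId, object@model@splitGenerations,
              object@nSnps,
              if (is.na(object@seed)) "unset" else object@seed))
  cat(sprintf("  %.1f%% of SNPs with |differential| >= %.2f\n",
              100 * object@exceedanceProportion, object@threshold))
})

#' All configured variants of one model family
#'
#' The study grid for a model id: every split time (1001, 740, 500
#' generations); for D/E additionally every substructure onset (295, 195,
#' 75), both migration topologies, and circumarctic flow off/on — 3
#' variants for A/B/C, 36 for D/E, all weighted equally by [runModel()].
#'
#' @inheritParams buildModel
#' @param splitTimes,structureTimes grids to span (defaults are the study
#'   grids).
#' @param ... further arguments passed to [buildModel()] (deme counts,
#'   sizes, migration rates).
#' @return list of [DemographicModel-class].
#' @export
modelEnsemble <- function(modelId, splitTimes = .SPLIT_TIMES,
                          structureTimes = .STRUCTURE_TIMES, ...) {
  modelId <- match.arg(modelId, c("A", "B", "C", "D", "E"))
  out <- list()
  if (modelId %in% c("A", "B", "C")) {
    for (t2 in splitTimes)
      out[[length(out) + 1L]] <- buildModel(modelId, t2, ...)
  } else {
    for (t2 in splitTimes)
      for (t1 in structureTimes)
        for (topo in c("island", "stepping_stone"))
          for (circ in c(FALSE, TRUE))
            out[[length(out) + 1L]] <-
              buildModel(modelId, t2, t1, topo, circumarctic = circ, ...)
  }
  out
}

#' Run model ensembles and average their exceedance
#'
#' Simulates `nSnps` replicate SNPs for every model variant in `models`
#' and averages the exceedance proportion per model id with equal weight
#' across that id's variants. Per-variant seeds are derived
#' deterministically from `seed` and reported in the per-variant table.
#'
#' @param models a list of [DemographicModel-class] (e.g. from
#'   [modelEnsemble()]), or a single model.
#' @param sample a [sampleConfig()].
#' @param nSnps replicate SNPs per variant (default 1000).
#' @param threshold exceedance threshold (default 0.29).
#' @param seed integer master seed; the i-th variant runs under the
#'   derived seed `(seed * 1000 + i) mod (2^31 - 1)`.
#' @return list with `results` (per-variant [SimResult-class]), `variants`
#'   (per-variant summary data.frame incl. seeds) and `exceedance`
#'   (named numeric, equal-weight mean exceedance proportion per model id).
#' @export
runModel <- function(models, sample = sampleConfig(), nSnps = 1000L,
                     threshold = 0.29, seed = 1L) {
  if (is(models, "DemographicModel")) models <- list(models)
  stopifnot(length(models) >= 1L, all(vapply(models, is, logical(1),
                                             "DemographicModel")))
  results <- vector("list", length(models))
  for (i in seq_along(models)) {
    vseed <- as.integer((as.double(seed) * 1000 + i) %% 2147483647)
    results[[i]] <- simulateSnps(models[[i]], sample = sample, nSnps = nSnps,
                                 seed = vseed, threshold = threshold)
  }
  variants <- data.frame(
    model = vapply(models, function(m) m@modelId, character(1)),
    split_generations = vapply(models, function(m) m@splitGenerations, numeric(1)),
    structure_generations = vapply(models, function(m) m@structureGenerations, numeric(1)),
    topology = vapply(models, function(m) m@topology, character(1)),
    circumarctic = vapply(models, function(m) m@circumarctic, logical(1)),
    seed = vapply(results, function(r) r@seed, integer(1)),
    exceedance = vapply(results, function(r) r@exceedanceProportion, numeric(1))
  )
  exceedance <- tapply(variants$exceedance, variants$model, mean)
  list(results = results, variants = variants,
       exceedance = setNames(as.numeric(exceedance), names(exceedance)))
}

#' Mean pairwise coalescence time under a model
#'
#' Monte-Carlo mean time to the most recent common ancestor of the sampled
#' chromosomes, used for analytic cross-checks (e.g. E[TMRCA] = 2N
#' generations for two chromosomes in one constant-size population).
#'
#' @inheritParams simulateSnps
#' @param nReps replicates.
#' @return numeric vector of per-replicate TMRCA in generations.
#' @export
simulateTmrca <- function(model, sample = sampleConfig(), nReps = 1000L,
                          seed = NULL) {
  stopifnot(is(model, "DemographicModel"))
  if (!is.null(seed)) set.seed(seed)
  a <- .simArgs(model, sample, minPerContinent = 1L)
  cpp_tmrca(as.integer(nReps), a$samplesAsia, a$samplesAmerica,
            a$T1, a$T2, a$asiaN, a$amerNPresent, a$alpha, a$ancestralN,
            a$topology, a$circumarctic, a$migFrac, a$circRate)
}

#' Write per-replicate simulation output as annotated TSV
#'
#' One row per replicate SNP (`replicate asia_freq america_freq
#' differential`) preceded by a metadata block carrying the full resolved
#' model parameters and seed, so the file reproduces itself.
#'
#' @param result a [SimResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimResult <- function(result, path) {
  stopifnot(is(result, "SimResult"))
  m <- result@model
  meta <- c(type = "coalescent-replicates",
            model = m@modelId,
            split_generations = formatC(m@splitGenerations, format = "g"),
            structure_generations = formatC(m@structureGenerations, format = "g"),
            topology = m@topology,
            circumarctic = as.character(m@circumarctic),
            migration_fraction = formatC(m@migrationFraction, format = "g"),
            circumarctic_rate = formatC(m@circumarcticRate, format = "g"),
            asia_N = formatC(m@asiaN, format = "g"),
            america_N_present = formatC(m@americaNPresent, format = "g"),
            america_N_at_split = formatC(m@americaNAtSplit, format = "g"),
            ancestral_N = formatC(m@ancestralN, format = "g"),
            threshold = formatC(result@threshold, format = "g"),
            signed = as.character(result@signed),
            seed = as.character(result@seed),
            exceedance_proportion = formatC(result@exceedanceProportion,
                                            format = "g", digits = 15))
  tab <- data.frame(replicate = seq_len(result@nSnps),
                    asia_freq = result@asiaFrequency,
                    america_freq = result@americaFrequency,
                    differential = result@differential)
  writeAnnotatedTsv(tab, path, meta)
}
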