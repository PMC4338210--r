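## Config-driven end-to-end smoke pipeline: synthetic panel -> haplotype
## selection statistics -> synthetic frequency table -> regional pooling
## and differentials -> a small coalescent run. Deterministic given the
## configured seed; every output carries its parameters.

.PIPELINE_KEYS <- c("seed", "panel_population_size", "panel_n_sites",
                    "panel_span_bp", "panel_selection", "panel_target_frequency",
                    "panel_recombination_per_bp", "panel_sample_chromosomes",
                    "table_populations_per_region", "table_chromosomes_min",
                    "table_chromosomes_max", "sim_model", "sim_split_generations",
                    "sim_n_snps", "threshold")

#' Run the demonstration pipeline from a plain-text config
#'
#' Reads a `key: value` config (unknown keys rejected; all keys optional
#' except `seed`), then (1) simulates a sweep haplotype panel and writes it
#' in the haplotype dialect plus its EHH curves and iHS table, (2)
#' simulates a regional frequency table, pools it and summarizes the
#' pooled-frequency differentials, and (3) runs a small coalescent batch
#' under the configured model, writing per-replicate output. All outputs
#' are annotated TSVs under `outDir`; re-running with the same config is
#' byte-identical.
#'
#' @param configPath plain-text config file (see `.PIPELINE_KEYS` in the
#'   source for the accepted keys).
#' @param outDir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
runPipeline <- function(configPath, outDir) {
  cfg <- readRunConfig(configPath, allowed = .PIPELINE_KEYS)
  get <- function(key, default) {
    if (key %in% names(cfg)) cfg[[key]] else default
  }
  if (!"seed" %in% names(cfg))
    stop("the pipeline config must set 'seed'", call. = FALSE)
  seed <- as.integer(cfg[["seed"]])
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c()

  # 1. synthetic sweep panel and its selection statistics
  scen <- sweepScenario(
    populationSize = as.integer(get("panel_population_size", 150L)),
    nSites = as.integer(get("panel_n_sites", 21L)),
    spanBp = as.integer(get("panel_span_bp", 510000L)),
    selectionCoefficient = as.numeric(get("panel_selection", 0.08)),
    targetFrequency = as.numeric(get("panel_target_frequency", 0.6)),
    recombinationPerBp = as.numeric(get("panel_recombination_per_bp", 1e-8)),
    sampleChromosomes = as.integer(get("panel_sample_chromosomes", 80L)))
  hap <- simulatePanel(scen, seed = seed)
  files["panel"] <- file.path(outDir, "panel.haps")
  writeHaplotypePanel(hap, files["panel"])
  focal <- which(hap@siteIds == "focal")
  curves <- rbind(
    cbind(core_allele = 1L, as.data.frame(ehhCurve(hap, focal, 1L))),
    cbind(core_allele = 0L, as.data.frame(ehhCurve(hap, focal, 0L))))
  files["ehh"] <- file.path(outDir, "ehh_curves.tsv")
  writeAnnotatedTsv(curves, files["ehh"],
                    c(type = "ehh-curves", core_site = as.character(focal),
                      seed = as.character(seed)))
  scores <- ihsScan(hap)
  if (length(scores) >= 2L) {
    scores <- tryCatch(standardizeIhs(scores, bins = 4L), error = function(e) scores)
    files["ihs"] <- file.path(outDir, "ihs.tsv")
    writeAnnotatedTsv(ihsTable(scores, hap), files["ihs"],
                      c(type = "ihs-table", truncation = "0.05",
                        bins = "4", seed = as.character(seed)))
  }

  # 2. regional frequency table -> pooling -> differential summary
  regions <- data.frame(
    region = c("Africa", "Middle East", "Europe", "Central and South Asia",
               "East Asia", "Oceania", "Americas"),
    n_populations = as.integer(get("table_populations_per_region", 6L)),
    mean_frequency = c(0.093, 0.392, 0.443, 0.502, 0.477, 0.495, 0.764),
    dispersion = 0.02)
  tab <- simulateFrequencyTable(
    regions,
    chromosomesRange = c(as.integer(get("table_chromosomes_min", 6L)),
                         as.integer(get("table_chromosomes_max", 60L))),
    seed = seed + 1L)
  kept <- suppressMessages(filterPopulations(tab))
  pools <- poolByRegion(mergeSameName(kept))
  files["pools"] <- file.path(outDir, "regional_pools.tsv")
  writeRegionalPools(pools, files["pools"],
                     c(seed = as.character(seed + 1L), min_genotypes = "4"))
  pairs <- t(combn(pools$pooled_frequency, 2L))
  summary <- differentialDistribution(pairs,
                                      threshold = as.numeric(get("threshold", 0.29)))
  files["differentials"] <- file.path(outDir, "differential_summary.tsv")
  writeDifferentialSummary(summary, files["differentials"],
                           c(seed = as.character(seed + 1L)))

  # 3. a small coalescent batch
  model <- buildModel(get("sim_model", "B"),
                      as.numeric(get("sim_split_generations", 740)))
  sim <- simulateSnps(model, sampleConfig(),
                      nSnps = as.integer(get("sim_n_snps", 200L)),
                      seed = seed + 2L,
                      threshold = as.numeric(get("threshold", 0.29)))
  files["simulation"] <- file.path(outDir, "simulated_replicates.tsv")
  writeSimResult(sim, files["simulation"])

  invisible(files)
}
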