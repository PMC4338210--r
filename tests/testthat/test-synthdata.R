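test_that("neutral fixation probability of a new mutation is ~ 1/(2N)", {
  set.seed(41)
  n2 <- 40L
  fate <- wrightFisherFate(n2, s = 0, initCount = 1L, nReps = 10000L)
  pFix <- mean(fate == n2)
  expect_true(all(fate %in% c(0L, n2)))      # absorbed within the cap
  # binomial 99.9% band around 1/(2N) = 0.025
  se <- sqrt(0.025 * 0.975 / 10000)
  expect_lt(abs(pFix - 1 / n2), 3.3 * se)
})

test_that("selection shortens the time to reach a target frequency", {
  set.seed(42)
  lenSel <- replicate(25, length(wrightFisherTrajectory(200L, s = 0.1,
                                                        targetFrequency = 0.5)))
  lenNeu <- replicate(25, length(wrightFisherTrajectory(200L, s = 0,
                                                        targetFrequency = 0.5)))
  expect_lt(mean(lenSel), mean(lenNeu))
})

test_that("trajectory conditioning fails loudly when the cap is exhausted", {
  set.seed(43)
  expect_error(wrightFisherTrajectory(500L, s = 0, targetFrequency = 0.99,
                                      maxGenerations = 5L, maxTries = 3L),
               "3 attempts")
})

test_that("complete linkage makes the derived core haplotype fully homozygous", {
  scen <- sweepScenario(populationSize = 100L, nSites = 11L,
                        selectionCoefficient = 0.1, targetFrequency = 0.5,
                        recombinationPerBp = 0, sampleChromosomes = 60L)
  hap <- simulatePanel(scen, seed = 44)
  focal <- which(siteIds(hap) == "focal")
  cv <- ehhCurve(hap, focal, 1L)
  expect_equal(cv@ehh, rep(1, nSites(hap)))
})

test_that("simulated panels satisfy the haplotype-matrix contract", {
  scen <- sweepScenario(populationSize = 120L, nSites = 15L,
                        selectionCoefficient = 0.08, targetFrequency = 0.6,
                        sampleChromosomes = 50L)
  hap <- simulatePanel(scen, seed = 45)
  expect_s4_class(hap, "HaplotypeMatrix")
  expect_true(validObject(hap))
  expect_equal(nChromosomes(hap), 50L)
  expect_equal(nSites(hap), 15L)
  expect_true(all(diff(positions(hap)) > 0))
  focal <- which(siteIds(hap) == "focal")
  expect_length(focal, 1L)
  f <- derivedFrequency(hap, focal)
  expect_gt(f, 0); expect_lt(f, 1)
  # determinism under a fixed seed
  hap2 <- simulatePanel(scen, seed = 45)
  expect_identical(alleles(hap), alleles(hap2))
  expect_identical(positions(hap), positions(hap2))
})

test_that("sweep panels show slower derived-side EHH decay than neutral", {
  set.seed(46)
  slower <- 0L
  for (i in 1:8) {
    scen <- sweepScenario(populationSize = 150L, nSites = 21L,
                          selectionCoefficient = 0.1, targetFrequency = 0.6,
                          sampleChromosomes = 100L)
    hap <- simulatePanel(scen)
    focal <- which(siteIds(hap) == "focal")
    d <- ehhCurve(hap, focal, 1L)
    a <- ehhCurve(hap, focal, 0L)
    if (mean(d@ehh) > mean(a@ehh)) slower <- slower + 1L
  }
  expect_gte(slower, 6L)   # clear majority of replicates
})

test_that("synthetic frequency tables honour their regional parameters", {
  regions <- data.frame(
    region = c("Africa", "Middle East", "Europe", "Central and South Asia",
               "East Asia", "Oceania", "Americas"),
    n_populations = 8L,
    mean_frequency = c(0.093, 0.392, 0.443, 0.502, 0.477, 0.495, 0.764),
    dispersion = 0)
  tab <- simulateFrequencyTable(regions, chromosomesRange = c(40L, 60L),
                                seed = 47)
  expect_equal(nrow(tab), 56L)
  pools <- poolByRegion(tab)
  # dispersion 0: pooled estimates recover the regional means within
  # binomial error (total 2n ~ 400 per region -> se ~ 0.025; the bound is
  # 4 se, sized for the maximum over seven regions)
  expect_true(all(abs(pools$pooled_frequency - regions$mean_frequency) < 0.1))

  # determinism
  tab2 <- simulateFrequencyTable(regions, chromosomesRange = c(40L, 60L),
                                 seed = 47)
  expect_identical(tab, tab2)

  # round trip through the loader without warnings
  tf <- tempfile(fileext = ".tsv")
  writeAnnotatedTsv(tab[, c("population", "region", "chromosomes",
                            "derived_count")], tf)
  expect_no_warning(back <- readFrequencyTable(tf))
  expect_equal(back$derived_count, tab$derived_count)

  # sub-threshold populations appear when the range allows them
  small <- simulateFrequencyTable(regions[1:2, ],
                                  chromosomesRange = c(4L, 6L), seed = 48)
  expect_true(all(small$chromosomes < 8L))
  expect_equal(nrow(suppressMessages(filterPopulations(small))), 0L)
})
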