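test_that("model families resolve sizes, growth and guards correctly", {
  b <- buildModel("B", 740)
  expect_equal(b@americaNPresent, 1350)
  expect_equal(b@americaNAtSplit, 1350)
  expect_false(b@growth)
  expect_equal(growthRate(b), 0)

  c5 <- buildModel("C", 500)
  expect_equal(c5@americaNAtSplit, 540)
  expect_equal(c5@americaNPresent, 1350)
  expect_equal(growthRate(c5), log(1350 / 540) / 500)

  a <- buildModel("A", 1001)
  expect_equal(a@americaNPresent, a@asiaN)   # two equal derived populations
  expect_equal(a@ancestralN, a@asiaN)

  d <- buildModel("D", 1001, 295, "island", circumarctic = TRUE)
  expect_equal(d@structureGenerations, 295)
  expect_true(d@circumarctic)

  # ordering guard: structure cannot pre-date the split
  expect_error(buildModel("D", 500, 740, "island"), "T1")
  # but a zero-duration or full-length structured epoch is legal
  expect_s4_class(buildModel("D", 500, 0, "island"), "DemographicModel")
  expect_s4_class(buildModel("D", 500, 500, "island"), "DemographicModel")
  # unstructured models take no structure arguments
  expect_error(buildModel("B", 740, 295, "island"), "substructure")
  expect_error(buildModel("A", 740, topology = "island"), "substructure")
})

test_that("model ensembles span the study grid", {
  expect_length(modelEnsemble("A"), 3L)
  expect_length(modelEnsemble("C"), 3L)
  ens <- modelEnsemble("D")
  expect_length(ens, 36L)   # 3 splits x 3 onsets x 2 topologies x 2 circ
  key <- vapply(ens, function(m)
    paste(m@splitGenerations, m@structureGenerations, m@topology,
          m@circumarctic), character(1))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("pairwise coalescence times match Kingman expectations", {
  # one chromosome per continent under model A: the pair cannot coalesce
  # before the split, then waits Exp(1/(2N)) in the ancestral population,
  # so E[TMRCA] = T2 + 2N = 500 + 18000
  m <- buildModel("A", 500, asiaDemes = 1L, americaDemes = 1L)
  t2 <- simulateTmrca(m, sampleConfig(1L, 1L), nReps = 3000L, seed = 51)
  se <- 18000 / sqrt(3000)
  expect_lt(abs(mean(t2) - 18500), 4 * se)
  expect_true(all(t2 >= 500))

  # two chromosomes in one constant population: E[TMRCA] = 2N
  t1 <- haplodrift:::cpp_tmrca(3000L, 2L, integer(0), 0, 1e-9, 9000, 9000,
                               0, 9000, 0L, FALSE, 0, 0)
  expect_lt(abs(mean(t1) - 18000), 4 * se)
})

test_that("the single-mutation frequency spectrum matches the analytic form", {
  set.seed(52)
  n <- 10L
  s <- haplodrift:::cpp_simulate_snps(12000L, n, integer(0), 0, 1e-9,
                                      9000, 9000, 0, 9000, 0L, FALSE, 0, 0)
  counts <- s[, 1]
  expect_true(all(counts >= 1 & counts <= n - 1))   # always segregating
  # weighting replicates by total branch length recovers P(i) = (1/i)/H_{n-1}
  w <- s[, 3]
  pW <- vapply(1:(n - 1), function(i) sum(w[counts == i]) / sum(w), numeric(1))
  analytic <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  expect_lt(max(abs(pW - analytic)), 0.02)
  # the raw (per-tree uniform placement) singleton share agrees with an
  # independent plain-R coalescent under the identical convention
  oracle <- replicate(3000, rCoalDerivedCount(n, 9000))
  pSing <- mean(counts == 1)
  pSingOracle <- mean(oracle == 1)
  seDiff <- sqrt(pSing * (1 - pSing) / length(counts) +
                 pSingOracle * (1 - pSingOracle) / length(oracle))
  expect_lt(abs(pSing - pSingOracle), 4 * seDiff)
})

test_that("replicates are segregating, bounded and seed-reproducible", {
  m <- buildModel("D", 740, 195, "stepping_stone", circumarctic = TRUE)
  r <- simulateSnps(m, sampleConfig(), nSnps = 300L, seed = 53)
  expect_true(all(r@asiaFrequency >= 0 & r@asiaFrequency <= 1))
  expect_true(all(r@americaFrequency >= 0 & r@americaFrequency <= 1))
  tot <- r@asiaFrequency * 200 + r@americaFrequency * 144
  expect_true(all(tot >= 1 & tot <= 343))
  r2 <- simulateSnps(m, sampleConfig(), nSnps = 300L, seed = 53)
  expect_identical(r@differential, r2@differential)
  # degenerate thresholds
  expect_equal(simulateSnps(m, nSnps = 50L, seed = 54,
                            threshold = 0)@exceedanceProportion, 1)
  expect_equal(simulateSnps(m, nSnps = 50L, seed = 54,
                            threshold = 1.01)@exceedanceProportion, 0)
})

test_that("equal-size derived populations give a sign-symmetric differential", {
  # equal continental sample sizes make the two sampling roles exchangeable
  m <- buildModel("A", 740, asiaDemes = 18L)
  r <- simulateSnps(m, sampleConfig(), nSnps = 3000L, seed = 55, signed = TRUE)
  d <- r@differential[r@differential != 0]
  expect_gt(binom.test(sum(d > 0), length(d))$p.value, 0.01)
})

test_that("bottlenecks raise exceedance and growth-from-bottleneck leads", {
  excA <- mean(simulateSnps(buildModel("A", 740), nSnps = 3000L,
                            seed = 56)@exceedanceProportion)
  excB <- mean(simulateSnps(buildModel("B", 740), nSnps = 3000L,
                            seed = 57)@exceedanceProportion)
  excC <- mean(simulateSnps(buildModel("C", 740), nSnps = 3000L,
                            seed = 58)@exceedanceProportion)
  expect_lt(excA, excB)
  expect_lt(excA, excC)
  expect_equal(max(excA, excB, excC), excC)
})

test_that("circumarctic gene flow does not increase exceedance", {
  deltas <- c()
  for (t2 in c(1001, 740, 500)) for (t1 in c(295, 195, 75)) {
    off <- simulateSnps(buildModel("D", t2, t1, "island"),
                        nSnps = 400L, seed = 59)
    on <- simulateSnps(buildModel("D", t2, t1, "island", circumarctic = TRUE),
                       nSnps = 400L, seed = 59)
    deltas <- c(deltas, on@exceedanceProportion - off@exceedanceProportion)
  }
  # one-sided trend over paired seeded runs: no significant increase
  expect_gt(t.test(deltas, alternative = "greater")$p.value, 0.01)
})

test_that("structured models collapse to their parents when substructure
           has zero duration", {
  b <- simulateSnps(buildModel("B", 500), nSnps = 2000L, seed = 60)
  d0 <- simulateSnps(buildModel("D", 500, 0, "island",
                                migrationFraction = 0),
                     nSnps = 2000L, seed = 61)
  ks1 <- suppressWarnings(ks.test(b@differential, d0@differential))
  expect_gt(ks1$p.value, 0.01)

  c5 <- simulateSnps(buildModel("C", 500), nSnps = 2000L, seed = 62)
  e0 <- simulateSnps(buildModel("E", 500, 0, "island",
                                migrationFraction = 0),
                     nSnps = 2000L, seed = 63)
  ks2 <- suppressWarnings(ks.test(c5@differential, e0@differential))
  expect_gt(ks2$p.value, 0.01)
})

test_that("per-replicate output carries a reproducing metadata block", {
  m <- buildModel("C", 740)
  r <- simulateSnps(m, nSnps = 30L, seed = 64)
  tf <- tempfile(fileext = ".tsv")
  writeSimResult(r, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("# seed: 64", lines)))
  expect_true(any(grepl("# america_N_at_split: 540", lines)))
  tab <- read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), 30L)
  expect_equal(tab$differential,
               abs(tab$america_freq - tab$asia_freq), tolerance = 1e-12)
})
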