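test_that("frequency tables load in both dialects with row-level validation", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("population\tregion\tchromosomes\tderived_count",
               "YRI\tAfrica\t226\t21",
               "Han\tEast Asia\t90\t43"), tf)
  tab <- readFrequencyTable(tf)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$frequency[1], 21 / 226, tolerance = 1e-12)
  expect_equal(round(tab$frequency[1], 4), 0.0929)

  # frequency dialect: 0.25 at 2n = 8 converts to count 2
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("population\tregion\tchromosomes\tfrequency",
               "P1\tR\t8\t0.25"), tf2)
  expect_equal(readFrequencyTable(tf2, dialect = "frequency")$derived_count, 2L)

  # invariant violation names the offending row
  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("population\tregion\tchromosomes\tderived_count",
               "Bad\tR\t4\t5"), tf3)
  expect_error(readFrequencyTable(tf3), "Bad")

  tf4 <- tempfile(fileext = ".tsv")
  writeLines(c("population\tchromosomes\tderived_count", "P\t4\t2"), tf4)
  expect_error(readFrequencyTable(tf4), "missing column")
})

test_that("population filtering drops small samples and listed names", {
  tab <- data.frame(population = c("Small", "Edge", "Mozabite", "Big"),
                    region = "Africa",
                    chromosomes = c(6L, 8L, 60L, 100L),
                    derived_count = c(1L, 2L, 10L, 30L))
  kept <- suppressMessages(
    filterPopulations(tab, minGenotypes = 4L, exclusions = "Mozabite"))
  # 3 genotypes removed, 4 genotypes (the boundary) retained, exclusion
  # removed regardless of size, order preserved
  expect_identical(kept$population, c("Edge", "Big"))
  expect_message(filterPopulations(tab, exclusions = "Mozabite"),
                 "exclusion list")
  expect_message(filterPopulations(tab), "genotypes")
  # empty result is legal
  expect_equal(nrow(suppressMessages(filterPopulations(tab, minGenotypes = 100L))), 0L)
})

test_that("same-name merging sums counts within a region only", {
  tab <- data.frame(population = c("Maya", "Maya", "Pima"),
                    region = "Americas",
                    chromosomes = c(20L, 10L, 30L),
                    derived_count = c(15L, 8L, 20L))
  merged <- mergeSameName(tab)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$chromosomes[merged$population == "Maya"], 30L)
  expect_equal(merged$derived_count[merged$population == "Maya"], 23L)

  # all-unique input is returned unchanged
  uniq <- tab[c(1, 3), ]
  expect_equal(mergeSameName(uniq)$chromosomes, uniq$chromosomes)

  # same name across regions: kept apart, with a warning
  cross <- data.frame(population = "Maya",
                      region = c("Americas", "East Asia"),
                      chromosomes = c(20L, 10L),
                      derived_count = c(15L, 2L))
  expect_warning(out <- mergeSameName(cross), "multiple regions")
  expect_equal(nrow(out), 2L)
})

test_that("regional pooling is chromosome-count-weighted and splitting-invariant", {
  tab <- data.frame(population = c("p1", "p2"), region = "R",
                    chromosomes = c(10L, 30L), derived_count = c(2L, 12L))
  pool <- poolByRegion(tab)
  expect_equal(pool$pooled_frequency, 14 / 40)
  expect_equal(pool$total_chromosomes, 40L)

  # single population pools to its own frequency
  one <- poolByRegion(tab[1, ])
  expect_equal(one$pooled_frequency, 0.2)

  # printed regional-scale round trip: 394 chromosomes at frequency 0.764
  # corresponds to ~301 derived chromosomes
  americas <- data.frame(population = "pooled", region = "Americas",
                         chromosomes = 394L,
                         derived_count = as.integer(round(0.764 * 394)))
  expect_equal(americas$derived_count, 301L)
  expect_equal(round(poolByRegion(americas)$pooled_frequency, 3), 0.764)

  # identical-frequency populations pool to that frequency exactly
  same <- data.frame(population = c("a", "b", "c"), region = "R",
                     chromosomes = c(10L, 20L, 50L),
                     derived_count = c(2L, 4L, 10L))
  expect_equal(poolByRegion(same)$pooled_frequency, 0.2)

  # pooling is invariant to splitting a population into sub-records
  set.seed(4)
  for (rep in 1:5) {
    n2 <- 2L * sample(20:60, 1); cnt <- sample.int(n2, 1)
    whole <- data.frame(population = "w", region = "R",
                        chromosomes = n2, derived_count = cnt)
    cut <- sample.int(n2 - 1L, 1)
    cntA <- rhyper(1, cnt, n2 - cnt, cut)
    split <- data.frame(population = c("w", "w"), region = "R",
                        chromosomes = c(cut, n2 - cut),
                        derived_count = c(cntA, cnt - cntA))
    expect_equal(poolByRegion(mergeSameName(split))$pooled_frequency,
                 poolByRegion(whole)$pooled_frequency)
  }
})

test_that("frequency differentials follow the unsigned/signed contract", {
  expect_equal(frequencyDifferential(0.764, 0.477), 0.287, tolerance = 1e-12)
  expect_equal(round(frequencyDifferential(0.764, 0.477), 2), 0.29)
  expect_equal(frequencyDifferential(0.31, 0.31), 0)
  expect_equal(frequencyDifferential(0.477, 0.764, signed = TRUE), -0.287,
               tolerance = 1e-12)
  expect_error(frequencyDifferential(1.2, 0.5), "\\[0, 1\\]")
})

test_that("differential distributions summarize quantiles and exceedance", {
  s <- differentialDistribution(c(0.1, 0.2, 0.3, 0.4), threshold = 0.29)
  expect_equal(exceedanceFraction(s), 0.5)

  # degenerate list: all zero differentials, threshold 0
  z <- differentialDistribution(matrix(0.5, 5, 2), threshold = 0)
  expect_equal(exceedanceFraction(z), 1)
  expect_equal(c(z@minimum, z@q1, z@median, z@q3, z@maximum), rep(0, 5))

  # the printed regional contrast sits just under the 0.29 threshold
  s1 <- differentialDistribution(matrix(c(0.764, 0.477), 1), threshold = 0.29)
  expect_equal(exceedanceFraction(s1), 0)

  expect_error(differentialDistribution(numeric(0)), "empty")

  # quantiles agree with an independent linear-interpolation oracle
  set.seed(11)
  for (rep in 1:10) {
    x <- runif(sample(2:100, 1))
    s <- differentialDistribution(x, threshold = 0.29)
    expect_equal(c(s@minimum, s@q1, s@median, s@q3, s@maximum),
                 oracleQuantile7(x, c(0, 0.25, 0.5, 0.75, 1)),
                 tolerance = 1e-12)
  }

  # exceedance is non-increasing in the threshold
  set.seed(12)
  x <- runif(200)
  exc <- vapply(seq(0, 1, by = 0.05), function(th)
    exceedanceFraction(differentialDistribution(x, threshold = th)), numeric(1))
  expect_true(all(diff(exc) <= 0))
})

test_that("pool and summary writers emit annotated, parseable TSV", {
  tab <- data.frame(population = c("p1", "p2"), region = "R",
                    chromosomes = c(10L, 30L), derived_count = c(2L, 12L))
  tf <- tempfile(fileext = ".tsv")
  writeRegionalPools(poolByRegion(tab), tf, c(seed = "1"))
  lines <- readLines(tf)
  expect_true(any(grepl("^# metadata", lines)))
  expect_true(any(grepl("pooling: chromosome-count-weighted", lines)))
  back <- read.delim(tf, comment.char = "#")
  expect_equal(back$pooled_frequency, 0.35)

  s <- differentialDistribution(c(0.1, 0.3), threshold = 0.29)
  tf2 <- tempfile(fileext = ".tsv")
  writeDifferentialSummary(s, tf2)
  expect_true(any(grepl("quantile_convention", readLines(tf2))))
})
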