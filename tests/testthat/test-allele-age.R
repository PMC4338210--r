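test_that("the frequency-based age estimator evaluates its closed form", {
  est <- alleleAge(0.5)
  expect_equal(est@t2N, 2 * log(2), tolerance = 1e-12)
  expect_equal(est@generations, 2 * log(2) * 12000, tolerance = 1e-9)
  expect_equal(round(est@generations), 16636)
  expect_equal(est@years, est@generations * 25)
  expect_true(est@pointEstimateOnly)

  # direct evaluation at an arbitrary frequency
  p <- 0.37
  expect_equal(alleleAge(p)@t2N, (-2 * p / (1 - p)) * log(p),
               tolerance = 1e-12)
})

test_that("age is monotone in frequency with the analytic limits 0 and 2", {
  ps <- seq(0.01, 0.99, by = 0.01)
  t2N <- vapply(ps, function(p) alleleAge(p)@t2N, numeric(1))
  expect_true(all(diff(t2N) > 0))
  expect_lt(alleleAge(1e-8)@t2N, 1e-6)           # p -> 0+ limit is 0
  expect_equal(alleleAge(1 - 1e-8)@t2N, 2, tolerance = 1e-5)  # p -> 1- is 2
  expect_true(all(t2N > 0 & t2N < 2))
})

test_that("scaling is dimensionally consistent in N and generation time", {
  a <- alleleAge(0.3, N = 6000, generationYears = 25)
  b <- alleleAge(0.3, N = 12000, generationYears = 25)
  expect_equal(b@generations, 2 * a@generations)
  expect_equal(b@years, 2 * a@years)
  expect_equal(b@t2N, a@t2N)
  c <- alleleAge(0.3, N = 6000, generationYears = 30)
  expect_equal(c@years, a@generations * 30)
})

test_that("fixed or absent alleles are rejected as out of the model's domain", {
  expect_error(alleleAge(0), "segregating")
  expect_error(alleleAge(1), "segregating")
  expect_error(alleleAge(-0.1), "segregating")
  expect_error(alleleAge(1.5), "segregating")
})
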