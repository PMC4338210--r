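test_that("EHH equals the brute-force pair-enumeration oracle", {
  # the canonical worked case: 4 carriers with extended haplotypes
  # {AB, AB, AA, BB} -> one identical pair of C(4,2) = 6
  mat <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  hap <- HaplotypeMatrix(mat, positions = c(100, 200, 300))
  expect_equal(ehhAt(hap, 1, 1, 3), 1 / 6)
  expect_equal(ehhAt(hap, 1, 1, 3), oracleEhh(mat, 1, 1, 3))

  # target == core is always 1; identical carriers give 1 over any span
  expect_equal(ehhAt(hap, 1, 1, 1), 1)
  same <- HaplotypeMatrix(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
                          positions = c(1, 2, 3))
  expect_equal(ehhAt(same, 1, 1, 3), 1)

  # random matrices up to 50 x 20, both alleles, both directions
  set.seed(31)
  for (rep in 1:12) {
    hap <- randomPanel(sample(10:50, 1), sample(5:20, 1))
    core <- sample.int(nSites(hap), 1)
    target <- sample.int(nSites(hap), 1)
    allele <- sample(0:1, 1)
    expect_equal(ehhAt(hap, core, allele, target),
                 oracleEhh(alleles(hap), core, allele, target))
  }
})

test_that("EHH is invariant to row order and to sites outside the span", {
  set.seed(32)
  hap <- randomPanel(30, 12)
  core <- 5L; target <- 9L
  ref <- ehhAt(hap, core, 1, target)
  perm <- hap[sample.int(nChromosomes(hap)), ]
  expect_equal(ehhAt(perm, core, 1, target), ref)
  # dropping a site outside [core, target] leaves the value unchanged
  dropped <- hap[, setdiff(seq_len(nSites(hap)), 12L)]
  expect_equal(ehhAt(dropped, core, 1, target), ref)
  dropped2 <- hap[, setdiff(seq_len(nSites(hap)), 1L)]
  expect_equal(ehhAt(dropped2, core - 1L, 1, target - 1L), ref)
})

test_that("EHH guards reject undefined statistics and bad indices", {
  hap <- HaplotypeMatrix(rbind(c(1, 0), c(0, 0), c(0, 1)),
                         positions = c(1, 2))
  expect_error(ehhAt(hap, 1, 1, 2), "only 1 chromosome")
  expect_error(ehhAt(hap, 1, 1, 7), "out of range")
  expect_error(ehhAt(hap, 9, 1, 1), "out of range")
  expect_error(ehhCurve(hap, 1, 1), "only 1 chromosome")
})

test_that("EHH curves anchor at 1, decay monotonically and match ehhAt", {
  set.seed(33)
  hap <- randomPanel(40, 15)
  core <- 8L
  for (allele in 0:1) {
    cv <- ehhCurve(hap, core, allele)
    expect_equal(cv@ehh[cv@distance == 0], 1)
    for (s in seq_len(nSites(hap)))
      expect_equal(cv@ehh[s], if (s == core) 1 else ehhAt(hap, core, allele, s))
    for (sgn in c(-1, 1)) {
      side <- cv@distance * sgn > 0
      e <- cv@ehh[side][order(abs(cv@distance[side]))]
      expect_true(all(diff(e) <= 1e-12))
    }
  }
  # two-site panel with identical carriers: flat curve at 1
  flat <- HaplotypeMatrix(rbind(c(1, 1), c(1, 1), c(0, 0)),
                          positions = c(10, 500))
  cv <- ehhCurve(flat, 1, 1)
  expect_equal(cv@ehh, c(1, 1))
  expect_equal(as.data.frame(cv)$distance_bp, c(0, 490))
})

test_that("relative EHH is the carrier/non-carrier homozygosity ratio", {
  set.seed(34)
  hap <- randomPanel(40, 12)
  core <- 6L; target <- 10L
  num <- oracleEhh(alleles(hap), core, 1, target)
  den <- oracleEhh(alleles(hap), core, 0, target)
  expect_equal(rehhAt(hap, core, 1, target), num / den)

  # identical decay on both classes gives 1 at every distance
  mirror <- HaplotypeMatrix(rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1),
                                  c(0, 0, 0), c(0, 0, 0), c(0, 1, 1)),
                            positions = c(1, 2, 3))
  for (s in 1:3) expect_equal(rehhAt(mirror, 1, 1, s), 1)

  # comparison class fully heterogeneous at the target: infinite ratio flag
  zero <- HaplotypeMatrix(rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 1)),
                          positions = c(1, 2))
  expect_warning(r <- rehhAt(zero, 1, 1, 2), "infinite")
  expect_identical(r, Inf)

  few <- HaplotypeMatrix(rbind(c(1, 0), c(1, 1), c(1, 0), c(0, 1)),
                         positions = c(1, 2))
  expect_error(rehhAt(few, 1, 1, 2), "2 carriers and 2 non-carriers")
})

test_that("iHS integrates EHH decay and is zero for mirrored alleles", {
  # derived and ancestral classes with identical internal structure:
  # both EHH curves coincide, so ln(iHH_A/iHH_D) = 0
  mirror <- HaplotypeMatrix(rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0),
                                  c(0, 0, 0), c(0, 0, 1), c(0, 1, 0)),
                            positions = c(1000, 2000, 3500))
  r <- ihs(mirror, 1)
  expect_equal(r@ihsUnstandardized, 0)
  expect_equal(r@ihhAncestral, r@ihhDerived)
  expect_true(any(r@edgeTruncated))   # EHH never falls below 0.05 here
  expect_true(is.na(r@ihsStandardized))

  hap <- HaplotypeMatrix(rbind(c(1, 0), c(0, 0), c(0, 1)),
                         positions = c(1, 2))
  expect_error(ihs(hap, 1), ">= 2 carriers")
})

test_that("standardization is bin-wise self-normalizing and names bad bins", {
  set.seed(35)
  scores <- list()
  for (i in 1:40) {
    hap <- randomPanel(30, 8)
    scores <- c(scores, ihsScan(hap, minCarriers = 6L)[1])
  }
  scores <- Filter(Negate(is.null), scores)
  std <- standardizeIhs(scores, bins = 2L)
  z <- vapply(std, function(r) r@ihsStandardized, numeric(1))
  bin <- vapply(std, function(r) r@frequencyBin, integer(1))
  for (b in unique(bin)) {
    expect_equal(mean(z[bin == b]), 0, tolerance = 1e-6)
    expect_equal(sd(z[bin == b]), 1, tolerance = 1e-6)
  }
  p <- vapply(std, function(r) r@pValue, numeric(1))
  expect_equal(p, 2 * pnorm(-abs(z)))

  # a bin holding fewer than two reference scores is a configuration error
  expect_error(standardizeIhs(scores, bins = 200L), "bin")
  expect_error(standardizeIhs(list(scores[[1]], scores[[1]]), bins = 1L),
               "zero score variance")
})
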