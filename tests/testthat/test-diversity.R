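test_that("hand-computed Hill values are reproduced", {
  # inverse-Simpson case: p = (.5, .25, .25) at q = 2
  d <- ClusterDistribution(c(2, 1, 1))
  expect_equal(hillDiversity(d, 2), 1 / (0.25 + 0.0625 + 0.0625),
               tolerance = 1e-12)
  # Shannon limit at q = 1: exp(1.5 ln 2)
  expect_equal(hillDiversity(d, 1), exp(1.5 * log(2)), tolerance = 1e-12)
  # the analytic q = 1 branch agrees with the generic formula nearby
  expect_equal(hillDiversity(d, 1), hillDiversity(d, 1 + 1e-6),
               tolerance = 1e-4)
  expect_equal(hillDiversity(d, 1), hillDiversity(d, 1 - 1e-6),
               tolerance = 1e-4)
  expect_equal(hillDiversity(d, 2), hillDiversity(d, 2 + 1e-6),
               tolerance = 1e-4)
})

test_that("uniform and degenerate distributions hit the boundary values", {
  for (q in c(0, 0.01, 0.5, 1, 2, 10, 100)) {
    expect_equal(hillDiversity(rep(7, 10), q), 10, tolerance = 1e-9)
    expect_equal(hillDiversity(c(0, 42, 0), q), 1, tolerance = 1e-12)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(hillDiversity(c(0, 0, 0), 1), "all counts are zero")
  expect_error(hillDiversity(c(1, 2), -1), "non-negative")
  expect_error(hillDiversity(c(1, 2), Inf), "finite")
  expect_error(hillDiversity(c(1, 2), c(1, 2)), "single")
  expect_error(ClusterDistribution(c(3, 1), clusterIds = c(2, 2)), "unique")
  expect_error(new("ClusterDistribution", clusterIds = c(2L, 1L),
                   counts = c(1, 1), label = "x"), "ascending")
})

test_that("zero-count clusters never contribute, including at q = 0", {
  withZeros <- ClusterDistribution(c(5, 0, 3, 0, 2))
  without <- ClusterDistribution(c(5, 3, 2))
  for (q in c(0, 0.3, 1, 2, 50)) {
    expect_equal(hillDiversity(withZeros, q), hillDiversity(without, q),
                 tolerance = 1e-12)
  }
  expect_identical(hillDiversity(withZeros, 0), 3)
})

test_that("profile is non-increasing in q and bounded by [1, richness]", {
  set.seed(41)
  grid <- defaultQGrid()
  for (i in 1:200) {
    counts <- randomCounts(sample(2:50, 1), allowZero = TRUE)
    s <- diversitySpectrum(counts, grid)  # validity enforces monotonicity
    d <- dValues(s)
    expect_true(all(diff(d) <= 1e-9))
    expect_true(all(d >= 1 - 1e-9))
    expect_true(all(d <= sum(counts > 0) + 1e-9))
  }
})

test_that("replication invariance: duplicating counts leaves ^qD unchanged", {
  set.seed(42)
  for (i in 1:50) {
    counts <- randomCounts(sample(2:20, 1))
    for (q in anchorQValues()) {
      expect_equal(hillDiversity(counts, q), hillDiversity(2 * counts, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("doubling: disjoint union of two copies doubles ^qD at every q", {
  set.seed(43)
  for (i in 1:50) {
    counts <- randomCounts(sample(2:15, 1))
    doubled <- c(counts, counts)  # two disjoint cluster blocks, equal weight
    for (q in c(0, anchorQValues())) {
      expect_equal(hillDiversity(doubled, q), 2 * hillDiversity(counts, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("log-space evaluation matches the direct formula on small cases", {
  set.seed(44)
  for (i in 1:200) {
    counts <- randomCounts(sample(2:6, 1))
    for (q in anchorQValues()) {
      expect_equal(hillDiversity(counts, q), bruteHill(counts, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("extreme orders reach the Berger-Parker dominance limit", {
  set.seed(45)
  for (i in 1:50) {
    counts <- randomCounts(sample(2:30, 1))
    p <- counts / sum(counts)
    # exact finite-q asymptote: (1/pmax) * (m * pmax)^(1/(1-q)) with m
    # clusters tied at the maximum proportion
    m <- sum(p == max(p))
    expect_lt(abs(hillDiversity(counts, 1e4) -
                  (1 / max(p)) * (m * max(p))^(1 / (1 - 1e4))), 1e-3)
  }
})

test_that("profile matches an independent ecology implementation", {
  set.seed(47)
  scales <- c(0, 0.5, 1, 2, 4, 16)
  for (i in 1:20) {
    counts <- randomCounts(sample(2:30, 1))
    ref <- exp(as.numeric(vegan::renyi(counts, scales = scales)))
    mine <- vapply(scales, function(q) hillDiversity(counts, q), numeric(1))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("named indices are consistent with the profile's special cases", {
  set.seed(46)
  for (i in 1:50) {
    counts <- randomCounts(sample(2:30, 1), allowZero = TRUE)
    idx <- namedIndices(counts)
    expect_identical(idx$richness, as.numeric(sum(counts > 0)))
    expect_equal(hillDiversity(counts, 1), exp(idx$shannon_log),
                 tolerance = 1e-9)
    expect_equal(hillDiversity(counts, 2), idx$simpson_inverse,
                 tolerance = 1e-9)
    p <- counts[counts > 0] / sum(counts)
    expect_equal(idx$berger_parker, 1 / max(p), tolerance = 1e-12)
  }
  # hand value: p = (.2,.3,.5)
  expect_equal(namedIndices(c(2, 3, 5))$simpson_inverse,
               1 / (0.04 + 0.09 + 0.25), tolerance = 1e-12)
})

test_that("spectrum handles anchor grids, length-1 grids, and bad grids", {
  s <- diversitySpectrum(rep(1, 4), c(0.01, 1, 100))
  expect_equal(unname(dValues(s)), c(4, 4, 4), tolerance = 1e-9)
  d <- ClusterDistribution(c(9, 1))
  s2 <- diversitySpectrum(d, c(0, 2))
  expect_equal(unname(dValues(s2)), c(2, 1 / 0.82), tolerance = 1e-9)
  s3 <- diversitySpectrum(d, 2)
  expect_equal(unname(dValues(s3)), hillDiversity(d, 2))
  expect_error(diversitySpectrum(d, numeric(0)), "empty")
  expect_error(diversitySpectrum(d, c(2, 1)), "increasing")
})

test_that("default q grid is strictly increasing and contains the anchors", {
  g <- defaultQGrid()
  expect_true(all(diff(g) > 0))
  expect_true(all(anchorQValues() %in% g))
  expect_equal(range(g), c(0.01, 100))
})

test_that("spectrum CSV writer round-trips at full precision", {
  s1 <- diversitySpectrum(c(5, 3, 2), anchorQValues(), label = "a")
  s2 <- diversitySpectrum(c(1, 1, 1, 7), anchorQValues(), label = "b")
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCsv(list(s1, s2), path)
  back <- readSpectrumCsv(path)
  expect_named(back, c("a", "b"))
  expect_identical(dValues(back$a), dValues(s1))
  expect_identical(qGrid(back$b), qGrid(s2))
})
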