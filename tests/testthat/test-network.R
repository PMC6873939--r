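profAnn <- function(clusters, conditions = NULL, barcodes = NULL) {
  n <- length(clusters)
  CellAnnotation(
    barcode = barcodes %||% sprintf("BC%04d-1", seq_len(n)),
    sample = "s1",
    condition = conditions %||% rep("c", n),
    cluster = clusters)
}

test_that("geometric-mean profiles match hand-computed values", {
  # one gene, cells with counts (2, 8): pseudocount -> 0 recovers gm = 4
  m <- makeCountsMatrix(matrix(c(2, 8), 1, 2))
  ann <- profAnn(c(1, 1))
  p <- clusterProfiles(m, ann, pseudocount = 1e-9)
  expect_equal(unname(profileMatrix(p)[1, 1]), 4, tolerance = 1e-6)
  # counts (0, 3) at pseudocount 1: exp((ln1 + ln4)/2) - 1 = 1
  m2 <- makeCountsMatrix(matrix(c(0, 3), 1, 2))
  p2 <- clusterProfiles(m2, ann, pseudocount = 1)
  expect_equal(unname(profileMatrix(p2)[1, 1]), 1, tolerance = 1e-12)
})

test_that("identical cells profile to their own counts at any pseudocount", {
  cellCol <- c(3, 0, 7, 1)
  m <- makeCountsMatrix(matrix(rep(cellCol, 5), 4, 5))
  ann <- profAnn(rep(1, 5))
  for (pc in c(0.1, 1, 10)) {
    p <- clusterProfiles(m, ann, pseudocount = pc)
    expect_equal(unname(profileMatrix(p)[, 1]), cellCol, tolerance = 1e-9)
  }
})

test_that("all-zero genes profile to exactly zero", {
  m <- makeCountsMatrix(rbind(c(0, 0, 0), c(1, 2, 3)))
  p <- clusterProfiles(m, profAnn(c(1, 1, 1)))
  expect_identical(unname(profileMatrix(p)[1, 1]), 0)
})

test_that("profiles are permutation-invariant and scale correctly", {
  set.seed(61)
  counts <- matrix(rpois(6 * 10, 3), 6, 10)
  ann <- profAnn(rep(c(1, 2), each = 5))
  perm <- sample(10)
  m1 <- makeCountsMatrix(counts)
  m2 <- makeCountsMatrix(counts[, perm],
                         barcodes = colnames(m1)[perm])
  p1 <- clusterProfiles(m1, ann)
  p2 <- clusterProfiles(m2, ann)
  expect_equal(profileMatrix(p1), profileMatrix(p2), tolerance = 1e-12)
  # one-gene cluster: scaling counts by c scales the pseudocount-free gm by c
  g <- makeCountsMatrix(matrix(c(2, 8, 4), 1, 3))
  g3 <- makeCountsMatrix(matrix(3 * c(2, 8, 4), 1, 3))
  a <- profAnn(rep(1, 3))
  pg <- clusterProfiles(g, a, pseudocount = 1e-10)
  pg3 <- clusterProfiles(g3, a, pseudocount = 1e-10)
  expect_equal(unname(profileMatrix(pg3)[1, 1]),
               3 * unname(profileMatrix(pg)[1, 1]), tolerance = 1e-5)
})

test_that("barcode mismatches and bad pseudocounts are rejected", {
  m <- makeCountsMatrix(matrix(1, 2, 2))
  ann <- profAnn(c(1, 1), barcodes = c("BC0001-1", "MISSING-1"))
  expect_error(clusterProfiles(m, ann), "missing from matrix")
  expect_error(clusterProfiles(m, profAnn(c(1, 1)), pseudocount = 0),
               "positive")
})

test_that("Euclidean distances between profiles behave as a metric", {
  # 3-4-5 triangle over two genes
  p <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(NULL, c(1, 2)))
  dm <- clusterDistanceMatrix(p)
  expect_equal(dm["1", "2"], 5, tolerance = 1e-12)
  expect_identical(unname(diag(dm)), c(0, 0))
  set.seed(62)
  for (i in 1:100) {
    pr <- matrix(runif(5 * 3, 0, 10), 5, 3, dimnames = list(NULL, 1:3))
    dm <- clusterDistanceMatrix(pr)
    expect_identical(dm, t(dm))
    expect_lte(dm[1, 3], dm[1, 2] + dm[2, 3] + 1e-12)
    # oracle: explicit sqrt-sum-of-squares
    expect_equal(dm[1, 2], sqrt(sum((pr[, 1] - pr[, 2])^2)),
                 tolerance = 1e-12)
  }
  expect_error(clusterDistanceMatrix(p[, 1, drop = FALSE]), "at least 2")
})

test_that("cluster graph carries sizes, compositions and tie-breaks", {
  ann <- makeAnnotation(list(
    h = list(condition = "healthy", clusters = c(`1` = 60, `2` = 25)),
    a = list(condition = "aml", clusters = c(`1` = 40, `2` = 25))))
  dm <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(1:2, 1:2))
  g <- buildClusterGraph(dm, ann)
  nodes <- graphNodes(g)
  expect_identical(nodes$size, c(100, 50))
  expect_identical(sum(nodes$size), as.numeric(length(ann)))
  # cluster 1: 60/100 healthy -> majority healthy
  expect_identical(nodes$majority_condition[1], "healthy")
  expect_equal(nodes$prop_healthy[1], 0.6)
  expect_equal(nodes$prop_aml[1] + nodes$prop_healthy[1], 1)
  # cluster 2 is an exact 50/50 tie -> lexicographically smallest label
  expect_identical(nodes$majority_condition[2], "aml")
  edges <- graphEdges(g)
  expect_identical(nrow(edges), 1L)
  expect_equal(edges$weight, 1 / (edges$distance + 1e-9))
  expect_error(buildClusterGraph(dm[1, 1, drop = FALSE], ann), "disagree")
})

test_that("graph tables round-trip through CSV output", {
  ann <- makeAnnotation(list(
    s = list(condition = "c", clusters = c(`1` = 4, `2` = 6, `3` = 2))))
  pr <- matrix(seq_len(9), 3, 3, dimnames = list(NULL, 1:3))
  g <- buildClusterGraph(clusterDistanceMatrix(pr), ann)
  dir <- withr::local_tempdir()
  writeClusterGraph(g, dir)
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  edges <- read.csv(file.path(dir, "edges.csv"))
  expect_identical(nodes$cluster, 1:3)
  expect_identical(nrow(edges), 3L)
  expect_equal(edges$distance, graphEdges(g)$distance, tolerance = 1e-15)
})

test_that("end-to-end: profile separation reflects expression programs", {
  # two clusters with distinct programs land far apart; replicate clusters
  # of one program land close
  set.seed(63)
  progA <- rlnorm(50, 0, 1); progB <- rlnorm(50, 2, 1)
  nb <- function(mu, n) matrix(rnbinom(50 * n, size = 5, mu = mu), 50, n)
  counts <- cbind(nb(progA, 30), nb(progA, 30), nb(progB, 30))
  m <- makeCountsMatrix(counts)
  ann <- profAnn(rep(c(1, 2, 3), each = 30))
  dm <- clusterDistanceMatrix(clusterProfiles(m, ann))
  expect_lt(dm["1", "2"], dm["1", "3"])
  expect_lt(dm["1", "2"], dm["2", "3"])
})
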