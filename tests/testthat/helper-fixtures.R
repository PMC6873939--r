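# Shared fixture builders. Everything is generated in code at test time;
# randomized helpers take an explicit seed so failures reproduce.

# random occupancy counts over nClusters clusters (all occupied unless
# allowZero, but never all-zero)
randomCounts <- function(nClusters, allowZero = FALSE, maxCount = 50L) {
  lo <- if (allowZero) 0L else 1L
  repeat {
    n <- sample(lo:maxCount, nClusters, replace = TRUE)
    if (sum(n) > 0) return(as.numeric(n))
  }
}

# CellAnnotation from a compact description:
#   samples = list(s1 = list(condition = "healthy", clusters = c(`1` = 30, `2` = 10)))
# where clusters is a named count vector (names = cluster ids)
makeAnnotation <- function(samples) {
  rows <- lapply(names(samples), function(sid) {
    s <- samples[[sid]]
    cl <- rep(as.integer(names(s$clusters)), s$clusters)
    k <- match(sid, names(samples))
    data.frame(
      barcode = sprintf("BC%s%05d-%d", sid, seq_along(cl), k),
      sample = sid, condition = s$condition, cluster = cl,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  CellAnnotation(tab$barcode, tab$sample, tab$condition, tab$cluster)
}

# tiny genes x cells sparse matrix with dimnames
makeCountsMatrix <- function(mat, genes = NULL, barcodes = NULL) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  rownames(m) <- genes %||% sprintf("G%d", seq_len(nrow(m)))
  colnames(m) <- barcodes %||% sprintf("BC%04d-1", seq_len(ncol(m)))
  methods::as(m, "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force Hill evaluation: direct power-sum formula,
# no log-space trick, extended-precision accumulation via sum()
bruteHill <- function(p, q) {
  p <- p[p > 0]
  p <- p / sum(p)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# brute-force discrete KS: check every prefix explicitly
bruteKS <- function(pa, pb) {
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  best <- 0
  for (k in seq_along(pa)) {
    best <- max(best, abs(sum(pa[1:k]) - sum(pb[1:k])))
  }
  best
}
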