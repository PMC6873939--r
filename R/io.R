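# Readers and writers for the 10x-style formats the pipeline touches:
# MatrixMarket triplet matrices with barcode/feature TSVs, Loupe-style
# cluster CSVs, and the samples sheet that maps aggregation suffixes
# ("-1", "-2", ...) to sample ids and conditions. Readers validate loudly
# rather than coerce; gzipped variants of every file are accepted.

.findFile <- function(dir, stems) {
    for (s in stems) for (ext in c("", ".gz")) {
        p <- file.path(dir, paste0(s, ext))
        if (file.exists(p)) return(p)
    }
    stop("none of [", paste(stems, collapse = ", "), "] found in ", dir,
         call. = FALSE)
}

#' Read a 10x-style MTX directory into a sparse count matrix
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or the older
#' `genes.tsv`), each optionally gzipped. The feature file may have 1, 2 or
#' 3 columns (id / id+name / id+name+type); the first column becomes the
#' row names.
#'
#' @param dir directory containing the three files.
#' @return a `dgCMatrix` (genes x cells) of non-negative integral UMI
#'   counts with feature-id row names and barcode column names.
#' @export
read10xMtx <- function(dir) {
    if (!dir.exists(dir))
        stop("not a directory: ", dir, call. = FALSE)
    mtx <- .findFile(dir, "matrix.mtx")
    bcf <- .findFile(dir, "barcodes.tsv")
    ftf <- .findFile(dir, c("features.tsv", "genes.tsv"))
    src <- if (endsWith(mtx, ".gz")) gzfile(mtx) else mtx
    m <- tryCatch(Matrix::readMM(src),
        error = function(e) stop("malformed MatrixMarket file ", mtx, ": ",
                                 conditionMessage(e), call. = FALSE))
    barcodes <- readLines(bcf)
    feat <- read.delim(ftf, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(feat) > 3L)
        stop("feature file ", ftf, " has ", ncol(feat),
             " columns; expected 1-3", call. = FALSE)
    if (nrow(m) != nrow(feat))
        stop(sprintf("dimension mismatch in %s: matrix has %d rows but %s has %d features",
                     dir, nrow(m), basename(ftf), nrow(feat)), call. = FALSE)
    if (ncol(m) != length(barcodes))
        stop(sprintf("dimension mismatch in %s: matrix has %d columns but %s has %d barcodes",
                     dir, ncol(m), basename(bcf), length(barcodes)), call. = FALSE)
    m <- methods::as(m, "CsparseMatrix")
    if (any(m@x < 0) || any(m@x != floor(m@x)))
        stop("matrix ", mtx, " contains negative or non-integer entries",
             call. = FALSE)
    dimnames(m) <- list(feat[[1L]], barcodes)
    m
}

#' Write a sparse count matrix as a 10x-style MTX directory
#'
#' Inverse of [read10xMtx()]: writes `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (two columns: id, name = id).
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write10xMtx <- function(counts, dir) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts needs feature row names and barcode column names",
             call. = FALSE)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    write.table(data.frame(rownames(counts), rownames(counts)),
                file.path(dir, "features.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    invisible(dir)
}

#' Barcode aggregation suffix ("-k")
#'
#' @param barcode character vector of 10x aggregated barcodes.
#' @return the suffix after the final dash, e.g. `"1"` for
#'   `"AAACCTGAGAAACGCC-1"`.
#' @export
barcodeSuffix <- function(barcode) {
    suf <- sub("^.*-", "", barcode)
    bad <- suf == barcode | !nzchar(suf)
    if (any(bad))
        stop("barcodes without an aggregation suffix: ",
             paste(utils::head(barcode[bad], 5), collapse = ", "),
             call. = FALSE)
    suf
}

#' Read Loupe-style cluster CSV + samples sheet into a CellAnnotation
#'
#' The cluster CSV has header `Barcode,Cluster` (Loupe export dialect); the
#' samples sheet has header `suffix,sample_id,condition` and maps each
#' barcode aggregation suffix to its sample of origin.
#'
#' @param clusterCsv path to the cluster assignment CSV.
#' @param samplesCsv path to the samples sheet CSV.
#' @return a [CellAnnotation-class].
#' @export
readAnnotations <- function(clusterCsv, samplesCsv) {
    cl <- read.csv(clusterCsv, stringsAsFactors = FALSE, check.names = FALSE)
    names(cl) <- tolower(names(cl))
    if (!all(c("barcode", "cluster") %in% names(cl)))
        stop("cluster CSV ", clusterCsv,
             " must have header Barcode,Cluster", call. = FALSE)
    if (anyDuplicated(cl$barcode))
        stop("duplicate barcodes in ", clusterCsv, ": ",
             paste(utils::head(unique(cl$barcode[duplicated(cl$barcode)]), 5),
                   collapse = ", "), call. = FALSE)
    clInt <- suppressWarnings(as.integer(cl$cluster))
    if (anyNA(clInt) || any(clInt != as.numeric(cl$cluster)))
        stop("non-integer cluster ids in ", clusterCsv, call. = FALSE)
    sh <- read.csv(samplesCsv, stringsAsFactors = FALSE)
    if (!all(c("suffix", "sample_id", "condition") %in% names(sh)))
        stop("samples sheet ", samplesCsv,
             " must have header suffix,sample_id,condition", call. = FALSE)
    suf <- barcodeSuffix(cl$barcode)
    hit <- match(suf, as.character(sh$suffix))
    if (anyNA(hit)) {
        offenders <- sort(unique(suf[is.na(hit)]))
        stop("barcode suffixes not in samples sheet: ",
             paste(paste0("-", offenders), collapse = ", "), call. = FALSE)
    }
    CellAnnotation(barcode = cl$barcode,
                   sample = sh$sample_id[hit],
                   condition = sh$condition[hit],
                   cluster = clInt)
}

#' Write a CellAnnotation as cluster CSV + samples sheet
#'
#' Inverse of [readAnnotations()]; suffixes are taken from the barcodes.
#'
#' @param annotation a [CellAnnotation-class].
#' @param clusterCsv,samplesCsv output paths.
#' @return invisibly, the two paths.
#' @export
writeAnnotations <- function(annotation, clusterCsv, samplesCsv) {
    stopifnot(is(annotation, "CellAnnotation"))
    tab <- annotation@table
    write.csv(data.frame(Barcode = tab$barcode, Cluster = tab$cluster),
              clusterCsv, row.names = FALSE, quote = FALSE)
    suf <- barcodeSuffix(tab$barcode)
    sheet <- unique(data.frame(suffix = suf, sample_id = tab$sample,
                               condition = tab$condition,
                               stringsAsFactors = FALSE))
    if (anyDuplicated(sheet$suffix))
        stop("barcode suffixes do not map one-to-one to samples",
             call. = FALSE)
    write.csv(sheet[order(sheet$suffix), ], samplesCsv,
              row.names = FALSE, quote = FALSE)
    invisible(c(clusterCsv, samplesCsv))
}

#' Minimal stand-in clusterer for end-to-end tests
#'
#' A deliberately simple pipeline stand-in for the platform clustering this
#' package sits downstream of: per-cell total-count scaling, log1p, PCA to
#' at most 20 components, then k-means. Useful for testing and as a
#' `reclusterHook`; not a replacement for a production clusterer.
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param k number of clusters (1 <= k <= cells).
#' @param seed integer seed; labels are deterministic given it.
#' @param nComponents maximum number of principal components (default 20).
#' @return integer vector of labels in 1..k, named by barcode when column
#'   names exist.
#' @export
quickClusterCells <- function(counts, k, seed = 1L, nComponents = 20L) {
    n <- ncol(counts)
    if (k < 1L || k > n)
        stop("k must be between 1 and the number of cells (", n, ")",
             call. = FALSE)
    if (k == 1L)
        return(setNames(rep(1L, n), colnames(counts)))
    tot <- Matrix::colSums(counts)
    tot[tot == 0] <- 1
    norm <- log1p(t(t(as.matrix(counts)) / tot * stats::median(tot)))
    old <- .getRandomSeed()
    on.exit(.restoreRandomSeed(old))
    set.seed(as.integer(seed))
    ncomp <- min(nComponents, n - 1L, nrow(norm))
    pcs <- stats::prcomp(t(norm), center = TRUE, scale. = FALSE,
                         rank. = ncomp)$x
    # k-means++ seeding: plain random starts almost never place a center in
    # a small, far-away cluster and instead split the big ones
    best <- NULL
    for (start in 1:10) {
        fit <- tryCatch(
            stats::kmeans(pcs, centers = .kmeansppInit(pcs, k),
                          iter.max = 100L),
            error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$tot.withinss < best$tot.withinss))
            best <- fit
    }
    setNames(as.integer(best$cluster), colnames(counts))
}

.kmeansppInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(0, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in seq_len(k)[-1L]) {
        pick <- sample.int(n, 1L, prob = pmax(d2, 1e-300))
        centers[j, ] <- x[pick, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
    centers
}
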