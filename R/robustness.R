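# Downsampling stability protocol: repeatedly subsample a fixed fraction
# of a group's cells, recompute the diversity profile at the anchor orders,
# and summarize absolute and relative change against the full-data value.
#
# Replicate r uses a sub-seed derived from the master seed by a counter
# scheme, so results are reproducible regardless of execution order, and
# two runs with the same master seed are bit-identical.

.subSeed <- function(seed, r) {
    # counter-based derivation, kept inside 32-bit signed integer range
    as.integer((as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483647)
}

#' @describeIn downsampleCells uniform subsampling without replacement
#' @export
setMethod("downsampleCells", "CellAnnotation", function(x, fraction, seed) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("fraction must be in (0, 1]", call. = FALSE)
    n <- nrow(x@table)
    keep <- floor(fraction * n)
    if (keep < 1L)
        stop("subsample would be empty (", n, " cells at fraction ",
             fraction, ")", call. = FALSE)
    if (keep == n) return(x)
    idx <- local({
        old <- .getRandomSeed()
        on.exit(.restoreRandomSeed(old))
        set.seed(as.integer(seed))
        sample.int(n, keep)
    })
    new("CellAnnotation", table = x@table[sort(idx), , drop = FALSE])
})

.getRandomSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreRandomSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Downsampling stability of the diversity profile
#'
#' Repeatedly draws `fraction` of a group's cells without replacement and
#' recomputes \eqn{^qD} at each order in `qValues`, holding the joint
#' cluster labels fixed by default. Passing a `reclusterHook` instead
#' re-derives labels per replicate (e.g. with [quickClusterCells()] and the
#' expression matrix), which folds clustering-algorithm stability into the
#' measurement; the default isolates the statistic's own stability.
#'
#' @param x a [CellAnnotation-class].
#' @param label which group to downsample; defaults to pooling all cells.
#' @param by `"sample"` or `"condition"` (used when `label` is given).
#' @param fraction fraction of cells kept per replicate (default 0.5).
#' @param nReplicates number of independent subsamples (default 1000).
#' @param qValues orders at which to evaluate the profile; default the six
#'   anchors [anchorQValues()].
#' @param seed master integer seed; replicate sub-seeds are derived from it
#'   by a counter scheme.
#' @param reclusterHook optional `function(annotation)` returning an
#'   integer cluster label per cell of the subsetted annotation.
#' @return a [DownsampleResult-class].
#' @export
downsampleSpectrum <- function(x, label = NULL, by = c("sample", "condition"),
                               fraction = 0.5, nReplicates = 1000L,
                               qValues = anchorQValues(), seed = 1L,
                               reclusterHook = NULL) {
    stopifnot(is(x, "CellAnnotation"))
    by <- match.arg(by)
    if (length(qValues) == 0L || any(!is.finite(qValues)) || any(qValues < 0))
        stop("qValues must be finite and non-negative", call. = FALSE)
    if (!is.null(label)) {
        col <- if (by == "sample") x@table$sample else x@table$condition
        if (!label %in% col)
            stop(sprintf("unknown %s: '%s'", by, label), call. = FALSE)
        x <- new("CellAnnotation",
                 table = x@table[col == label, , drop = FALSE])
    } else label <- "pooled"
    if (nrow(x@table) < 2L)
        stop("need at least 2 cells to downsample", call. = FALSE)
    space <- clusterSpace(x)
    qValues <- as.numeric(qValues)
    baseD <- vapply(qValues,
        function(q) hillDiversity(as.numeric(table(factor(x@table$cluster,
            levels = space))), q), numeric(1))
    reps <- matrix(NA_real_, nReplicates, length(qValues))
    for (r in seq_len(nReplicates)) {
        sub <- downsampleCells(x, fraction, .subSeed(seed, r))
        cl <- if (is.null(reclusterHook)) sub@table$cluster
              else as.integer(reclusterHook(sub))
        counts <- as.numeric(table(cl))
        reps[r, ] <- vapply(qValues,
            function(q) hillDiversity(counts, q), numeric(1))
    }
    new("DownsampleResult", label = as.character(label),
        qValues = qValues, replicateD = reps, baselineD = baseD,
        fraction = fraction, nReplicates = as.integer(nReplicates),
        seed = as.integer(seed),
        reclustered = !is.null(reclusterHook))
}

#' @describeIn relativeChange normalize each per-q replicate distribution by
#'   its mean and report absolute deviations from baseline
#' @export
setMethod("relativeChange", "DownsampleResult", function(result) {
    reps <- result@replicateD
    mu <- colMeans(reps)
    normalized <- sweep(reps, 2L, mu, "/")
    absolute <- sweep(reps, 2L, result@baselineD, "-")
    summary <- data.frame(
        label = result@label,
        q = result@qValues,
        baseline_d = result@baselineD,
        mean_d = mu,
        sd_d = apply(reps, 2L, sd),
        max_abs_change = apply(abs(absolute), 2L, max),
        stringsAsFactors = FALSE)
    colnames(normalized) <- colnames(absolute) <- result@qValues
    list(normalized = normalized, absolute_change = absolute,
         summary = summary)
})

#' Write a downsampling experiment as long + summary CSV tables
#'
#' Writes `downsample_replicates.csv` (`label,q,replicate,d,normalized_d`)
#' and `downsample_summary.csv`
#' (`label,q,baseline_d,mean_d,sd_d,max_abs_change`).
#'
#' @param result a [DownsampleResult-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDownsampleCsv <- function(result, dir) {
    stopifnot(is(result, "DownsampleResult"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rc <- relativeChange(result)
    nq <- length(result@qValues)
    long <- data.frame(
        label = result@label,
        q = rep(result@qValues, each = result@nReplicates),
        replicate = rep(seq_len(result@nReplicates), nq),
        d = as.vector(result@replicateD),
        normalized_d = as.vector(rc$normalized),
        stringsAsFactors = FALSE)
    .writeFullPrecisionCsv(long, file.path(dir, "downsample_replicates.csv"))
    .writeFullPrecisionCsv(rc$summary, file.path(dir, "downsample_summary.csv"))
    invisible(dir)
}
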