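# Cluster occupancy distributions per sample/condition and their discrete
# Kolmogorov-Smirnov distances.
#
# The KS distance on categorical clusters depends on the cluster ordering;
# the canonical order used throughout is ascending numeric cluster id from
# the joint clustering, which is the order Loupe-style exports use. All
# distances are computed on proportions, never raw counts, so samples of
# different depth compare fairly.

#' @describeIn occupancy tally one group's cells over the shared space
#' @export
setMethod("occupancy", "CellAnnotation",
    function(x, group, by = c("sample", "condition"), clusterSpace = NULL) {
        by <- match.arg(by)
        tab <- x@table
        col <- if (by == "sample") tab$sample else tab$condition
        if (!group %in% col)
            stop(sprintf("unknown %s: '%s'", by, group), call. = FALSE)
        sub <- tab$cluster[col == group]
        if (is.null(clusterSpace)) clusterSpace <- sort(unique(tab$cluster))
        clusterSpace <- as.integer(clusterSpace)
        if (is.unsorted(clusterSpace, strictly = TRUE))
            stop("clusterSpace must be strictly ascending", call. = FALSE)
        missing <- setdiff(sub, clusterSpace)
        if (length(missing))
            stop("observed clusters outside clusterSpace: ",
                 paste(sort(missing), collapse = ", "), call. = FALSE)
        counts <- vapply(clusterSpace, function(k) sum(sub == k), numeric(1))
        new("ClusterDistribution", clusterIds = clusterSpace,
            counts = counts, label = as.character(group))
    })

#' Kolmogorov-Smirnov distance between two aligned occupancy distributions
#'
#' The maximum absolute difference between the two cumulative occupancy
#' proportion curves, accumulating along the canonical ascending cluster
#' order. Both distributions must be aligned to the same cluster space
#' (build them with [occupancy()] and a shared `clusterSpace`).
#'
#' @param a,b [ClusterDistribution-class] objects on identical cluster
#'   spaces.
#' @return distance in \[0, 1\]; 0 iff the proportion vectors are identical.
#' @examples
#' a <- ClusterDistribution(c(2, 3, 5))
#' b <- ClusterDistribution(c(4, 4, 2))
#' ksDistance(a, b)  # CDFs (.2,.5,1) vs (.4,.8,1) -> 0.3
#' @export
ksDistance <- function(a, b) {
    stopifnot(is(a, "ClusterDistribution"), is(b, "ClusterDistribution"))
    if (!identical(a@clusterIds, b@clusterIds))
        stop("distributions are not aligned on the same cluster space; ",
             "recompute with occupancy() and a common clusterSpace",
             call. = FALSE)
    pa <- a@counts / sum(a@counts)
    pb <- b@counts / sum(b@counts)
    max(abs(cumsum(pa) - cumsum(pb)))
}

#' All pairwise KS distances between samples or conditions
#'
#' Builds the occupancy distribution of every group over the full shared
#' cluster space and returns the symmetric matrix of discrete KS distances.
#'
#' @param x a [CellAnnotation-class].
#' @param by `"sample"` or `"condition"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = group
#'   labels (in order of first appearance).
#' @export
pairwiseKS <- function(x, by = c("sample", "condition")) {
    by <- match.arg(by)
    stopifnot(is(x, "CellAnnotation"))
    groups <- if (by == "sample") sampleIds(x) else conditionLabels(x)
    if (length(groups) < 2L)
        stop("need at least 2 groups to compare (found ",
             length(groups), ")", call. = FALSE)
    space <- clusterSpace(x)
    dists <- lapply(groups, function(g) occupancy(x, g, by, space))
    n <- length(groups)
    m <- matrix(0, n, n, dimnames = list(groups, groups))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- ksDistance(dists[[i]], dists[[j]])
    }
    m
}

#' Write a square distance matrix as CSV with labels
#'
#' @param m symmetric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatrixCsv <- function(m, path) {
    df <- data.frame(group = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeFullPrecisionCsv(df, path)
    invisible(path)
}
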