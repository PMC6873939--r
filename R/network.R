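# Cluster expression summaries and the cluster similarity graph.
#
# Each cluster is summarized by the per-gene geometric mean of UMI counts
# over all its cells (pooled across samples). Zero counts make a plain
# geometric mean degenerate, so a pseudocount is added before the log and
# subtracted afterwards: exp(mean(log(x + c))) - c. All-zero genes profile
# to exactly 0, and a constant cluster profiles to its own counts for any
# pseudocount.

#' Per-cluster geometric-mean expression profiles
#'
#' @param counts sparse or dense genes x cells matrix of non-negative
#'   integral UMI counts with barcode column names.
#' @param annotation a [CellAnnotation-class]; every barcode must be a
#'   column of `counts`.
#' @param pseudocount positive value added before the log and subtracted
#'   after (default 1).
#' @param normalize if TRUE, scale each cell to counts-per-median-total
#'   before profiling. Off by default: upstream pipelines typically
#'   normalize already.
#' @return a [ClusterProfiles-class] (genes x clusters). Clusters with no
#'   cells in `annotation` cannot occur (the table defines them), but
#'   clusters whose cells are all missing from `counts` raise an error.
#' @export
clusterProfiles <- function(counts, annotation, pseudocount = 1,
                            normalize = FALSE) {
    stopifnot(is(annotation, "CellAnnotation"))
    if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
        stop("pseudocount must be a positive scalar", call. = FALSE)
    tab <- annotation@table
    if (is.null(colnames(counts)))
        stop("counts matrix needs barcode column names", call. = FALSE)
    missing <- setdiff(tab$barcode, colnames(counts))
    if (length(missing))
        stop("annotation barcodes missing from matrix: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5)
             else "", call. = FALSE)
    counts <- methods::as(counts, "CsparseMatrix")
    if (normalize) {
        cn <- colnames(counts)
        tot <- Matrix::colSums(counts)
        tot[tot == 0] <- 1
        counts <- counts %*% Matrix::Diagonal(
            ncol(counts), stats::median(tot) / tot)
        colnames(counts) <- cn
    }
    clusters <- sort(unique(tab$cluster))
    prof <- matrix(0, nrow(counts), length(clusters),
                   dimnames = list(rownames(counts), clusters))
    ncells <- integer(length(clusters))
    for (i in seq_along(clusters)) {
        bc <- tab$barcode[tab$cluster == clusters[i]]
        sub <- counts[, bc, drop = FALSE]
        ncells[i] <- length(bc)
        # sum of log(x + c) over cells = nnz terms + (ncells - nnz) * log(c),
        # computed without densifying
        logsub <- sub
        logsub@x <- log(sub@x + pseudocount) - log(pseudocount)
        rowlog <- Matrix::rowSums(logsub) + length(bc) * log(pseudocount)
        prof[, i] <- pmax(exp(rowlog / length(bc)) - pseudocount, 0)
    }
    new("ClusterProfiles", profiles = prof,
        nCells = setNames(ncells, clusters), pseudocount = pseudocount)
}

#' Euclidean distance matrix between cluster expression profiles
#'
#' @param profiles a [ClusterProfiles-class], or a genes x clusters numeric
#'   matrix with identical gene order across columns.
#' @return symmetric non-negative matrix with zero diagonal, dimnames =
#'   cluster ids.
#' @export
clusterDistanceMatrix <- function(profiles) {
    p <- if (is(profiles, "ClusterProfiles")) profiles@profiles else profiles
    if (ncol(p) < 2L)
        stop("need at least 2 cluster profiles", call. = FALSE)
    as.matrix(stats::dist(t(p), method = "euclidean"))
}

#' Build the condition-annotated cluster graph
#'
#' Nodes are clusters with their total cell count, per-condition occupancy
#' composition and majority condition (ties broken by the lexicographically
#' smallest condition label); edges carry the raw Euclidean profile distance
#' plus a layout weight 1/(distance + eps).
#'
#' @param distmat symmetric cluster distance matrix (from
#'   [clusterDistanceMatrix()]); dimnames must be the cluster ids.
#' @param annotation a [CellAnnotation-class] over the same clusters.
#' @param eps small positive constant in the layout weight.
#' @return a [ClusterGraph-class].
#' @export
buildClusterGraph <- function(distmat, annotation, eps = 1e-9) {
    stopifnot(is(annotation, "CellAnnotation"))
    tab <- annotation@table
    clusters <- sort(unique(tab$cluster))
    if (!setequal(rownames(distmat), as.character(clusters)))
        stop("distance matrix clusters disagree with annotation clusters",
             call. = FALSE)
    distmat <- distmat[as.character(clusters), as.character(clusters)]
    conds <- sort(unique(tab$condition))
    comp <- matrix(0, length(clusters), length(conds),
                   dimnames = list(clusters, conds))
    for (i in seq_along(clusters)) {
        cc <- tab$condition[tab$cluster == clusters[i]]
        comp[i, ] <- vapply(conds, function(cn) mean(cc == cn), numeric(1))
    }
    # argmax with deterministic tie-break: conds is sorted, which.max takes
    # the first maximum, i.e. the lexicographically smallest label
    maj <- conds[apply(comp, 1L, which.max)]
    nodes <- data.frame(
        cluster = clusters,
        size = vapply(clusters, function(k) sum(tab$cluster == k), numeric(1)),
        majority_condition = maj,
        stringsAsFactors = FALSE)
    for (j in seq_along(conds)) nodes[[paste0("prop_", conds[j])]] <- comp[, j]
    pairs <- which(upper.tri(distmat), arr.ind = TRUE)
    edges <- data.frame(
        cluster_a = clusters[pairs[, 1L]],
        cluster_b = clusters[pairs[, 2L]],
        distance = distmat[pairs],
        stringsAsFactors = FALSE)
    edges$weight <- 1 / (edges$distance + eps)
    new("ClusterGraph", nodes = nodes, edges = edges)
}

#' Convert a ClusterGraph to an igraph object
#'
#' Optional convenience for layout/plotting; requires the igraph package.
#'
#' @param graph a [ClusterGraph-class].
#' @return an igraph undirected weighted graph.
#' @export
asIgraph <- function(graph) {
    if (!requireNamespace("igraph", quietly = TRUE))
        stop("asIgraph() requires the igraph package", call. = FALSE)
    stopifnot(is(graph, "ClusterGraph"))
    igraph::graph_from_data_frame(
        graph@edges, directed = FALSE,
        vertices = data.frame(name = graph@nodes$cluster,
                              graph@nodes[-1L], check.names = FALSE))
}

#' Write a ClusterGraph as node and edge CSV tables
#'
#' @param graph a [ClusterGraph-class].
#' @param dir output directory (created if needed); writes `nodes.csv` and
#'   `edges.csv`.
#' @return the directory, invisibly.
#' @export
writeClusterGraph <- function(graph, dir) {
    stopifnot(is(graph, "ClusterGraph"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    .writeFullPrecisionCsv(graph@nodes, file.path(dir, "nodes.csv"))
    .writeFullPrecisionCsv(graph@edges, file.path(dir, "edges.csv"))
    invisible(dir)
}
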