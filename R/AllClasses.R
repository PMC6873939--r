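#' @import methods
#' @importFrom stats rmultinom rnbinom rlnorm kmeans prcomp sd setNames
#' @importFrom utils read.csv write.csv read.delim
NULL

#' ClusterDistribution: cluster occupancy counts for one group of cells
#'
#' Holds the number of cells assigned to each cluster of a joint clustering
#' for one sample, condition, or pooled group. The derived proportions
#' \eqn{p_i = n_i / \sum_j n_j} are the discrete probability mass function
#' scored by all diversity and distance functions in this package.
#'
#' Cluster identifiers are kept in strictly ascending order; this canonical
#' order is what makes the discrete Kolmogorov-Smirnov distance (a maximum
#' over cumulative sums along the cluster axis) reproducible.
#'
#' @slot clusterIds integer vector of unique cluster identifiers, strictly
#'   ascending.
#' @slot counts numeric vector of non-negative integral cell counts, one per
#'   cluster, with at least one positive entry.
#' @slot label character scalar naming the group the distribution describes.
#'
#' @seealso [ClusterDistribution()] for the constructor,
#'   [hillDiversity()], [ksDistance()].
#' @export
setClass("ClusterDistribution",
    representation(
        clusterIds = "integer",
        counts = "numeric",
        label = "character"
    ),
    prototype(label = NA_character_)
)

setValidity("ClusterDistribution", function(object) {
    msg <- character()
    ids <- object@clusterIds
    n <- object@counts
    if (length(ids) != length(n))
        msg <- c(msg, "clusterIds and counts must have the same length")
    if (length(n) == 0L)
        msg <- c(msg, "distribution must have at least one cluster")
    if (anyNA(ids) || anyNA(n))
        msg <- c(msg, "clusterIds and counts must not contain NA")
    else {
        if (anyDuplicated(ids))
            msg <- c(msg, "clusterIds must be unique")
        if (is.unsorted(ids, strictly = TRUE))
            msg <- c(msg, "clusterIds must be strictly ascending")
        if (any(n < 0) || any(n != floor(n)) || any(!is.finite(n)))
            msg <- c(msg, "counts must be finite non-negative integers")
        if (length(n) > 0L && sum(n) <= 0)
            msg <- c(msg, "at least one count must be positive")
        if (sum(n) > 0 && abs(sum(n / sum(n)) - 1) > 1e-9)
            msg <- c(msg, "proportions must sum to 1 within 1e-9")
    }
    if (length(object@label) != 1L)
        msg <- c(msg, "label must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a ClusterDistribution
#'
#' @param counts non-negative integral cell counts, one per cluster. A named
#'   vector may carry the cluster ids as names.
#' @param clusterIds cluster identifiers (coerced to integer); defaults to
#'   the names of `counts` or `seq_along(counts)`. Reordered to ascending
#'   order together with `counts`.
#' @param label optional group label.
#' @return A [ClusterDistribution-class] object.
#' @examples
#' d <- ClusterDistribution(c(60, 30, 10))
#' proportions(d)
#' hillDiversity(d, q = 2)
#' @export
ClusterDistribution <- function(counts, clusterIds = NULL, label = NA_character_) {
    if (is.null(clusterIds)) {
        clusterIds <- if (!is.null(names(counts))) names(counts) else seq_along(counts)
    }
    ids <- suppressWarnings(as.integer(clusterIds))
    if (anyNA(ids))
        stop("clusterIds must be coercible to integer", call. = FALSE)
    ord <- order(ids)
    new("ClusterDistribution",
        clusterIds = ids[ord],
        counts = as.numeric(counts)[ord],
        label = as.character(label))
}

#' DiversitySpectrum: Hill diversity evaluated over a grid of orders q
#'
#' The diversity profile of one occupancy distribution: the effective number
#' of clusters \eqn{^qD} at each order \eqn{q} of a strictly increasing grid.
#' By a classical result for Hill numbers the profile is non-increasing in
#' \eqn{q}; the validity method enforces this within numerical slack.
#'
#' @slot qGrid numeric vector of orders, strictly increasing, all >= 0.
#' @slot dValues numeric vector of \eqn{^qD} values, same length as `qGrid`.
#' @slot label character scalar naming the source distribution.
#' @export
setClass("DiversitySpectrum",
    representation(
        qGrid = "numeric",
        dValues = "numeric",
        label = "character"
    ),
    prototype(label = NA_character_)
)

setValidity("DiversitySpectrum", function(object) {
    msg <- character()
    q <- object@qGrid
    d <- object@dValues
    if (length(q) != length(d))
        msg <- c(msg, "qGrid and dValues must have the same length")
    if (length(q) == 0L)
        msg <- c(msg, "spectrum must contain at least one order q")
    if (any(!is.finite(q)) || any(q < 0))
        msg <- c(msg, "qGrid must be finite and non-negative")
    if (length(q) > 1L && is.unsorted(q, strictly = TRUE))
        msg <- c(msg, "qGrid must be strictly increasing")
    if (any(!is.finite(d)) || any(d < 1 - 1e-9))
        msg <- c(msg, "dValues must be finite and >= 1")
    if (length(d) > 1L && any(diff(d) > 1e-9))
        msg <- c(msg, "dValues must be non-increasing along qGrid (within 1e-9)")
    if (length(msg)) msg else TRUE
})

#' CellAnnotation: one row per cell with sample, condition and cluster
#'
#' The central per-cell table of the pipeline: barcode (with its 10x
#' aggregation suffix), sample of origin, condition, and joint-clustering
#' cluster id. All samples share one cluster space; a sample may simply have
#' zero cells in some clusters.
#'
#' @slot table data.frame with columns `barcode`, `sample`, `condition`,
#'   `cluster` (integer).
#' @seealso [CellAnnotation()], [readAnnotations()], [occupancy()].
#' @export
setClass("CellAnnotation", representation(table = "data.frame"))

setValidity("CellAnnotation", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("barcode", "sample", "condition", "cluster")
    if (!all(need %in% names(tab)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tab) == 0L)
        msg <- c(msg, "annotation must contain at least one cell")
    if (anyDuplicated(tab$barcode))
        msg <- c(msg, "barcodes must be unique")
    if (any(is.na(tab$barcode)) || any(!nzchar(tab$barcode)))
        msg <- c(msg, "barcodes must be non-empty")
    if (any(is.na(tab$sample)) || any(!nzchar(tab$sample)))
        msg <- c(msg, "every cell needs a non-empty sample id")
    if (any(is.na(tab$condition)) || any(!nzchar(tab$condition)))
        msg <- c(msg, "every cell needs a non-empty condition")
    cl <- tab$cluster
    if (any(is.na(cl)) || !is.numeric(cl) || any(cl != floor(cl)) || any(cl < 0))
        msg <- c(msg, "cluster ids must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Construct a CellAnnotation table
#'
#' @param barcode,sample,condition,cluster per-cell vectors of equal length.
#' @return A [CellAnnotation-class] object.
#' @export
CellAnnotation <- function(barcode, sample, condition, cluster) {
    new("CellAnnotation", table = data.frame(
        barcode = as.character(barcode),
        sample = as.character(sample),
        condition = as.character(condition),
        cluster = as.integer(cluster),
        stringsAsFactors = FALSE))
}

#' ClusterProfiles: per-cluster geometric-mean expression vectors
#'
#' One column per cluster, one row per gene: the geometric mean of UMI
#' counts over the cluster's cells, computed with a pseudocount that is
#' added before the log and subtracted after, so all-zero genes profile to
#' exactly zero.
#'
#' @slot profiles numeric matrix, genes x clusters; column names are cluster
#'   ids.
#' @slot nCells named integer vector: cells per cluster.
#' @slot pseudocount numeric scalar used in the geometric mean.
#' @export
setClass("ClusterProfiles",
    representation(
        profiles = "matrix",
        nCells = "integer",
        pseudocount = "numeric"
    )
)

setValidity("ClusterProfiles", function(object) {
    msg <- character()
    if (ncol(object@profiles) != length(object@nCells))
        msg <- c(msg, "one nCells entry per profile column required")
    if (any(object@profiles < -1e-9))
        msg <- c(msg, "profiles must be non-negative")
    if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
        msg <- c(msg, "pseudocount must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' ClusterGraph: condition-annotated cluster similarity graph
#'
#' Nodes are clusters of the joint clustering with their size and condition
#' composition; edges carry the Euclidean distance between geometric-mean
#' expression profiles, plus an inverse-distance layout weight.
#'
#' @slot nodes data.frame with columns `cluster`, `size`,
#'   `majority_condition` and one `prop_<condition>` column per condition.
#' @slot edges data.frame with columns `cluster_a`, `cluster_b`, `distance`,
#'   `weight`.
#' @export
setClass("ClusterGraph",
    representation(nodes = "data.frame", edges = "data.frame"))

setValidity("ClusterGraph", function(object) {
    msg <- character()
    nd <- object@nodes
    ed <- object@edges
    if (!all(c("cluster", "size", "majority_condition") %in% names(nd)))
        msg <- c(msg, "nodes need cluster, size, majority_condition columns")
    if (!all(c("cluster_a", "cluster_b", "distance", "weight") %in% names(ed)))
        msg <- c(msg, "edges need cluster_a, cluster_b, distance, weight columns")
    propcols <- grep("^prop_", names(nd))
    if (length(propcols)) {
        s <- rowSums(nd[, propcols, drop = FALSE])
        if (any(abs(s - 1) > 1e-9))
            msg <- c(msg, "condition proportions per node must sum to 1")
    }
    if (nrow(ed) && any(ed$distance < 0))
        msg <- c(msg, "edge distances must be non-negative")
    if (length(msg)) msg else TRUE
})

#' DownsampleResult: diversity of repeated cell subsamples
#'
#' Result of the downsampling stability protocol: \eqn{^qD} recomputed on
#' many random subsets of a group's cells at a fixed fraction, against the
#' full-data baseline.
#'
#' @slot label group (sample or condition) that was downsampled.
#' @slot qValues orders q at which diversity was evaluated.
#' @slot replicateD numeric matrix, replicates x length(qValues).
#' @slot baselineD full-data \eqn{^qD} per q.
#' @slot fraction subsample fraction in (0, 1].
#' @slot nReplicates number of replicates.
#' @slot seed master seed the replicate streams were derived from.
#' @slot reclustered logical: were labels re-derived per replicate?
#' @export
setClass("DownsampleResult",
    representation(
        label = "character",
        qValues = "numeric",
        replicateD = "matrix",
        baselineD = "numeric",
        fraction = "numeric",
        nReplicates = "integer",
        seed = "integer",
        reclustered = "logical"
    )
)

setValidity("DownsampleResult", function(object) {
    msg <- character()
    if (ncol(object@replicateD) != length(object@qValues))
        msg <- c(msg, "replicateD needs one column per q value")
    if (nrow(object@replicateD) != object@nReplicates)
        msg <- c(msg, "replicateD needs one row per replicate")
    if (length(object@baselineD) != length(object@qValues))
        msg <- c(msg, "baselineD needs one entry per q value")
    if (any(!is.finite(object@replicateD)) || any(object@replicateD < 1 - 1e-9))
        msg <- c(msg, "replicate diversities must be finite and >= 1")
    if (object@fraction <= 0 || object@fraction > 1)
        msg <- c(msg, "fraction must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' ScenarioSpec: parameters of a synthetic single-cell cohort
#'
#' Describes a cohort with known clonal structure: conditions with several
#' samples each, per-condition cluster occupancy proportions over a shared
#' cluster space, and per-cluster negative-binomial expression programs
#' (log-normal gene means, shared dispersion).
#'
#' @slot conditions named integer vector: samples per condition.
#' @slot proportions named list, one numeric proportion vector per condition
#'   over the shared cluster space (entries sum to 1; zeros allowed).
#' @slot nCellsPerSample integer: cells simulated per sample.
#' @slot nGenes integer: genes in the expression matrix.
#' @slot meanLog,sdLog log-normal parameters of per-cluster gene means.
#' @slot dispersion negative-binomial size parameter shared by all genes.
#' @slot name scenario label.
#' @export
setClass("ScenarioSpec",
    representation(
        conditions = "integer",
        proportions = "list",
        nCellsPerSample = "integer",
        nGenes = "integer",
        meanLog = "numeric",
        sdLog = "numeric",
        dispersion = "numeric",
        name = "character"
    ),
    prototype(meanLog = 1, sdLog = 2, dispersion = 5, name = "scenario")
)

setValidity("ScenarioSpec", function(object) {
    msg <- character()
    if (length(object@conditions) == 0L || is.null(names(object@conditions)))
        msg <- c(msg, "conditions must be a named vector (samples per condition)")
    else if (any(object@conditions < 1))
        msg <- c(msg, "conditions: every condition needs >= 1 sample")
    if (!identical(sort(names(object@proportions)), sort(names(object@conditions))))
        msg <- c(msg, "proportions must name exactly the conditions")
    ncl <- unique(vapply(object@proportions, length, 1L))
    if (length(ncl) > 1L)
        msg <- c(msg, "proportions: all conditions must share one cluster space")
    for (cn in names(object@proportions)) {
        p <- object@proportions[[cn]]
        if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, sprintf("proportions[%s]: entries must be >= 0 and sum to 1", cn))
    }
    if (object@nCellsPerSample < 1L) msg <- c(msg, "nCellsPerSample must be >= 1")
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@sdLog <= 0) msg <- c(msg, "sdLog must be > 0")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a ScenarioSpec
#'
#' @param conditions named integer vector: samples per condition.
#' @param proportions named list of per-condition cluster proportion vectors
#'   over a shared cluster space.
#' @param nCellsPerSample cells per simulated sample.
#' @param nGenes genes in the simulated matrix.
#' @param meanLog,sdLog log-normal parameters for per-cluster gene means.
#' @param dispersion shared negative-binomial size parameter.
#' @param name scenario label.
#' @return A [ScenarioSpec-class] object.
#' @export
ScenarioSpec <- function(conditions, proportions, nCellsPerSample = 1000L,
                         nGenes = 200L, meanLog = 1, sdLog = 2,
                         dispersion = 5, name = "scenario") {
    new("ScenarioSpec",
        conditions = setNames(as.integer(conditions), names(conditions)),
        proportions = lapply(proportions, as.numeric),
        nCellsPerSample = as.integer(nCellsPerSample),
        nGenes = as.integer(nGenes),
        meanLog = meanLog, sdLog = sdLog, dispersion = dispersion,
        name = name)
}
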