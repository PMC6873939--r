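#' @rdname ClusterDistribution-class
#' @param object,x a package object
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname ClusterDistribution-class
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' @rdname ClusterDistribution-class
#' @export
setGeneric("proportions")

#' Hill diversity of order q (effective number of clusters)
#'
#' @param x a [ClusterDistribution-class], or a numeric vector of
#'   non-negative abundances/counts (normalized internally).
#' @param q a single non-negative finite order.
#' @return the effective number of clusters \eqn{^qD}.
#' @export
setGeneric("hillDiversity", function(x, q) standardGeneric("hillDiversity"))

#' Diversity profile over a grid of orders
#'
#' @param x a [ClusterDistribution-class] or numeric abundance vector.
#' @param qGrid strictly increasing non-negative orders; defaults to
#'   [defaultQGrid()].
#' @param label label for the resulting spectrum.
#' @return a [DiversitySpectrum-class].
#' @export
setGeneric("diversitySpectrum",
    function(x, qGrid = defaultQGrid(), label = NA_character_)
        standardGeneric("diversitySpectrum"))

#' Classical diversity indices of a cluster occupancy distribution
#'
#' @param x a [ClusterDistribution-class] or numeric abundance vector.
#' @return named list: `richness`, `shannon_log`, `simpson_inverse`,
#'   `berger_parker`.
#' @export
setGeneric("namedIndices", function(x) standardGeneric("namedIndices"))

#' Cluster occupancy distribution of a sample or condition
#'
#' @param x a [CellAnnotation-class].
#' @param group a sample id or condition label present in `x`.
#' @param by `"sample"` or `"condition"`.
#' @param clusterSpace ordered cluster ids to align counts to; must contain
#'   every cluster observed in the group. Defaults to all clusters in `x`.
#' @return a [ClusterDistribution-class] aligned to `clusterSpace`.
#' @export
setGeneric("occupancy",
    function(x, group, by = c("sample", "condition"), clusterSpace = NULL)
        standardGeneric("occupancy"))

#' Downsample cells without replacement
#'
#' @param x a [CellAnnotation-class].
#' @param fraction fraction of cells to keep, in (0, 1]; `floor(fraction *
#'   n)` cells are drawn uniformly without replacement.
#' @param seed integer seed making the draw deterministic.
#' @return a [CellAnnotation-class] subset.
#' @export
setGeneric("downsampleCells",
    function(x, fraction, seed) standardGeneric("downsampleCells"))

#' Relative-change summary of a downsampling experiment
#'
#' @param result a [DownsampleResult-class].
#' @return list with `normalized` (replicates x q matrix, each column
#'   divided by its mean), `absolute_change` (replicate minus baseline), and
#'   a `summary` data.frame per q.
#' @export
setGeneric("relativeChange", function(result) standardGeneric("relativeChange"))

#' Simulate a synthetic cohort with known clonal structure
#'
#' @param spec a [ScenarioSpec-class].
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list with `matrix` (sparse genes x cells UMI counts),
#'   `annotation` ([CellAnnotation-class]), and `truth` (per-sample true
#'   proportion vectors over the shared cluster space).
#' @export
setGeneric("simulateCohort", function(spec, seed) standardGeneric("simulateCohort"))
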