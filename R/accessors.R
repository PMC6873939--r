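#' @describeIn ClusterDistribution-class cluster identifiers
#' @export
setMethod("clusterIds", "ClusterDistribution", function(x) x@clusterIds)

#' @describeIn ClusterDistribution-class cell counts per cluster
#' @export
setMethod("cellCounts", "ClusterDistribution", function(x)
    setNames(x@counts, x@clusterIds))

#' @describeIn ClusterDistribution-class occupancy proportions p_i
#' @param margin ignored (base-R compatibility)
#' @export
setMethod("proportions", "ClusterDistribution", function(x, margin = NULL)
    setNames(x@counts / sum(x@counts), x@clusterIds))

setMethod("show", "ClusterDistribution", function(object) {
    occ <- sum(object@counts > 0)
    cat(sprintf(
        "ClusterDistribution '%s': %d cells over %d clusters (%d occupied)\n",
        object@label, sum(object@counts), length(object@counts), occ))
})

#' @describeIn DiversitySpectrum-class orders q
#' @export
setGeneric("qGrid", function(x) standardGeneric("qGrid"))

#' @rdname DiversitySpectrum-class
#' @export
setMethod("qGrid", "DiversitySpectrum", function(x) x@qGrid)

#' @describeIn DiversitySpectrum-class effective numbers per order
#' @export
setGeneric("dValues", function(x) standardGeneric("dValues"))

#' @rdname DiversitySpectrum-class
#' @export
setMethod("dValues", "DiversitySpectrum", function(x)
    setNames(x@dValues, x@qGrid))

#' @describeIn DiversitySpectrum-class spectrum as a data.frame
#' @param x a DiversitySpectrum
#' @param ... ignored
#' @export
as.data.frame.DiversitySpectrum <- function(x, ...) {
    data.frame(label = x@label, q = x@qGrid, d = x@dValues,
               stringsAsFactors = FALSE)
}

setMethod("show", "DiversitySpectrum", function(object) {
    cat(sprintf("DiversitySpectrum '%s': %d orders on [%g, %g], ^qD in [%.4g, %.4g]\n",
        object@label, length(object@qGrid), min(object@qGrid),
        max(object@qGrid), min(object@dValues), max(object@dValues)))
})

#' @describeIn CellAnnotation-class annotation as a data.frame
#' @param x a CellAnnotation
#' @param ... ignored
#' @export
as.data.frame.CellAnnotation <- function(x, ...) x@table

#' Number of cells in a CellAnnotation
#' @param x a [CellAnnotation-class]
#' @export
setMethod("length", "CellAnnotation", function(x) nrow(x@table))

#' @describeIn CellAnnotation-class sample ids present
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname CellAnnotation-class
#' @export
setMethod("sampleIds", "CellAnnotation", function(x) unique(x@table$sample))

#' @describeIn CellAnnotation-class condition labels present
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname CellAnnotation-class
#' @export
setMethod("conditionLabels", "CellAnnotation", function(x)
    unique(x@table$condition))

#' @describeIn CellAnnotation-class shared cluster space (ascending ids)
#' @export
setGeneric("clusterSpace", function(x) standardGeneric("clusterSpace"))

#' @rdname CellAnnotation-class
#' @export
setMethod("clusterSpace", "CellAnnotation", function(x)
    sort(unique(x@table$cluster)))

setMethod("show", "CellAnnotation", function(object) {
    tab <- object@table
    cat(sprintf(
        "CellAnnotation: %d cells, %d samples, %d conditions, %d clusters\n",
        nrow(tab), length(unique(tab$sample)),
        length(unique(tab$condition)), length(unique(tab$cluster))))
})

#' @describeIn ClusterProfiles-class genes x clusters profile matrix
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ClusterProfiles-class
#' @param x a ClusterProfiles
#' @export
setMethod("profileMatrix", "ClusterProfiles", function(x) x@profiles)

setMethod("show", "ClusterProfiles", function(object) {
    cat(sprintf(
        "ClusterProfiles: %d genes x %d clusters (pseudocount %g)\n",
        nrow(object@profiles), ncol(object@profiles), object@pseudocount))
})

#' @describeIn ClusterGraph-class node table
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname ClusterGraph-class
#' @param x a ClusterGraph
#' @export
setMethod("graphNodes", "ClusterGraph", function(x) x@nodes)

#' @describeIn ClusterGraph-class edge table
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname ClusterGraph-class
#' @export
setMethod("graphEdges", "ClusterGraph", function(x) x@edges)

setMethod("show", "ClusterGraph", function(object) {
    cat(sprintf("ClusterGraph: %d clusters, %d edges\n",
        nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "DownsampleResult", function(object) {
    cat(sprintf(
        "DownsampleResult '%s': %d replicates at fraction %g over q = {%s}%s\n",
        object@label, object@nReplicates, object@fraction,
        paste(object@qValues, collapse = ", "),
        if (object@reclustered) " (reclustered per replicate)" else ""))
})

setMethod("show", "ScenarioSpec", function(object) {
    cat(sprintf(
        "ScenarioSpec '%s': %d conditions (%s), %d cells/sample, %d genes, %d clusters\n",
        object@name, length(object@conditions),
        paste(sprintf("%s x%d", names(object@conditions), object@conditions),
              collapse = ", "),
        object@nCellsPerSample, object@nGenes,
        length(object@proportions[[1]])))
})
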