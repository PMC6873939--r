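# Synthetic cohorts with known clonal structure.
#
# Cells are assigned to clusters by multinomial draws from their sample's
# condition-specific proportion vector; UMI counts come from per-cluster
# negative-binomial expression programs with log-normal gene means and a
# shared dispersion. The generator exists so every pipeline stage is
# testable against analytic ground truth; it makes no biological claims.

# 16-base barcodes, unique by construction: a bijective affine map of the
# cell index modulo 4^16 (odd multiplier), with a random offset so that
# different seeds give different barcode sets
.randomBarcodes <- function(n, start = 0L) {
    base <- 4294967296  # 4^16, exact in double precision
    offset <- floor(stats::runif(1) * base)
    j <- (offset + (start + seq_len(n) - 1) * 2654435761) %% base
    chars <- c("A", "C", "G", "T")
    vapply(j, function(x) {
        d <- integer(16L)
        for (k in 1:16) { d[k] <- x %% 4; x <- x %/% 4 }
        paste(chars[d + 1L], collapse = "")
    }, character(1))
}

#' @describeIn simulateCohort multinomial cluster assignment + NB counts
#' @export
setMethod("simulateCohort", "ScenarioSpec", function(spec, seed) {
    validObject(spec)
    old <- .getRandomSeed()
    on.exit(.restoreRandomSeed(old))
    set.seed(as.integer(seed))
    nClusters <- length(spec@proportions[[1L]])
    # one expression program per cluster: log-normal per-gene means
    programs <- matrix(rlnorm(spec@nGenes * nClusters,
                              meanlog = spec@meanLog, sdlog = spec@sdLog),
                       spec@nGenes, nClusters)
    geneIds <- sprintf("GENE%04d", seq_len(spec@nGenes))
    rows <- list(); truth <- list()
    suffix <- 0L
    for (cond in names(spec@conditions)) {
        p <- spec@proportions[[cond]]
        for (s in seq_len(spec@conditions[[cond]])) {
            suffix <- suffix + 1L
            sid <- sprintf("%s_s%d", cond, s)
            n <- spec@nCellsPerSample
            cl <- sample.int(nClusters, n, replace = TRUE, prob = p)
            bc <- paste0(.randomBarcodes(n), "-", suffix)
            rows[[sid]] <- data.frame(
                barcode = bc, sample = sid, condition = cond,
                cluster = cl, stringsAsFactors = FALSE)
            truth[[sid]] <- setNames(p, seq_len(nClusters))
        }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    counts <- matrix(rnbinom(spec@nGenes * nrow(tab),
                             size = spec@dispersion,
                             mu = programs[, tab$cluster]),
                     spec@nGenes, nrow(tab),
                     dimnames = list(geneIds, tab$barcode))
    list(matrix = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         annotation = new("CellAnnotation", table = tab),
         truth = truth)
})

#' Preset synthetic scenarios spanning the diversity range
#'
#' Four labelled scenarios over a shared 16-cluster space, covering the
#' qualitative ordering the diversity profile is designed to resolve:
#' \describe{
#'   \item{healthy-like}{a few dominant clusters, steep abundance decay —
#'     low evenness, low effective cluster number.}
#'   \item{aml-like}{more occupied clusters with a flatter decay, so its
#'     profile dominates the healthy-like one at every order q.}
#'   \item{polyclonal-cd34-like}{uniform over all 16 clusters — the profile
#'     is constant at 16, the maximal diversity preset.}
#'   \item{homogeneous-sorted-like}{one dominant cluster with trace
#'     occupancy elsewhere — profile close to 1 at high q.}
#' }
#' The proportion vectors are synthetic inventions chosen once for their
#' ordering properties; `^qD(aml-like) > ^qD(healthy-like)` holds for every
#' q by construction. Analytic ground truth is available via
#' [trueSpectrum()].
#'
#' @param nCellsPerSample,nGenes cohort size knobs shared by all presets.
#' @return named list of [ScenarioSpec-class] objects, each single-condition
#'   with two samples; combine presets with [combineScenarios()] for a
#'   case/control cohort.
#' @export
presetScenarios <- function(nCellsPerSample = 1500L, nGenes = 300L) {
    S <- 16L
    pad <- function(p) c(p / sum(p), rep(0, S - length(p)))
    props <- list(
        "healthy-like" = pad(0.55^(0:7)),          # 8 occupied, steep decay
        "aml-like" = pad(0.82^(0:13)),             # 14 occupied, flat decay
        "polyclonal-cd34-like" = rep(1 / S, S),    # uniform
        "homogeneous-sorted-like" = pad(c(0.94, rep(0.01, 6)))
    )
    out <- lapply(names(props), function(nm) {
        ScenarioSpec(
            conditions = setNames(2L, nm),
            proportions = setNames(list(props[[nm]]), nm),
            nCellsPerSample = nCellsPerSample, nGenes = nGenes,
            name = nm)
    })
    setNames(out, names(props))
}

#' Combine single-condition scenarios into one multi-condition cohort
#'
#' @param ... [ScenarioSpec-class] objects with disjoint condition names and
#'   equal cluster-space size.
#' @param name name for the combined scenario.
#' @return a [ScenarioSpec-class] covering all conditions.
#' @export
combineScenarios <- function(..., name = "combined") {
    specs <- list(...)
    stopifnot(length(specs) >= 2L)
    conds <- do.call(c, lapply(specs, function(s) s@conditions))
    props <- do.call(c, lapply(specs, function(s) s@proportions))
    if (anyDuplicated(names(conds)))
        stop("condition names must be disjoint", call. = FALSE)
    base <- specs[[1L]]
    new("ScenarioSpec", conditions = conds, proportions = props,
        nCellsPerSample = base@nCellsPerSample, nGenes = base@nGenes,
        meanLog = base@meanLog, sdLog = base@sdLog,
        dispersion = base@dispersion, name = name)
}

#' Analytic diversity spectrum of a scenario's true proportions
#'
#' @param spec a [ScenarioSpec-class].
#' @param condition which condition's proportion vector to use (default the
#'   first).
#' @param qGrid orders; default [defaultQGrid()].
#' @return a [DiversitySpectrum-class] of the exact mixing proportions —
#'   the ground truth that pipeline estimates are compared against.
#' @export
trueSpectrum <- function(spec, condition = names(spec@conditions)[1L],
                         qGrid = defaultQGrid()) {
    stopifnot(is(spec, "ScenarioSpec"))
    p <- spec@proportions[[condition]]
    if (is.null(p))
        stop("unknown condition: ", condition, call. = FALSE)
    diversitySpectrum(p, qGrid, label = paste0(spec@name, ":", condition))
}
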