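# Hill-number diversity of cluster occupancy distributions.
#
# ^qD = (sum_i p_i^q)^(1/(1-q)) over occupied clusters only, with the
# analytic exp-Shannon branch at q = 1. Evaluated in log space so that
# orders as large as q = 100 do not underflow (p^100 underflows double
# precision already for p < ~0.02).

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# p: proportions over occupied clusters only (all > 0, sum to 1)
.hillFromP <- function(p, q) {
    if (abs(q - 1) < 1e-9)
        return(exp(-sum(p * log(p))))
    if (q == 0)
        return(as.numeric(length(p)))
    exp(.logSumExp(q * log(p)) / (1 - q))
}

.checkQ <- function(q) {
    if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
        stop("order q must be a single finite non-negative number", call. = FALSE)
}

.occupiedP <- function(x) {
    if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x < 0))
        stop("abundances must be finite and non-negative", call. = FALSE)
    if (sum(x) <= 0)
        stop("invalid distribution: all counts are zero", call. = FALSE)
    p <- x[x > 0]
    p / sum(p)
}

#' @describeIn hillDiversity occupancy distribution input
#' @export
setMethod("hillDiversity", "ClusterDistribution", function(x, q) {
    .checkQ(q)
    .hillFromP(.occupiedP(x@counts), q)
})

#' @describeIn hillDiversity raw abundance vector (counts or proportions)
#' @export
setMethod("hillDiversity", "numeric", function(x, q) {
    .checkQ(q)
    .hillFromP(.occupiedP(x), q)
})

#' Default grid of diversity orders
#'
#' 100 points log-spaced on \eqn{[10^{-2}, 10^2]}, always augmented with the
#' exact anchor orders 0.01, 0.1, 1, 2, 10 and 100 at which named indices
#' live (richness-like, exp-Shannon, inverse Simpson, dominance).
#'
#' @param qMin,qMax grid range (both > 0).
#' @param nPoints number of log-spaced points.
#' @return strictly increasing numeric vector of orders.
#' @export
defaultQGrid <- function(qMin = 1e-2, qMax = 1e2, nPoints = 100L) {
    if (qMin <= 0 || qMax <= qMin)
        stop("need 0 < qMin < qMax", call. = FALSE)
    grid <- exp(seq(log(qMin), log(qMax), length.out = nPoints))
    anchors <- c(0.01, 0.1, 1, 2, 10, 100)
    sort(unique(c(grid, anchors[anchors >= qMin & anchors <= qMax])))
}

#' Anchor orders of the diversity profile
#'
#' The six orders at which the downsampling protocol and the acceptance
#' summaries evaluate the profile: 0.01, 0.1, 1, 2, 10, 100.
#' @return numeric vector of length 6.
#' @export
anchorQValues <- function() c(0.01, 0.1, 1, 2, 10, 100)

.spectrumFromP <- function(p, qGrid, label) {
    if (length(qGrid) == 0L)
        stop("qGrid must not be empty", call. = FALSE)
    if (any(!is.finite(qGrid)) || any(qGrid < 0))
        stop("qGrid must be finite and non-negative", call. = FALSE)
    if (is.unsorted(qGrid, strictly = TRUE))
        stop("qGrid must be strictly increasing", call. = FALSE)
    d <- vapply(qGrid, function(q) .hillFromP(p, q), numeric(1))
    new("DiversitySpectrum", qGrid = as.numeric(qGrid), dValues = d,
        label = as.character(label))
}

#' @describeIn diversitySpectrum occupancy distribution input
#' @export
setMethod("diversitySpectrum", "ClusterDistribution",
    function(x, qGrid = defaultQGrid(), label = NA_character_) {
        if (is.na(label) && !is.na(x@label)) label <- x@label
        .spectrumFromP(.occupiedP(x@counts), qGrid, label)
    })

#' @describeIn diversitySpectrum raw abundance vector
#' @export
setMethod("diversitySpectrum", "numeric",
    function(x, qGrid = defaultQGrid(), label = NA_character_) {
        .spectrumFromP(.occupiedP(x), qGrid, label)
    })

.namedFromP <- function(p) {
    list(
        richness = as.numeric(length(p)),
        shannon_log = -sum(p * log(p)),
        simpson_inverse = 1 / sum(p^2),
        berger_parker = 1 / max(p)
    )
}

#' @describeIn namedIndices occupancy distribution input
#' @export
setMethod("namedIndices", "ClusterDistribution",
    function(x) .namedFromP(.occupiedP(x@counts)))

#' @describeIn namedIndices raw abundance vector
#' @export
setMethod("namedIndices", "numeric",
    function(x) .namedFromP(.occupiedP(x)))

#' Write one or more diversity spectra as long-format CSV
#'
#' One row per grid point with header `label,q,d`, full double precision.
#'
#' @param spectra a [DiversitySpectrum-class] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSpectrumCsv <- function(spectra, path) {
    if (is(spectra, "DiversitySpectrum")) spectra <- list(spectra)
    rows <- do.call(rbind, lapply(spectra, function(s) {
        data.frame(label = s@label, q = s@qGrid, d = s@dValues,
                   stringsAsFactors = FALSE)
    }))
    .writeFullPrecisionCsv(rows, path)
    invisible(path)
}

# write.csv at full double precision (format() would round)
.writeFullPrecisionCsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a long-format spectrum CSV back into DiversitySpectrum objects
#'
#' @param path CSV written by [writeSpectrumCsv()].
#' @return named list of [DiversitySpectrum-class] objects.
#' @export
readSpectrumCsv <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("label", "q", "d") %in% names(df)))
        stop("spectrum CSV needs columns label,q,d: ", path, call. = FALSE)
    out <- lapply(split(df, df$label), function(s) {
        s <- s[order(s$q), ]
        new("DiversitySpectrum", qGrid = s$q, dValues = s$d,
            label = s$label[1])
    })
    out[unique(df$label)]
}
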