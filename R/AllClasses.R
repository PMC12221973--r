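#' @import methods
NULL

#' ContactMatrix: a per-chromosome binned contact matrix
#'
#' Symmetric raw contact counts for one chromosome together with its bin
#' table (0-based, half-open, fixed-width bins with a possibly short
#' terminal bin), per-bin ICE balancing weights and a validity mask.
#' Invalid bins (unmappable or low coverage) carry `NA` weights.
#'
#' @slot chrom chromosome identifier.
#' @slot binSize bin width in bp.
#' @slot bins data.frame with `start`/`end` columns (bp).
#' @slot counts symmetric numeric matrix of raw counts.
#' @slot weights per-bin balancing weight; `NA` for invalid bins.
#' @slot valid logical mask of usable bins.
#' @slot balanced has \code{\link{iceBalance}} been run.
#'
#' @exportClass ContactMatrix
setClass("ContactMatrix", slots = c(
    chrom    = "character",
    binSize  = "numeric",
    bins     = "data.frame",
    counts   = "matrix",
    weights  = "numeric",
    valid    = "logical",
    balanced = "logical"
))

setValidity("ContactMatrix", function(object) {
    n <- nrow(object@counts)
    msg <- character()
    if (ncol(object@counts) != n)
        msg <- c(msg, "counts must be square")
    if (nrow(object@bins) != n)
        msg <- c(msg, "bin table and counts dimensions differ")
    if (length(object@weights) != n || length(object@valid) != n)
        msg <- c(msg, "weights/valid length must match bin count")
    if (any(object@counts < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    if (n > 0 && max(abs(object@counts - t(object@counts))) > 1e-8 * (1 + max(abs(object@counts))))
        msg <- c(msg, "counts must be symmetric")
    if (n > 0) {
        if (any(diff(object@bins$start) <= 0))
            msg <- c(msg, "bin table must be sorted with positive widths")
        if (any(object@bins$end <= object@bins$start))
            msg <- c(msg, "bins must have end > start")
    }
    if (any(!is.na(object@weights) & !object@valid))
        msg <- c(msg, "invalid bins must not carry weights")
    if (length(msg)) msg else TRUE
})

#' EigenProfile: leading eigenvectors of the cis O/E correlation matrix
#'
#' Holds the first few eigenvectors (unit norm) of the Pearson-correlation
#' matrix of a chromosome's observed/expected map, the index of the
#' eigenvector selected as the compartment signal, and its (rank)
#' correlation with the orientation reference after sign-orientation.
#'
#' @slot chrom chromosome identifier.
#' @slot vectors bins x nVec matrix of eigenvectors (`NA` rows = invalid bins).
#' @slot eigenvalues the corresponding eigenvalues.
#' @slot selected index of the compartment eigenvector.
#' @slot refCor rank correlation of the selected vector with the reference
#'   (non-negative after orientation).
#' @slot ambiguous TRUE when the two leading eigenvalues are (near-)tied.
#'
#' @exportClass EigenProfile
setClass("EigenProfile", slots = c(
    chrom       = "character",
    vectors     = "matrix",
    eigenvalues = "numeric",
    selected    = "integer",
    refCor      = "numeric",
    ambiguous   = "logical"
))

setValidity("EigenProfile", function(object) {
    msg <- character()
    if (object@selected < 1L || object@selected > ncol(object@vectors))
        msg <- c(msg, "selected eigenvector index out of range")
    nrm <- sqrt(sum(object@vectors[, object@selected]^2, na.rm = TRUE))
    if (abs(nrm - 1) > 1e-6)
        msg <- c(msg, "eigenvectors must be unit norm")
    if (!is.na(object@refCor) && object@refCor < -1e-12)
        msg <- c(msg, "selected vector must be oriented towards the reference")
    if (length(msg)) msg else TRUE
})

#' CompartmentSegments: per-bin A/I/B states and merged intervals
#'
#' @slot chrom chromosome identifier.
#' @slot binSize bin width in bp.
#' @slot states per-bin state factor with levels B, I, A (`NA` = invalid bin).
#' @slot intervals merged same-state runs (data.frame: start/end bin, state).
#' @slot limits bin indices of state-change points (compartment limits).
#' @slot thresholds numeric c(BI, IA) eigenvalue thresholds, BI < IA.
#'
#' @exportClass CompartmentSegments
setClass("CompartmentSegments", slots = c(
    chrom      = "character",
    binSize    = "numeric",
    states     = "factor",
    intervals  = "data.frame",
    limits     = "integer",
    thresholds = "numeric"
))

setValidity("CompartmentSegments", function(object) {
    msg <- character()
    if (length(object@thresholds) != 2L || !(object@thresholds[1] < object@thresholds[2]))
        msg <- c(msg, "thresholds must be ordered B-I < I-A")
    if (!identical(levels(object@states), c("B", "I", "A")))
        msg <- c(msg, "state levels must be B, I, A")
    if (length(msg)) msg else TRUE
})

#' BoundarySet: insulation minima with prominence, strength class and feature class
#'
#' @slot chrom chromosome identifier.
#' @slot binSize bin width (bp) of the profile the boundaries were called on.
#' @slot bin 1-based bin indices of the boundaries.
#' @slot strength topographic prominence of the insulation minimum.
#' @slot strong logical; strength >= the Li threshold.
#' @slot class one of loop-anchor, TSS, accessible, compartment-limit, unassigned.
#' @slot liThreshold the minimum cross-entropy threshold used for the split.
#'
#' @exportClass BoundarySet
setClass("BoundarySet", slots = c(
    chrom       = "character",
    binSize     = "numeric",
    bin         = "integer",
    strength    = "numeric",
    strong      = "logical",
    featureClass = "character",
    liThreshold = "numeric"
))

setValidity("BoundarySet", function(object) {
    msg <- character()
    nb <- length(object@bin)
    if (length(object@strength) != nb || length(object@strong) != nb ||
        length(object@featureClass) != nb)
        msg <- c(msg, "per-boundary slots must have equal length")
    if (any(object@strength < 0, na.rm = TRUE))
        msg <- c(msg, "strengths must be non-negative")
    ok <- c("loop-anchor", "TSS", "accessible", "compartment-limit", "unassigned")
    if (!all(object@featureClass %in% ok))
        msg <- c(msg, "unknown boundary class")
    if (length(msg)) msg else TRUE
})

#' LoopSet: focal chromatin loops as anchor-pair bins
#'
#' @slot chrom chromosome identifier.
#' @slot binSize bin width in bp.
#' @slot anchor1 1-based bin index of the upstream anchor (anchor1 < anchor2).
#' @slot anchor2 1-based bin index of the downstream anchor.
#' @slot enrichment O/E value at the peak pixel.
#' @slot count raw count at the peak pixel.
#' @slot apa per-loop APA score (`NA` before \code{\link{apaScore}} is run).
#' @slot anchorWidth anchor interval width in bins.
#'
#' @exportClass LoopSet
setClass("LoopSet", slots = c(
    chrom       = "character",
    binSize     = "numeric",
    anchor1     = "integer",
    anchor2     = "integer",
    enrichment  = "numeric",
    count       = "numeric",
    apa         = "numeric",
    anchorWidth = "integer"
))

setValidity("LoopSet", function(object) {
    msg <- character()
    if (any(object@anchor1 >= object@anchor2))
        msg <- c(msg, "anchor1 must precede anchor2")
    if (any(object@apa <= 0, na.rm = TRUE))
        msg <- c(msg, "APA scores must be positive")
    if (length(msg)) msg else TRUE
})

#' RegionPairSet: foreground/background regions with flanking-gene anchors
#'
#' Produced by \code{\link{mapRegionToFlankingGenes}}; consumed by
#' \code{\link{syntenyConservationTest}}. Carries, for each region, the two
#' flanking anchor genes in species A, their orthologous counterparts in
#' species B, and the per-region shared-orthogroup count.
#'
#' @slot foreground data.frame of mapped foreground regions.
#' @slot background data.frame of mapped background regions.
#' @slot genesA species-A gene table.
#' @slot genesB species-B gene table.
#' @slot orthology two-column orthology table (gene, orthogroup per species).
#' @slot unmappable counts of regions dropped for missing anchors/orthologs.
#'
#' @exportClass RegionPairSet
setClass("RegionPairSet", slots = c(
    foreground = "data.frame",
    background = "data.frame",
    genesA     = "data.frame",
    genesB     = "data.frame",
    orthology  = "data.frame",
    unmappable = "numeric"
))
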