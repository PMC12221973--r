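#' Construct a ContactMatrix
#'
#' Wraps a symmetric raw count matrix into a \linkS4class{ContactMatrix}.
#' Bins are fixed-width, 0-based half-open; the terminal bin may be short
#' when `chromLength` is given and is not a multiple of `binSize`.
#'
#' @param counts symmetric, non-negative numeric matrix.
#' @param binSize bin width in bp.
#' @param chrom chromosome name.
#' @param chromLength chromosome length in bp (default `nbins * binSize`).
#' @param valid optional logical mask of usable bins; bins with zero
#'   marginal are always flagged invalid.
#' @return A \linkS4class{ContactMatrix}.
#' @examples
#' cm <- contactMatrix(matrix(1, 4, 4), binSize = 1000)
#' nbins(cm)
#' @export
contactMatrix <- function(counts, binSize, chrom = "chr1",
                          chromLength = NULL, valid = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    n <- nrow(counts)
    if (is.null(chromLength)) chromLength <- n * binSize
    start <- seq(0, by = binSize, length.out = n)
    end <- pmin(start + binSize, chromLength)
    if (is.null(valid)) valid <- rep(TRUE, n)
    valid <- valid & rowSums(counts, na.rm = TRUE) > 0
    counts[!valid, ] <- 0
    counts[, !valid] <- 0
    new("ContactMatrix",
        chrom = chrom, binSize = as.numeric(binSize),
        bins = data.frame(start = start, end = end),
        counts = counts,
        weights = rep(NA_real_, n),
        valid = valid,
        balanced = FALSE)
}

#' @rdname contactMatrix
#' @param x,object a ContactMatrix.
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' @rdname contactMatrix
#' @export
setMethod("nbins", "ContactMatrix", function(x) nrow(x@counts))

#' @rdname contactMatrix
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname contactMatrix
#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

#' @rdname contactMatrix
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname contactMatrix
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)

#' @rdname contactMatrix
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @rdname contactMatrix
#' @export
setMethod("binTable", "ContactMatrix", function(x) x@bins)

#' @rdname contactMatrix
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname contactMatrix
#' @export
setMethod("rawCounts", "ContactMatrix", function(x) x@counts)

#' @rdname contactMatrix
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))

#' @rdname contactMatrix
#' @export
setMethod("validBins", "ContactMatrix", function(x) x@valid)

#' @rdname contactMatrix
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))

#' @rdname contactMatrix
#' @export
setMethod("balancingWeights", "ContactMatrix", function(x) x@weights)

#' @rdname contactMatrix
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname contactMatrix
#' @export
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)

#' Balanced (ICE-corrected) matrix
#'
#' Returns `counts * w_i * w_j` with `NA` at invalid bins. Requires
#' \code{\link{iceBalance}} to have been run.
#'
#' @param x a balanced \linkS4class{ContactMatrix}.
#' @return numeric matrix with `NA` rows/columns at invalid bins.
#' @export
setGeneric("balancedMatrix", function(x) standardGeneric("balancedMatrix"))

#' @rdname balancedMatrix
#' @export
setMethod("balancedMatrix", "ContactMatrix", function(x) {
    if (!x@balanced)
        stop("matrix is not balanced; run iceBalance() first")
    w <- x@weights
    b <- x@counts * outer(w, w)
    b[!x@valid, ] <- NA_real_
    b[, !x@valid] <- NA_real_
    b
})

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix:", object@chrom, "\n")
    cat("  bins:", nbins(object), "x", format(object@binSize, big.mark = ","),
        "bp (", sum(object@valid), "valid )\n")
    cat("  total counts:", format(sum(object@counts) / 2, big.mark = ","),
        if (object@balanced) " [balanced]\n" else " [raw]\n")
})

setMethod("show", "EigenProfile", function(object) {
    cat("EigenProfile:", object@chrom, "- E", object@selected,
        " selected (|rank cor| = ", round(object@refCor, 3), ")",
        if (object@ambiguous) " [ambiguous leading eigenvalues]", "\n", sep = "")
})

setMethod("show", "CompartmentSegments", function(object) {
    tab <- table(object@states)
    cat("CompartmentSegments:", object@chrom, "-",
        paste(names(tab), tab, sep = ":", collapse = " "),
        "|", length(object@limits), "limits\n")
})

setMethod("show", "BoundarySet", function(object) {
    cat("BoundarySet:", object@chrom, "-", length(object@bin), "boundaries (",
        sum(object@strong), "strong; Li threshold",
        signif(object@liThreshold, 3), ")\n")
})

setMethod("show", "LoopSet", function(object) {
    cat("LoopSet:", object@chrom, "-", length(object@anchor1), "loops, median span",
        format(stats::median((object@anchor2 - object@anchor1) * object@binSize),
               big.mark = ","), "bp\n")
})

setMethod("show", "RegionPairSet", function(object) {
    cat("RegionPairSet:", nrow(object@foreground), "foreground /",
        nrow(object@background), "background regions (",
        sum(object@unmappable), "unmappable )\n")
})

#' @rdname boundaryTable
#' @export
setMethod("as.data.frame", "BoundarySet", function(x, ...) {
    data.frame(chrom = x@chrom, bin = x@bin,
               start = (x@bin - 1) * x@binSize, end = x@bin * x@binSize,
               strength = x@strength, strong = x@strong, class = x@featureClass)
})

#' Tabular views of result objects
#'
#' `as.data.frame` methods give flat tables for \linkS4class{BoundarySet}
#' and \linkS4class{LoopSet} objects (bp coordinates are 0-based half-open).
#'
#' @param x the object.
#' @param ... ignored.
#' @name boundaryTable
#' @return a data.frame.
#' @export
setMethod("as.data.frame", "LoopSet", function(x, ...) {
    hw <- (x@anchorWidth - 1L) %/% 2L
    data.frame(chrom = x@chrom,
               anchor1 = x@anchor1, anchor2 = x@anchor2,
               start1 = pmax(0, (x@anchor1 - 1 - hw)) * x@binSize,
               end1 = (x@anchor1 + hw) * x@binSize,
               start2 = pmax(0, (x@anchor2 - 1 - hw)) * x@binSize,
               end2 = (x@anchor2 + hw) * x@binSize,
               span = (x@anchor2 - x@anchor1) * x@binSize,
               enrichment = x@enrichment, count = x@count, apa = x@apa)
})

#' Number of loops in a LoopSet
#' @param x a LoopSet.
#' @return integer count.
#' @export
nLoops <- function(x) length(x@anchor1)
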