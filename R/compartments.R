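#' Assign A/I/B compartment states from eigenvalues and thresholds
#'
#' Labels every valid bin B if its eigenvalue is below the B-I threshold,
#' A if above the I-A threshold, and I otherwise; merges adjacent
#' same-state bins into intervals and records the state-change points as
#' compartment limits.
#'
#' @param profile an \linkS4class{EigenProfile} (or a plain numeric vector
#'   of per-bin eigenvalues).
#' @param thresholds numeric c(BI, IA) with BI < IA, e.g. from
#'   \code{\link{fitThreeStateGmm}}.
#' @param binSize bin width in bp (for interval coordinates).
#' @param chrom chromosome name.
#' @return a \linkS4class{CompartmentSegments}.
#' @export
assignCompartments <- function(profile, thresholds, binSize = 1,
                               chrom = "chr1") {
    e1 <- if (is(profile, "EigenProfile")) compartmentEigenvector(profile)
          else as.numeric(profile)
    stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
    lab <- rep(NA_character_, length(e1))
    ok <- is.finite(e1)
    lab[ok] <- ifelse(e1[ok] < thresholds[1], "B",
               ifelse(e1[ok] > thresholds[2], "A", "I"))
    states <- factor(lab, levels = c("B", "I", "A"))
    # merge runs of equal (non-NA) state
    runs <- rle(ifelse(is.na(lab), "<NA>", lab))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != "<NA>"
    intervals <- data.frame(startBin = starts[keep], endBin = ends[keep],
                            start = (starts[keep] - 1) * binSize,
                            end = ends[keep] * binSize,
                            state = runs$values[keep])
    limits <- integer()
    if (nrow(intervals) > 1) {
        adj <- intervals$startBin[-1] == intervals$endBin[-nrow(intervals)] + 1L
        limits <- intervals$startBin[-1][adj] - 1L
    }
    new("CompartmentSegments", chrom = chrom, binSize = as.numeric(binSize),
        states = states, intervals = intervals,
        limits = as.integer(limits), thresholds = as.numeric(thresholds))
}

#' Per-bin compartment states
#' @param segments a \linkS4class{CompartmentSegments}.
#' @return factor with levels B, I, A.
#' @export
compartmentStates <- function(segments) segments@states

#' Compartment limits (state-change points)
#' @param segments a \linkS4class{CompartmentSegments}.
#' @return integer bin indices of the last bin before each state change.
#' @export
compartmentLimits <- function(segments) segments@limits

#' Quantile-normalized feature score
#'
#' Maps feature coverage values onto `-log2(1 - q)` where `q` is the
#' empirical quantile of each value (mid-rank for ties, so the maximum of
#' `n` untied values gets quantile `(n - 0.5)/n`). A value at the median
#' scores 1; a value in the upper `2^-k` tail scores about `k` (exactly
#' `k` when its mid-rank quantile equals `1 - 2^-k`).
#'
#' @param values finite numeric feature values.
#' @return numeric scores of the same length.
#' @examples
#' quantileNormScore(c(1, 2, 3))[2]  # median -> 1
#' @export
quantileNormScore <- function(values) {
    if (!length(values)) stop("empty input")
    stopifnot(all(is.finite(values)))
    n <- length(values)
    q <- (rank(values, ties.method = "average") - 0.5) / n
    -log2(1 - q)
}
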