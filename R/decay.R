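#' Mean balanced contact frequency by genomic distance
#'
#' Computes the exact per-diagonal (per-distance) mean of the balanced
#' matrix over valid bin pairs, and aggregates it onto a log-spaced
#' distance grid (ratio `gridRatio` per step, spanning `minDist` to
#' `maxDist` clipped to the chromosome length). When several chromosomes
#' are supplied, per-chromosome curves are computed separately and
#' averaged on the shared grid.
#'
#' @param m a balanced \linkS4class{ContactMatrix}, or a list of them.
#' @param minDist,maxDist distance range of the grid in bp.
#' @param gridRatio multiplicative step of the log-spaced grid.
#' @return list with `distance` (bp, strictly increasing), `frequency`
#'   (grid-averaged mean frequency; `NA` where no valid pairs exist),
#'   `perChrom` (matrix of per-chromosome curves) and `diagonal` (exact
#'   per-diagonal means for each chromosome, distances `0..n-1` bins).
#' @export
expectedByDistance <- function(m, minDist = 1e3, maxDist = 1e8,
                               gridRatio = 1.12) {
    if (is(m, "ContactMatrix")) m <- list(m)
    stopifnot(all(vapply(m, function(x) is(x, "ContactMatrix"), logical(1))))
    if (!all(vapply(m, isBalanced, logical(1))))
        stop("all matrices must be balanced")
    chromLen <- vapply(m, function(x) max(binTable(x)$end), numeric(1))
    hi <- min(maxDist, max(chromLen))
    grid <- exp(seq(log(minDist), log(hi), by = log(gridRatio)))
    diag_ <- lapply(m, function(x) diagMeans(balancedMatrix(x)))
    perChrom <- vapply(m, function(x) {
        dm <- diagMeans(balancedMatrix(x))
        bs <- binSize(x)
        dists <- (seq_along(dm) - 1) * bs
        vapply(seq_along(grid), function(g) {
            lo <- if (g == 1) 0 else grid[g - 1]
            sel <- dists > lo & dists <= grid[g]
            if (!any(sel) || all(is.na(dm[sel]))) NA_real_
            else mean(dm[sel], na.rm = TRUE)
        }, numeric(1))
    }, numeric(length(grid)))
    perChrom <- matrix(perChrom, nrow = length(grid))
    colnames(perChrom) <- vapply(m, chromName, character(1))
    avg <- rowMeans(perChrom, na.rm = TRUE)
    avg[!is.finite(avg)] <- NA_real_
    names(diag_) <- colnames(perChrom)
    list(distance = grid, frequency = avg, perChrom = perChrom,
         diagonal = diag_)
}

#' Observed-over-expected matrix
#'
#' Divides each diagonal of the balanced matrix by its own mean over valid
#' bin pairs, so every retained diagonal of the result has mean 1 (exact
#' up to float tolerance). Invalid bins propagate as `NA`; diagonals with
#' zero expected value are flagged missing.
#'
#' @param m a balanced \linkS4class{ContactMatrix}.
#' @return numeric matrix with attribute `expected` = the per-distance
#'   mean vector (index = distance in bins + 1).
#' @export
observedOverExpected <- function(m) {
    stopifnot(is(m, "ContactMatrix"))
    bal <- balancedMatrix(m)
    expd <- diagMeans(bal)
    expd[!is.finite(expd) | expd <= 0] <- NA_real_
    n <- nrow(bal)
    oe <- bal / distanceMatrix(expd, n)
    attr(oe, "expected") <- expd
    oe
}
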