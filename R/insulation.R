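#' Diamond insulation profile
#'
#' For each bin `i` with a full diamond, computes
#' `log2(mean(balanced[i-w..i-1, i+1..i+w]) / chromosome-wide mean of such
#' diamonds)`. The score is missing where fewer than 50% of the diamond's
#' pixels come from valid bins or where the diamond leaves the
#' chromosome. The score is invariant to global scaling of the matrix.
#'
#' @param m a balanced \linkS4class{ContactMatrix}.
#' @param window diamond size in bp (a multiple of the bin size).
#' @param minCoverage minimum fraction of valid diamond pixels.
#' @return numeric per-bin insulation score (log2), with attribute
#'   `window` (bp).
#' @export
insulationProfile <- function(m, window, minCoverage = 0.5) {
    stopifnot(is(m, "ContactMatrix"))
    bal <- balancedMatrix(m)
    n <- nbins(m)
    w <- as.integer(round(window / binSize(m)))
    if (w < 1) stop("window smaller than one bin")
    if (w >= n / 2) stop("window must be smaller than half the chromosome")
    raw <- rep(NA_real_, n)
    npix <- w * w
    for (i in (w + 1L):(n - w)) {
        d <- bal[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
        nOK <- sum(is.finite(d))
        if (nOK >= minCoverage * npix)
            raw[i] <- mean(d, na.rm = TRUE)
    }
    mu <- mean(raw, na.rm = TRUE)
    score <- log2(raw / mu)
    attr(score, "window") <- window
    score
}

#' Scan resolutions and windows for the strongest insulation signal
#'
#' Evaluates a grid of coarsened resolutions and diamond windows
#' (`windowMultipliers` times each resolution), calls candidate boundaries
#' (local insulation minima) at every grid point and scores the grid point
#' by the mean topographic prominence of its minima (the strongest
#' partitioning of the genome). Returns the resolution with the highest
#' mean over its windows together with that resolution's two best windows.
#' Ties break deterministically to the smallest resolution, then the
#' smallest windows.
#'
#' @param m a raw \linkS4class{ContactMatrix} at base resolution.
#' @param resolutions target resolutions in bp (multiples of the base bin
#'   size; at least 2).
#' @param windowMultipliers window sizes as multiples of each resolution.
#' @return list with `resolution`, `windows` (two bp sizes, ascending) and
#'   `grid` (data.frame report of every grid point: resolution, window,
#'   nBoundaries, meanProminence).
#' @export
scanInsulationParameters <- function(m, resolutions,
                                     windowMultipliers = c(5, 10, 25)) {
    stopifnot(is(m, "ContactMatrix"), length(resolutions) >= 2)
    base <- binSize(m)
    resolutions <- sort(unique(resolutions))
    rows <- list()
    for (res in resolutions) {
        k <- as.integer(round(res / base))
        if (k < 1 || abs(k * base - res) > 1e-6)
            stop("resolution must be a multiple of the base bin size")
        cmR <- if (k == 1) m else coarsenContactMatrix(m, k)
        cmR <- suppressWarnings(iceBalance(cmR))
        for (mult in sort(windowMultipliers)) {
            window <- mult * res
            if (window / res >= nbins(cmR) / 2) next
            sc <- insulationProfile(cmR, window)
            mins <- localMinima(sc)
            prom <- if (length(mins)) peakProminence(-sc, mins) else numeric()
            rows[[length(rows) + 1L]] <- data.frame(
                resolution = res, window = window,
                nBoundaries = length(mins),
                meanProminence = if (length(prom)) mean(prom) else NA_real_)
        }
    }
    grid <- do.call(rbind, rows)
    if (all(grid$nBoundaries == 0)) stop("no boundaries at any grid point")
    perRes <- stats::aggregate(meanProminence ~ resolution, grid, mean,
                               na.action = stats::na.omit)
    best <- perRes$resolution[order(-perRes$meanProminence,
                                    perRes$resolution)][1]
    sub <- grid[grid$resolution == best & !is.na(grid$meanProminence), ]
    sub <- sub[order(-sub$meanProminence, sub$window), ]
    wins <- sort(sub$window[seq_len(min(2L, nrow(sub)))])
    list(resolution = best, windows = wins, grid = grid)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums `k x k` blocks of raw counts; a coarse bin is valid when any of
#' its constituent fine bins is valid.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param k aggregation factor (bins).
#' @return a raw \linkS4class{ContactMatrix} at `k * binSize(m)` bp.
#' @export
coarsenContactMatrix <- function(m, k) {
    stopifnot(is(m, "ContactMatrix"), k >= 1)
    k <- as.integer(k)
    if (k == 1L) return(m)
    n <- nbins(m)
    grp <- (seq_len(n) - 1L) %/% k + 1L
    agg <- rowsum(t(rowsum(m@counts, grp)), grp)
    validC <- as.vector(rowsum(as.numeric(m@valid), grp)) > 0
    contactMatrix(agg, binSize(m) * k, chrom = chromName(m),
                  chromLength = max(binTable(m)$end), valid = validC)
}
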