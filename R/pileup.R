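#' Rescaled pile-up of inter-boundary contact domains
#'
#' Contact domains are the valleys between two consecutive strong
#' boundaries no further apart than `maxSpan`. Each domain's O/E
#' submatrix, extended by one domain length of flank on each side, is
#' area-resampled onto a fixed `3*grid x 3*grid` raster (flank / domain /
#' flank thirds) and the rasters are averaged element-wise.
#'
#' @param m a balanced \linkS4class{ContactMatrix}.
#' @param b a \linkS4class{BoundarySet} called on the same binning.
#' @param maxSpan maximum inter-boundary distance in bp.
#' @param grid cells per domain third of the output raster.
#' @return list with `pileup` (`3*grid x 3*grid` matrix), `nDomains` and
#'   `domains` (data.frame of the bins used).
#' @export
rescaledPileup <- function(m, b, maxSpan = 1e5, grid = 30L) {
    stopifnot(is(m, "ContactMatrix"), is(b, "BoundarySet"))
    oe <- observedOverExpected(m)
    n <- nrow(oe)
    sb <- sort(b@bin[b@strong])
    doms <- NULL
    if (length(sb) >= 2) {
        d1 <- sb[-length(sb)]; d2 <- sb[-1]
        span <- (d2 - d1) * b@binSize
        keep <- span <= maxSpan & (d2 - d1) >= 2
        doms <- data.frame(from = d1[keep], to = d2[keep])
    }
    if (is.null(doms) || nrow(doms) == 0) stop("no domains within maxSpan")
    G <- as.integer(grid)
    acc <- matrix(0, 3 * G, 3 * G)
    cnt <- matrix(0, 3 * G, 3 * G)
    used <- 0L
    for (k in seq_len(nrow(doms))) {
        L <- doms$to[k] - doms$from[k]
        lo <- doms$from[k] - L
        hi <- doms$to[k] + L
        if (lo < 1 || hi > n) next
        sub <- oe[lo:hi, lo:hi]
        rb <- rebinMatrix(sub, 3L * G, 3L * G)
        ok <- is.finite(rb)
        acc[ok] <- acc[ok] + rb[ok]
        cnt[ok] <- cnt[ok] + 1
        used <- used + 1L
    }
    if (used == 0L) stop("no domains with full flanks inside the matrix")
    pile <- acc / cnt
    pile[cnt == 0] <- NA_real_
    list(pileup = pile, nDomains = used, domains = doms)
}
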