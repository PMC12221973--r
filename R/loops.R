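#' Call focal chromatin loops from an O/E map
#'
#' Transparent ring-background focal caller: candidate pixels in the
#' distance band `[minDist, maxDist]` (bins) must have O/E at least
#' `foldThreshold` times the local background (mean of a square ring of
#' half-width `ringWidth` excluding the central 3x3) and raw count at
#' least `minCount`. 8-connected candidates are merged and the peak (max
#' O/E) pixel of each component is kept. Anchors are reported as 1-bin
#' intervals expanded to `anchorWidth` bins. Externally called loops can
#' be imported with \code{\link{readBedpe}} and flow through APA and
#' annotation unchanged.
#'
#' @param m a balanced \linkS4class{ContactMatrix}.
#' @param minDist,maxDist loop span band in bins (`minDist >= 2`).
#' @param foldThreshold O/E enrichment over the ring background.
#' @param minCount minimum raw count at the pixel.
#' @param ringWidth half-width of the background ring in bins.
#' @param anchorWidth anchor interval width in bins.
#' @return a \linkS4class{LoopSet}.
#' @export
callLoops <- function(m, minDist = 5L, maxDist = 200L, foldThreshold = 2,
                      minCount = 3, ringWidth = 5L, anchorWidth = 2L) {
    stopifnot(is(m, "ContactMatrix"), minDist >= 2)
    oe <- observedOverExpected(m)
    n <- nrow(oe)
    maxDist <- min(maxDist, n - 1L)
    if (maxDist < minDist) stop("empty O/E band")
    # ring background: big box minus central 3x3, NA-aware exact sums
    big <- boxStats2D(oe, ringWidth)
    ctr <- boxStats2D(oe, 1L)
    ringMean <- (big$sum - ctr$sum) / pmax(big$count - ctr$count, 1)
    ringMean[big$count - ctr$count == 0] <- NA_real_
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    cand <- is.finite(oe) & is.finite(ringMean) &
        oe >= foldThreshold * pmax(ringMean, .Machine$double.eps) &
        m@counts >= minCount & d >= minDist & d <= maxDist &
        upper.tri(oe)
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0)
        return(new("LoopSet", chrom = chromName(m), binSize = binSize(m),
                   anchor1 = integer(), anchor2 = integer(),
                   enrichment = numeric(), count = numeric(),
                   apa = numeric(), anchorWidth = as.integer(anchorWidth)))
    # 8-connected components over candidate pixels
    key <- (idx[, 1] - 1) * n + idx[, 2]
    lookup <- stats::setNames(seq_along(key), key)
    edges <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        nk <- (idx[, 1] + di - 1) * n + (idx[, 2] + dj)
        hit <- !is.na(lookup[as.character(nk)])
        if (any(hit))
            edges <- c(edges, rbind(which(hit),
                                    unname(lookup[as.character(nk[hit])])))
    }
    g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    peaks <- vapply(split(seq_len(nrow(idx)), comp), function(members) {
        vals <- oe[idx[members, , drop = FALSE]]
        members[which.max(vals)]
    }, integer(1))
    a1 <- idx[peaks, 1]; a2 <- idx[peaks, 2]
    o <- order(a1, a2)
    new("LoopSet", chrom = chromName(m), binSize = binSize(m),
        anchor1 = as.integer(a1[o]), anchor2 = as.integer(a2[o]),
        enrichment = oe[cbind(a1, a2)][o],
        count = m@counts[cbind(a1, a2)][o],
        apa = rep(NA_real_, length(peaks)),
        anchorWidth = as.integer(anchorWidth))
}

#' Aggregate peak analysis (APA)
#'
#' For each loop, extracts the `(2*halfWindow+1)^2` O/E submatrix centred
#' on the loop pixel and scores it as the centre value (a
#' `centerSize x centerSize` block mean, default the single centre pixel)
#' divided by the mean of the lower-left corner quadrant
#' (`halfWindow/2 x halfWindow/2`, the short-distance control corner).
#' The aggregate APA applies the same statistic to the element-wise mean
#' map. Loops closer than `2*halfWindow` bins to the matrix edge or the
#' diagonal are skipped and counted.
#'
#' @param m a balanced \linkS4class{ContactMatrix}.
#' @param loops a \linkS4class{LoopSet}.
#' @param halfWindow submatrix half-width in bins.
#' @param centerSize side of the central block (1 or 3).
#' @return list with `loops` (the LoopSet with per-loop `apa` filled),
#'   `aggregate` (scalar APA of the mean map), `map` (the mean map) and
#'   `nSkipped`.
#' @export
apaScore <- function(m, loops, halfWindow = 10L, centerSize = 1L) {
    stopifnot(is(m, "ContactMatrix"), is(loops, "LoopSet"))
    oe <- observedOverExpected(m)
    n <- nrow(oe)
    h <- as.integer(halfWindow)
    q <- max(1L, h %/% 2L)
    stat <- function(sub) {
        c0 <- h + 1L
        cs <- (centerSize - 1L) %/% 2L
        ctr <- mean(sub[(c0 - cs):(c0 + cs), (c0 - cs):(c0 + cs)], na.rm = TRUE)
        corner <- mean(sub[(2L * h + 2L - q):(2L * h + 1L), 1:q], na.rm = TRUE)
        ctr / corner
    }
    apa <- rep(NA_real_, nLoops(loops))
    acc <- matrix(0, 2L * h + 1L, 2L * h + 1L)
    cnt <- matrix(0, 2L * h + 1L, 2L * h + 1L)
    skipped <- 0L
    for (k in seq_len(nLoops(loops))) {
        i <- loops@anchor1[k]; j <- loops@anchor2[k]
        if (i - h < 1 || j + h > n || (j - h) - (i + h) < 1) {
            skipped <- skipped + 1L
            next
        }
        sub <- oe[(i - h):(i + h), (j - h):(j + h)]
        apa[k] <- stat(sub)
        ok <- is.finite(sub)
        acc[ok] <- acc[ok] + sub[ok]
        cnt[ok] <- cnt[ok] + 1
    }
    if (all(cnt == 0)) stop("all loops skipped in APA")
    avg <- acc / cnt
    avg[cnt == 0] <- NA_real_
    loops@apa <- apa
    list(loops = loops, aggregate = stat(avg), map = avg,
         nSkipped = skipped)
}

#' Remove APA outliers from a loop set
#'
#' Drops loops whose log-APA z-score exceeds `zMax` in absolute value
#' (both tails; high-intensity artefacts from rearrangements as well as
#' implausibly weak calls). Idempotent on well-behaved sets.
#'
#' @param loops a \linkS4class{LoopSet} with per-loop APA computed.
#' @param zMax z-score cutoff.
#' @return list with `loops` (filtered) and `removed` (the dropped loops'
#'   table).
#' @export
filterApaOutliers <- function(loops, zMax = 3) {
    stopifnot(is(loops, "LoopSet"))
    if (nLoops(loops) < 10) stop("need at least 10 loops")
    la <- log(loops@apa)
    ok <- is.finite(la)
    z <- rep(0, length(la))
    z[ok] <- (la[ok] - mean(la[ok])) / stats::sd(la[ok])
    keep <- abs(z) <= zMax
    removed <- as.data.frame(loops)[!keep, , drop = FALSE]
    loops@anchor1 <- loops@anchor1[keep]
    loops@anchor2 <- loops@anchor2[keep]
    loops@enrichment <- loops@enrichment[keep]
    loops@count <- loops@count[keep]
    loops@apa <- loops@apa[keep]
    list(loops = loops, removed = removed)
}
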