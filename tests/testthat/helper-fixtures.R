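# Shared fixture builders. Everything is generated in code at test time.

# a small balanced matrix from sampled pure-decay counts
decayMatrix <- function(n = 100, binSize = 2e3, alpha = 1, depth = 1e6,
                        seed = 1) {
    cfg <- simulationConfig(n * binSize, binSize, alpha = alpha,
                            depth = depth, seed = seed)
    iceBalance(simulateContactMap(cfg)$matrix)
}

# an ideal two-block checkerboard O/E matrix (AA = BB = hi, AB = lo)
blockCheckerboard <- function(nPerBlock = 30, hi = 2, lo = 0.5) {
    s <- rep(c(1, -1), each = nPerBlock)
    ifelse(outer(s, s) > 0, hi, lo)
}

# brute-force Sinkhorn-style fixed point balancing oracle (full-division
# updates, run to many iterations); independent of iceBalance internals
sinkhornOracle <- function(counts, iter = 10000) {
    w <- rep(1, nrow(counts))
    for (i in seq_len(iter)) {
        s <- as.vector(counts %*% w) * w
        w <- w / sqrt(s / mean(s))
    }
    s <- as.vector(counts %*% w) * w
    w <- w / sqrt(mean(s))
    counts * outer(w, w)
}

# exhaustive-search oracle for the Li minimum cross-entropy threshold
liOracle <- function(x) {
    x <- sort(x + max(x) * 1e-12 + .Machine$double.eps)
    cand <- unique((x[-1] + x[-length(x)]) / 2)
    obj <- vapply(cand, function(t) {
        lo <- x[x <= t]; hi <- x[x > t]
        if (!length(lo) || !length(hi)) return(Inf)
        -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
    }, numeric(1))
    cand[which.min(obj)]
}

# brute-force union-find for connected components of an edge list
unionFindOracle <- function(nodes, edges1, edges2) {
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) {
        while (parent[[x]] != x) x <- parent[[x]]
        x
    }
    for (k in seq_along(edges1)) {
        r1 <- find(as.character(edges1[k]))
        r2 <- find(as.character(edges2[k]))
        if (r1 != r2) parent[[r1]] <- r2
    }
    vapply(as.character(nodes), find, character(1))
}

# a LoopSet built directly from anchor bins (for APA / classification tests)
loopSetFromBins <- function(bin1, bin2, binSize, chrom = "chr1",
                            anchorWidth = 2L) {
    new("LoopSet", chrom = chrom, binSize = as.numeric(binSize),
        anchor1 = as.integer(bin1), anchor2 = as.integer(bin2),
        enrichment = rep(NA_real_, length(bin1)),
        count = rep(NA_real_, length(bin1)),
        apa = rep(NA_real_, length(bin1)),
        anchorWidth = as.integer(anchorWidth))
}

# loop recovery metrics at +/- tol bins
loopRecovery <- function(called, planted, tol = 1L) {
    ct <- as.data.frame(called)
    prec <- if (nrow(ct)) mean(mapply(function(a, b)
        any(abs(planted$bin1 - a) <= tol & abs(planted$bin2 - b) <= tol),
        ct$anchor1, ct$anchor2)) else NA_real_
    rec <- mean(mapply(function(a, b)
        any(abs(ct$anchor1 - a) <= tol & abs(ct$anchor2 - b) <= tol),
        planted$bin1, planted$bin2))
    list(precision = prec, recall = rec)
}
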