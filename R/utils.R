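# Shared numeric helpers. All are internal.

# Per-distance (diagonal) means of a square matrix, NA-aware.
# Returns a vector indexed by distance 0..n-1.
diagMeans <- function(m) {
    n <- nrow(m)
    vapply(0:(n - 1L), function(d) {
        idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
        mean(m[idx], na.rm = TRUE)
    }, numeric(1))
}

diagSums <- function(m) {
    n <- nrow(m)
    vapply(0:(n - 1L), function(d) {
        idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
        v <- m[idx]
        c(sum(v, na.rm = TRUE))
    }, numeric(1))
}

# Expand a per-distance vector into a full matrix: out[i,j] = v[|i-j|+1]
distanceMatrix <- function(v, n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    matrix(v[d + 1L], n, n)
}

# NA-aware box mean filter with half-width h (window (2h+1)^2), via
# summed-area tables. Cells that are NA stay NA; neighbourhood means use
# available cells only.
meanFilter2D <- function(m, h) {
    if (h <= 0) return(m)
    n1 <- nrow(m); n2 <- ncol(m)
    a <- ifelse(is.na(m), 0, m)
    v <- (!is.na(m)) * 1
    sat <- function(x) {
        x <- apply(x, 2, cumsum)
        t(apply(x, 1, cumsum))
    }
    Sa <- sat(a); Sv <- sat(v)
    boxSum <- function(S) {
        P <- matrix(0, n1 + 1, n2 + 1)
        P[-1, -1] <- S
        r1 <- pmax(seq_len(n1) - h, 1); r2 <- pmin(seq_len(n1) + h, n1)
        c1 <- pmax(seq_len(n2) - h, 1); c2 <- pmin(seq_len(n2) + h, n2)
        P[r2 + 1, c2 + 1, drop = FALSE] - P[r1, c2 + 1, drop = FALSE] -
            P[r2 + 1, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
    }
    num <- boxSum(Sa); den <- boxSum(Sv)
    out <- num / den
    out[den == 0] <- NA_real_
    out[is.na(m)] <- NA_real_
    out
}

# NA-aware box sums and valid-cell counts over a (2h+1)^2 window.
boxStats2D <- function(m, h) {
    n1 <- nrow(m); n2 <- ncol(m)
    a <- ifelse(is.na(m), 0, m)
    v <- (!is.na(m)) * 1
    sat <- function(x) {
        x <- apply(x, 2, cumsum)
        t(apply(x, 1, cumsum))
    }
    boxSum <- function(S) {
        P <- matrix(0, n1 + 1, n2 + 1)
        P[-1, -1] <- S
        r1 <- pmax(seq_len(n1) - h, 1); r2 <- pmin(seq_len(n1) + h, n1)
        c1 <- pmax(seq_len(n2) - h, 1); c2 <- pmin(seq_len(n2) + h, n2)
        P[r2 + 1, c2 + 1, drop = FALSE] - P[r1, c2 + 1, drop = FALSE] -
            P[r2 + 1, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
    }
    list(sum = boxSum(sat(a)), count = boxSum(sat(v)))
}

# Area-overlap weight matrix mapping nSrc equal cells onto nDst equal cells.
overlapWeights <- function(nSrc, nDst) {
    W <- matrix(0, nSrc, nDst)
    edges <- seq(0, nSrc, length.out = nDst + 1)
    for (u in seq_len(nDst)) {
        lo <- edges[u]; hi <- edges[u + 1]
        i0 <- floor(lo) + 1L; i1 <- ceiling(hi)
        for (i in i0:min(i1, nSrc)) {
            ov <- min(i, hi) - max(i - 1, lo)
            if (ov > 0) W[i, u] <- ov
        }
    }
    W
}

# Area-weighted resampling of a matrix onto newdim = c(nr, nc), NA-aware.
rebinMatrix <- function(m, nr, nc) {
    Wr <- overlapWeights(nrow(m), nr)
    Wc <- overlapWeights(ncol(m), nc)
    a <- ifelse(is.na(m), 0, m)
    v <- (!is.na(m)) * 1
    num <- t(Wr) %*% a %*% Wc
    den <- t(Wr) %*% v %*% Wc
    out <- num / den
    out[den == 0] <- NA_real_
    out
}

# Local minima of a numeric vector, plateau-aware (center of a flat run
# flanked by strictly higher values on both sides). NA values break runs.
localMinima <- function(x) {
    n <- length(x)
    if (n < 3) return(integer())
    out <- integer()
    i <- 2L
    while (i <= n - 1L) {
        if (is.na(x[i])) { i <- i + 1L; next }
        j <- i
        while (j < n && !is.na(x[j + 1L]) && x[j + 1L] == x[i]) j <- j + 1L
        leftOK <- !is.na(x[i - 1L]) && x[i - 1L] > x[i]
        rightOK <- j < n && !is.na(x[j + 1L]) && x[j + 1L] > x[i]
        if (leftOK && rightOK)
            out <- c(out, as.integer(floor((i + j) / 2)))
        i <- j + 1L
    }
    out
}

# Topographic prominence of maxima of `x` at positions `peaks`.
# Prominence = peak height minus the higher of the two key saddles, where
# each saddle is the minimum along the path to the nearest higher peak.
# NA values and signal edges terminate a walk (saddle = lowest point seen).
peakProminence <- function(x, peaks) {
    n <- length(x)
    vapply(peaks, function(p) {
        h <- x[p]
        lmin <- h
        i <- p - 1L
        while (i >= 1L && !is.na(x[i]) && x[i] <= h) {
            lmin <- min(lmin, x[i])
            i <- i - 1L
        }
        rmin <- h
        i <- p + 1L
        while (i <= n && !is.na(x[i]) && x[i] <= h) {
            rmin <- min(rmin, x[i])
            i <- i + 1L
        }
        h - max(lmin, rmin)
    }, numeric(1))
}

# Deterministic RNG scope: run `expr` under a given seed without
# clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}
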