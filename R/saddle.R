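#' Saddle matrix over eigenvector-ranked bin groups
#'
#' Ranks valid bins by the selected compartment eigenvector, partitions
#' them into `nGroups` equal-count groups, drops the extreme `trim`
#' fraction of groups at each end (with the defaults, the first and last
#' of 40 groups, i.e. the bottom and top 2.5% of eigenvalues), and
#' averages the O/E value over every group pair. With list inputs the
#' group-pair means are accumulated across chromosomes (each chromosome
#' ranked on its own eigenvector) before averaging.
#'
#' @param oe O/E matrix (or list of them).
#' @param profile matching \linkS4class{EigenProfile} (or list).
#' @param nGroups number of eigenvector-ranked groups.
#' @param trim fraction of groups dropped at each extreme.
#' @return list of class `SaddleResult` with `saddle` (retained-groups
#'   square matrix, ordered B -> A), `nGroups`, `nTrimmed` and `counts`
#'   (pairs contributing to each cell).
#' @export
saddleMatrix <- function(oe, profile, nGroups = 40L, trim = 0.025) {
    if (is.matrix(oe)) { oe <- list(oe); profile <- list(profile) }
    stopifnot(length(oe) == length(profile))
    nTrim <- round(trim * nGroups)
    keep <- (nTrim + 1L):(nGroups - nTrim)
    nk <- length(keep)
    acc <- matrix(0, nk, nk)
    cnt <- matrix(0, nk, nk)
    for (c in seq_along(oe)) {
        m <- oe[[c]]
        e1 <- compartmentEigenvector(profile[[c]])
        if (length(e1) != nrow(m))
            stop("profile and O/E matrix have different bin counts")
        ok <- is.finite(e1)
        if (sum(ok) < nGroups) stop("fewer valid bins than groups")
        grp <- rep(NA_integer_, length(e1))
        grp[ok] <- as.integer(ceiling(rank(e1[ok], ties.method = "first") /
                                      (sum(ok) / nGroups)))
        grp[ok] <- pmin(pmax(grp[ok], 1L), nGroups)
        for (gi in seq_len(nk)) {
            bi <- which(grp == keep[gi])
            if (!length(bi)) next
            for (gj in gi:nk) {
                bj <- which(grp == keep[gj])
                if (!length(bj)) next
                v <- m[bi, bj, drop = FALSE]
                s <- sum(v, na.rm = TRUE)
                nOK <- sum(is.finite(v))
                acc[gi, gj] <- acc[gi, gj] + s
                cnt[gi, gj] <- cnt[gi, gj] + nOK
                if (gj > gi) {
                    acc[gj, gi] <- acc[gj, gi] + s
                    cnt[gj, gi] <- cnt[gj, gi] + nOK
                }
            }
        }
    }
    sad <- acc / cnt
    sad[cnt == 0] <- NA_real_
    structure(list(saddle = sad, nGroups = as.integer(nGroups),
                   nTrimmed = as.integer(nTrim), counts = cnt),
              class = "SaddleResult")
}

#' Compartmentalization strength from a saddle matrix
#'
#' The corner blocks cover the extreme `topFrac` of the retained
#' eigenvector-ranked groups (`ceil(topFrac * retained)` groups per
#' corner, symmetric). Strength = (mean AA + mean BB) / (mean AB + mean
#' BA); the two heterotypic corners are averaged symmetrically. An
#' all-ones saddle gives exactly 1; the value is invariant under global
#' positive scaling of the O/E.
#'
#' @param s a `SaddleResult` from \code{\link{saddleMatrix}}.
#' @param topFrac fraction of retained groups per corner.
#' @return list with `strength`, and the corner means `AA`, `BB`, `AB`.
#' @export
compartmentStrength <- function(s, topFrac = 0.20) {
    sad <- s$saddle
    nk <- nrow(sad)
    k <- ceiling(topFrac * nk)
    if (k < 1 || k > nk %/% 1) stop("empty corner")
    lo <- seq_len(k)             # B extreme (lowest eigenvalues)
    hi <- (nk - k + 1L):nk       # A extreme
    BB <- mean(sad[lo, lo], na.rm = TRUE)
    AA <- mean(sad[hi, hi], na.rm = TRUE)
    AB <- (mean(sad[hi, lo], na.rm = TRUE) + mean(sad[lo, hi], na.rm = TRUE)) / 2
    if (!is.finite(AA) || !is.finite(BB) || !is.finite(AB))
        stop("empty corner")
    list(strength = (AA + BB) / (2 * AB), AA = AA, BB = BB, AB = AB,
         cornerGroups = k)
}
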