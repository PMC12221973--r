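#' ICE (iterative correction) matrix balancing
#'
#' Iteratively equalizes the marginals of a symmetric contact matrix.
#' Bins whose raw marginal falls below `minFrac` of the median valid
#' marginal are flagged invalid before iteration (coverage filter). On
#' convergence the balanced matrix `counts * w_i * w_j` has all valid-bin
#' marginals equal to 1 within `tol` (coefficient of variation).
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param maxIter maximum number of iterations.
#' @param tol convergence tolerance on the marginal coefficient of variation.
#' @param minFrac coverage filter: drop bins with marginal below this
#'   fraction of the median valid marginal.
#' @return the ContactMatrix with weights filled in and `balanced = TRUE`.
#'   Attributes `iterations` and `residual` record the fit. A warning is
#'   emitted (with the residual) if `maxIter` is reached without
#'   convergence.
#' @examples
#' cm <- contactMatrix(matrix(c(0, 4, 4, 0), 2), binSize = 1000)
#' cm <- iceBalance(cm)
#' balancedMatrix(cm)
#' @export
iceBalance <- function(m, maxIter = 200L, tol = 1e-8, minFrac = 0.02) {
    stopifnot(is(m, "ContactMatrix"))
    counts <- m@counts
    valid <- m@valid
    marg <- rowSums(counts)
    medm <- stats::median(marg[valid & marg > 0])
    valid <- valid & marg >= minFrac * medm
    if (sum(valid) < 2) stop("fewer than 2 valid bins after coverage filter")
    idx <- which(valid)
    sub <- counts[idx, idx, drop = FALSE]
    w <- rep(1, length(idx))
    iter <- 0L
    residual <- Inf
    repeat {
        iter <- iter + 1L
        s <- as.vector(sub %*% w) * w
        mu <- mean(s)
        residual <- stats::sd(s) / mu
        if (is.na(residual)) residual <- 0
        if (residual < tol || iter >= maxIter) break
        adj <- s / mu
        w <- w / sqrt(adj)
    }
    # scale so valid marginals equal 1
    s <- as.vector(sub %*% w) * w
    w <- w / sqrt(mean(s))
    if (residual >= tol)
        warning(sprintf("ICE did not converge in %d iterations (residual %.3g)",
                        iter, residual))
    weights <- rep(NA_real_, nbins(m))
    weights[idx] <- w
    m@weights <- weights
    m@valid <- valid
    m@balanced <- TRUE
    out <- m
    attr(out, "iterations") <- iter
    attr(out, "residual") <- residual
    out
}
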