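#' Three-component Gaussian mixture for A/I/B eigenvalue states
#'
#' Fits a univariate three-component Gaussian mixture by EM with a
#' deterministic initialization (component means at the 10th/50th/90th
#' percentiles, shared initial variance, equal weights; component-specific
#' variances thereafter), then derives the B-I and I-A thresholds as the
#' density-intersection points between the low/middle and middle/high
#' components that lie between their means. If no real intersection exists
#' in the inter-mean interval the midpoint of the means is used and
#' flagged. The fit is equivariant under affine transforms of the input:
#' `thresholds(a*x + b) = a*thresholds(x) + b` for `a > 0`.
#'
#' @param values finite per-bin eigenvalues (>= 300 required).
#' @param maxIter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return list with `means`, `sds`, `weights` (sorted by mean),
#'   `thresholds` (numeric c(BI, IA)), `fallback` (logical per threshold),
#'   `logLik`, `iterations` and `converged`.
#' @export
fitThreeStateGmm <- function(values, maxIter = 500L, tol = 1e-8) {
    x <- values[is.finite(values)]
    if (length(x) < 300) stop("need at least 300 finite values")
    if (stats::sd(x) == 0) stop("degenerate input: all values identical")
    K <- 3L
    mu <- as.numeric(stats::quantile(x, c(0.1, 0.5, 0.9)))
    if (any(duplicated(mu)))
        mu <- mu + c(-1, 0, 1) * 1e-6 * max(stats::sd(x), 1e-12)
    s2 <- rep(stats::var(x), K)
    w <- rep(1 / K, K)
    n <- length(x)
    ll0 <- -Inf
    converged <- FALSE
    iter <- 0L
    varFloor <- 1e-10 * stats::var(x)
    for (iter in seq_len(maxIter)) {
        dens <- vapply(seq_len(K), function(k)
            w[k] * stats::dnorm(x, mu[k], sqrt(s2[k])), numeric(n))
        tot <- rowSums(dens)
        tot[tot == 0] <- .Machine$double.xmin
        ll <- sum(log(tot))
        resp <- dens / tot
        nk <- colSums(resp)
        w <- nk / n
        mu <- colSums(resp * x) / nk
        s2 <- vapply(seq_len(K), function(k)
            sum(resp[, k] * (x - mu[k])^2) / nk[k], numeric(1))
        s2 <- pmax(s2, varFloor)
        if (is.finite(ll0) && abs(ll - ll0) < tol * (1 + abs(ll))) {
            converged <- TRUE
            break
        }
        ll0 <- ll
    }
    if (!converged)
        warning(sprintf("EM did not converge in %d iterations", maxIter))
    o <- order(mu)
    mu <- mu[o]; s2 <- s2[o]; w <- w[o]
    thr <- numeric(2)
    fb <- logical(2)
    for (t in 1:2) {
        iv <- gaussianIntersection(mu[t], sqrt(s2[t]), w[t],
                                   mu[t + 1], sqrt(s2[t + 1]), w[t + 1])
        if (is.na(iv)) {
            thr[t] <- (mu[t] + mu[t + 1]) / 2
            fb[t] <- TRUE
        } else thr[t] <- iv
    }
    list(means = mu, sds = sqrt(s2), weights = w, thresholds = thr,
         fallback = fb, logLik = ll, iterations = iter, converged = converged)
}

# Intersection of two weighted Gaussian densities inside (m1, m2).
# Returns NA when no real root lies strictly between the means.
gaussianIntersection <- function(m1, s1, w1, m2, s2, w2) {
    if (m1 > m2) stop("means must be ordered")
    a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
    roots <- if (abs(a) < 1e-14 * (1 / s1^2 + 1 / s2^2)) {
        if (b == 0) numeric() else -cc / b
    } else {
        disc <- b^2 - 4 * a * cc
        if (disc < 0) numeric()
        else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    }
    inside <- roots[roots > m1 & roots < m2]
    if (!length(inside)) return(NA_real_)
    inside[1]
}
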