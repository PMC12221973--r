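#' Compartment eigenvectors of the cis O/E correlation matrix
#'
#' Eigendecomposes the Pearson-correlation matrix of a chromosome's
#' observed/expected map (missing entries excluded pairwise) and selects
#' the compartment eigenvector automatically: the one among the leading
#' `nVec` with maximal absolute Spearman correlation to the per-bin
#' reference track (GC fraction or H3K4me3 coverage), sign-oriented so
#' that the correlation is non-negative (A = high values). This replaces
#' visual inspection of eigenvectors with a reproducible rule; the chosen
#' index is recorded in the result.
#'
#' @param oe O/E matrix from \code{\link{observedOverExpected}}.
#' @param reference per-bin orientation track covering all valid bins.
#' @param nVec number of leading eigenvectors to compute (default 3).
#' @param chrom chromosome name stored in the result.
#' @return an \linkS4class{EigenProfile}. The `ambiguous` flag is set when
#'   the two leading eigenvalues differ by less than 1%.
#' @export
computeEigenvectors <- function(oe, reference, nVec = 3L, chrom = "chr1") {
    stopifnot(is.matrix(oe), length(reference) == nrow(oe))
    validBin <- colSums(is.finite(oe)) > 0
    if (sum(validBin) < 10) stop("fewer than 10 valid bins")
    sub <- oe[validBin, validBin, drop = FALSE]
    cc <- if (anyNA(sub))
        suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    else suppressWarnings(stats::cor(sub))
    cc[!is.finite(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    nVec <- min(nVec, ncol(cc))
    vecs <- matrix(NA_real_, nrow(oe), nVec)
    vecs[validBin, ] <- eg$vectors[, seq_len(nVec), drop = FALSE]
    ref <- reference
    cors <- vapply(seq_len(nVec), function(k) {
        ok <- is.finite(vecs[, k]) & is.finite(ref)
        if (sum(ok) < 3) return(NA_real_)
        suppressWarnings(stats::cor(vecs[ok, k], ref[ok], method = "spearman"))
    }, numeric(1))
    sel <- which.max(abs(cors))
    if (length(sel) == 0 || all(is.na(cors))) { sel <- 1L; cors[1] <- 0 }
    if (!is.na(cors[sel]) && cors[sel] < 0) {
        vecs[, sel] <- -vecs[, sel]
        cors[sel] <- -cors[sel]
    }
    ambiguous <- length(eg$values) >= 2 &&
        abs(eg$values[1] - eg$values[2]) < 0.01 * abs(eg$values[1])
    new("EigenProfile", chrom = chrom, vectors = vecs,
        eigenvalues = eg$values[seq_len(nVec)],
        selected = as.integer(sel),
        refCor = as.numeric(cors[sel]),
        ambiguous = ambiguous)
}

#' Selected compartment eigenvector
#' @param profile an \linkS4class{EigenProfile}.
#' @return numeric per-bin vector (`NA` at invalid bins).
#' @export
compartmentEigenvector <- function(profile) {
    profile@vectors[, profile@selected]
}
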