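#' Minimum cross-entropy (Li) threshold
#'
#' Iterative Li threshold on non-negative values: starting from the mean,
#' alternates `t <- (mu_lo - mu_hi) / (log(mu_lo) - log(mu_hi))` where
#' `mu_lo`/`mu_hi` are the means of values at or below / above `t`, until
#' the threshold stabilizes. This is the fixed point of the minimum
#' cross-entropy objective between the data and its two-level segmentation.
#'
#' @param x non-negative numeric values.
#' @param tol convergence tolerance.
#' @param maxIter iteration cap.
#' @return the threshold (scalar).
#' @export
liThreshold <- function(x, tol = 1e-10, maxIter = 200L) {
    x <- x[is.finite(x)]
    stopifnot(length(x) >= 2, all(x >= 0))
    if (stats::sd(x) == 0) return(x[1])
    eps <- max(x) * 1e-12 + .Machine$double.eps
    x <- x + eps
    t0 <- mean(x)
    for (i in seq_len(maxIter)) {
        lo <- x[x <= t0]; hi <- x[x > t0]
        if (!length(lo) || !length(hi)) break
        muL <- mean(lo); muH <- mean(hi)
        t1 <- if (abs(log(muL) - log(muH)) < 1e-30) (muL + muH) / 2
              else (muL - muH) / (log(muL) - log(muH))
        if (abs(t1 - t0) < tol) { t0 <- t1; break }
        t0 <- t1
    }
    t0 - eps
}

#' Call insulation boundaries and grade them strong/weak
#'
#' Boundaries are the local minima of the insulation profile; their
#' strength is the topographic prominence of the inverted score
#' (prominence against the lower of the two flanking maxima). Minima
#' within `maskBins` bins of any unmappable interval are removed, then the
#' strength distribution is split at the Li minimum cross-entropy
#' threshold into strong and weak boundaries. When a second profile is
#' supplied (the two optimal window sizes used jointly), a minimum must
#' appear in both profiles within 1 bin to be kept, and the strength from
#' the first profile is reported.
#'
#' @param profile per-bin insulation score from
#'   \code{\link{insulationProfile}}.
#' @param mask data.frame(start, end) of unmappable intervals (bp), or NULL.
#' @param binSize bin width of the profile in bp.
#' @param profile2 optional second-window profile for joint calling.
#' @param maskBins exclusion distance around unmappable intervals (bins).
#' @param chrom chromosome name.
#' @return a \linkS4class{BoundarySet} (classes all "unassigned").
#' @export
callBoundaries <- function(profile, mask = NULL, binSize = 1,
                           profile2 = NULL, maskBins = 2L, chrom = "chr1") {
    if (sum(is.finite(profile)) < 10)
        stop("fewer than 10 finite insulation scores")
    mins <- localMinima(profile)
    if (!is.null(profile2)) {
        mins2 <- localMinima(profile2)
        if (length(mins2))
            mins <- mins[vapply(mins, function(b)
                any(abs(mins2 - b) <= 1L), logical(1))]
        else mins <- integer()
    }
    if (!is.null(mask) && nrow(mask) && length(mins)) {
        badBin <- unlist(lapply(seq_len(nrow(mask)), function(k) {
            i0 <- binIndex(mask$start[k], binSize)
            i1 <- binIndex(mask$end[k] - 1, binSize)
            i0:i1
        }))
        keep <- vapply(mins, function(b)
            all(abs(badBin - b) > maskBins), logical(1))
        mins <- mins[keep]
    }
    strength <- if (length(mins)) peakProminence(-profile, mins) else numeric()
    liT <- if (length(mins) >= 2) liThreshold(strength) else NA_real_
    strong <- if (is.na(liT)) rep(TRUE, length(mins)) else strength >= liT
    new("BoundarySet", chrom = chrom, binSize = as.numeric(binSize),
        bin = as.integer(mins), strength = as.numeric(strength),
        strong = strong, featureClass = rep("unassigned", length(mins)),
        liThreshold = as.numeric(liT))
}

#' Hierarchical classification of insulation boundaries
#'
#' Assigns each boundary to the first matching feature class in the
#' strict precedence order loop-anchor > TSS > accessible >
#' compartment-limit > unassigned. A feature matches when its interval
#' lies within `tolerance` bins of the boundary bin. TSSs of
#' loop-participating genes are excluded from the TSS class. Permuting
#' the order of the input feature tables never changes the result.
#'
#' @param b a \linkS4class{BoundarySet}.
#' @param loops a \linkS4class{LoopSet} (same chromosome/binning as the
#'   boundary profile's matrix), or NULL.
#' @param tss gene table with `tss` (bp) and `gene` columns, or NULL.
#' @param accessible data.frame(start, end) of accessible-chromatin peaks,
#'   or NULL.
#' @param limits a \linkS4class{CompartmentSegments} (any resolution; its
#'   limit positions are converted to bp), or NULL.
#' @param tolerance matching distance in bins of the boundary profile.
#' @return the BoundarySet with classes filled in; attribute `fractions`
#'   holds the per-class fractions.
#' @export
classifyBoundaries <- function(b, loops = NULL, tss = NULL,
                               accessible = NULL, limits = NULL,
                               tolerance = 1L) {
    stopifnot(is(b, "BoundarySet"))
    bs <- b@binSize
    tolBp <- tolerance * bs
    bStart <- (b@bin - 1) * bs
    bEnd <- b@bin * bs
    nB <- length(b@bin)
    cls <- rep("unassigned", nB)
    near <- function(fs, fe) {
        # does [fs, fe) lie within tolBp of the boundary bin interval?
        IRanges::overlapsAny(
            IRanges::IRanges(start = round(bStart - tolBp) + 1L,
                             end = round(bEnd + tolBp)),
            IRanges::IRanges(start = round(fs) + 1L, end = round(pmax(fe, fs + 1))))
    }
    loopGenes <- character()
    if (!is.null(loops) && nLoops(loops) > 0) {
        if (!identical(loops@chrom, b@chrom))
            stop("inconsistent chromosome names: ", loops@chrom, " vs ", b@chrom)
        lt <- as.data.frame(loops)
        anchorS <- c(lt$start1, lt$start2)
        anchorE <- c(lt$end1, lt$end2)
        hit <- near(anchorS, anchorE)
        cls[hit] <- "loop-anchor"
        if (!is.null(tss) && nrow(tss)) {
            gIv <- IRanges::IRanges(start = round(tss$tss) + 1L,
                                    width = 1L)
            aIv <- IRanges::IRanges(start = round(anchorS) + 1L,
                                    end = round(anchorE))
            loopGenes <- tss$gene[IRanges::overlapsAny(gIv, aIv)]
        }
    }
    if (!is.null(tss) && nrow(tss)) {
        keep <- !(tss$gene %in% loopGenes)
        if (any(keep)) {
            hit <- near(tss$tss[keep], tss$tss[keep] + 1)
            cls[cls == "unassigned" & hit] <- "TSS"
        }
    }
    if (!is.null(accessible) && nrow(accessible)) {
        hit <- near(accessible$start, accessible$end)
        cls[cls == "unassigned" & hit] <- "accessible"
    }
    if (!is.null(limits) && length(compartmentLimits(limits))) {
        lim <- compartmentLimits(limits)
        limBp <- lim * limits@binSize     # state change after this bin
        hit <- near(limBp - limits@binSize, limBp + limits@binSize)
        cls[cls == "unassigned" & hit] <- "compartment-limit"
    }
    b@featureClass <- cls
    out <- b
    attr(out, "fractions") <- if (nB) table(factor(cls,
        levels = c("loop-anchor", "TSS", "accessible",
                   "compartment-limit", "unassigned"))) / nB else NULL
    out
}
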