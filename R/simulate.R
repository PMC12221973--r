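#' Simulation configuration for synthetic Micro-C maps
#'
#' Bundles every parameter of the synthetic contact-map generator: a
#' power-law distance decay (contact frequency proportional to
#' distance^-alpha), checkerboard A/I/B compartments with homotypic boost
#' factors, insulating boundaries with attenuation factors, focal loops
#' with enrichment factors and a decayed halo, self-interacting domains,
#' unmappable intervals, gene/enhancer placement and chromatin-track
#' parameters. Coordinates are 0-based half-open bp; bins are fixed-width
#' with a possibly short terminal bin.
#'
#' @param chromLength chromosome length in bp.
#' @param binSize bin width in bp.
#' @param alpha decay exponent (>= 0); contact frequency ~ distance^-alpha.
#' @param depth total contact count for sampling.
#' @param compartments data.frame(start, end, state, f): non-overlapping
#'   intervals with state in A/I/B and homotypic boost f >= 1.
#' @param boundaries data.frame(pos, b): boundary positions (bp) with
#'   insulation attenuation 0 < b <= 1 applied to pairs straddling them.
#' @param loops data.frame(bin1, bin2, e): 1-based anchor bins, e >= 1.
#' @param domains data.frame(start, end, boost): self-interacting domains;
#'   pairs with both bins inside get multiplied by boost.
#' @param unmappable data.frame(start, end) of masked intervals (bp).
#' @param genes integer gene count (TSSs placed evenly, classes cycled
#'   GP1/GP2/GP3) or data.frame(tss, class).
#' @param enhancers numeric vector of planted enhancer positions (bp).
#' @param geneLength gene body length in bp.
#' @param trackBin resolution of generated signal tracks (bp).
#' @param peakHeight,peakWidth Gaussian peak height (reads/track bin at the
#'   mode) and sd (bp) for planted ATAC/ChIP peaks.
#' @param noise Poisson background rate per track bin.
#' @param seed integer seed; all generator randomness flows through it.
#' @return a validated `SimulationConfig` object (a classed list).
#' @examples
#' cfg <- simulationConfig(chromLength = 1e5, binSize = 1000, alpha = 1)
#' @export
simulationConfig <- function(chromLength, binSize, alpha = 1, depth = 1e6,
                             compartments = NULL, boundaries = NULL,
                             loops = NULL, domains = NULL, unmappable = NULL,
                             genes = 0L, enhancers = numeric(),
                             geneLength = 2000, trackBin = 200,
                             peakHeight = 50, peakWidth = 400,
                             noise = 1, seed = 1L) {
    stopifnot(chromLength >= binSize, binSize > 0, alpha >= 0, depth > 0,
              trackBin > 0, peakHeight > 0, peakWidth > 0, noise >= 0)
    empty <- function(...) {
        cols <- list(...)
        as.data.frame(stats::setNames(lapply(cols, function(x) vector(x, 0)),
                                      names(cols)))
    }
    if (is.null(compartments))
        compartments <- empty(start = "numeric", end = "numeric",
                              state = "character", f = "numeric")
    if (is.null(boundaries))
        boundaries <- empty(pos = "numeric", b = "numeric")
    if (is.null(loops))
        loops <- empty(bin1 = "integer", bin2 = "integer", e = "numeric")
    if (is.null(domains))
        domains <- empty(start = "numeric", end = "numeric", boost = "numeric")
    if (is.null(unmappable))
        unmappable <- empty(start = "numeric", end = "numeric")
    if (is.numeric(genes) && length(genes) == 1L) {
        ng <- as.integer(genes)
        if (ng > 0) {
            tss <- round(seq_len(ng) * chromLength / (ng + 1))
            genes <- data.frame(tss = tss,
                                class = rep(c("GP1", "GP2", "GP3"),
                                            length.out = ng))
        } else {
            genes <- empty(tss = "numeric", class = "character")
        }
    }
    if (nrow(compartments)) {
        stopifnot(all(compartments$state %in% c("A", "I", "B")),
                  all(compartments$f >= 1))
        o <- order(compartments$start)
        compartments <- compartments[o, ]
        if (any(compartments$start[-1] < compartments$end[-nrow(compartments)]))
            stop("overlapping compartment intervals")
        if (any(compartments$start < 0) || any(compartments$end > chromLength))
            stop("compartment intervals outside chromosome bounds")
    }
    if (nrow(boundaries))
        stopifnot(all(boundaries$b > 0), all(boundaries$b <= 1),
                  all(boundaries$pos > 0), all(boundaries$pos < chromLength))
    nb <- ceiling(chromLength / binSize)
    if (nrow(loops))
        stopifnot(all(loops$e >= 1), all(loops$bin1 >= 1),
                  all(loops$bin2 <= nb), all(loops$bin1 < loops$bin2))
    if (nrow(genes))
        stopifnot(all(genes$tss >= 0), all(genes$tss < chromLength),
                  all(genes$class %in% c("GP1", "GP2", "GP3")))
    structure(list(chromLength = chromLength, binSize = binSize,
                   alpha = alpha, depth = depth,
                   compartments = compartments, boundaries = boundaries,
                   loops = loops, domains = domains, unmappable = unmappable,
                   genes = genes, enhancers = enhancers,
                   geneLength = geneLength, trackBin = trackBin,
                   peakHeight = peakHeight, peakWidth = peakWidth,
                   noise = noise, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' @rdname simulationConfig
#' @param x a SimulationConfig.
#' @param ... ignored.
#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", format(x$chromLength, big.mark = ","), "bp @",
        x$binSize, "bp bins; alpha =", x$alpha, "\n")
    cat("  ", nrow(x$compartments), "compartment intervals,",
        nrow(x$boundaries), "boundaries,", nrow(x$loops), "loops,",
        nrow(x$genes), "genes\n")
    invisible(x)
}

# number of bins implied by a config
configBins <- function(config) as.integer(ceiling(config$chromLength / config$binSize))

# 1-based bin index of a bp position
binIndex <- function(pos, binSize) as.integer(floor(pos / binSize)) + 1L

# per-bin compartment state ("A"/"I"/"B"; bins outside intervals are "I")
# and per-bin boost factor
plantedStates <- function(config) {
    n <- configBins(config)
    state <- rep("I", n)
    f <- rep(1, n)
    cp <- config$compartments
    for (k in seq_len(nrow(cp))) {
        i0 <- binIndex(cp$start[k], config$binSize)
        i1 <- binIndex(cp$end[k] - 1, config$binSize)
        state[i0:i1] <- cp$state[k]
        f[i0:i1] <- cp$f[k]
    }
    list(state = state, f = f)
}

# logical mask of unmappable bins
unmappableBins <- function(config) {
    n <- configBins(config)
    bad <- rep(FALSE, n)
    um <- config$unmappable
    for (k in seq_len(nrow(um))) {
        i0 <- binIndex(um$start[k], config$binSize)
        i1 <- binIndex(um$end[k] - 1, config$binSize)
        bad[i0:min(i1, n)] <- TRUE
    }
    bad
}

#' Random alternating A/B compartment segmentation
#'
#' Draws alternating A/B intervals with exponentially distributed lengths
#' (mean `meanLength`, floor `minLength`, rounded to `roundTo`), covering
#' the chromosome. Irregular interval lengths mirror real compartment
#' maps, where segment sizes vary widely along the chromosome.
#'
#' @param chromLength chromosome length in bp.
#' @param meanLength mean interval length in bp.
#' @param minLength minimum interval length in bp.
#' @param f homotypic boost factor applied to every interval.
#' @param seed integer seed.
#' @param roundTo round interval edges to this multiple (bp).
#' @return data.frame(start, end, state, f) for
#'   \code{\link{simulationConfig}}.
#' @export
randomCompartmentSegments <- function(chromLength, meanLength = 1e5,
                                      minLength = 3e4, f = 2, seed = 1L,
                                      roundTo = 1e4) {
    withSeed(seed, {
        lens <- numeric()
        while (sum(lens) < chromLength)
            lens <- c(lens, pmax(minLength,
                round(stats::rexp(50, 1 / meanLength) / roundTo) * roundTo))
        cut <- which(cumsum(lens) >= chromLength)[1]
        lens <- lens[seq_len(cut)]
        edges <- c(0, cumsum(lens))
        edges[length(edges)] <- chromLength
        data.frame(start = utils::head(edges, -1), end = edges[-1],
                   state = rep(c("A", "B"),
                               length.out = length(edges) - 1),
                   f = f)
    })
}

#' Closed-form expected contact matrix of a simulation
#'
#' Evaluates the generative model exactly:
#' `expected[i,j] = (max(|i-j|,1)*binSize)^-alpha * comp(i,j) * ins(i,j) *
#' loop(i,j) * dom(i,j)`, where `comp` is the geometric mean of the two
#' bins' boost factors when both carry the same A or B state, `ins`
#' multiplies in the attenuation `b` of every boundary the pair straddles,
#' `loop` places enrichment `e` at each anchor pixel with `(1+e)/2` on its
#' 8 neighbours, and `dom` boosts pairs inside a common self-interacting
#' domain. Unmappable bins are zeroed. The matrix is exactly symmetric.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return non-negative numeric matrix (bins x bins).
#' @export
buildExpectedMatrix <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    n <- configBins(config)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    expected <- (pmax(d, 1) * config$binSize)^(-config$alpha)
    ps <- plantedStates(config)
    for (s in c("A", "B")) {
        inS <- ps$state == s
        if (any(inS)) {
            boost <- sqrt(outer(ps$f, ps$f))
            mask <- outer(inS, inS, "&")
            expected[mask] <- expected[mask] * boost[mask]
        }
    }
    for (k in seq_len(nrow(config$boundaries))) {
        kb <- binIndex(config$boundaries$pos[k], config$binSize) - 1L
        left <- seq_len(n) <= kb
        cross <- outer(left, !left) | outer(!left, left)
        expected[cross] <- expected[cross] * config$boundaries$b[k]
    }
    for (k in seq_len(nrow(config$domains))) {
        i0 <- binIndex(config$domains$start[k], config$binSize)
        i1 <- binIndex(config$domains$end[k] - 1, config$binSize)
        inD <- seq_len(n) >= i0 & seq_len(n) <= i1
        inside <- outer(inD, inD, "&")
        diag(inside) <- FALSE
        expected[inside] <- expected[inside] * config$domains$boost[k]
    }
    bad <- unmappableBins(config)
    lp <- config$loops
    if (nrow(lp) && any(bad[lp$bin1] | bad[lp$bin2]))
        stop("loop anchor in unmappable bin")
    for (k in seq_len(nrow(lp))) {
        i <- lp$bin1[k]; j <- lp$bin2[k]; e <- lp$e[k]
        halo <- (1 + e) / 2
        ri <- intersect((i - 1):(i + 1), seq_len(n))
        rj <- intersect((j - 1):(j + 1), seq_len(n))
        expected[ri, rj] <- expected[ri, rj] * halo
        expected[rj, ri] <- expected[rj, ri] * halo
        expected[i, j] <- expected[i, j] / halo * e
        expected[j, i] <- expected[j, i] / halo * e
    }
    expected[bad, ] <- 0
    expected[, bad] <- 0
    expected
}

#' Sample Poisson contact counts from an expected matrix
#'
#' Draws independent Poisson counts for every upper-triangle pixel
#' (including the diagonal) with means scaled so the total is
#' approximately `depth`, then symmetrizes. Reproducible given `seed`.
#'
#' @param expected non-negative matrix from \code{\link{buildExpectedMatrix}}.
#' @param depth target total contact count.
#' @param seed integer seed.
#' @return integer-valued symmetric count matrix.
#' @export
sampleContactCounts <- function(expected, depth, seed = 1L) {
    stopifnot(is.matrix(expected), all(is.finite(expected)), depth > 0)
    n <- nrow(expected)
    ut <- upper.tri(expected, diag = TRUE)
    tot <- sum(expected[ut])
    if (tot <= 0) stop("all-zero expected matrix")
    lam <- expected[ut] * depth / tot
    cnt <- withSeed(seed, stats::rpois(length(lam), lam))
    m <- matrix(0, n, n)
    m[ut] <- cnt
    m <- m + t(m)
    diag(m) <- diag(m) / 2
    m
}

#' Simulate a contact map plus its ground truth in one call
#'
#' Convenience wrapper: builds the expected matrix, samples counts at the
#' configured depth/seed and wraps them into a \linkS4class{ContactMatrix}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param chrom chromosome name for the resulting object.
#' @return list with `matrix` (ContactMatrix), `expected` (the noise-free
#'   matrix) and `truth` (planted states/boundaries/loops).
#' @export
simulateContactMap <- function(config, chrom = "chr1") {
    expected <- buildExpectedMatrix(config)
    counts <- sampleContactCounts(expected, config$depth, config$seed)
    cm <- contactMatrix(counts, config$binSize, chrom = chrom,
                        chromLength = config$chromLength,
                        valid = !unmappableBins(config))
    truth <- list(
        states = plantedStates(config)$state,
        boundaryBins = if (nrow(config$boundaries))
            binIndex(config$boundaries$pos, config$binSize) else integer(),
        loops = config$loops,
        unmappable = unmappableBins(config))
    list(matrix = cm, expected = expected, truth = truth)
}

# Gaussian bump (area ~ height * width * sqrt(2*pi) / trackBin) added to a
# track vector at position `center` (bp).
addPeak <- function(track, trackBin, center, height, width) {
    n <- length(track)
    i0 <- max(1L, binIndex(center - 4 * width, trackBin))
    i1 <- min(n, binIndex(center + 4 * width, trackBin))
    mid <- ((i0:i1) - 0.5) * trackBin
    track[i0:i1] <- track[i0:i1] + height * exp(-(mid - center)^2 / (2 * width^2))
    track
}

#' Simulate chromatin signal tracks, gene annotations and ground truth
#'
#' GP1 and GP2 genes receive ATAC, H3K4me3 and H3K4me2 peaks at their TSS;
#' planted enhancers receive H3K4me1 (and H3K4me2 and ATAC) peaks without
#' H3K4me3; GP3 genes receive nothing. All tracks carry Poisson background
#' noise. Peak intervals (TSS/enhancer +/- 2 peak widths) are recorded in
#' the returned ground truth.
#'
#' @param config a \code{\link{simulationConfig}} with genes/enhancers set.
#' @return list with `tracks` (named list of numeric vectors at `trackBin`
#'   resolution, marks ATAC/H3K4me3/H3K4me2/H3K4me1), `genes` (data.frame
#'   with tss, start, end, class, exon coordinates), `peaks` (named list of
#'   interval data.frames) and `truth` (planted gene classes, enhancer and
#'   peak intervals).
#' @export
simulateAnnotations <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    nT <- as.integer(ceiling(config$chromLength / config$trackBin))
    genes <- config$genes
    if (nrow(genes) > nT) stop("more genes than track bins")
    marks <- c("ATAC", "H3K4me3", "H3K4me2", "H3K4me1")
    tracks <- withSeed(config$seed + 1L, {
        tr <- lapply(marks, function(m) as.numeric(stats::rpois(nT, config$noise)))
        names(tr) <- marks
        tr
    })
    w <- config$peakWidth
    peakIv <- function(center) c(max(0, center - 2 * w), min(config$chromLength, center + 2 * w))
    peaks <- list(ATAC = NULL, H3K4me3 = NULL, H3K4me1 = NULL)
    addIv <- function(set, center) rbind(set, peakIv(center))
    for (g in seq_len(nrow(genes))) {
        if (genes$class[g] %in% c("GP1", "GP2")) {
            tss <- genes$tss[g]
            for (m in c("ATAC", "H3K4me3", "H3K4me2"))
                tracks[[m]] <- addPeak(tracks[[m]], config$trackBin, tss,
                                       config$peakHeight, w)
            peaks$ATAC <- addIv(peaks$ATAC, tss)
            peaks$H3K4me3 <- addIv(peaks$H3K4me3, tss)
        }
    }
    for (enh in config$enhancers) {
        for (m in c("ATAC", "H3K4me1", "H3K4me2"))
            tracks[[m]] <- addPeak(tracks[[m]], config$trackBin, enh,
                                   config$peakHeight, w)
        peaks$ATAC <- addIv(peaks$ATAC, enh)
        peaks$H3K4me1 <- addIv(peaks$H3K4me1, enh)
    }
    peaks <- lapply(peaks, function(p) {
        if (is.null(p)) data.frame(start = numeric(), end = numeric())
        else data.frame(start = p[, 1], end = p[, 2])
    })
    geneTab <- if (nrow(genes)) {
        gl <- config$geneLength
        data.frame(gene = paste0("g", seq_len(nrow(genes))),
                   tss = genes$tss,
                   start = genes$tss,
                   end = pmin(genes$tss + gl, config$chromLength),
                   class = genes$class,
                   exon1_start = genes$tss,
                   exon1_end = pmin(genes$tss + 300, config$chromLength),
                   exon2_start = pmin(genes$tss + gl - 300, config$chromLength),
                   exon2_end = pmin(genes$tss + gl, config$chromLength))
    } else {
        data.frame(gene = character(), tss = numeric(), start = numeric(),
                   end = numeric(), class = character(),
                   exon1_start = numeric(), exon1_end = numeric(),
                   exon2_start = numeric(), exon2_end = numeric())
    }
    list(tracks = tracks, genes = geneTab, peaks = peaks,
         truth = list(geneClasses = stats::setNames(geneTab$class, geneTab$gene),
                      enhancers = config$enhancers,
                      peaks = peaks))
}

#' Sum of a signal track over a bp interval
#'
#' @param track numeric vector at `trackBin` resolution.
#' @param trackBin track resolution in bp.
#' @param start,end 0-based half-open interval (bp).
#' @return the summed signal.
#' @export
trackWindowSum <- function(track, trackBin, start, end) {
    i0 <- max(1L, binIndex(max(start, 0), trackBin))
    i1 <- min(length(track), binIndex(end - 1, trackBin))
    if (i1 < i0) return(0)
    sum(track[i0:i1])
}

#' Simulate a pair of genomes with partially conserved gene order
#'
#' Genome B carries the same genes as genome A, with a stated fraction of
#' the genes outside `nConservedBlocks` protected blocks relocated to
#' uniformly random positions in the gene order. The orthology map is
#' one-to-one. With `shuffleFraction = 1` and no blocks the gene order of
#' genome B is a uniform random permutation.
#'
#' @param nGenes number of genes.
#' @param nConservedBlocks number of contiguous blocks exempt from
#'   relocation (0 for none).
#' @param shuffleFraction fraction of eligible genes relocated (0..1).
#' @param seed integer seed.
#' @param blockSize genes per conserved block.
#' @param geneSpacing distance between gene starts (bp).
#' @param geneWidth gene length (bp).
#' @return list with `genomeA`, `genomeB` (data.frames: gene, chrom, start,
#'   end, index), `orthology` (geneA, geneB, orthogroup) and `blocks`
#'   (data.frame of protected gene-index ranges and bp extents in A).
#' @export
simulateOrthologGenomes <- function(nGenes, nConservedBlocks = 0,
                                    shuffleFraction = 0, seed = 1L,
                                    blockSize = 10, geneSpacing = 2000,
                                    geneWidth = 1000) {
    stopifnot(shuffleFraction >= 0, shuffleFraction <= 1, nGenes >= 1)
    if (nConservedBlocks * blockSize > nGenes)
        stop("conserved blocks exceed gene count")
    ids <- paste0("g", seq_len(nGenes))
    mkGenome <- function(order, chrom) {
        data.frame(gene = ids[order], chrom = chrom,
                   start = (seq_len(nGenes) - 1) * geneSpacing,
                   end = (seq_len(nGenes) - 1) * geneSpacing + geneWidth,
                   index = seq_len(nGenes))
    }
    inBlock <- rep(FALSE, nGenes)
    blocks <- data.frame(firstGene = integer(), lastGene = integer(),
                         start = numeric(), end = numeric())
    if (nConservedBlocks > 0) {
        gap <- nGenes / nConservedBlocks
        firsts <- floor((seq_len(nConservedBlocks) - 1) * gap) + 1L
        for (f in firsts) inBlock[f:(f + blockSize - 1L)] <- TRUE
        blocks <- data.frame(firstGene = firsts,
                             lastGene = firsts + blockSize - 1L,
                             start = (firsts - 1) * geneSpacing,
                             end = (firsts + blockSize - 1L) * geneSpacing)
    }
    orderB <- withSeed(seed, {
        eligible <- which(!inBlock)
        nMove <- round(shuffleFraction * length(eligible))
        moved <- if (nMove > 0) sample(eligible, nMove) else integer()
        keep <- setdiff(seq_len(nGenes), moved)
        key <- numeric(nGenes)
        key[keep] <- seq_along(keep)
        if (nMove > 0)
            key[moved] <- stats::runif(nMove, 0, length(keep) + 1)
        order(key)
    })
    list(genomeA = mkGenome(seq_len(nGenes), "A1"),
         genomeB = mkGenome(orderB, "B1"),
         orthology = data.frame(geneA = ids, geneB = ids,
                                orthogroup = paste0("OG", seq_len(nGenes))),
         blocks = blocks)
}
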