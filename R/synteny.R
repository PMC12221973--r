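#' Simulate a complete synteny-conservation scenario
#'
#' Builds a pair of orthologous genomes, places foreground regions (either
#' over conserved blocks, giving a planted conservation contrast, or
#' uniformly at random, giving a null scenario), samples 3x length-matched
#' background regions, maps all regions to flanking anchor genes and runs
#' the conservation tests.
#'
#' @param nGenes genes per genome.
#' @param nForeground foreground region count.
#' @param shuffleFraction fraction of (eligible) genes relocated in
#'   genome B.
#' @param conservedForeground when TRUE the foreground regions cover
#'   conserved blocks exempt from shuffling (shuffle only outside the
#'   foreground); when FALSE shuffling is uniform and foreground regions
#'   are random (null).
#' @param seed integer seed.
#' @param blockSize genes per conserved block / foreground region.
#' @param regionGenes range (min, max) of genes spanned by a random
#'   foreground region under the null.
#' @param multiplier background/foreground ratio.
#' @return the \code{\link{syntenyConservationTest}} report.
#' @export
simulateSyntenyScenario <- function(nGenes = 400, nForeground = 40,
                                    shuffleFraction = 0.5,
                                    conservedForeground = FALSE, seed = 1L,
                                    blockSize = 8L, regionGenes = c(5, 25),
                                    multiplier = 3L) {
    spacing <- 2000; width <- 1000
    if (conservedForeground) {
        sim <- simulateOrthologGenomes(nGenes, nConservedBlocks = nForeground,
                                       shuffleFraction = shuffleFraction,
                                       seed = seed, blockSize = blockSize,
                                       geneSpacing = spacing, geneWidth = width)
        fg <- data.frame(chrom = "A1",
                         start = sim$blocks$start + width / 2,
                         end = sim$blocks$end - spacing + width / 2)
    } else {
        sim <- simulateOrthologGenomes(nGenes, nConservedBlocks = 0,
                                       shuffleFraction = shuffleFraction,
                                       seed = seed, geneSpacing = spacing,
                                       geneWidth = width)
        fg <- withSeed(seed + 10000L, {
            k <- sample(regionGenes[1]:regionGenes[2], nForeground,
                        replace = TRUE)
            s <- vapply(k, function(kk)
                sample.int(nGenes - kk, 1), integer(1))
            data.frame(chrom = "A1",
                       start = (s - 1) * spacing + width / 2,
                       end = (s + k - 2) * spacing + width / 2)
        })
    }
    genome <- data.frame(chrom = "A1", length = nGenes * spacing)
    bg <- sampleBackgroundRegions(genome, fg, multiplier = multiplier,
                                  seed = seed + 20000L)
    pairs <- mapRegionToFlankingGenes(fg, bg, sim$genomeA, sim$genomeB,
                                      sim$orthology)
    syntenyConservationTest(pairs)
}

#' Sample length-matched non-overlapping background regions
#'
#' Draws `multiplier` times as many background regions as there are
#' foreground regions; each background length is drawn (with replacement)
#' from the foreground length multiset and the region is placed uniformly
#' on the chromosome, rejecting placements that overlap any foreground
#' region or run off a chromosome end. Reproducible given `seed`.
#'
#' @param genome data.frame(chrom, length) of chromosome sizes.
#' @param foreground data.frame(chrom, start, end) of foreground regions.
#' @param multiplier background/foreground count ratio.
#' @param seed integer seed.
#' @param maxTries placement attempts per region before giving up.
#' @return data.frame(chrom, start, end) with `multiplier * nrow(foreground)`
#'   rows.
#' @export
sampleBackgroundRegions <- function(genome, foreground, multiplier = 3L,
                                    seed = 1L, maxTries = 1000L) {
    stopifnot(nrow(foreground) > 0, all(c("chrom", "length") %in% names(genome)))
    nBg <- multiplier * nrow(foreground)
    lens <- foreground$end - foreground$start
    withSeed(seed, {
        pickLen <- sample(rep(lens, multiplier))
        out <- vector("list", nBg)
        for (k in seq_len(nBg)) {
            L <- pickLen[k]
            placed <- FALSE
            for (try in seq_len(maxTries)) {
                ci <- sample(nrow(genome), 1)
                maxStart <- genome$length[ci] - L
                if (maxStart < 0) next
                s <- floor(stats::runif(1, 0, maxStart + 1))
                fg <- foreground[foreground$chrom == genome$chrom[ci], ]
                if (nrow(fg) && any(s < fg$end & s + L > fg$start)) next
                out[[k]] <- data.frame(chrom = genome$chrom[ci],
                                       start = s, end = s + L)
                placed <- TRUE
                break
            }
            if (!placed)
                stop(sprintf(
                    "could not place background region %d (length %d) after %d tries",
                    k, L, maxTries))
        }
        do.call(rbind, out)
    })
}

# closest overlapping gene to a point: overlap first, then nearest by
# distance, ties to the smaller start. Returns a row index or NA.
closestGene <- function(pos, genes) {
    ov <- which(genes$start <= pos & pos < genes$end)
    if (length(ov)) return(ov[which.min(genes$start[ov])])
    d <- pmax(genes$start - pos, pos - genes$end + 1, 0)
    cand <- which(d == min(d))
    cand[which.min(genes$start[cand])]
}

#' Map regions to flanking anchor genes and their orthologs
#'
#' Each region end is assigned its closest overlapping gene in species A
#' (overlap first, then nearest, ties to the smaller start); the two
#' anchor genes are mapped through the orthology table to species B.
#' Regions whose anchor genes lack orthologs (or where a chromosome has
#' no genes) are flagged unmappable and excluded, with counts reported.
#' For every mappable region the per-region shared-orthogroup count is
#' computed: the number of orthogroups present both among the genes
#' between (and including) the two anchors in species A and among the
#' genes between the two ortholog counterparts in species B (at most one
#' count per orthogroup per region).
#'
#' @param foreground,background data.frame(chrom, start, end) region sets.
#' @param genesA,genesB gene tables (gene, chrom, start, end, index).
#' @param orthology data.frame(geneA, geneB, orthogroup).
#' @return a \linkS4class{RegionPairSet}. The per-region tables gain
#'   columns `geneA1`, `geneA2`, `nBetweenA`, `shared` and `degenerate`
#'   (same gene at both ends).
#' @export
mapRegionToFlankingGenes <- function(foreground, background,
                                     genesA, genesB, orthology) {
    ogOfA <- stats::setNames(orthology$orthogroup, orthology$geneA)
    idxB <- stats::setNames(genesB$index, genesB$gene)
    ogByIndexB <- stats::setNames(
        orthology$orthogroup[match(genesB$gene, orthology$geneB)],
        genesB$index)
    mapSet <- function(regions) {
        if (!nrow(regions))
            return(list(tab = regions, dropped = 0L))
        rows <- vector("list", nrow(regions))
        dropped <- 0L
        for (k in seq_len(nrow(regions))) {
            gsub <- genesA[genesA$chrom == regions$chrom[k], ]
            if (!nrow(gsub)) { dropped <- dropped + 1L; next }
            i1 <- closestGene(regions$start[k], gsub)
            i2 <- closestGene(regions$end[k] - 1, gsub)
            g1 <- gsub$gene[i1]; g2 <- gsub$gene[i2]
            og1 <- ogOfA[g1]; og2 <- ogOfA[g2]
            b1g <- orthology$geneB[match(g1, orthology$geneA)]
            b2g <- orthology$geneB[match(g2, orthology$geneA)]
            if (is.na(og1) || is.na(og2) || is.na(idxB[b1g]) || is.na(idxB[b2g])) {
                dropped <- dropped + 1L
                next
            }
            lo <- min(gsub$index[i1], gsub$index[i2])
            hi <- max(gsub$index[i1], gsub$index[i2])
            ogA <- unique(stats::na.omit(ogOfA[genesA$gene[genesA$index >= lo &
                                                           genesA$index <= hi]]))
            bl <- min(idxB[b1g], idxB[b2g]); bh <- max(idxB[b1g], idxB[b2g])
            ogB <- unique(stats::na.omit(ogByIndexB[as.character(bl:bh)]))
            rows[[k]] <- data.frame(
                chrom = regions$chrom[k], start = regions$start[k],
                end = regions$end[k], geneA1 = g1, geneA2 = g2,
                geneB1 = b1g, geneB2 = b2g,
                nBetweenA = length(ogA),
                shared = length(intersect(ogA, ogB)),
                degenerate = g1 == g2)
        }
        list(tab = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
             dropped = dropped)
    }
    fg <- mapSet(foreground)
    bg <- mapSet(background)
    emptyTab <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), geneA1 = character(),
                           geneA2 = character(), geneB1 = character(),
                           geneB2 = character(), nBetweenA = integer(),
                           shared = integer(), degenerate = logical())
    new("RegionPairSet",
        foreground = if (is.null(fg$tab)) emptyTab else fg$tab,
        background = if (is.null(bg$tab)) emptyTab else bg$tab,
        genesA = genesA, genesB = genesB, orthology = orthology,
        unmappable = c(foreground = fg$dropped, background = bg$dropped))
}

#' Loop-synteny conservation tests
#'
#' Compares the syntenic conservation of foreground (loop) regions against
#' length-matched background regions using two statistics: (1) the global
#' fraction of shared orthogroups among inter-anchor genes, tested with a
#' chi-squared goodness-of-fit test of the foreground shared/unshared
#' counts against the background-derived probabilities; (2) the per-region
#' shared-ortholog distributions, tested with a one-sided (foreground
#' greater) Wilcoxon rank-sum test with continuity correction.
#'
#' @param pairs a \linkS4class{RegionPairSet} from
#'   \code{\link{mapRegionToFlankingGenes}}.
#' @param minRegions minimum testable regions per set.
#' @return list with `fractionForeground`, `fractionBackground`,
#'   `chisqP`, `wilcoxP`, `effect` (difference of mean per-region shared
#'   counts) and the per-region count vectors. Degenerate zero-variance
#'   inputs yield `NA` p-values.
#' @export
syntenyConservationTest <- function(pairs, minRegions = 5L) {
    stopifnot(is(pairs, "RegionPairSet"))
    fg <- pairs@foreground
    bg <- pairs@background
    if (nrow(fg) < minRegions || nrow(bg) < minRegions)
        stop("fewer than ", minRegions, " testable regions in a set")
    fracF <- sum(fg$shared) / max(sum(fg$nBetweenA), 1)
    fracB <- sum(bg$shared) / max(sum(bg$nBetweenA), 1)
    chisqP <- NA_real_
    if (fracB > 0 && fracB < 1 && sum(fg$nBetweenA) > 0) {
        obs <- c(sum(fg$shared), sum(fg$nBetweenA) - sum(fg$shared))
        chisqP <- suppressWarnings(
            stats::chisq.test(obs, p = c(fracB, 1 - fracB))$p.value)
    }
    wilcoxP <- NA_real_
    if (stats::sd(c(fg$shared, bg$shared)) > 0) {
        wilcoxP <- suppressWarnings(
            stats::wilcox.test(fg$shared, bg$shared,
                               alternative = "greater", correct = TRUE,
                               exact = FALSE)$p.value)
    }
    list(fractionForeground = fracF, fractionBackground = fracB,
         chisqP = chisqP, wilcoxP = wilcoxP,
         effect = mean(fg$shared) - mean(bg$shared),
         foregroundShared = fg$shared, backgroundShared = bg$shared,
         nForeground = nrow(fg), nBackground = nrow(bg))
}
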