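#' Quantile normalization across columns
#'
#' Classic mean-of-sorted-values quantile normalization with mid-rank
#' ties: every column is mapped onto the common reference distribution
#' (the row means of the sorted columns).
#'
#' @param m numeric matrix (rows = observations, columns = assays/marks).
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    ref <- rowMeans(apply(m, 2, sort))
    apply(m, 2, function(col) {
        r <- rank(col, ties.method = "average")
        stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
    })
}

#' Classify loop anchors as promoter, enhancer or undefined
#'
#' Computes CPM coverage of the H3K4me3/H3K4me2/H3K4me1 tracks in a
#' window of `window` bp around each anchor centre, quantile-normalizes
#' the three marks against genome-wide windows of the same size, and
#' classifies: P when normalized H3K4me3 is at or above the activity
#' threshold and at least the H3K4me1 level; E when H3K4me1 (or H3K4me2,
#' per `enhancerMark`) reaches the threshold and dominates H3K4me3; U
#' otherwise. The activity threshold is the `activityQuantile` quantile
#' of the normalized genome-wide window coverage per mark.
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param tracks named list with numeric vectors `H3K4me3`, `H3K4me2`,
#'   `H3K4me1` at `trackBin` resolution covering the chromosome.
#' @param trackBin track resolution in bp.
#' @param window anchor window in bp (1, 2 or 10 kb by species).
#' @param enhancerMark "H3K4me1" or "H3K4me2".
#' @param activityQuantile genome-wide quantile defining "active".
#' @return list with `anchors` (data.frame: bin, class, normalized CPMs),
#'   `loopClasses` (per-loop P-P/P-E/E-E/U category) and `categories`
#'   (tabulated loop categories).
#' @export
classifyAnchors <- function(loops, tracks, trackBin, window = 2000,
                            enhancerMark = "H3K4me1",
                            activityQuantile = 0.70) {
    stopifnot(is(loops, "LoopSet"),
              all(c("H3K4me3", "H3K4me2", "H3K4me1") %in% names(tracks)))
    marks <- c("H3K4me3", "H3K4me2", "H3K4me1")
    bs <- loops@binSize
    anchorBins <- sort(unique(c(loops@anchor1, loops@anchor2)))
    centers <- (anchorBins - 0.5) * bs
    genomeLen <- length(tracks[[1]]) * trackBin
    tileStarts <- seq(0, genomeLen - window, by = window)
    cpm <- function(track, starts) {
        tot <- sum(track)
        v <- vapply(starts, function(s)
            trackWindowSum(track, trackBin, s, s + window), numeric(1))
        v / max(tot, 1) * 1e6
    }
    tiles <- vapply(marks, function(mk) cpm(tracks[[mk]], tileStarts),
                    numeric(length(tileStarts)))
    tilesN <- quantileNormalize(tiles)
    thr <- apply(tilesN, 2, stats::quantile, probs = activityQuantile)
    anchorCpm <- vapply(marks, function(mk)
        cpm(tracks[[mk]], pmax(centers - window / 2, 0)),
        numeric(length(centers)))
    anchorCpm <- matrix(anchorCpm, ncol = length(marks),
                        dimnames = list(NULL, marks))
    # map anchor CPMs onto each mark's normalized scale by interpolation
    anchorN <- vapply(marks, function(mk) {
        so <- sort(tiles[, mk])
        sn <- sort(tilesN[, mk])
        stats::approx(so, sn, xout = anchorCpm[, mk], rule = 2,
                      ties = "ordered")$y
    }, numeric(length(centers)))
    anchorN <- matrix(anchorN, ncol = length(marks),
                      dimnames = list(NULL, marks))
    me3 <- anchorN[, "H3K4me3"]
    enh <- anchorN[, enhancerMark]
    # P: promoter mark active and dominant; E: enhancer mark active and
    # dominant over H3K4me3 (dominance rather than a hard H3K4me3 cutoff,
    # so near-threshold background noise cannot veto a strong enhancer)
    cls <- ifelse(me3 >= thr["H3K4me3"] & me3 >= anchorN[, "H3K4me1"], "P",
           ifelse(enh >= thr[enhancerMark] & enh > me3, "E", "U"))
    anchors <- data.frame(bin = anchorBins, class = cls, anchorN)
    byBin <- stats::setNames(cls, anchorBins)
    c1 <- byBin[as.character(loops@anchor1)]
    c2 <- byBin[as.character(loops@anchor2)]
    loopClasses <- ifelse(c1 == "U" | c2 == "U", "involving-U",
                   ifelse(c1 == c2, paste(c1, c2, sep = "-"), "P-E"))
    list(anchors = anchors, loopClasses = unname(loopClasses),
         categories = table(loopClasses), thresholds = thr)
}

#' Detect promoter hubs
#'
#' Builds a graph whose nodes are promoter-classified anchors and whose
#' edges are P-P loops; connected components linking at least two
#' promoters are hubs. Hub membership is invariant to loop-list order.
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param anchors anchor classification from \code{\link{classifyAnchors}}
#'   (or a data.frame with `bin` and `class`).
#' @param genes optional gene table with `tss` (bp) and `gene` columns;
#'   each promoter anchor is assigned its nearest TSS.
#' @return list with `hubs` (per-hub data.frame: hub id, promoter count,
#'   span in bins, member bins, member genes), `medianPromoters` and
#'   `membership` (per-anchor hub id).
#' @export
promoterHubs <- function(loops, anchors, genes = NULL) {
    if (is.list(anchors) && !is.data.frame(anchors)) anchors <- anchors$anchors
    pBins <- anchors$bin[anchors$class == "P"]
    isPP <- loops@anchor1 %in% pBins & loops@anchor2 %in% pBins
    if (!any(isPP))
        return(list(hubs = data.frame(), medianPromoters = NA_real_,
                    membership = integer()))
    v <- sort(unique(c(loops@anchor1[isPP], loops@anchor2[isPP])))
    g <- igraph::make_empty_graph(n = length(v), directed = FALSE)
    e <- rbind(match(loops@anchor1[isPP], v), match(loops@anchor2[isPP], v))
    g <- igraph::add_edges(g, as.vector(e))
    comp <- igraph::components(g)$membership
    hubIds <- sort(unique(comp[tabulate(comp)[comp] >= 2]))
    bs <- loops@binSize
    rows <- lapply(seq_along(hubIds), function(hI) {
        members <- v[comp == hubIds[hI]]
        memberGenes <- if (!is.null(genes) && nrow(genes)) {
            ctr <- (members - 0.5) * bs
            unique(genes$gene[vapply(ctr, function(p)
                which.min(abs(genes$tss - p)), integer(1))])
        } else character()
        data.frame(hub = hI, nPromoters = length(members),
                   spanBins = diff(range(members)),
                   bins = paste(members, collapse = ","),
                   genes = paste(memberGenes, collapse = ","))
    })
    hubs <- do.call(rbind, rows)
    list(hubs = hubs,
         medianPromoters = stats::median(hubs$nPromoters),
         membership = stats::setNames(comp, v))
}

#' Classify genes into GP1/GP2/GP3 groups
#'
#' Evaluates, in a window of `tssWindow` bp around each TSS, whether the
#' gene has an ATAC peak, an H3K4me3 peak and whether it overlaps a loop
#' anchor. GP1 = both peaks + loop; GP2 = both peaks, no loop (genes with
#' only one of the two peaks are GP2 with `partial = TRUE`); GP3 = no
#' peaks. The classification is a pure function of its inputs.
#'
#' @param genes gene table with `gene` and `tss` columns.
#' @param atacPeaks,k4me3Peaks data.frame(start, end) peak intervals (bp).
#' @param loops a \linkS4class{LoopSet} (anchors expanded to their
#'   configured width).
#' @param tssWindow half-window around the TSS in bp.
#' @return data.frame with per-gene flags (`atac`, `k4me3`, `loop`),
#'   `partial` and `group`.
#' @export
classifyGenesGp <- function(genes, atacPeaks, k4me3Peaks, loops,
                            tssWindow = 1000) {
    stopifnot(is(loops, "LoopSet"))
    if (!nrow(genes)) stop("empty gene table")
    bad <- !is.finite(genes$tss)
    if (any(bad)) {
        warning(sum(bad), " gene(s) without TSS skipped")
        genes <- genes[!bad, ]
    }
    tssIv <- IRanges::IRanges(start = round(genes$tss - tssWindow) + 1L,
                              end = round(genes$tss + tssWindow))
    ivOf <- function(p) IRanges::IRanges(start = round(p$start) + 1L,
                                         end = round(pmax(p$end, p$start + 1)))
    atac <- if (nrow(atacPeaks)) IRanges::overlapsAny(tssIv, ivOf(atacPeaks))
            else rep(FALSE, nrow(genes))
    k4 <- if (nrow(k4me3Peaks)) IRanges::overlapsAny(tssIv, ivOf(k4me3Peaks))
          else rep(FALSE, nrow(genes))
    lp <- rep(FALSE, nrow(genes))
    if (nLoops(loops) > 0) {
        lt <- as.data.frame(loops)
        aIv <- IRanges::IRanges(start = round(c(lt$start1, lt$start2)) + 1L,
                                end = round(c(lt$end1, lt$end2)))
        lp <- IRanges::overlapsAny(tssIv, aIv)
    }
    grp <- ifelse(atac & k4 & lp, "GP1", ifelse(atac | k4, "GP2", "GP3"))
    data.frame(gene = genes$gene, tss = genes$tss,
               atac = atac, k4me3 = k4, loop = lp,
               partial = xor(atac, k4), group = grp)
}

#' Summary statistics of an annotated loop set
#'
#' Median loop span, the enhancers-per-promoter histogram over P-E loops,
#' and the genomic context of enhancer anchors (exonic > intronic >
#' intergenic precedence by interval overlap of the anchor centre).
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param genes gene table with `start`, `end` and exon coordinate
#'   columns (`exon1_start` ... as produced by
#'   \code{\link{simulateAnnotations}}), or NULL to skip context.
#' @param anchors anchor classification from \code{\link{classifyAnchors}}.
#' @return list with `medianSpan` (bp), `enhancersPerPromoter` (table)
#'   and `enhancerContext` (table over exonic/intronic/intergenic).
#' @export
loopStatistics <- function(loops, genes = NULL, anchors = NULL) {
    stopifnot(is(loops, "LoopSet"))
    span <- (loops@anchor2 - loops@anchor1) * loops@binSize
    out <- list(medianSpan = stats::median(span),
                enhancersPerPromoter = NULL, enhancerContext = NULL)
    if (is.null(anchors)) return(out)
    if (is.list(anchors) && !is.data.frame(anchors)) anchors <- anchors$anchors
    cls <- stats::setNames(anchors$class, anchors$bin)
    c1 <- cls[as.character(loops@anchor1)]
    c2 <- cls[as.character(loops@anchor2)]
    pe <- (c1 == "P" & c2 == "E") | (c1 == "E" & c2 == "P")
    pAnchor <- ifelse(c1 == "P", loops@anchor1, loops@anchor2)[pe]
    eAnchor <- ifelse(c1 == "E", loops@anchor1, loops@anchor2)[pe]
    if (length(pAnchor))
        out$enhancersPerPromoter <-
            table(vapply(split(eAnchor, pAnchor), function(x)
                length(unique(x)), integer(1)))
    if (!is.null(genes) && nrow(genes)) {
        eBins <- unique(anchors$bin[anchors$class == "E"])
        ctr <- (eBins - 0.5) * loops@binSize
        pos <- IRanges::IRanges(start = round(ctr) + 1L, width = 1L)
        exIv <- IRanges::IRanges(
            start = round(c(genes$exon1_start, genes$exon2_start)) + 1L,
            end = round(c(genes$exon1_end, genes$exon2_end)))
        gIv <- IRanges::IRanges(start = round(genes$start) + 1L,
                                end = round(genes$end))
        inEx <- IRanges::overlapsAny(pos, exIv)
        inGene <- IRanges::overlapsAny(pos, gIv)
        ctx <- ifelse(inEx, "exonic", ifelse(inGene, "intronic", "intergenic"))
        out$enhancerContext <- table(factor(ctx,
            levels = c("exonic", "intronic", "intergenic")))
    }
    out
}
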