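# On-disk interchange. Dense TSV is the contact-matrix format; interval
# and track formats go through rtracklayer when it is available.

#' Write / read a contact matrix as dense TSV
#'
#' Layout: three leading columns (chrom, start, end; 0-based half-open)
#' followed by one column per bin of raw counts. Balancing weights are not
#' serialized; re-run \code{\link{iceBalance}} after reading.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param path output file.
#' @return `writeContactTSV` returns `path` invisibly; `readContactTSV`
#'   returns a raw \linkS4class{ContactMatrix}.
#' @export
writeContactTSV <- function(m, path) {
    stopifnot(is(m, "ContactMatrix"))
    df <- cbind(data.frame(chrom = chromName(m)), binTable(m),
                as.data.frame(rawCounts(m)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeContactTSV
#' @export
readContactTSV <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    counts <- as.matrix(df[, -(1:3), drop = FALSE])
    dimnames(counts) <- NULL
    bs <- df$end[1] - df$start[1]
    contactMatrix(counts, binSize = bs, chrom = as.character(df$chrom[1]),
                  chromLength = max(df$end))
}

#' Write a signal track as bedGraph
#'
#' @param track numeric vector at `trackBin` resolution.
#' @param trackBin track resolution (bp).
#' @param path output file.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, trackBin, path, chrom = "chr1") {
    start <- (seq_along(track) - 1) * trackBin
    df <- data.frame(chrom = chrom, start = start, end = start + trackBin,
                     value = track)
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = df$start + 1, end = df$end),
            score = df$value)
        rtracklayer::export(gr, path, format = "bedGraph")
    } else {
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read a bedGraph signal track into a per-bin vector
#'
#' @param path bedGraph file.
#' @param trackBin expected track resolution (bp).
#' @return numeric vector (one value per `trackBin`), zero-filled gaps.
#' @export
readBedGraph <- function(path, trackBin) {
    df <- if (requireNamespace("rtracklayer", quietly = TRUE)) {
        gr <- rtracklayer::import(path, format = "bedGraph")
        data.frame(start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), value = gr$score)
    } else {
        stats::setNames(utils::read.table(path, sep = "\t")[, 2:4],
                        c("start", "end", "value"))
    }
    n <- ceiling(max(df$end) / trackBin)
    out <- numeric(n)
    for (k in seq_len(nrow(df))) {
        i0 <- floor(df$start[k] / trackBin) + 1
        i1 <- ceiling(df$end[k] / trackBin)
        out[i0:i1] <- df$value[k]
    }
    out
}

#' Write loops as 10-column BEDPE
#'
#' chrom1/start1/end1/chrom2/start2/end2/name/score/strand1/strand2 with
#' the O/E enrichment as score; extra columns carry count and APA.
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(loops, path) {
    lt <- as.data.frame(loops)
    df <- data.frame(chrom1 = lt$chrom, start1 = lt$start1, end1 = lt$end1,
                     chrom2 = lt$chrom, start2 = lt$start2, end2 = lt$end2,
                     name = sprintf("loop_%d", seq_len(nrow(lt))),
                     score = lt$enrichment, strand1 = ".", strand2 = ".",
                     count = lt$count, apa = lt$apa)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BEDPE loop file into a LoopSet
#'
#' Anchor bins are taken as the bin containing each anchor interval's
#' midpoint; extra columns 11/12 (count, APA), when present, are kept.
#'
#' @param path BEDPE file (at least 6 columns).
#' @param binSize bin width (bp) of the matrix the loops refer to.
#' @param anchorWidth anchor width in bins.
#' @return a \linkS4class{LoopSet}.
#' @export
readBedpe <- function(path, binSize, anchorWidth = 2L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    mid1 <- (df[[2]] + df[[3]]) / 2
    mid2 <- (df[[5]] + df[[6]]) / 2
    a1 <- binIndex(mid1, binSize)
    a2 <- binIndex(mid2, binSize)
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    new("LoopSet", chrom = as.character(df[[1]][1]),
        binSize = as.numeric(binSize),
        anchor1 = as.integer(a1), anchor2 = as.integer(a2),
        enrichment = if (ncol(df) >= 8) as.numeric(df[[8]])
                     else rep(NA_real_, nrow(df)),
        count = if (ncol(df) >= 11) as.numeric(df[[11]])
                else rep(NA_real_, nrow(df)),
        apa = if (ncol(df) >= 12) as.numeric(df[[12]])
              else rep(NA_real_, nrow(df)),
        anchorWidth = as.integer(anchorWidth))
}

#' Write boundaries or intervals as BED
#'
#' @param b a \linkS4class{BoundarySet} or a data.frame with chrom,
#'   start, end (plus optional extra columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(b, path) {
    df <- if (is(b, "BoundarySet")) {
        bt <- as.data.frame(b)
        data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
                   name = bt$class, score = bt$strength,
                   strand = ".", strong = bt$strong)
    } else b
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a simulation ground-truth manifest as JSON
#'
#' @param truth ground-truth list (from \code{\link{simulateContactMap}} /
#'   \code{\link{simulateAnnotations}}).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(path)
}
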