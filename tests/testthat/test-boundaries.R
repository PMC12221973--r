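test_that("boundary calling finds dips and honours the unmappable filter", {
    sc <- rep(0, 50)
    sc[25] <- -1; sc[24] <- -0.5; sc[26] <- -0.5
    b <- callBoundaries(sc, binSize = 1e3)
    expect_equal(b@bin, 25L)
    expect_equal(b@strength, 1)

    # a dip within two bins of a masked interval is removed
    mask <- data.frame(start = 26e3, end = 28e3)   # bins 27-28
    b2 <- callBoundaries(sc, mask = mask, binSize = 1e3)
    expect_equal(length(b2@bin), 0)
    # a mask further away leaves it untouched
    b3 <- callBoundaries(sc, mask = data.frame(start = 30e3, end = 32e3),
                         binSize = 1e3)
    expect_equal(b3@bin, 25L)
    expect_error(callBoundaries(c(0, -1, 0)), "10 finite")
})

test_that("two-window joint calling keeps only reproducible minima", {
    sc1 <- rep(0, 60); sc1[c(20, 40)] <- -1
    sc2 <- rep(0, 60); sc2[c(21, 50)] <- -1
    b <- callBoundaries(sc1, binSize = 1e3, profile2 = sc2)
    expect_equal(b@bin, 20L)   # bin 40 absent from the second profile
})

test_that("Li threshold matches the exhaustive cross-entropy oracle", {
    set.seed(14)
    weak <- abs(rnorm(120, 0.1, 0.03))
    strong <- abs(rnorm(80, 1.0, 0.2))
    x <- sample(c(weak, strong))
    t1 <- liThreshold(x)
    t2 <- liOracle(x)
    # both thresholds split the bimodal sample identically
    expect_identical(x <= t1, x <= t2)
    # split accuracy >= 95% against the planted labels
    lab <- sample(rep(c(FALSE, TRUE), c(120, 80)))
    x2 <- ifelse(lab, abs(rnorm(200, 1.0, 0.2)), abs(rnorm(200, 0.1, 0.03)))
    tt <- liThreshold(x2)
    expect_gte(mean((x2 > tt) == lab), 0.95)
})

test_that("prominence matches a brute-force definition on random profiles", {
    bruteProminence <- function(x, p) {
        n <- length(x)
        h <- x[p]
        leftHigher <- which(x[seq_len(p - 1)] > h)
        lo <- if (length(leftHigher)) max(leftHigher) + 1 else 1
        rightHigher <- which(x[(p + 1):n] > h) + p
        hi <- if (length(rightHigher)) min(rightHigher) - 1 else n
        h - max(min(x[lo:p]), min(x[p:hi]))
    }
    set.seed(6)
    for (rep in 1:20) {
        x <- rnorm(80)
        peaks <- which(diff(sign(diff(x))) == -2) + 1
        if (!length(peaks)) next
        got <- chromarch:::peakProminence(x, peaks)
        want <- vapply(peaks, function(p) bruteProminence(x, p), numeric(1))
        expect_equal(got, want)
    }
})

test_that("hierarchical classification respects precedence and tolerance", {
    bs <- 1e3
    mkB <- function(bins) new("BoundarySet", chrom = "chr1", binSize = bs,
        bin = as.integer(bins), strength = rep(1, length(bins)),
        strong = rep(TRUE, length(bins)),
        featureClass = rep("unassigned", length(bins)),
        liThreshold = 0.5)
    loops <- loopSetFromBins(10, 30, bs, anchorWidth = 1L)
    tss <- data.frame(gene = c("g1", "g2"), tss = c(9.5e3, 50.2e3))
    acc <- data.frame(start = 70e3, end = 71e3)

    # boundary at a loop anchor that also has a TSS: loop-anchor wins
    b <- classifyBoundaries(mkB(c(10, 50, 71, 90)), loops = loops,
                            tss = tss, accessible = acc)
    expect_equal(b@featureClass,
                 c("loop-anchor", "TSS", "accessible", "unassigned"))

    # 1 bin from an ATAC peak, nothing else nearby -> accessible
    b2 <- classifyBoundaries(mkB(72), accessible = acc)
    expect_equal(b2@featureClass, "accessible")
    b3 <- classifyBoundaries(mkB(74), accessible = acc)
    expect_equal(b3@featureClass, "unassigned")

    # TSS of a loop-participating gene is excluded from the TSS class
    bTss <- classifyBoundaries(mkB(10), tss = tss)   # g1 sits in the anchor
    expect_equal(bTss@featureClass, "TSS")
    bLoop <- classifyBoundaries(mkB(10), loops = loops, tss = tss)
    expect_equal(bLoop@featureClass, "loop-anchor")
})

test_that("classification equals a brute-force interval scan on random fixtures", {
    bruteClassify <- function(bins, bs, tol, loopIv, tssPos, loopGenePos,
                              accIv, limIv) {
        vapply(bins, function(bin) {
            lo <- (bin - 1) * bs - tol * bs
            hi <- bin * bs + tol * bs
            hitIv <- function(iv) nrow(iv) > 0 &&
                any(iv$start < hi & iv$end > lo)
            if (hitIv(loopIv)) return("loop-anchor")
            freeTss <- setdiff(tssPos, loopGenePos)
            if (length(freeTss) &&
                any(freeTss >= lo & freeTss < hi)) return("TSS")
            if (hitIv(accIv)) return("accessible")
            if (hitIv(limIv)) return("compartment-limit")
            "unassigned"
        }, character(1))
    }
    set.seed(33)
    bs <- 1e3
    for (fix in 1:100) {
        bins <- sort(sample(5:195, 8))
        a1 <- sample(5:80, 3); a2 <- a1 + sample(20:100, 3)
        loops <- loopSetFromBins(a1, a2, bs, anchorWidth = 1L)
        lt <- as.data.frame(loops)
        loopIv <- data.frame(start = c(lt$start1, lt$start2),
                             end = c(lt$end1, lt$end2))
        tss <- data.frame(gene = paste0("g", 1:6),
                          tss = sort(sample(seq(2e3, 195e3, 500), 6)))
        acc <- data.frame(start = sort(sample(seq(0, 19e4, 1e4), 3)))
        acc$end <- acc$start + 1500
        e1 <- rnorm(40)
        seg <- assignCompartments(e1, c(-0.5, 0.5), binSize = 5e3)
        got <- classifyBoundaries(
            new("BoundarySet", chrom = "chr1", binSize = bs,
                bin = as.integer(bins), strength = rep(1, 8),
                strong = rep(TRUE, 8),
                featureClass = rep("unassigned", 8), liThreshold = 0.1),
            loops = loops, tss = tss, accessible = acc, limits = seg)
        loopGenePos <- tss$tss[vapply(tss$tss, function(p)
            any(p >= loopIv$start & p < loopIv$end), logical(1))]
        lim <- compartmentLimits(seg)
        limIv <- data.frame(start = lim * 5e3 - 5e3, end = lim * 5e3 + 5e3)
        want <- bruteClassify(bins, bs, 1, loopIv, tss$tss, loopGenePos,
                              acc, limIv)
        expect_identical(got@featureClass, want)
    }
})
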