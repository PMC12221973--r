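test_that("background sampling is length-matched, non-overlapping and seeded", {
    set.seed(1)
    fg <- data.frame(chrom = "A1",
                     start = c(1e4, 5e4, 12e4),
                     end = c(2e4, 6.5e4, 13e4))
    genome <- data.frame(chrom = "A1", length = 1e6)
    bg <- sampleBackgroundRegions(genome, fg, multiplier = 3, seed = 5)
    expect_equal(nrow(bg), 9)
    expect_setequal(bg$end - bg$start, fg$end - fg$start)
    # zero overlap with foreground, verified by interval intersection
    for (k in seq_len(nrow(bg)))
        expect_false(any(bg$start[k] < fg$end & bg$end[k] > fg$start))
    bg2 <- sampleBackgroundRegions(genome, fg, multiplier = 3, seed = 5)
    expect_identical(bg, bg2)
    # lengths drawn from the foreground multiset (KS on a larger draw)
    bgBig <- sampleBackgroundRegions(genome, fg, multiplier = 30, seed = 6)
    expect_equal(sort(unique(bgBig$end - bgBig$start)),
                 sort(unique(fg$end - fg$start)))
    # an impossible request errors with diagnostics
    expect_error(sampleBackgroundRegions(
        data.frame(chrom = "A1", length = 3e4),
        data.frame(chrom = "A1", start = 0, end = 2.9e4),
        multiplier = 3, seed = 1, maxTries = 50), "could not place")
})

test_that("flanking-gene mapping equals a brute-force nearest-gene scan", {
    set.seed(12)
    sim <- simulateOrthologGenomes(120, shuffleFraction = 0.3, seed = 2)
    gA <- sim$genomeA
    bruteNearest <- function(pos) {
        ov <- which(gA$start <= pos & pos < gA$end)
        if (length(ov)) return(gA$gene[ov[which.min(gA$start[ov])]])
        d <- pmax(gA$start - pos, pos - gA$end + 1, 0)
        cand <- which(d == min(d))
        gA$gene[cand[which.min(gA$start[cand])]]
    }
    for (rep in 1:100) {
        s <- runif(1, 0, max(gA$end) - 3e4)
        fg <- data.frame(chrom = "A1", start = s, end = s + 3e4)
        rp <- mapRegionToFlankingGenes(fg, fg, gA, sim$genomeB,
                                       sim$orthology)
        expect_equal(rp@foreground$geneA1, bruteNearest(s))
        expect_equal(rp@foreground$geneA2, bruteNearest(s + 3e4 - 1))
    }
    # a region inside a single gene is degenerate but mapped
    mid <- gA$start[50] + 100
    rp1 <- mapRegionToFlankingGenes(
        data.frame(chrom = "A1", start = mid, end = mid + 200),
        data.frame(chrom = "A1", start = mid, end = mid + 200),
        gA, sim$genomeB, sim$orthology)
    expect_true(rp1@foreground$degenerate)
    expect_equal(rp1@foreground$geneA1, rp1@foreground$geneA2)
    # anchor genes without orthologs exclude the region, with counts
    orthDrop <- sim$orthology[sim$orthology$geneA != gA$gene[50], ]
    rpD <- mapRegionToFlankingGenes(
        data.frame(chrom = "A1", start = mid, end = mid + 200),
        data.frame(chrom = "A1", start = 1, end = 300),
        gA, sim$genomeB, orthDrop)
    expect_equal(nrow(rpD@foreground), 0)
    expect_equal(unname(rpD@unmappable["foreground"]), 1)
})

test_that("identical foreground and background show no signal", {
    sim <- simulateOrthologGenomes(200, shuffleFraction = 0.5, seed = 9)
    set.seed(4)
    s <- sample(seq(0, 3.5e5, 1e3), 30)
    fg <- data.frame(chrom = "A1", start = s, end = s + 2e4)
    rp <- mapRegionToFlankingGenes(fg, fg, sim$genomeA, sim$genomeB,
                                   sim$orthology)
    res <- syntenyConservationTest(rp)
    expect_gte(res$chisqP, 0.99)
    expect_gte(res$wilcoxP, 0.5)
    expect_equal(res$effect, 0)
    # statistics invariant under relabelling of gene identifiers
    relab <- sim
    relab$genomeA$gene <- paste0("x_", relab$genomeA$gene)
    relab$orthology$geneA <- paste0("x_", relab$orthology$geneA)
    rpR <- mapRegionToFlankingGenes(fg, fg, relab$genomeA, relab$genomeB,
                                    relab$orthology)
    resR <- syntenyConservationTest(rpR)
    expect_equal(resR$wilcoxP, res$wilcoxP)
    expect_equal(resR$chisqP, res$chisqP)
})

test_that("planted conservation contrast is detected with high power", {
    rej <- replicate(10, NA)
    for (s in 1:10) {
        r <- simulateSyntenyScenario(nGenes = 2000, nForeground = 100,
                                     shuffleFraction = 0.5,
                                     conservedForeground = TRUE, seed = s)
        rej[s] <- (r$chisqP < 0.05) && (r$wilcoxP < 0.05)
    }
    expect_gte(mean(rej), 0.9)
    # power grows with the planted contrast
    pAt <- function(sh) {
        r <- simulateSyntenyScenario(nGenes = 2000, nForeground = 100,
                                     shuffleFraction = sh,
                                     conservedForeground = TRUE, seed = 77)
        r$wilcoxP
    }
    expect_true(pAt(0.6) <= pAt(0.3) || pAt(0.3) <= pAt(0.1))
})
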