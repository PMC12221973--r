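# shared fixture: a simulated chromosome with GP1 promoter loops,
# promoter-enhancer loops and all three gene classes
anchorFixture <- function() {
    bs <- 2e3; n <- 500
    tssBins <- seq(20, 470, by = 10)
    classes <- rep(c("GP1", "GP2", "GP3"), length.out = length(tssBins))
    genes <- data.frame(tss = (tssBins - 0.5) * bs, class = classes)
    gp1 <- tssBins[classes == "GP1"]
    enhBins <- gp1[seq(2, length(gp1), by = 2)] + 5L
    enh <- (enhBins - 0.5) * bs
    pp <- data.frame(bin1 = as.integer(head(gp1, -1)),
                     bin2 = as.integer(tail(gp1, -1)), e = 3)
    pe <- data.frame(bin1 = as.integer(gp1[seq(1, length(enhBins))]),
                     bin2 = as.integer(enhBins), e = 3)
    loops <- unique(rbind(pp, pe))
    loops <- loops[loops$bin2 - loops$bin1 >= 5, ]
    cfg <- simulationConfig(n * bs, bs, alpha = 0, depth = 1e7,
                            loops = loops, genes = genes, enhancers = enh,
                            seed = 9)
    list(cfg = cfg, bs = bs, genes = genes, enh = enh,
         loops = loops, gp1 = gp1, enhBins = enhBins,
         ann = simulateAnnotations(cfg))
}

test_that("anchors at planted promoters and enhancers classify as P and E", {
    fx <- anchorFixture()
    planted <- loopSetFromBins(fx$loops$bin1, fx$loops$bin2, fx$bs)
    ac <- classifyAnchors(planted, fx$ann$tracks,
                          trackBin = fx$cfg$trackBin, window = 2000)
    byBin <- setNames(ac$anchors$class, ac$anchors$bin)
    expect_true(all(byBin[as.character(fx$gp1)] == "P", na.rm = TRUE))
    expect_true(all(byBin[as.character(fx$enhBins)] == "E", na.rm = TRUE))
    expect_true(all(c("P-P", "P-E") %in% names(ac$categories)))

    # an anchor with background-only signal is U
    bare <- loopSetFromBins(c(fx$loops$bin1, 255L),
                            c(fx$loops$bin2, 455L), fx$bs)
    acB <- classifyAnchors(bare, fx$ann$tracks,
                           trackBin = fx$cfg$trackBin, window = 2000)
    byBinB <- setNames(acB$anchors$class, acB$anchors$bin)
    expect_equal(unname(byBinB["255"]), "U")
})

test_that("promoter hubs equal a brute-force union-find oracle", {
    # transitivity: P1-P2 and P2-P3 form one hub of three
    anchors <- data.frame(bin = c(10, 30, 60), class = "P")
    loops <- loopSetFromBins(c(10, 30), c(30, 60), 1e3)
    h <- promoterHubs(loops, anchors)
    expect_equal(nrow(h$hubs), 1)
    expect_equal(h$hubs$nPromoters, 3)

    # disjoint P-P loops: two hubs of two
    anchors2 <- data.frame(bin = c(10, 30, 60, 90), class = "P")
    loops2 <- loopSetFromBins(c(10, 60), c(30, 90), 1e3)
    h2 <- promoterHubs(loops2, anchors2)
    expect_equal(h2$hubs$nPromoters, c(2, 2))
    expect_equal(h2$medianPromoters, 2)

    # random loop graphs match the union-find oracle exactly
    set.seed(21)
    for (rep in 1:20) {
        bins <- sort(sample(1:300, 40))
        e1 <- sample(bins, 25, replace = TRUE)
        e2 <- sample(bins, 25, replace = TRUE)
        ok <- e1 != e2
        l1 <- pmin(e1[ok], e2[ok]); l2 <- pmax(e1[ok], e2[ok])
        dup <- duplicated(paste(l1, l2))
        l1 <- l1[!dup]; l2 <- l2[!dup]
        anchorsR <- data.frame(bin = bins, class = "P")
        loopsR <- loopSetFromBins(l1, l2, 1e3)
        got <- promoterHubs(loopsR, anchorsR)
        roots <- unionFindOracle(unique(c(l1, l2)), l1, l2)
        oracleSizes <- sort(unname(table(roots)[table(roots) >= 2]))
        expect_equal(sort(got$hubs$nPromoters), as.integer(oracleSizes))
        # loop-list order never changes membership
        perm <- sample(length(l1))
        got2 <- promoterHubs(loopSetFromBins(l1[perm], l2[perm], 1e3),
                             anchorsR)
        expect_equal(sort(got2$hubs$nPromoters),
                     sort(got$hubs$nPromoters))
    }
})

test_that("GP gene groups follow peaks and loop participation", {
    fx <- anchorFixture()
    planted <- loopSetFromBins(fx$loops$bin1, fx$loops$bin2, fx$bs)
    gp <- classifyGenesGp(fx$ann$genes, fx$ann$peaks$ATAC,
                          fx$ann$peaks$H3K4me3, planted, tssWindow = 1000)
    expect_gte(mean(gp$group == fx$genes$class), 0.95)
    # a gene with both peaks but no loop is GP2 by definition
    gp2row <- gp[fx$genes$class == "GP2", ][1, ]
    expect_true(gp2row$atac && gp2row$k4me3 && !gp2row$loop)
    expect_equal(gp2row$group, "GP2")
    # pure function: identical rerun
    gpAgain <- classifyGenesGp(fx$ann$genes, fx$ann$peaks$ATAC,
                               fx$ann$peaks$H3K4me3, planted,
                               tssWindow = 1000)
    expect_identical(gp, gpAgain)
})

test_that("loop statistics match a brute-force context scan", {
    fx <- anchorFixture()
    planted <- loopSetFromBins(fx$loops$bin1, fx$loops$bin2, fx$bs)
    ac <- classifyAnchors(planted, fx$ann$tracks,
                          trackBin = fx$cfg$trackBin, window = 2000)
    st <- loopStatistics(planted, fx$ann$genes, ac)
    expect_equal(st$medianSpan,
                 median((fx$loops$bin2 - fx$loops$bin1) * fx$bs))
    expect_true(!is.null(st$enhancersPerPromoter))

    # brute-force enhancer-context oracle
    eBins <- unique(ac$anchors$bin[ac$anchors$class == "E"])
    g <- fx$ann$genes
    want <- vapply(eBins, function(b) {
        p <- (b - 0.5) * fx$bs
        inExon <- any((p >= g$exon1_start & p < g$exon1_end) |
                      (p >= g$exon2_start & p < g$exon2_end))
        inGene <- any(p >= g$start & p < g$end)
        if (inExon) "exonic" else if (inGene) "intronic" else "intergenic"
    }, character(1))
    expect_equal(as.vector(st$enhancerContext),
                 as.vector(table(factor(want,
                     levels = c("exonic", "intronic", "intergenic")))))

    # single loop: median span is its own span
    one <- loopSetFromBins(10L, 20L, fx$bs)
    expect_equal(loopStatistics(one)$medianSpan, 10 * fx$bs)
})
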