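test_that("expected matrix follows the closed-form generative model", {
    # alpha = 0, no features: constant symmetric matrix
    cfg <- simulationConfig(1e4, 1e3, alpha = 0, depth = 1e4)
    expd <- buildExpectedMatrix(cfg)
    expect_equal(dim(expd), c(10, 10))
    expect_true(all(expd == expd[1, 1]))
    expect_identical(expd, t(expd))

    # boundary attenuation: pairs straddling the boundary scaled by b
    base <- buildExpectedMatrix(simulationConfig(2e4, 1e3, alpha = 1,
                                                 depth = 1e4))
    withB <- buildExpectedMatrix(simulationConfig(2e4, 1e3, alpha = 1,
        depth = 1e4, boundaries = data.frame(pos = 5e3, b = 0.5)))
    expect_equal(withB[4, 8], 0.5 * base[4, 8])   # straddles, distance 4
    expect_equal(withB[7, 9], base[7, 9])         # same side: untouched

    # loop pixel ratio e, halo (1+e)/2 on the 8 neighbours
    lp <- data.frame(bin1 = 10L, bin2 = 40L, e = 3)
    withL <- buildExpectedMatrix(simulationConfig(5e4, 1e3, alpha = 1,
                                                  depth = 1e4, loops = lp))
    base2 <- buildExpectedMatrix(simulationConfig(5e4, 1e3, alpha = 1,
                                                  depth = 1e4))
    expect_equal(withL[10, 40] / base2[10, 40], 3)
    expect_equal(withL[40, 10] / base2[40, 10], 3)
    expect_equal(withL[9, 40] / base2[9, 40], 2)   # (1 + 3) / 2
    expect_equal(withL[11, 41] / base2[11, 41], 2)

    # unmappable bins zeroed; loop anchors there rejected
    um <- data.frame(start = 3e3, end = 5e3)
    masked <- buildExpectedMatrix(simulationConfig(2e4, 1e3, alpha = 0,
                                                   depth = 1e4,
                                                   unmappable = um))
    expect_true(all(masked[4:5, ] == 0) && all(masked[, 4:5] == 0))
    expect_error(buildExpectedMatrix(simulationConfig(5e4, 1e3, alpha = 0,
        depth = 1e4, loops = data.frame(bin1 = 4L, bin2 = 30L, e = 2),
        unmappable = um)), "unmappable")

    # overlapping compartment intervals rejected
    expect_error(simulationConfig(1e5, 1e3, compartments = data.frame(
        start = c(0, 3e4), end = c(5e4, 8e4), state = c("A", "B"), f = 2)),
        "overlap")
})

test_that("contact sampling is Poisson with the configured depth and seed", {
    cfg <- simulationConfig(1e5, 1e3, alpha = 1, depth = 1e5)
    expd <- buildExpectedMatrix(cfg)
    m1 <- sampleContactCounts(expd, 1e5, seed = 3)
    m2 <- sampleContactCounts(expd, 1e5, seed = 3)
    expect_identical(m1, m2)                       # determinism
    expect_identical(m1, t(m1))                    # symmetrized
    m3 <- sampleContactCounts(expd, 1e5, seed = 4)
    expect_false(identical(m1, m3))

    # depth -> 1 limit: a near-empty matrix
    tiny <- sampleContactCounts(expd, 1, seed = 1)
    expect_lte(sum(tiny[upper.tri(tiny, diag = TRUE)]), 5)

    # Poisson oracle on a flat expected map: per-pixel counts within 3 SD
    # of lambda = depth / Npixels for >= 99% of pixels
    n <- 100
    flat <- matrix(1, n, n)
    depth <- 1e6
    cnt <- sampleContactCounts(flat, depth, seed = 9)
    ut <- upper.tri(flat, diag = TRUE)
    lam <- depth / sum(ut)
    frac <- mean(abs(cnt[ut] - lam) <= 3 * sqrt(lam))
    expect_gte(frac, 0.99)
    expect_error(sampleContactCounts(matrix(0, 4, 4), 100), "all-zero")
})

test_that("simulated annotations plant peaks consistent with gene classes", {
    # zero genes: background-only tracks, no peak intervals
    cfg0 <- simulationConfig(1e5, 1e3, genes = 0L, noise = 1, seed = 2)
    ann0 <- simulateAnnotations(cfg0)
    expect_equal(nrow(ann0$peaks$ATAC), 0)
    expect_lt(max(ann0$tracks$ATAC), 10)           # Poisson(1) background

    genes <- data.frame(tss = c(2e4, 5e4, 8e4),
                        class = c("GP1", "GP2", "GP3"))
    cfg <- simulationConfig(1e5, 1e3, genes = genes, enhancers = 65e3,
                            peakHeight = 50, peakWidth = 400, seed = 2)
    ann <- simulateAnnotations(cfg)
    tb <- cfg$trackBin
    # GP3 TSS carries no ATAC peak within +/- 1 kb
    gp3 <- trackWindowSum(ann$tracks$ATAC, tb, 8e4 - 1e3, 8e4 + 1e3)
    gp1 <- trackWindowSum(ann$tracks$ATAC, tb, 2e4 - 1e3, 2e4 + 1e3)
    expect_lt(gp3, 30)          # background only over 10 track bins
    expect_gt(gp1, 200)         # planted peak
    expect_false(any(abs((ann$peaks$ATAC$start + ann$peaks$ATAC$end) / 2
                         - 8e4) < 1e3))
    # planted enhancer: H3K4me1 over H3K4me3 ratio > 1 in its window
    me1 <- trackWindowSum(ann$tracks$H3K4me1, tb, 64e3, 66e3)
    me3 <- trackWindowSum(ann$tracks$H3K4me3, tb, 64e3, 66e3)
    expect_gt(me1 / me3, 1)
    expect_error(simulateAnnotations(simulationConfig(2e3, 1e3,
        genes = data.frame(tss = c(100, 500, 900, 1300, 1500,
                                   1600, 1700, 1800, 1850, 1900, 1950),
                           class = rep("GP1", 11)))),
        "more genes")
})

test_that("ortholog genome pairs shuffle gene order as configured", {
    same <- simulateOrthologGenomes(100, shuffleFraction = 0, seed = 1)
    expect_identical(same$genomeA$gene, same$genomeB$gene)
    expect_identical(same$orthology$geneA, same$orthology$geneB)

    rep1 <- simulateOrthologGenomes(100, shuffleFraction = 0.5, seed = 7)
    rep2 <- simulateOrthologGenomes(100, shuffleFraction = 0.5, seed = 7)
    expect_identical(rep1$genomeB$gene, rep2$genomeB$gene)

    # shuffle = 1: neighbour conservation at the random-permutation
    # baseline (permutation oracle over 1000 shuffles)
    n <- 200
    neighbourFrac <- function(orderB) {
        pos <- match(paste0("g", seq_len(n)), orderB)
        mean(abs(diff(pos)) == 1)
    }
    full <- simulateOrthologGenomes(n, shuffleFraction = 1, seed = 3)
    obs <- neighbourFrac(full$genomeB$gene)
    set.seed(99)
    perm <- replicate(1000, neighbourFrac(paste0("g", sample(n))))
    expect_lte(obs, quantile(perm, 0.999))
    expect_gte(obs, quantile(perm, 0.001))
})
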