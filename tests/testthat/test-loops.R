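test_that("the focal caller recovers planted loops and nothing on flat maps", {
    bs <- 2e3; n <- 500
    set.seed(3)
    a1 <- sample(20:200, 20); a2 <- a1 + sample(30:250, 20)
    keep <- a2 <= 480
    lp <- unique(data.frame(bin1 = as.integer(a1[keep]),
                            bin2 = as.integer(a2[keep]), e = 3))
    cfg <- simulationConfig(n * bs, bs, alpha = 0, depth = 1e7,
                            loops = lp, seed = 11)
    cm <- iceBalance(simulateContactMap(cfg)$matrix)
    calls <- callLoops(cm, minDist = 5, maxDist = 450)
    rec <- loopRecovery(calls, lp)
    expect_gte(rec$precision, 0.9)
    expect_gte(rec$recall, 0.9)

    # loop-free map: zero calls
    cfg0 <- simulationConfig(n * bs, bs, alpha = 0, depth = 1e7, seed = 12)
    cm0 <- iceBalance(simulateContactMap(cfg0)$matrix)
    expect_equal(nLoops(callLoops(cm0, minDist = 5, maxDist = 450)), 0)

    # two loops sharing an anchor stay two loops; the anchor table
    # deduplicates the shared anchor
    lpS <- data.frame(bin1 = c(50L, 50L), bin2 = c(150L, 260L), e = 4)
    cfgS <- simulationConfig(n * bs, bs, alpha = 0, depth = 1e7,
                             loops = lpS, seed = 13)
    cmS <- iceBalance(simulateContactMap(cfgS)$matrix)
    callsS <- callLoops(cmS, minDist = 5, maxDist = 450)
    expect_equal(nLoops(callsS), 2)
    allAnchors <- c(callsS@anchor1, callsS@anchor2)
    expect_equal(length(unique(allAnchors)), 3)
    expect_error(callLoops(cm, minDist = 600, maxDist = 700), "band")
})

test_that("APA reflects planted enrichment and is scale-invariant", {
    bs <- 2e3; n <- 400
    set.seed(7)
    a1 <- seq(30, 150, by = 15)
    a2 <- a1 + 170 + 4 * seq_along(a1)   # distinct spans per loop
    lp <- data.frame(bin1 = as.integer(a1), bin2 = as.integer(a2), e = 3)
    cfg <- simulationConfig(n * bs, bs, alpha = 0, depth = 1e7,
                            loops = lp, seed = 14)
    sim <- simulateContactMap(cfg)
    cm <- iceBalance(sim$matrix)
    planted <- loopSetFromBins(lp$bin1, lp$bin2, bs)
    ap <- apaScore(cm, planted, halfWindow = 10)
    expect_gte(ap$aggregate, 2.5)
    expect_lte(ap$aggregate, 3.5)
    # closed form on the noise-free expected matrix: center/corner = e
    cmE <- iceBalance(contactMatrix(sim$expected * 1e6, bs), tol = 1e-12)
    apE <- apaScore(cmE, planted, halfWindow = 10)
    expect_equal(apE$aggregate, 3, tolerance = 0.1)

    # scaling all counts leaves APA unchanged
    cm2 <- iceBalance(contactMatrix(rawCounts(cm) * 3, bs))
    ap2 <- apaScore(cm2, planted, halfWindow = 10)
    expect_equal(ap2$aggregate, ap$aggregate, tolerance = 1e-9)

    # distance-preserving shuffle of loop positions: no enrichment
    shift <- loopSetFromBins(lp$bin1 + 40, lp$bin2 + 40, bs)
    apS <- apaScore(cm, shift, halfWindow = 10)
    expect_gte(apS$aggregate, 0.9)
    expect_lte(apS$aggregate, 1.1)

    # loops too close to the diagonal/edge are skipped and counted
    tight <- loopSetFromBins(c(5L, 100L), c(15L, 280L), bs)
    apT <- apaScore(cm, tight, halfWindow = 10)
    expect_equal(apT$nSkipped, 1L)
})

test_that("APA outlier filtering removes extreme loops and is idempotent", {
    mk <- function(apas) {
        ls <- loopSetFromBins(seq(10, by = 10,
                                  length.out = length(apas)),
                              seq(110, by = 10, length.out = length(apas)),
                              1e3)
        ls@apa <- apas
        ls
    }
    set.seed(9)
    homog <- mk(exp(rnorm(50, 0, 0.1)))
    out <- filterApaOutliers(homog)
    expect_equal(nLoops(out$loops), 50)

    spiked <- mk(c(exp(rnorm(50, 0, 0.1)), 100 * exp(0)))
    out2 <- filterApaOutliers(spiked)
    expect_equal(nrow(out2$removed), 1)
    expect_equal(out2$removed$apa, 100)

    # idempotent on its own output
    out3 <- filterApaOutliers(out2$loops)
    expect_equal(nLoops(out3$loops), nLoops(out2$loops))
    expect_error(filterApaOutliers(mk(rep(1, 5))), "10 loops")
})
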