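test_that("site classes follow the configured proportions", {
    truth <- simulateTruth(simConfig(nSites = 500, propTrueSnp = 0,
                                     propParalog = 0, seed = 2))
    expect_true(all(truth@siteClass == "monomorphic"))
    expect_true(all(truth@freqFast == 0) && all(truth@freqSlow == 0))

    truth2 <- simulateTruth(simConfig(nSites = 10000, propTrueSnp = 0.1,
                                      seed = 3))
    nSnp <- sum(truth2@siteClass == "true_snp")
    ## 99% binomial interval around 1000
    expect_gt(nSnp, qbinom(0.005, 10000, 0.1))
    expect_lt(nSnp, qbinom(0.995, 10000, 0.1))
})

test_that("the simulator is reproducible from its seed", {
    cfg <- simConfig(nSites = 300, seed = 99)
    t1 <- simulateTruth(cfg); t2 <- simulateTruth(cfg)
    expect_identical(truthTable(t1), truthTable(t2))
    e1 <- simulateEvidence(t1); e2 <- simulateEvidence(t2)
    expect_identical(writeSiteEvidence(e1), writeSiteEvidence(e2))
    t3 <- simulateTruth(simConfig(nSites = 300, seed = 100))
    expect_false(identical(truthTable(t1), truthTable(t3)))
})

test_that("fixed divergent genotypes force the expected pool frequencies", {
    cfg <- simConfig(nSites = 50, propTrueSnp = 1, propParalog = 0,
                     errorRate = 0, coveragePerFish = 5,
                     freqPairs = matrix(c(1, 0), 1,
                                        dimnames = list(NULL,
                                                        c("fast", "slow"))),
                     seed = 6)
    truth <- simulateTruth(cfg)
    expect_true(all(truth@genoFast == 2L) && all(truth@genoSlow == 0L))
    se <- simulateEvidence(truth)
    ok <- rowSums(poolCounts(se, "fast")) > 0 &
          rowSums(poolCounts(se, "slow")) > 0
    alt <- truth@alt
    fF <- poolAlleleFrequency(se[ok], alt[ok], "fast")
    fS <- poolAlleleFrequency(se[ok], alt[ok], "slow")
    expect_true(all(fF == 1))
    expect_true(all(fS == 0))
})

test_that("pool depth matches the coverage model", {
    truth <- simulateTruth(simConfig(nSites = 10000, seed = 21))
    se <- simulateEvidence(truth)
    mono <- truth@siteClass != "paralog"
    m <- mean(poolDepth(se, "fast")[mono])
    se3 <- 3 * sqrt(9.7 / sum(mono))
    expect_lt(abs(m - 9.7), se3)
})

test_that("discovery evaluation metrics match a hand-built confusion table", {
    cfg <- simConfig(nSites = 5, seed = 1)
    truth <- new("SimTruth",
        contig = sprintf("tc%06d", 1:5), pos = rep(100L, 5),
        ref = rep("A", 5), alt = rep("T", 5),
        siteClass = c("true_snp", "true_snp", "paralog", "monomorphic",
                      "true_snp"),
        freqFast = c(0.9, 0.8, NA, 0, 0.5),
        freqSlow = c(0.1, 0.7, NA, 0, 0.04),
        genoFast = matrix(0L, 5, 10), genoSlow = matrix(0L, 5, 10),
        dhHetSites = integer(), config = cfg)
    recs <- data.frame(
        contig = sprintf("tc%06d", c(1, 3, 5)), pos = rep(100L, 3),
        ref = "A", variantAllele = "T",
        fFast = c(0.85, 0.5, 0.5), fSlow = c(0.12, 0.5, 0.05),
        score = c(0.85 / 0.12, 1, 10),
        class = c("amplification", "balanced", "amplification"),
        detectedFast = TRUE, detectedSlow = FALSE,
        nFast = 10L, nSlow = 10L, siteDepth = 20L,
        key = sprintf("tc%06d:100", c(1, 3, 5)), flags = "")
    dsc <- new("PoolDiscovery", records = recs,
               paralogs = recs[0, ],
               funnel = c(sitesExamined = 5L, putativeSNPs = 3L,
                          postParalogFilter = 3L, imbalanced = 2L),
               config = stringencyConfig())
    m <- evaluateDiscovery(truth, dsc, margin = 0.25)
    ## discovered: sites 1 (true), 3 (paralog), 5 (true) -> 2/3 validated
    expect_equal(m$validationRate, 2 / 3)
    ## divergent true SNPs (|dF| > 0.25): sites 1 and 5; both discovered
    expect_equal(m$sensitivity, 1)
    expect_equal(m$falseDiscoveryCount, 1L)
    ## true classes: 0.9/0.1 = 9 -> amplification (match);
    ## 0.5/0.04 = 12.5 -> amplification (match)
    expect_equal(m$imbalanceClassAccuracy, 1)

    ## an unknown site key is a contract violation
    bad <- dsc; bad@records$key[1] <- "nope:1"
    expect_error(evaluateDiscovery(truth, bad), "mismatch")
})

test_that("empty discovery reports NA validation rate and zero sensitivity", {
    truth <- simulateTruth(simConfig(nSites = 50, seed = 4))
    dsc <- discoverSNPs(parseSiteEvidence(character()))
    dsc@funnel["sitesExamined"] <- 50L
    m <- evaluateDiscovery(truth, dsc)
    expect_true(is.na(m$validationRate))
    expect_equal(m$sensitivity, 0)
})

test_that("with no error and no paralogs every discovery is a true SNP", {
    cfg <- simConfig(nSites = 3000, propParalog = 0, errorRate = 0, seed = 12)
    truth <- simulateTruth(cfg)
    dsc <- discoverSNPs(simulateEvidence(truth))
    m <- evaluateDiscovery(truth, dsc)
    expect_gt(m$nDiscovered, 0)
    expect_equal(m$validationRate, 1.0)
})

test_that("pooled frequency recovery sharpens with depth", {
    depths <- c(5, 10, 50, 200)
    rmse <- bias <- se3 <- numeric(length(depths))
    for (i in seq_along(depths)) {
        cfg <- simConfig(nSites = 1500, propTrueSnp = 1, propParalog = 0,
                         errorRate = 0,
                         coveragePerFish = depths[i] / 10, seed = 41)
        truth <- simulateTruth(cfg)
        se <- simulateEvidence(truth)
        ok <- rowSums(poolCounts(se, "fast")) > 0
        est <- poolAlleleFrequency(se[ok], truth@alt[ok], "fast")
        target <- rowMeans(truth@genoFast)[ok] / 2   # pool sample frequency
        err <- est - target
        rmse[i] <- sqrt(mean(err^2))
        bias[i] <- mean(err)
        se3[i] <- 3 * sd(err) / sqrt(length(err))
    }
    expect_true(all(diff(rmse) < 0))          # monotone over 5,10,50,200
    expect_true(all(abs(bias) < se3))         # unbiased within 3 SE
})

test_that("family mode produces full-sib genotype structure", {
    cfg <- simConfig(nSites = 400, propTrueSnp = 1, propParalog = 0,
                     familyMode = TRUE, seed = 77)
    truth <- simulateTruth(cfg)
    ## with two parents, at most 3 distinct offspring genotypes per site
    nDistinct <- apply(truth@genoFast, 1, function(g) length(unique(g)))
    expect_true(all(nDistinct <= 3))
})
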