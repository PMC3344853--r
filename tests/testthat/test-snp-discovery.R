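cfgDefault <- stringencyConfig()

test_that("stringency boundaries are pinned exactly as stated", {
    ## 4 reads, 40% fraction, Q30: passes all three rules
    se <- makeSite("A", c(A = 6, T = 4), c(A = 35, T = 30))
    d <- detectVariant(se, "fast")
    expect_true(d$pass); expect_equal(d$allele, "T")

    ## 3 reads: below the "at least 4 reads" minimum
    d <- detectVariant(makeSite("A", c(A = 7, T = 3), c(A = 35, T = 30)),
                       "fast")
    expect_false(d$pass); expect_equal(d$reason, "too_few_reads")

    ## fraction exactly 20% is not > 20%
    d <- detectVariant(makeSite("A", c(A = 16, T = 4), c(A = 35, T = 30)),
                       "fast")
    expect_false(d$pass); expect_equal(d$reason, "low_fraction")

    ## quality exactly 20 is not > 20; just above passes
    expect_false(detectVariant(
        makeSite("A", c(A = 6, T = 4), c(A = 35, T = 20)), "fast")$pass)
    expect_true(detectVariant(
        makeSite("A", c(A = 6, T = 4), c(A = 35, T = 20.01)), "fast")$pass)

    ## "at least 4" is inclusive: exactly 4 reads pass
    expect_true(detectVariant(
        makeSite("A", c(A = 5, T = 4), c(A = 35, T = 30)), "fast")$pass)
})

test_that("variant allele is the top non-reference base, ties alphabetical", {
    d <- detectVariant(makeSite("A", c(A = 2, C = 4, G = 4),
                                c(A = 30, C = 30, G = 30)), "fast")
    expect_equal(d$allele, "C")
    d2 <- detectVariant(makeSite("T", c(T = 2, G = 5, C = 3),
                                 c(T = 30, G = 30, C = 30)), "fast")
    expect_equal(d2$allele, "G")
})

test_that("zero coverage fails softly with a reason, not an error", {
    se <- makeSite("A", c(A = 0), countsSlow = c(A = 10), qualSlow = c(A = 30))
    d <- detectVariant(se, "fast")
    expect_false(d$pass)
    expect_equal(d$reason, "no_coverage")
})

test_that("pooled allele frequencies come from read counting", {
    se <- makeSite("A", c(A = 6, T = 4))
    expect_equal(poolAlleleFrequency(se, "T", "fast"), 0.4)
    expect_equal(poolAlleleFrequency(se, "C", "fast"), 0.0)
    empty <- makeSite("A", c(A = 0), countsSlow = c(A = 5))
    expect_error(poolAlleleFrequency(empty, "T", "fast"), "zero usable")
})

test_that("imbalance score is the fast/slow frequency ratio with Inf limit", {
    expect_equal(imbalanceScore(0.40, 0.05), 8.0)
    expect_equal(imbalanceScore(0.30, 0.30), 1.0)
    expect_identical(imbalanceScore(0.20, 0), Inf)
    expect_equal(imbalanceScore(0, 0.3), 0)
    expect_error(imbalanceScore(0, 0), "both pool frequencies")
})

test_that("score duality holds: score(a,b) * score(b,a) = 1", {
    set.seed(31)
    a <- runif(200, 0.01, 1); b <- runif(200, 0.01, 1)
    expect_equal(imbalanceScore(a, b) * imbalanceScore(b, a),
                 rep(1, 200), tolerance = 1e-12)
})

test_that("imbalance classification is strict at both boundaries", {
    expect_equal(classifyImbalance(5.0 + 1e-9), "amplification")
    expect_equal(classifyImbalance(5.0), "balanced")
    expect_equal(classifyImbalance(0.2), "balanced")
    expect_equal(classifyImbalance(0.2 - 1e-9), "LOH")
    expect_equal(classifyImbalance(0.18), "LOH")
    expect_equal(classifyImbalance(Inf), "amplification")
    expect_equal(classifyImbalance(0), "LOH")
})

test_that("classification is monotone in the fast-pool frequency", {
    fSlow <- 0.1
    rank <- c(LOH = 1, balanced = 2, amplification = 3)
    classes <- classifyImbalance(imbalanceScore(seq(0, 1, by = 0.01), fSlow))
    expect_true(all(diff(rank[classes]) >= 0))
})

test_that("paralog filter applies the self-variant list and depth rule", {
    recs <- data.frame(
        key = c("tc1:1", "tc2:1", "tc3:1"),
        fFast = c(0.05, 0.5, 0.5), fSlow = c(0.01, 0.5, 0.5),
        siteDepth = c(20L, 200L, 20L))
    flagged <- paralogFilter(recs, dhHetSites = "tc1:1", medianDepth = 20)
    expect_equal(flagged, c(TRUE, TRUE, FALSE))
    ## without the list, only the deep balanced-fraction site is flagged
    expect_equal(paralogFilter(recs, medianDepth = 20),
                 c(FALSE, TRUE, FALSE))
})

test_that("engineered funnel fixture yields the designed survivor count", {
    n <- 100L
    B <- c("A", "C", "G", "T")
    cf <- matrix(0L, n, 4, dimnames = list(NULL, B))
    qf <- matrix(0, n, 4, dimnames = list(NULL, B))
    cf[, "A"] <- 10L; qf[, "A"] <- 35
    cs <- cf; qs <- qf
    hot <- 1:10   # 10 sites engineered to pass and be amplifications
    cf[hot, "A"] <- 4L; cf[hot, "T"] <- 6L; qf[hot, "T"] <- 35
    se <- SiteEvidence(sprintf("tc%06d", 1:n), rep(100L, n), rep("A", n),
                       countsFast = cf, qualFast = qf,
                       countsSlow = cs, qualSlow = qs)
    dsc <- discoverSNPs(se)
    expect_equal(unname(funnelReport(dsc)),
                 c(100L, 10L, 10L, 10L))
    recs <- imbalanceRecords(dsc)
    expect_true(all(recs$class == "amplification"))
    expect_true(all(is.infinite(recs$score)))   # f_slow = 0
})

test_that("all-reference evidence yields no putative SNPs", {
    se <- makeVariantGrid(rep(10L, 50), rep(0L, 50), rep(0, 50))
    dsc <- discoverSNPs(se)
    expect_equal(funnelReport(dsc)[["putativeSNPs"]], 0L)
})

test_that("discovery is deterministic and funnel counts weakly decrease", {
    truth <- simulateTruth(simConfig(nSites = 1500, seed = 17))
    se <- simulateEvidence(truth)
    d1 <- discoverSNPs(se, dhHetSites = dhHetSiteKeys(truth))
    d2 <- discoverSNPs(se, dhHetSites = dhHetSiteKeys(truth))
    expect_identical(writeDiscoveryVcf(d1), writeDiscoveryVcf(d2))
    f <- funnelReport(d1)
    expect_true(all(diff(unname(f)) <= 0))
    ## removing the paralog filter never decreases any funnel count
    d0 <- discoverSNPs(se, dhHetSites = character(),
                       depthMultiplier = Inf)
    expect_true(all(unname(funnelReport(d0)) >= unname(funnelReport(d1))))
})

test_that("unsorted evidence is rejected", {
    se <- makeVariantGrid(c(10L, 10L), c(0L, 0L), c(0, 0))
    se@contig <- c("tc2", "tc1")
    expect_error(discoverSNPs(se), "sorted")
})

test_that("pools passing on different alleles are excluded as discordant", {
    se <- makeSite("A", c(A = 4, T = 6), c(A = 30, T = 30),
                   countsSlow = c(A = 4, G = 6), qualSlow = c(A = 30, G = 30))
    dsc <- discoverSNPs(se)
    expect_equal(nrow(imbalanceRecords(dsc)), 0)
    expect_equal(paralogRecords(dsc)$flags, "discordant_allele")
})

test_that("a variant with no usable reads in the other pool is set aside", {
    se <- makeSite("A", c(A = 4, T = 6), c(A = 30, T = 30),
                   countsSlow = c(A = 0), qualSlow = NULL)
    dsc <- discoverSNPs(se)
    expect_equal(nrow(imbalanceRecords(dsc)), 0)
    expect_equal(paralogRecords(dsc)$flags, "no_coverage_other_pool")
})
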