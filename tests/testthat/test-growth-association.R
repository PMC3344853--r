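test_that("specific growth rate follows the log-ratio-per-day formula", {
    expect_equal(sgr(100, 200, 170, 218), 100 * log(2) / 48)
    expect_equal(sgr(350, 350, 218, 282), 0)
    expect_error(sgr(100, 200, 218, 218), "strictly increasing")
    expect_error(sgr(-1, 200, 170, 218), "positive")
})

test_that("coefficient of variation is SD over mean", {
    x <- c(75, 100, 125)
    expect_equal(cv(x), sd(x) / 100)
    expect_equal(cv(rep(7, 5)), 0)
    expect_error(cv(5), "two values")
    expect_error(cv(c(-1, 1)), "mean is zero")
})

test_that("allele-count regression matches the closed-form OLS oracle", {
    d <- c(0, 0, 1, 1, 2, 2)
    y <- c(10.2, 11.1, 13.4, 12.8, 16.1, 15.7)
    res <- alleleCountRegression(y, d)
    ora <- olsOracle(y, d)
    expect_equal(res$b, ora$b, tolerance = 1e-10)
    expect_equal(res$t, ora$t, tolerance = 1e-10)
    expect_equal(res$p, ora$p, tolerance = 1e-10)
    expect_equal(res$r2, ora$r2, tolerance = 1e-10)
})

test_that("regression degenerate cases behave as documented", {
    expect_equal(alleleCountRegression(rep(5, 6), c(0, 0, 1, 1, 2, 2))[
        c("b", "t", "p")], list(b = 0, t = 0, p = 1))
    expect_error(alleleCountRegression(rnorm(6), rep(1, 6)), "degenerate")
    res <- suppressWarnings(alleleCountRegression(2 * c(0, 0, 1, 1, 2, 2),
                                                  c(0, 0, 1, 1, 2, 2)))
    expect_equal(res$r2, 1)
    expect_true(res$degenerateSE)
})

test_that("R2 identity t^2/(t^2+df) holds for simple regressions", {
    set.seed(11)
    for (i in 1:25) {
        n <- sample(10:60, 1)
        d <- rbinom(n, 2, 0.3)
        if (var(d) == 0) next
        y <- rnorm(n) + 0.3 * d
        res <- alleleCountRegression(y, d)
        expect_equal(res$r2, res$t^2 / (res$t^2 + res$df), tolerance = 1e-10)
    }
})

test_that("the slope sign flips under allele relabelling", {
    set.seed(12)
    d <- rbinom(40, 2, 0.4); y <- rnorm(40) + d
    r1 <- alleleCountRegression(y, d)
    r2 <- alleleCountRegression(y, 2 - d)
    expect_equal(r1$b, -r2$b)
    expect_equal(r1$p, r2$p)
})

test_that("permutation P is deterministic given a seed and in range", {
    set.seed(13)
    d <- rbinom(50, 2, 0.4); y <- rnorm(50) + 0.5 * d
    e1 <- empiricalP(y, d, K = 999, seed = 21)
    e2 <- empiricalP(y, d, K = 999, seed = 21)
    expect_identical(e1$empiricalP, e2$empiricalP)
    expect_gte(e1$empiricalP, 1 / 1000)
    expect_lte(e1$empiricalP, 1)
    expect_equal(empiricalP(rep(3, 30), rbinom(30, 2, 0.5), K = 99,
                            seed = 1)$empiricalP, 1)
})

test_that("empirical P agrees with the asymptotic P under normality", {
    set.seed(14)
    n <- 200
    d <- rbinom(n, 2, 0.4)
    y <- rnorm(n) + 0.12 * d
    res <- alleleCountRegression(y, d)
    K <- 4000
    ep <- empiricalP(y, d, K = K, seed = 3)$empiricalP
    se <- sqrt(res$p * (1 - res$p) / K)
    expect_lt(abs(ep - res$p), 3 * se + 2 / (K + 1))
})

test_that("within-family permutation preserves family structure", {
    set.seed(15)
    fam <- rep(sprintf("F%02d", 1:10), each = 6)
    d <- rbinom(60, 2, 0.4)
    famEff <- rep(rnorm(10, sd = 3), each = 6)
    y <- famEff + rnorm(60)
    ## the trait is family-structured but unlinked to dosage within family:
    ## the within-family empirical P should not be systematically small
    ep <- empiricalP(y, d, K = 499, scheme = "within_family",
                     family = fam, seed = 8)
    expect_gte(ep$empiricalP, 1 / 500)
    expect_error(empiricalP(y, d, scheme = "within_family"), "family")
})

test_that("BH adjustment matches the hand step-up and is idempotent", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
    expect_equal(bhFdr(0.2), 0.2)
    expect_equal(bhFdr(rep(0.03, 4)), rep(0.03, 4))
    p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
    adj <- bhFdr(p)
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_equal(order(adj), order(p))           # monotone in order stats
    ## re-adjustment preserves order and bounds
    re <- bhFdr(adj)
    expect_equal(order(re), order(adj))
    expect_true(all(re >= adj) && all(re <= 1))
    expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("unrelated sampling draws one offspring per family", {
    fp <- simulateFamilyPanel(nFamilies = 40, nOffspring = 5, seed = 30)
    sets <- sampleUnrelated(fp$pedigree, sampleIds(fp$genotypes),
                            nSets = 3, seed = 31)
    expect_length(sets, 3)
    for (s in sets) {
        expect_length(s, 40)
        fams <- fp$pedigree$family[match(s, fp$pedigree$sample)]
        expect_equal(anyDuplicated(fams), 0)
    }
    expect_identical(sets,
                     sampleUnrelated(fp$pedigree, sampleIds(fp$genotypes),
                                     nSets = 3, seed = 31))
})

test_that("mitochondrial haplotypes collapse, rescue and stay distinct", {
    fp <- simulateFamilyPanel(nFamilies = 30, nOffspring = 6, seed = 33,
                              missingRate = 0)
    ht <- buildMtHaplotypes(fp$genotypes)
    expect_equal(nrow(ht$haplotypes), 3)
    expect_equal(sum(ht$haplotypes$frequency), 1)
    ## the two near-identical haplotypes differ at exactly two markers
    s <- strsplit(ht$haplotypes$string, "")
    diffs <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
        sum(s[[i]] != s[[j]])))
    expect_true(2 %in% diffs[upper.tri(diffs)])
    ## dam haplotype is recovered exactly when nothing is missing
    off <- fp$pedigree$generation == "offspring"
    ord <- match(fp$pedigree$sample[off], names(ht$assignment))
    hapOfString <- ht$assignment[ord]
    expect_equal(length(unique(paste(hapOfString, fp$hapAssign))),
                 length(unique(fp$hapAssign)))

    ## rescue: up to 2 missing calls still assign uniquely
    gm <- fp$genotypes
    calls <- genoCalls(gm)
    mito <- markerInfo(gm)$marker[markerInfo(gm)$genome == "mito"]
    calls[1, mito[3:4]] <- NA_integer_
    gm2 <- new("GenotypeMatrix", calls = calls, markers = markerInfo(gm))
    ht2 <- buildMtHaplotypes(gm2)
    expect_false(is.na(ht2$assignment[1]))
    ## masking both distinguishing markers of a carrier of one of the two
    ## near-identical haplotypes makes the assignment ambiguous
    off1 <- fp$pedigree$sample[off][match(2, fp$hapAssign)]
    calls2 <- genoCalls(fp$genotypes)
    calls2[off1, mito[c(8, 21)]] <- NA_integer_
    gm3 <- new("GenotypeMatrix", calls = calls2, markers = markerInfo(gm))
    ht3 <- buildMtHaplotypes(gm3)
    expect_true(is.na(ht3$assignment[off1]))
})

test_that("haplotype association recovers a known carrier effect", {
    set.seed(16)
    delta <- 25
    hits <- 0
    for (r in 1:20) {
        carrier <- rbinom(80, 1, 0.3)
        if (var(carrier) == 0) next
        y <- 500 + delta * carrier + rnorm(80, sd = 40)
        res <- haplotypeAssociation(y, carrier, K = 199, seed = r)
        if (abs(res$b - delta) <= 2 * res$se) hits <- hits + 1
        expect_gte(res$empiricalP, 1 / 200)
    }
    expect_gte(hits, 16)   # ~95% coverage over 20 replicates
    expect_error(haplotypeAssociation(rnorm(10), rep(1, 10)), "degenerate")
})

test_that("slope estimation is unbiased with near-nominal CI coverage", {
    set.seed(17)
    beta <- 12; nRep <- 300; n <- 80
    est <- se <- numeric(nRep)
    for (r in 1:nRep) {
        d <- rbinom(n, 2, 0.35)
        y <- beta * d + rnorm(n, sd = 10)
        res <- alleleCountRegression(y, d)
        est[r] <- res$b; se[r] <- res$se
    }
    bias <- mean(est) - beta
    expect_lt(abs(bias), 3 * sd(est) / sqrt(nRep))
    cover <- mean(abs(est - beta) <= qt(0.975, n - 2) * se)
    expect_gt(cover, 0.91); expect_lt(cover, 0.99)
})
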