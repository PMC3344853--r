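test_that("empty evidence streams parse to zero-length objects", {
    expect_length(parseSiteEvidence(character(), dialect = "mpileup2"), 0)
    expect_length(parseSiteEvidence(character(), dialect = "native_tsv"), 0)
    expect_length(parseSiteEvidence("contig\tpos\tref\tdepth_fast\tbases_fast\tdepth_slow\tbases_slow"), 0)
})

test_that("mpileup read-base strings are decoded by hand-countable rules", {
    ## fast block: 6 reference (./,) + 4 T among depth 10
    line <- paste("tc1", "5", "A", "10", "..,,TTTT..", "IIIIIFFFFI",
                  "8", "........", "IIIIIIII", sep = "\t")
    se <- parseSiteEvidence(line, dialect = "mpileup2")
    expect_equal(unname(poolCounts(se, "fast")[1, ]), c(6L, 0L, 0L, 4L))
    expect_equal(unname(poolCounts(se, "slow")[1, ]), c(8L, 0L, 0L, 0L))
    ## 'I' is Phred 40, 'F' is 37; T reads (positions 5-8) carry I,F,F,F
    expect_equal(unname(poolQuals(se, "fast")[1, "T"]), (40 + 3 * 37) / 4)
    expect_equal(unname(poolQuals(se, "fast")[1, "A"]), (5 * 40 + 37) / 6)

    ## caret (start + mapq), dollar, indels and N consume correctly
    line2 <- paste("tc1", "6", "G", "6", "^F..+2ATt$,N*", "IIHHGF",
                   "3", ",,.", "III", sep = "\t")
    se2 <- parseSiteEvidence(line2, dialect = "mpileup2")
    cnt <- poolCounts(se2, "fast")[1, ]
    expect_equal(unname(cnt), c(0L, 0L, 3L, 1L))  # three ref G, one t
    ## lower-case (reverse-strand) bases merge with upper-case
    expect_equal(unname(poolQuals(se2, "fast")[1, "T"]),
                 utf8ToInt("H") - 33)

    ## min-quality aggregation is available at parse time
    se3 <- parseSiteEvidence(line, dialect = "mpileup2",
                             qualityAggregation = "min")
    expect_equal(unname(poolQuals(se3, "fast")[1, "A"]), 37)
})

test_that("malformed pileup lines report the offending line", {
    good <- "tc1\t5\tA\t4\t....\tIIII\t2\t..\tII"
    short <- "tc1\t6\tA\t4\t....\tIII\t2\t..\tII"
    expect_error(parseSiteEvidence(c(good, short), dialect = "mpileup2"),
                 "line 2")
    expect_error(parseSiteEvidence("tc1\tx\tA\t1\t.\tI\t1\t.\tI",
                                   dialect = "mpileup2"), "position")
    expect_error(parseSiteEvidence("tc1\t5\tA\t1\t.\tI", dialect = "mpileup2"),
                 "9 mpileup columns")
})

test_that("native TSV evidence round-trips field for field", {
    truth <- simulateTruth(simConfig(nSites = 300, seed = 5))
    se <- simulateEvidence(truth)
    lines <- writeSiteEvidence(se)
    back <- parseSiteEvidence(lines, dialect = "native_tsv")
    expect_equal(back@contig, se@contig)
    expect_equal(back@pos, se@pos)
    expect_equal(back@ref, se@ref)
    expect_equal(back@countsFast, se@countsFast)
    expect_equal(back@countsSlow, se@countsSlow)
    expect_equal(back@depthFast, se@depthFast)
    expect_equal(back@qualFast, se@qualFast, tolerance = 1e-4)
    ## counted reads never exceed depth
    expect_true(all(rowSums(back@countsFast) <= back@depthFast))
})

test_that("genotype, pedigree and phenotype TSVs validate on read", {
    dir <- withr::local_tempdir()
    gm <- new("GenotypeMatrix",
              calls = matrix(c(0L, 1L), 2, 1,
                             dimnames = list(c("s1", "s2"), "m1")),
              markers = data.frame(marker = "m1", a1 = "A", a2 = "G",
                                   genome = "nuclear"))
    writeGenotypes(gm, file.path(dir, "g.tsv"), file.path(dir, "m.tsv"))
    back <- readGenotypes(file.path(dir, "g.tsv"), file.path(dir, "m.tsv"))
    expect_equal(genoCalls(back), genoCalls(gm))
    expect_equal(markerInfo(back)$a2, "G")

    ped <- data.frame(sample = c("s1", "s2"), sire = c(NA, "s1"),
                      dam = c(NA, NA), family = c("F1", "F1"),
                      generation = c("parent", "offspring"))
    expect_silent(readPedigree(ped))
    bad <- data.frame(sample = "s1", sire = "s1", dam = NA,
                      family = "F1", generation = "x")
    expect_error(readPedigree(bad), "own ancestor")

    ph <- data.frame(sample = c("s1", "s2"), weight_170 = c(60, 65),
                     weight_218 = c(150, 140))
    expect_equal(attr(readPhenotypes(ph), "times"), c(170L, 218L))
    ph$weight_218[1] <- -1
    expect_error(readPhenotypes(ph), "non-positive")
})

test_that("heterozygous calls at mitochondrial markers are flagged on read", {
    dir <- withr::local_tempdir()
    writeLines(c("sample\tmt1", "s1\tA/G", "s2\tA/A"),
               file.path(dir, "g.tsv"))
    writeLines(c("marker\ta1\ta2\tgenome", "mt1\tA\tG\tmito"),
               file.path(dir, "m.tsv"))
    expect_warning(
        gm <- readGenotypes(file.path(dir, "g.tsv"), file.path(dir, "m.tsv")),
        "mitochondrial")
    expect_equal(attr(gm, "mitoHet"), "mt1")
})

test_that("discovery VCF writes valid v4.2 and round-trips", {
    emptyVcf <- writeDiscoveryVcf(discoverSNPs(parseSiteEvidence(character())))
    expect_true(all(startsWith(emptyVcf, "#")))

    truth <- simulateTruth(simConfig(nSites = 1500, seed = 8))
    dsc <- discoverSNPs(simulateEvidence(truth),
                        dhHetSites = dhHetSiteKeys(truth))
    lines <- writeDiscoveryVcf(dsc)
    expect_equal(lines[1], "##fileformat=VCFv4.2")
    back <- readDiscoveryVcf(lines)
    both <- rbind(imbalanceRecords(dsc), paralogRecords(dsc))
    both <- both[order(both$contig, both$pos), ]
    expect_equal(back$key, both$key)
    expect_equal(back$fFast, both$fFast, tolerance = 1e-5)
    expect_equal(back$score, both$score, tolerance = 1e-5)
    expect_equal(back$class, both$class)
    expect_equal(back$flags, both$flags)

    ## an extreme imbalance serialises its score as 8 (0.40 / 0.05)
    rec <- data.frame(contig = "tc1", pos = 7L, ref = "A",
                      variantAllele = "T", fFast = 0.40, fSlow = 0.05,
                      score = 0.40 / 0.05, class = "amplification",
                      flags = "", key = "tc1:7")
    expect_match(writeDiscoveryVcf(rec)[length(writeDiscoveryVcf(rec))],
                 "AIS=8;")
    ## unsorted input is rejected
    two <- rbind(rec, transform(rec, pos = 3L, key = "tc1:3"))
    expect_error(writeDiscoveryVcf(two), "sorted")
})

test_that("written VCF is parseable by an independent VCF reader", {
    skip_if_not_installed("vcfR")
    truth <- simulateTruth(simConfig(nSites = 800, seed = 13))
    dsc <- discoverSNPs(simulateEvidence(truth))
    f <- withr::local_tempfile(fileext = ".vcf")
    writeDiscoveryVcf(dsc, f)
    v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
    expect_equal(nrow(v@fix),
                 nrow(imbalanceRecords(dsc)) + nrow(paralogRecords(dsc)))
    aff <- as.numeric(vcfR::extract.info(v, "AFF"))
    both <- rbind(imbalanceRecords(dsc), paralogRecords(dsc))
    both <- both[order(both$contig, both$pos), ]
    expect_equal(aff, both$fFast, tolerance = 1e-5)
})
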