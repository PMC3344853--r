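#' Create a stringency / imbalance threshold configuration
#'
#' Defaults reproduce the discovery rules: a variant call needs at least 4
#' reads calling the variant, strictly more than 20% of reads calling the
#' variant and variant-supporting base quality strictly above Phred 20; an
#' imbalance score above 5.0 is an amplification, below 0.2 a loss of
#' heterozygosity.
#'
#' @param minVariantReads minimum reads supporting the variant (inclusive).
#' @param minVariantFraction minimum variant read fraction (exclusive).
#' @param minQuality minimum variant base quality (exclusive).
#' @param ampThreshold amplification score cut-off (exclusive).
#' @param lohThreshold loss-of-heterozygosity score cut-off (exclusive).
#' @return a [StringencyConfig-class] object.
#' @examples
#' stringencyConfig()
#' stringencyConfig(minVariantReads = 6L)
#' @export
stringencyConfig <- function(minVariantReads = 4L, minVariantFraction = 0.20,
                             minQuality = 20, ampThreshold = 5.0,
                             lohThreshold = 0.2) {
    new("StringencyConfig",
        minVariantReads = as.integer(minVariantReads),
        minVariantFraction = minVariantFraction,
        minQuality = minQuality,
        ampThreshold = ampThreshold,
        lohThreshold = lohThreshold)
}

setMethod("show", "StringencyConfig", function(object) {
    cat("StringencyConfig\n")
    cat(sprintf("  variant reads >= %d, fraction > %g, quality > %g\n",
                object@minVariantReads, object@minVariantFraction,
                object@minQuality))
    cat(sprintf("  amplification: score > %g; LOH: score < %g\n",
                object@ampThreshold, object@lohThreshold))
    invisible(NULL)
})

#' Detect a variant in one pool under the stringency rules
#'
#' For each site, the candidate variant allele is the non-reference base with
#' the highest read count in the given pool (ties broken alphabetically).
#' The site passes iff the variant read count is at least
#' `minVariantReads`, the variant fraction of counted reads is strictly
#' greater than `minVariantFraction`, and the aggregated quality of
#' variant-supporting bases is strictly greater than `minQuality`.  The
#' variant fraction uses counted A/C/G/T reads as the denominator, the same
#' denominator used for pooled allele-frequency estimation.
#'
#' A site with no usable reads fails with reason `"no_coverage"` rather than
#' raising an error.
#'
#' @param se a [SiteEvidence-class] object.
#' @param pool `"fast"` or `"slow"`.
#' @param cfg a [StringencyConfig-class].
#' @return a data.frame with one row per site: `pass` (logical), `allele`
#'   (character, NA when no non-reference read exists), `count`, `fraction`,
#'   `quality` and `reason` (NA when passing).
#' @examples
#' cf <- matrix(c(6L, 0L, 0L, 4L), 1, dimnames = list(NULL, c("A","C","G","T")))
#' qf <- matrix(c(35, 0, 0, 30), 1, dimnames = list(NULL, c("A","C","G","T")))
#' se <- SiteEvidence("tc1", 10L, "A", cf, qf, cf, qf)
#' detectVariant(se, "fast")   # T passes: 4 reads, 40% > 20%, Q30 > 20
#' @export
detectVariant <- function(se, pool = c("fast", "slow"),
                          cfg = stringencyConfig()) {
    pool <- match.arg(pool)
    counts <- poolCounts(se, pool)
    quals <- poolQuals(se, pool)
    n <- length(se)
    if (n == 0L)
        return(data.frame(pass = logical(), allele = character(),
                          count = integer(), fraction = numeric(),
                          quality = numeric(), reason = character()))
    refIdx <- match(refAllele(se), BASES)
    nonref <- counts
    nonref[cbind(seq_len(n), refIdx)] <- -1L
    aIdx <- max.col(nonref, ties.method = "first")  # columns are A<C<G<T
    cnt <- nonref[cbind(seq_len(n), aIdx)]
    usable <- rowSums(counts)
    hasVar <- cnt > 0L
    frac <- ifelse(usable > 0, cnt / usable, 0)
    qual <- quals[cbind(seq_len(n), aIdx)]
    pass <- hasVar &
        cnt >= cfg@minVariantReads &
        frac > cfg@minVariantFraction &
        qual > cfg@minQuality
    reason <- rep(NA_character_, n)
    reason[!pass] <- "low_quality"
    reason[!pass & qual > cfg@minQuality] <- "low_fraction"
    reason[!pass & frac > cfg@minVariantFraction & qual > cfg@minQuality] <-
        "too_few_reads"
    reason[!hasVar] <- "no_variant_reads"
    reason[usable == 0L] <- "no_coverage"
    data.frame(pass = pass,
               allele = ifelse(hasVar, BASES[aIdx], NA_character_),
               count = pmax(cnt, 0L), fraction = frac, quality = qual,
               reason = reason)
}

#' Pooled allele frequency from read counts
#'
#' Estimates the frequency of `allele` in one pool by counting the reads
#' representing each allele: count(allele) divided by the counted A/C/G/T
#' reads at the site.
#'
#' @param se a [SiteEvidence-class] object.
#' @param allele character vector of bases (recycled to the number of sites).
#' @param pool `"fast"` or `"slow"`.
#' @return numeric vector of frequencies in \[0, 1\].
#' @examples
#' cf <- matrix(c(6L, 0L, 0L, 4L), 1, dimnames = list(NULL, c("A","C","G","T")))
#' se <- SiteEvidence("tc1", 1L, "A", cf, cf * 0, cf, cf * 0)
#' poolAlleleFrequency(se, "T", "fast")   # 0.4
#' @export
poolAlleleFrequency <- function(se, allele, pool = c("fast", "slow")) {
    pool <- match.arg(pool)
    counts <- poolCounts(se, pool)
    n <- length(se)
    allele <- rep_len(toupper(allele), n)
    stopifnot(all(allele %in% BASES))
    usable <- rowSums(counts)
    if (any(usable == 0L))
        stop("undefined allele frequency: site(s) with zero usable reads: ",
             paste(head(siteKeys(se)[usable == 0L], 5L), collapse = ", "))
    counts[cbind(seq_len(n), match(allele, BASES))] / usable
}

#' Allelic imbalance score
#'
#' The ratio of the variant-allele frequency in the fast-growth pool to that
#' in the slow-growth pool.  A slow-pool frequency of zero with a positive
#' fast-pool frequency gives `Inf` (the strongest possible amplification);
#' both frequencies zero is an error, since such a site is not a variant.
#'
#' @param fFast,fSlow variant-allele frequencies in \[0, 1\] (vectorised).
#' @return numeric scores in \[0, Inf\].
#' @examples
#' imbalanceScore(0.40, 0.05)   # 8
#' imbalanceScore(0.20, 0)      # Inf
#' @export
imbalanceScore <- function(fFast, fSlow) {
    stopifnot(all(fFast >= 0 & fFast <= 1), all(fSlow >= 0 & fSlow <= 1))
    if (any(fFast == 0 & fSlow == 0))
        stop("undefined imbalance score: both pool frequencies are zero")
    ifelse(fSlow == 0, Inf, fFast / fSlow)
}

#' Classify an imbalance score
#'
#' Scores strictly above the amplification threshold (default 5.0) are
#' amplifications, strictly below the LOH threshold (default 0.2) losses of
#' heterozygosity, anything else (boundaries included) balanced.
#'
#' @param score numeric score vector (`Inf` allowed).
#' @param cfg a [StringencyConfig-class].
#' @return character vector in `{"amplification", "LOH", "balanced"}`.
#' @examples
#' classifyImbalance(c(8, 5, 1, 0.2, 0.18))
#' @export
classifyImbalance <- function(score, cfg = stringencyConfig()) {
    stopifnot(all(score >= 0))
    ifelse(score > cfg@ampThreshold, "amplification",
           ifelse(score < cfg@lohThreshold, "LOH", "balanced"))
}

#' Flag paralog-artifact records
#'
#' Reads mapped to a collapsed pair of paralogous loci mimic heterozygous
#' SNPs.  Because the reference transcriptome derives from a doubled-haploid
#' individual, sites at which that individual's own reads call a variant are
#' paralog artifacts; rule (a) flags any record whose site appears in that
#' self-variant list.  Rule (b) flags the residual signature: an
#' intermediate variant fraction in *both* pools combined with excess depth
#' (`> depthMultiplier` times the median site depth).
#'
#' @param records discovery record data.frame (from [discoverSNPs()]'s
#'   internal table) with columns fFast, fSlow, siteDepth and key.
#' @param dhHetSites character vector of `"contig:pos"` keys from the
#'   doubled-haploid self-variant list.
#' @param medianDepth median total site depth over all examined sites.
#' @param fractionWindow both-pool variant-fraction window for rule (b).
#' @param depthMultiplier depth-excess multiplier for rule (b).
#' @return logical vector, TRUE where the record is a paralog suspect.
#' @export
paralogFilter <- function(records, dhHetSites = character(),
                          medianDepth = stats::median(records$siteDepth),
                          fractionWindow = c(0.3, 0.7),
                          depthMultiplier = 3) {
    if (nrow(records) == 0L) return(logical(0))
    inList <- records$key %in% dhHetSites
    inWindow <- records$fFast >= fractionWindow[1L] &
        records$fFast <= fractionWindow[2L] &
        records$fSlow >= fractionWindow[1L] &
        records$fSlow <= fractionWindow[2L]
    deep <- records$siteDepth > depthMultiplier * medianDepth
    inList | (inWindow & deep)
}

#' Run the staged SNP discovery funnel
#'
#' For each site, variant detection is run independently in both pools under
#' the stringency rules; a site is a putative SNP when it passes in at least
#' one pool (both pools with `requireBothPools = TRUE`).  The variant-allele
#' frequency is then computed in both pools by read counting, the allelic
#' imbalance score (fast/slow) is formed and classified, paralog suspects
#' are removed to a side table, and staged funnel counts are reported.
#'
#' Sites excluded before classification are kept in the side table with a
#' reason flag: `discordant_allele` when the two pools pass on different
#' variant alleles, and `no_coverage_other_pool` when the pool that did not
#' trigger detection has no usable reads (its frequency, and hence the
#' score, is undefined there).
#'
#' @param se a [SiteEvidence-class] object, sorted by (contig, pos).
#' @param cfg a [StringencyConfig-class].
#' @param dhHetSites doubled-haploid self-variant site keys for
#'   [paralogFilter()] rule (a).
#' @param requireBothPools require stringency pass in both pools.
#' @param fractionWindow,depthMultiplier rule (b) parameters of
#'   [paralogFilter()].
#' @return a [PoolDiscovery-class] object.
#' @examples
#' se <- simulateEvidence(simulateTruth(simConfig(nSites = 200, seed = 7)))
#' dsc <- discoverSNPs(se)
#' funnelReport(dsc)
#' @export
discoverSNPs <- function(se, cfg = stringencyConfig(),
                         dhHetSites = character(),
                         requireBothPools = FALSE,
                         fractionWindow = c(0.3, 0.7),
                         depthMultiplier = 3) {
    n <- length(se)
    if (!identical(order(se@contig, se@pos), seq_len(n)))
        stop("evidence must be sorted by (contig, pos)")
    detF <- detectVariant(se, "fast", cfg)
    detS <- detectVariant(se, "slow", cfg)
    putative <- if (requireBothPools) detF$pass & detS$pass
                else detF$pass | detS$pass
    idx <- which(putative)
    empty <- data.frame(contig = character(), pos = integer(),
                        ref = character(), variantAllele = character(),
                        fFast = numeric(), fSlow = numeric(),
                        score = numeric(), class = character(),
                        detectedFast = logical(), detectedSlow = logical(),
                        nFast = integer(), nSlow = integer(),
                        siteDepth = integer(), key = character(),
                        flags = character())
    if (length(idx) == 0L) {
        funnel <- c(sitesExamined = n, putativeSNPs = 0L,
                    postParalogFilter = 0L, imbalanced = 0L)
        return(new("PoolDiscovery", records = empty, paralogs = empty,
                   funnel = funnel, config = cfg))
    }
    sub <- se[idx]
    pf <- detF$pass[idx]; ps <- detS$pass[idx]
    alleleF <- detF$allele[idx]; alleleS <- detS$allele[idx]
    discordant <- pf & ps & alleleF != alleleS
    allele <- ifelse(pf, alleleF, alleleS)
    nF <- rowSums(poolCounts(sub, "fast"))
    nS <- rowSums(poolCounts(sub, "slow"))
    noCov <- (nF == 0L) | (nS == 0L)
    ok <- !discordant & !noCov
    fFast <- fSlow <- rep(NA_real_, length(idx))
    score <- rep(NA_real_, length(idx))
    klass <- rep(NA_character_, length(idx))
    if (any(ok)) {
        okSub <- sub[ok]
        fFast[ok] <- poolAlleleFrequency(okSub, allele[ok], "fast")
        fSlow[ok] <- poolAlleleFrequency(okSub, allele[ok], "slow")
        score[ok] <- imbalanceScore(fFast[ok], fSlow[ok])
        klass[ok] <- classifyImbalance(score[ok], cfg)
    }
    recs <- data.frame(
        contig = sub@contig, pos = sub@pos, ref = sub@ref,
        variantAllele = allele, fFast = fFast, fSlow = fSlow,
        score = score, class = klass,
        detectedFast = pf, detectedSlow = ps,
        nFast = nF, nSlow = nS,
        siteDepth = as.integer(nF + nS),
        key = paste(sub@contig, sub@pos, sep = ":"),
        flags = "")
    medDepth <- stats::median(rowSums(poolCounts(se, "fast")) +
                              rowSums(poolCounts(se, "slow")))
    suspect <- rep(FALSE, nrow(recs))
    suspect[ok] <- paralogFilter(recs[ok, , drop = FALSE], dhHetSites,
                                 medianDepth = medDepth,
                                 fractionWindow = fractionWindow,
                                 depthMultiplier = depthMultiplier)
    recs$flags[discordant] <- "discordant_allele"
    recs$flags[noCov & !discordant] <- "no_coverage_other_pool"
    recs$flags[suspect] <- "paralog_suspect"
    keep <- ok & !suspect
    kept <- recs[keep, , drop = FALSE]
    dropped <- recs[!keep, , drop = FALSE]
    rownames(kept) <- NULL; rownames(dropped) <- NULL
    funnel <- c(sitesExamined = n,
                putativeSNPs = length(idx),
                postParalogFilter = nrow(kept),
                imbalanced = sum(kept$class %in% c("amplification", "LOH")))
    new("PoolDiscovery", records = kept, paralogs = dropped,
        funnel = funnel, config = cfg)
}

#' @rdname PoolDiscovery-class
#' @export
setMethod("imbalanceRecords", "PoolDiscovery", function(x) x@records)

#' @rdname PoolDiscovery-class
#' @export
setMethod("paralogRecords", "PoolDiscovery", function(x) x@paralogs)

#' @rdname PoolDiscovery-class
#' @export
setMethod("funnelReport", "PoolDiscovery", function(x) x@funnel)

setMethod("show", "PoolDiscovery", function(object) {
    f <- object@funnel
    cat("PoolDiscovery funnel\n")
    cat(sprintf("  sites examined     %d\n", f[["sitesExamined"]]))
    cat(sprintf("  putative SNPs      %d\n", f[["putativeSNPs"]]))
    cat(sprintf("  post paralog filter %d\n", f[["postParalogFilter"]]))
    cat(sprintf("  imbalanced (amp+LOH) %d\n", f[["imbalanced"]]))
    if (nrow(object@records) > 0) {
        tab <- table(object@records$class)
        cat("  classes: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    invisible(NULL)
})
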