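#' Create a pooled-sequencing simulation configuration
#'
#' Defaults emulate the discovery study design: two pools of 10 diploid
#' full-sib fish sequenced at ~0.97X per fish (expected pool depth ~9.7),
#' a base-call error rate of 1%, and a site mixture of 3% true SNPs and 1%
#' paralog-artifact sites among candidate sites (the remainder
#' monomorphic).  Population allele frequencies at true SNP sites are drawn
#' per pool from a U-shaped Beta(0.5, 0.5) spectrum unless explicit
#' `freqPairs` are supplied.
#'
#' @param nSites number of sites to simulate.
#' @param propTrueSnp,propParalog site-class proportions.
#' @param nFishPerPool diploid fish per pool.
#' @param coveragePerFish expected reads per fish per site.
#' @param errorRate per-base sequencing error probability.
#' @param qualMean,qualSd Phred base-quality model.
#' @param betaShape1,betaShape2 Beta allele-frequency model for true SNPs.
#' @param freqPairs optional matrix (columns fast, slow) of explicit
#'   per-site frequency pairs for true SNP sites, recycled as needed.
#' @param paralogAltFraction alternate-read fraction at paralog sites.
#' @param paralogDepthMultiplier depth inflation at paralog sites.
#' @param dhDetectionRate probability a paralog site is present in the
#'   doubled-haploid self-variant list.
#' @param familyMode draw each pool as a full-sib family instead of
#'   Hardy-Weinberg individuals.
#' @param seed mandatory integer seed.
#' @return a [SimConfig-class] object.
#' @examples
#' simConfig(nSites = 1000, seed = 1)
#' @export
simConfig <- function(nSites = 10000L, propTrueSnp = 0.03,
                      propParalog = 0.01, nFishPerPool = 10L,
                      coveragePerFish = 0.97, errorRate = 0.01,
                      qualMean = 35, qualSd = 5,
                      betaShape1 = 0.5, betaShape2 = 0.5,
                      freqPairs = NULL,
                      paralogAltFraction = 0.5,
                      paralogDepthMultiplier = 2,
                      dhDetectionRate = 0.5,
                      familyMode = FALSE, seed) {
    if (missing(seed)) stop("an integer seed is mandatory")
    if (is.null(freqPairs))
        freqPairs <- matrix(numeric(), 0L, 2L,
                            dimnames = list(NULL, c("fast", "slow")))
    new("SimConfig", nSites = as.integer(nSites),
        propTrueSnp = propTrueSnp, propParalog = propParalog,
        nFishPerPool = as.integer(nFishPerPool),
        coveragePerFish = coveragePerFish, errorRate = errorRate,
        qualMean = qualMean, qualSd = qualSd,
        betaShape1 = betaShape1, betaShape2 = betaShape2,
        freqPairs = freqPairs,
        paralogAltFraction = paralogAltFraction,
        paralogDepthMultiplier = paralogDepthMultiplier,
        dhDetectionRate = dhDetectionRate,
        familyMode = familyMode, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  %d sites: %.1f%% true SNP, %.1f%% paralog, rest monomorphic\n",
                object@nSites, 100 * object@propTrueSnp,
                100 * object@propParalog))
    cat(sprintf("  %d fish/pool at %.2fX/fish (pool depth ~ Poisson(%.2f))\n",
                object@nFishPerPool, object@coveragePerFish,
                object@nFishPerPool * object@coveragePerFish))
    cat(sprintf("  error rate %.3g, quality ~ N(%g, %g), seed %d\n",
                object@errorRate, object@qualMean, object@qualSd, object@seed))
    invisible(NULL)
})

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [simConfig()] in snake_case
#' (e.g. `n_sites`, `prop_true_snp`, `error_rate`).
#'
#' @param file path to a YAML file.
#' @param seed overrides the seed in the file when not `NULL`.
#' @return a [SimConfig-class] object.
#' @export
readSimConfig <- function(file, seed = NULL) {
    y <- yaml::read_yaml(file)
    camel <- function(s) gsub("_(\\w)", "\\U\\1", s, perl = TRUE)
    names(y) <- vapply(names(y), camel, "")
    if (!is.null(y$freqPairs))
        y$freqPairs <- matrix(unlist(y$freqPairs), ncol = 2L, byrow = TRUE,
                              dimnames = list(NULL, c("fast", "slow")))
    if (!is.null(seed)) y$seed <- seed
    do.call(simConfig, y)
}

## Full-sib family genotypes: two parents drawn at frequency p, offspring by
## Mendelian segregation. Returns integer dosage vector length nFish.
.familyGenotypes <- function(p, nFish) {
    parents <- stats::rbinom(2L, 2L, p)
    fromP <- function(g) stats::rbinom(nFish, 1L, g / 2)
    as.integer(fromP(parents[1L]) + fromP(parents[2L]))
}

#' Draw ground truth for a pooled-sequencing simulation
#'
#' Site classes are drawn by the configured proportions.  At true SNP
#' sites, each pool gets a population variant-allele frequency (Beta model
#' or explicit pairs) and per-fish diploid genotypes drawn binomially under
#' Hardy-Weinberg within the pool (or by Mendelian segregation from two
#' drawn parents in family mode).  Paralog sites carry no true genotypes;
#' the fraction of them exposed in the doubled-haploid self-variant list is
#' drawn with `dhDetectionRate`.  Fully reproducible from the config seed.
#'
#' @param cfg a [SimConfig-class] object.
#' @return a [SimTruth-class] object.
#' @examples
#' truth <- simulateTruth(simConfig(nSites = 100, seed = 42))
#' table(truth@siteClass)
#' @export
simulateTruth <- function(cfg) {
    validObject(cfg)
    withSeed(subSeed(cfg@seed, "truth"), {
        n <- cfg@nSites
        classes <- sample(c("true_snp", "paralog", "monomorphic"), n,
                          replace = TRUE,
                          prob = c(cfg@propTrueSnp, cfg@propParalog,
                                   1 - cfg@propTrueSnp - cfg@propParalog))
        ref <- sample(BASES, n, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
        fF <- fS <- numeric(n)
        isSnp <- classes == "true_snp"
        nSnp <- sum(isSnp)
        if (nSnp > 0) {
            if (nrow(cfg@freqPairs) > 0) {
                pairs <- cfg@freqPairs[rep_len(seq_len(nrow(cfg@freqPairs)),
                                               nSnp), , drop = FALSE]
                fF[isSnp] <- pairs[, 1L]; fS[isSnp] <- pairs[, 2L]
            } else {
                fF[isSnp] <- stats::rbeta(nSnp, cfg@betaShape1, cfg@betaShape2)
                fS[isSnp] <- stats::rbeta(nSnp, cfg@betaShape1, cfg@betaShape2)
            }
        }
        fF[classes == "paralog"] <- NA_real_
        fS[classes == "paralog"] <- NA_real_
        gF <- matrix(0L, n, cfg@nFishPerPool)
        gS <- matrix(0L, n, cfg@nFishPerPool)
        for (i in which(isSnp)) {
            if (cfg@familyMode) {
                gF[i, ] <- .familyGenotypes(fF[i], cfg@nFishPerPool)
                gS[i, ] <- .familyGenotypes(fS[i], cfg@nFishPerPool)
            } else {
                gF[i, ] <- stats::rbinom(cfg@nFishPerPool, 2L, fF[i])
                gS[i, ] <- stats::rbinom(cfg@nFishPerPool, 2L, fS[i])
            }
        }
        paralogIdx <- which(classes == "paralog")
        dh <- paralogIdx[stats::runif(length(paralogIdx)) < cfg@dhDetectionRate]
        new("SimTruth",
            contig = sprintf("tc%06d", seq_len(n)),
            pos = rep(100L, n), ref = ref, alt = alt, siteClass = classes,
            freqFast = fF, freqSlow = fS, genoFast = gF, genoSlow = gS,
            dhHetSites = as.integer(dh), config = cfg)
    })
}

#' @rdname SimTruth-class
#' @export
setMethod("truthTable", "SimTruth", function(x)
    data.frame(contig = x@contig, pos = x@pos, ref = x@ref, alt = x@alt,
               class = x@siteClass, freqFast = x@freqFast, freqSlow = x@freqSlow,
               sampleFreqFast = rowMeans(x@genoFast) / 2,
               sampleFreqSlow = rowMeans(x@genoSlow) / 2,
               dhHet = seq_along(x@pos) %in% x@dhHetSites))

setMethod("show", "SimTruth", function(object) {
    tab <- table(object@siteClass)
    cat(sprintf("SimTruth with %d sites (%s); %d fish/pool, seed %d\n",
                length(object@pos),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
                ncol(object@genoFast), object@config@seed))
    invisible(NULL)
})

#' Doubled-haploid self-variant site keys of a simulated truth
#'
#' The `"contig:pos"` keys of the paralog sites exposed in the simulated
#' doubled-haploid self-variant list, in the form [discoverSNPs()] expects
#' for its `dhHetSites` argument.
#'
#' @param truth a [SimTruth-class] object.
#' @return character vector of site keys.
#' @export
dhHetSiteKeys <- function(truth)
    paste(truth@contig[truth@dhHetSites], truth@pos[truth@dhHetSites],
          sep = ":")

## Error-spread k erroneous reads of a true base across the other 3 bases.
.spreadErrors <- function(counts, trueIdx, nErr) {
    for (i in which(nErr > 0L)) {
        others <- setdiff(1:4, trueIdx[i])
        spread <- stats::rmultinom(1L, nErr[i], rep(1 / 3, 3L))[, 1L]
        counts[i, others] <- counts[i, others] + spread
    }
    counts
}

## Simulate one pool's counts/qualities for all sites.
.simulatePool <- function(pReads, refIdx, altIdx, depthMult, cfg) {
    n <- length(pReads)
    lambda <- cfg@nFishPerPool * cfg@coveragePerFish * depthMult
    depth <- stats::rpois(n, lambda)
    altTrue <- stats::rbinom(n, depth, pReads)
    refTrue <- depth - altTrue
    errRef <- stats::rbinom(n, refTrue, cfg@errorRate)
    errAlt <- stats::rbinom(n, altTrue, cfg@errorRate)
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
    counts[cbind(seq_len(n), refIdx)] <- refTrue - errRef
    counts[cbind(seq_len(n), altIdx)] <-
        counts[cbind(seq_len(n), altIdx)] + (altTrue - errAlt)
    counts <- .spreadErrors(counts, refIdx, errRef)
    counts <- .spreadErrors(counts, altIdx, errAlt)
    quals <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
    nz <- which(counts > 0L)
    k <- counts[nz]
    quals[nz] <- pmax(2, round(
        cfg@qualMean + stats::rnorm(length(nz)) * cfg@qualSd / sqrt(k), 2))
    list(counts = counts, quals = quals, depth = depth)
}

#' Simulate pooled read evidence from ground truth
#'
#' Per pool and site, depth is Poisson with mean `nFishPerPool *
#' coveragePerFish`; each read is drawn from a uniformly chosen fish
#' chromosome (so the read-level variant probability is the pool sample
#' allele frequency), base-call errors flip a read to a uniformly chosen
#' other base with probability `errorRate`, and the stored per-base quality
#' summary is drawn from the configured quality model.  Paralog sites emit
#' a fixed alternate-read fraction in both pools at inflated depth.
#'
#' @param truth a [SimTruth-class] object.
#' @param cfg the [SimConfig-class]; defaults to the one inside `truth`.
#' @return a [SiteEvidence-class] object, sorted by (contig, pos).
#' @examples
#' truth <- simulateTruth(simConfig(nSites = 100, seed = 42))
#' se <- simulateEvidence(truth)
#' mean(poolDepth(se, "fast"))
#' @export
simulateEvidence <- function(truth, cfg = truth@config) {
    withSeed(subSeed(cfg@seed, "evidence"), {
        n <- length(truth@pos)
        refIdx <- match(truth@ref, BASES)
        altIdx <- match(truth@alt, BASES)
        isPar <- truth@siteClass == "paralog"
        pF <- rowMeans(truth@genoFast) / 2
        pS <- rowMeans(truth@genoSlow) / 2
        pF[isPar] <- cfg@paralogAltFraction
        pS[isPar] <- cfg@paralogAltFraction
        mult <- ifelse(isPar, cfg@paralogDepthMultiplier, 1)
        fast <- .simulatePool(pF, refIdx, altIdx, mult, cfg)
        slow <- .simulatePool(pS, refIdx, altIdx, mult, cfg)
        SiteEvidence(truth@contig, truth@pos, truth@ref,
                     countsFast = fast$counts, qualFast = fast$quals,
                     countsSlow = slow$counts, qualSlow = slow$quals,
                     depthFast = fast$depth, depthSlow = slow$depth)
    })
}

#' Score discovery output against simulation ground truth
#'
#' Joins discovered records to truth by site and reports:
#' \describe{
#'   \item{validationRate}{fraction of discovered sites whose true class is
#'     `true_snp` (NA when nothing was discovered) -- the in-silico analogue
#'     of the panel-genotyping success rate.}
#'   \item{sensitivity}{fraction of true SNPs whose population frequencies
#'     differ by more than `margin` that were discovered.}
#'   \item{falseDiscoveryCount}{discovered sites that are not true SNPs.}
#'   \item{imbalanceClassAccuracy}{among discovered true SNPs, agreement of
#'     the called imbalance class with the class implied by the true
#'     population frequencies.}
#' }
#'
#' @param truth a [SimTruth-class] object.
#' @param discovery a [PoolDiscovery-class] from evidence simulated from
#'   `truth`.
#' @param margin population-frequency divergence defining a discoverable
#'   SNP for the sensitivity denominator.
#' @return a list of the four metrics plus `nDiscovered`.
#' @examples
#' truth <- simulateTruth(simConfig(nSites = 500, seed = 11))
#' dsc <- discoverSNPs(simulateEvidence(truth))
#' evaluateDiscovery(truth, dsc)
#' @export
evaluateDiscovery <- function(truth, discovery, margin = 0.25) {
    recs <- imbalanceRecords(discovery)
    truthKey <- paste(truth@contig, truth@pos, sep = ":")
    hit <- match(recs$key, truthKey)
    if (any(is.na(hit)))
        stop("site-id mismatch: discovered site absent from truth")
    discClass <- truth@siteClass[hit]
    validationRate <- if (nrow(recs) == 0L) NA_real_
                      else mean(discClass == "true_snp")
    divergent <- which(truth@siteClass == "true_snp" &
                       abs(truth@freqFast - truth@freqSlow) > margin)
    sensitivity <- if (length(divergent) == 0L) NA_real_
                   else mean(truthKey[divergent] %in% recs$key)
    if (nrow(recs) == 0L) sensitivity <- 0
    isTrue <- discClass == "true_snp"
    classAcc <- NA_real_
    if (any(isTrue)) {
        fF <- truth@freqFast[hit[isTrue]]
        fS <- truth@freqSlow[hit[isTrue]]
        ok <- !(fF == 0 & fS == 0)
        trueScore <- ifelse(fS == 0, Inf, fF / fS)
        trueClass <- classifyImbalance(trueScore[ok], discovery@config)
        classAcc <- mean(recs$class[isTrue][ok] == trueClass)
    }
    list(validationRate = validationRate,
         sensitivity = sensitivity,
         falseDiscoveryCount = sum(!isTrue),
         imbalanceClassAccuracy = classAcc,
         nDiscovered = nrow(recs))
}
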