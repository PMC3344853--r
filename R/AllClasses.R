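#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

.checkBaseMatrix <- function(m, n, what) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 4L ||
        !identical(colnames(m), BASES))
        return(sprintf("'%s' must be an n x 4 matrix with columns A,C,G,T", what))
    if (any(is.na(m)) || any(m < 0))
        return(sprintf("'%s' must be non-negative and non-missing", what))
    NULL
}

#' Per-site read evidence for two sequencing pools
#'
#' `SiteEvidence` holds, for each candidate site, the reference base and the
#' per-pool read support: a raw pileup depth, read counts per base
#' (A, C, G, T) and an aggregated Phred base-quality summary per base for the
#' "fast" and "slow" pools.  It is the container the discovery funnel
#' consumes; pooled allele frequencies are estimated by counting reads per
#' allele in each pool.
#'
#' Coordinates are 1-based.  Read strand is ignored (upper- and lower-case
#' pileup bases are merged).  The quality matrices store one summary value
#' (mean by default, optionally minimum; see [parseSiteEvidence()]) of the
#' Phred base qualities of the reads supporting each base; entries for bases
#' with zero reads are 0.
#'
#' @slot contig character, contig/transcript name per site.
#' @slot pos integer, 1-based position per site.
#' @slot ref character, reference base per site (one of A, C, G, T).
#' @slot countsFast,countsSlow integer matrix (sites x 4, columns A,C,G,T) of
#'   read counts per base in each pool.
#' @slot qualFast,qualSlow numeric matrix (sites x 4) of aggregated Phred base
#'   quality per base in each pool.
#' @slot depthFast,depthSlow integer, raw pileup depth per site and pool
#'   (counted bases can be fewer when Ns, deletions or reference skips were
#'   dropped).
#'
#' @seealso [parseSiteEvidence()], [writeSiteEvidence()], [discoverSNPs()]
#' @export
setClass("SiteEvidence",
    representation(
        contig = "character",
        pos = "integer",
        ref = "character",
        countsFast = "matrix",
        qualFast = "matrix",
        countsSlow = "matrix",
        qualSlow = "matrix",
        depthFast = "integer",
        depthSlow = "integer"
    )
)

setValidity("SiteEvidence", function(object) {
    n <- length(object@pos)
    msgs <- character()
    if (length(object@contig) != n || length(object@ref) != n ||
        length(object@depthFast) != n || length(object@depthSlow) != n)
        msgs <- c(msgs, "slot lengths disagree")
    if (any(object@pos < 1L, na.rm = TRUE))
        msgs <- c(msgs, "positions must be >= 1")
    if (n > 0 && !all(object@ref %in% BASES))
        msgs <- c(msgs, "reference alleles must be one of A, C, G, T")
    for (w in c("countsFast", "qualFast", "countsSlow", "qualSlow")) {
        m <- .checkBaseMatrix(slot(object, w), n, w)
        if (!is.null(m)) msgs <- c(msgs, m)
    }
    if (length(msgs) == 0L) {
        if (any(rowSums(object@countsFast) > object@depthFast) ||
            any(rowSums(object@countsSlow) > object@depthSlow))
            msgs <- c(msgs, "base counts exceed pool depth")
    }
    if (length(msgs)) msgs else TRUE
})

#' Stringency and imbalance thresholds for variant detection
#'
#' Bundles the detection stringency rules applied per pool -- at least
#' `minVariantReads` reads calling the variant, strictly more than
#' `minVariantFraction` of reads calling the variant, and variant-supporting
#' base quality strictly above `minQuality` -- together with the allelic
#' imbalance classification cut-offs: a fast/slow frequency ratio above
#' `ampThreshold` is classified as an amplification and below `lohThreshold`
#' as loss of heterozygosity.
#'
#' All inequalities except the read-count minimum are strict: a variant
#' fraction of exactly 0.20 fails, a score of exactly 5.0 is balanced.
#'
#' @slot minVariantReads integer, minimum reads calling the variant (default 4,
#'   inclusive).
#' @slot minVariantFraction numeric in (0,1), minimum fraction of reads calling
#'   the variant (default 0.20, exclusive).
#' @slot minQuality numeric, minimum Phred quality of variant-supporting bases
#'   (default 20, exclusive).
#' @slot ampThreshold numeric, imbalance score above which a site is an
#'   amplification (default 5.0, exclusive).
#' @slot lohThreshold numeric, imbalance score below which a site is a loss of
#'   heterozygosity (default 0.2, exclusive).
#'
#' @seealso [stringencyConfig()], [detectVariant()], [classifyImbalance()]
#' @export
setClass("StringencyConfig",
    representation(
        minVariantReads = "integer",
        minVariantFraction = "numeric",
        minQuality = "numeric",
        ampThreshold = "numeric",
        lohThreshold = "numeric"
    ),
    prototype(
        minVariantReads = 4L,
        minVariantFraction = 0.20,
        minQuality = 20,
        ampThreshold = 5.0,
        lohThreshold = 0.2
    )
)

setValidity("StringencyConfig", function(object) {
    msgs <- character()
    if (object@minVariantReads < 1L)
        msgs <- c(msgs, "minVariantReads must be >= 1")
    if (object@minVariantFraction <= 0 || object@minVariantFraction >= 1)
        msgs <- c(msgs, "minVariantFraction must be in (0, 1)")
    if (!(object@lohThreshold < 1 && 1 < object@ampThreshold))
        msgs <- c(msgs, "need lohThreshold < 1 < ampThreshold")
    if (length(msgs)) msgs else TRUE
})

#' Result of the staged SNP discovery funnel
#'
#' Holds the imbalance records retained by [discoverSNPs()], the records set
#' aside as paralog suspects, the staged funnel counts, and the configuration
#' used.  Access with [imbalanceRecords()], [paralogRecords()] and
#' [funnelReport()].
#'
#' @slot records data.frame of retained records: contig, pos, ref,
#'   variantAllele, fFast, fSlow, score, class, flags.
#' @slot paralogs data.frame of records flagged as paralog suspects (same
#'   columns).
#' @slot funnel named integer vector of staged counts: sitesExamined,
#'   putativeSNPs, postParalogFilter, imbalanced.
#' @slot config the [StringencyConfig-class] used.
#' @export
setClass("PoolDiscovery",
    representation(
        records = "data.frame",
        paralogs = "data.frame",
        funnel = "integer",
        config = "StringencyConfig"
    )
)

setValidity("PoolDiscovery", function(object) {
    need <- c("sitesExamined", "putativeSNPs", "postParalogFilter", "imbalanced")
    if (!all(need %in% names(object@funnel)))
        return("funnel must contain the four staged counts")
    f <- object@funnel[need]
    if (is.unsorted(rev(f)))
        return("funnel counts must be weakly decreasing")
    TRUE
})

#' Simulation settings for pooled low-coverage sequencing
#'
#' Describes the study design emulated by the simulator: two pools of
#' full-sib diploid fish sequenced at low per-fish coverage, a mixture of
#' true SNP sites with pool-divergent frequencies, monomorphic sites where
#' only sequencing error produces alternate reads, and paralog-artifact
#' sites where collapsed duplicated loci produce a persistent intermediate
#' alternate-allele signal in both pools.
#'
#' @slot nSites integer, number of simulated sites.
#' @slot propTrueSnp,propParalog numeric, site-class proportions (the
#'   remainder is monomorphic).
#' @slot nFishPerPool integer, diploid individuals per pool (default 10).
#' @slot coveragePerFish numeric, expected read depth contributed per fish
#'   (default 0.97); pool depth is Poisson with mean
#'   `nFishPerPool * coveragePerFish`.
#' @slot errorRate numeric, per-base sequencing error probability; an
#'   erroneous read shows a uniformly chosen other base.
#' @slot qualMean,qualSd numeric, Phred base-quality model (Normal, truncated
#'   at 2, rounded).
#' @slot betaShape1,betaShape2 numeric, Beta parameters for independent
#'   per-pool population allele-frequency draws at true SNP sites.
#' @slot freqPairs matrix with columns fast, slow: explicit per-site frequency
#'   pairs for true SNP sites (recycled); overrides the Beta model when
#'   non-empty.
#' @slot paralogAltFraction numeric, alternate-read fraction emitted at
#'   paralog sites in both pools.
#' @slot paralogDepthMultiplier numeric, depth inflation at paralog sites
#'   (collapsed duplicate loci attract the reads of both copies).
#' @slot dhDetectionRate numeric, probability that a paralog site appears in
#'   the doubled-haploid self-variant list used by the paralog filter.
#' @slot familyMode logical; when TRUE each pool is a full-sib family
#'   (two parental genotypes drawn at the pool frequency, offspring by
#'   Mendelian segregation) instead of independent Hardy-Weinberg draws.
#' @slot seed integer random seed (mandatory).
#' @seealso [simConfig()], [simulateTruth()], [simulateEvidence()]
#' @export
setClass("SimConfig",
    representation(
        nSites = "integer",
        propTrueSnp = "numeric",
        propParalog = "numeric",
        nFishPerPool = "integer",
        coveragePerFish = "numeric",
        errorRate = "numeric",
        qualMean = "numeric",
        qualSd = "numeric",
        betaShape1 = "numeric",
        betaShape2 = "numeric",
        freqPairs = "matrix",
        paralogAltFraction = "numeric",
        paralogDepthMultiplier = "numeric",
        dhDetectionRate = "numeric",
        familyMode = "logical",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msgs <- character()
    if (object@nSites < 1L) msgs <- c(msgs, "nSites must be >= 1")
    props <- c(object@propTrueSnp, object@propParalog)
    if (any(props < 0) || any(props > 1) || sum(props) > 1)
        msgs <- c(msgs, "site-class proportions must lie in [0,1] and sum to <= 1")
    if (object@coveragePerFish <= 0) msgs <- c(msgs, "coveragePerFish must be > 0")
    if (object@errorRate < 0 || object@errorRate > 1)
        msgs <- c(msgs, "errorRate must be in [0,1]")
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "an integer seed is mandatory")
    if (nrow(object@freqPairs) > 0 &&
        (ncol(object@freqPairs) != 2L || any(object@freqPairs < 0) ||
         any(object@freqPairs > 1)))
        msgs <- c(msgs, "freqPairs must be a 2-column matrix of proportions")
    if (length(msgs)) msgs else TRUE
})

#' Ground truth of a pooled-sequencing simulation
#'
#' Per-site truth produced by [simulateTruth()]: the site class, the
#' population variant-allele frequency in each pool, and the diploid
#' genotype (variant-allele dosage 0/1/2) of every fish in each pool.
#' `dhHetSites` lists the paralog sites that the doubled-haploid
#' self-variant list would expose to the paralog filter.
#'
#' @slot contig,pos,ref,alt site coordinates and alleles.
#' @slot siteClass character, one of "true_snp", "monomorphic", "paralog".
#' @slot freqFast,freqSlow numeric population variant-allele frequencies.
#' @slot genoFast,genoSlow integer matrix (sites x fish) of per-fish variant
#'   dosages.
#' @slot dhHetSites integer indices of paralog sites present in the
#'   doubled-haploid self-variant list.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimTruth",
    representation(
        contig = "character",
        pos = "integer",
        ref = "character",
        alt = "character",
        siteClass = "character",
        freqFast = "numeric",
        freqSlow = "numeric",
        genoFast = "matrix",
        genoSlow = "matrix",
        dhHetSites = "integer",
        config = "SimConfig"
    )
)

setValidity("SimTruth", function(object) {
    n <- length(object@pos)
    msgs <- character()
    if (!all(object@siteClass %in% c("true_snp", "monomorphic", "paralog")))
        msgs <- c(msgs, "unknown site class")
    mono <- object@siteClass == "monomorphic"
    if (any(object@freqFast[mono] != 0) || any(object@freqSlow[mono] != 0))
        msgs <- c(msgs, "monomorphic sites must have frequency 0 in both pools")
    if (nrow(object@genoFast) != n || nrow(object@genoSlow) != n)
        msgs <- c(msgs, "genotype matrices must have one row per site")
    if (length(msgs)) msgs else TRUE
})

#' Genotype calls for samples by markers
#'
#' Diploid genotype calls coded as the count of the alternate (A2) allele:
#' 0 = homozygous A1, 1 = heterozygous, 2 = homozygous A2, NA = missing.
#' Marker metadata records both alleles and whether the marker is nuclear or
#' mitochondrial; mitochondrial markers are haploid (maternally inherited) so
#' heterozygous calls there are flagged at read time and rejected by QC.
#'
#' @slot calls integer matrix, samples (rows) x markers (columns).
#' @slot markers data.frame with columns marker, a1, a2, genome
#'   ("nuclear"/"mito") and optional contig, pos.
#' @seealso [readGenotypes()], [qcFilter()], [minorAlleleFrequency()]
#' @export
setClass("GenotypeMatrix",
    representation(calls = "matrix", markers = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
    msgs <- character()
    if (!all(object@calls %in% c(0L, 1L, 2L, NA)))
        msgs <- c(msgs, "calls must be 0, 1, 2 or NA")
    if (!identical(colnames(object@calls), object@markers$marker))
        msgs <- c(msgs, "call columns must match marker table order")
    if (anyDuplicated(rownames(object@calls)))
        msgs <- c(msgs, "duplicate sample ids")
    if (anyDuplicated(object@markers$marker))
        msgs <- c(msgs, "duplicate marker ids")
    if (!all(object@markers$genome %in% c("nuclear", "mito")))
        msgs <- c(msgs, "marker genome must be 'nuclear' or 'mito'")
    if (length(msgs)) msgs else TRUE
})

#' Individual genotypes of the two discovery pools
#'
#' Per-marker diploid calls for the fish of the fast and slow discovery
#' panels (up to 10 fish each), with an assay status.  Used to validate
#' pooled discovery calls marker by marker: a successfully assayed marker is
#' polymorphic if any two called genotypes differ, monomorphic otherwise.
#'
#' @slot marker character marker ids.
#' @slot status character, "ok" or "failed" per marker; failed assays carry
#'   no calls.
#' @slot callsFast,callsSlow integer matrix (markers x fish) of variant-allele
#'   dosages 0/1/2, NA = missing.
#' @seealso [classifyValidation()], [validationReport()]
#' @export
setClass("PanelGenotypes",
    representation(
        marker = "character",
        status = "character",
        callsFast = "matrix",
        callsSlow = "matrix"
    )
)

setValidity("PanelGenotypes", function(object) {
    msgs <- character()
    n <- length(object@marker)
    if (length(object@status) != n ||
        nrow(object@callsFast) != n || nrow(object@callsSlow) != n)
        msgs <- c(msgs, "slot lengths disagree")
    if (!all(object@status %in% c("ok", "failed")))
        msgs <- c(msgs, "status must be 'ok' or 'failed'")
    if (ncol(object@callsFast) > 10L || ncol(object@callsSlow) > 10L)
        msgs <- c(msgs, "panel sizes exceed 10 fish")
    failed <- object@status == "failed"
    if (any(!is.na(object@callsFast[failed, ])) ||
        any(!is.na(object@callsSlow[failed, ])))
        msgs <- c(msgs, "failed assays must carry no calls")
    if (length(msgs)) msgs else TRUE
})
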