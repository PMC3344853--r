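#' Build discovery-panel genotypes from simulated truth
#'
#' Extracts the per-fish diploid genotypes of both pools at the given sites,
#' emulating individual genotyping of the 10+10 discovery panel.  Sites
#' whose truth class is not `true_snp` carry all-reference genotypes (the
#' genomic locus behind a paralog artifact or error call is monomorphic).
#' A fraction of assays can be marked failed, emulating assay-design or
#' multiplexing failures.
#'
#' @param truth a [SimTruth-class] object.
#' @param keys site keys (`"contig:pos"`) to assay; defaults to all sites.
#' @param assayFailRate probability an assay fails (carries no calls).
#' @param seed integer seed for the failure draw (only used when
#'   `assayFailRate > 0`).
#' @return a [PanelGenotypes-class] object with marker ids equal to the
#'   site keys.
#' @export
panelFromTruth <- function(truth, keys = NULL, assayFailRate = 0,
                           seed = truth@config@seed) {
    truthKey <- paste(truth@contig, truth@pos, sep = ":")
    if (is.null(keys)) keys <- truthKey
    idx <- match(keys, truthKey)
    if (any(is.na(idx))) stop("site-id mismatch: key absent from truth")
    cf <- truth@genoFast[idx, , drop = FALSE]
    cs <- truth@genoSlow[idx, , drop = FALSE]
    status <- rep("ok", length(idx))
    if (assayFailRate > 0) {
        fail <- withSeed(subSeed(seed, "panel"),
                         stats::runif(length(idx)) < assayFailRate)
        status[fail] <- "failed"
        cf[fail, ] <- NA_integer_
        cs[fail, ] <- NA_integer_
    }
    storage.mode(cf) <- "integer"; storage.mode(cs) <- "integer"
    new("PanelGenotypes", marker = keys, status = status,
        callsFast = cf, callsSlow = cs)
}

setMethod("show", "PanelGenotypes", function(object) {
    cat(sprintf("PanelGenotypes: %d markers (%d failed), %d + %d fish\n",
                length(object@marker), sum(object@status == "failed"),
                ncol(object@callsFast), ncol(object@callsSlow)))
    invisible(NULL)
})

#' Allele frequency from diploid panel genotypes
#'
#' Counts alleles over the called genotypes of one panel:
#' `(2 * hom + het) / (2 * n_called)` for the variant (dosage-counted)
#' allele.
#'
#' @param calls integer vector of diploid dosages (0/1/2, NA missing).
#' @return the variant-allele frequency in \[0, 1\].
#' @examples
#' genotypeFrequency(c(2, 2, 1, 1, 1, 1, 0, 0, 0, 0))  # 0.4
#' @export
genotypeFrequency <- function(calls) {
    called <- calls[!is.na(calls)]
    if (length(called) == 0L)
        stop("undefined frequency: all panel calls missing")
    sum(called) / (2 * length(called))
}

#' Classify panel-genotyping outcomes per marker
#'
#' A marker is `failed` when its assay failed, `monomorphic` when every
#' called genotype across both panels is the same homozygote, and
#' `polymorphic` otherwise (two alternate homozygotes with no heterozygote
#' still count as polymorphic).
#'
#' @param panel a [PanelGenotypes-class] object.
#' @return character vector, one of `polymorphic`, `monomorphic`, `failed`
#'   per marker.
#' @export
classifyValidation <- function(panel) {
    vapply(seq_along(panel@marker), function(i) {
        if (panel@status[i] == "failed") return("failed")
        calls <- c(panel@callsFast[i, ], panel@callsSlow[i, ])
        calls <- calls[!is.na(calls)]
        if (length(calls) == 0L) return("failed")
        if (all(calls == calls[1L]) && calls[1L] != 1L) "monomorphic"
        else "polymorphic"
    }, "")
}

#' Validate pooled discovery calls against panel genotypes
#'
#' Joins discovery records to individually-genotyped panel markers, computes
#' the validation rate (polymorphic / successful assays), recomputes allele
#' frequencies and the imbalance score from genotypes with the same
#' thresholds, and flags agreement between the pooled and genotype-based
#' imbalance classes.
#'
#' @param records a [PoolDiscovery-class] or a record data.frame with
#'   columns `key`, `class`.
#' @param panel a [PanelGenotypes-class] whose marker ids are site keys.
#' @param cfg a [StringencyConfig-class] for the genotype-based
#'   classification.
#' @param requireImbalance when TRUE, only markers whose genotype-based
#'   score is itself an amplification or LOH are retained in the
#'   `retained` element (the downstream marker short-list).
#' @return a list: `validationRate`, `nPolymorphic`, `nMonomorphic`,
#'   `nFailed`, `table` (per-marker data.frame with genotype frequencies,
#'   score, classes, agreement) and `retained` (marker keys).
#' @export
validationReport <- function(records, panel, cfg = stringencyConfig(),
                             requireImbalance = FALSE) {
    recs <- if (is(records, "PoolDiscovery")) imbalanceRecords(records)
            else records
    idx <- match(recs$key, panel@marker)
    if (all(is.na(idx)) || nrow(recs) == 0L)
        stop("empty join between discovery records and panel markers")
    keep <- !is.na(idx)
    recs <- recs[keep, , drop = FALSE]
    idx <- idx[keep]
    outcome <- classifyValidation(panel)[idx]
    gF <- gS <- score <- rep(NA_real_, nrow(recs))
    gClass <- rep(NA_character_, nrow(recs))
    for (i in which(outcome == "polymorphic")) {
        gF[i] <- genotypeFrequency(panel@callsFast[idx[i], ])
        gS[i] <- genotypeFrequency(panel@callsSlow[idx[i], ])
        if (gF[i] > 0 || gS[i] > 0) {
            score[i] <- imbalanceScore(gF[i], gS[i])
            gClass[i] <- classifyImbalance(score[i], cfg)
        }
    }
    nPoly <- sum(outcome == "polymorphic")
    nMono <- sum(outcome == "monomorphic")
    tab <- data.frame(
        marker = recs$key, outcome = outcome,
        pooledClass = recs$class,
        genoFreqFast = gF, genoFreqSlow = gS, genoScore = score,
        genoClass = gClass,
        agreement = !is.na(gClass) & gClass == recs$class)
    retained <- tab$marker[outcome == "polymorphic" &
        (!requireImbalance | (!is.na(gClass) &
                              gClass %in% c("amplification", "LOH")))]
    list(validationRate = if (nPoly + nMono > 0) nPoly / (nPoly + nMono)
                          else NA_real_,
         nPolymorphic = nPoly, nMonomorphic = nMono,
         nFailed = sum(outcome == "failed"),
         table = tab, retained = retained)
}
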