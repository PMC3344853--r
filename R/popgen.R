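#' Marker quality-control filter
#'
#' Drops markers with a genotype completion rate below `minCompletion` or
#' with monomorphic alleles among the called genotypes.  Heterozygous calls
#' at mitochondrial (haploid) markers are set to missing before the
#' completion rate is computed.  Markers deviating from Hardy-Weinberg are
#' deliberately *not* dropped: in a growth-selected line such deviation may
#' reflect directional selection rather than genotyping error.
#'
#' The filter is idempotent: applying it to its own output changes nothing.
#'
#' @param gm a [GenotypeMatrix-class] object.
#' @param minCompletion minimum completion rate (calls / samples), default
#'   0.70 (strict: exactly 0.70 is kept).
#' @return a list: `kept` (filtered [GenotypeMatrix-class]), `dropped`
#'   (data.frame of marker and reason), `mitoHetMasked` (count of masked
#'   calls).
#' @examples
#' panel <- simulateFamilyPanel(nFamilies = 6, nOffspring = 4, seed = 9)
#' qcFilter(panel$genotypes)$dropped
#' @export
qcFilter <- function(gm, minCompletion = 0.70) {
    calls <- genoCalls(gm)
    m <- markerInfo(gm)
    mito <- m$genome == "mito"
    masked <- 0L
    if (any(mito)) {
        het <- !is.na(calls[, mito, drop = FALSE]) &
            calls[, mito, drop = FALSE] == 1L
        masked <- sum(het)
        calls[, mito][het] <- NA_integer_
    }
    completion <- colMeans(!is.na(calls))
    mono <- vapply(seq_len(ncol(calls)), function(k) {
        v <- calls[, k][!is.na(calls[, k])]
        length(v) == 0L || (all(v == v[1L]) && v[1L] != 1L)
    }, TRUE)
    reason <- rep(NA_character_, ncol(calls))
    reason[mono] <- "monomorphic"
    reason[completion < minCompletion] <- "low_completion"
    drop <- !is.na(reason)
    kept <- new("GenotypeMatrix", calls = calls[, !drop, drop = FALSE],
                markers = m[!drop, , drop = FALSE])
    list(kept = kept,
         dropped = data.frame(marker = m$marker[drop],
                              reason = reason[drop],
                              completion = unname(completion[drop])),
         mitoHetMasked = masked)
}

#' Minor allele frequency from genotype calls
#'
#' Counts alleles over called genotypes and returns `min(f, 1 - f)`; a
#' marker where both alleles are equally frequent returns 0.5 and a
#' monomorphic marker 0.
#'
#' @param calls integer dosage vector (0/1/2, NA missing).
#' @return the minor allele frequency in \[0, 0.5\].
#' @examples
#' minorAlleleFrequency(c(0, 0, 1, 1, 1, 1, 2, 2, 2, 2))  # 0.4
#' @export
minorAlleleFrequency <- function(calls) {
    called <- calls[!is.na(calls)]
    if (length(called) == 0L) stop("no called genotypes")
    f <- sum(called) / (2 * length(called))
    min(f, 1 - f)
}

## Log-probability of the genotype table (nAA, nAa, naa) conditional on its
## allele counts, under Hardy-Weinberg.
.hweLogProb <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    n1 <- 2L * nAA + nAa
    n2 <- 2L * naa + nAa
    lfactorial(n) - lfactorial(nAA) - lfactorial(nAa) - lfactorial(naa) +
        nAa * log(2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2L * n)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Biallelic conditional exact test: all genotype tables with the observed
#' allele counts are enumerated and the P-value is the sum of probabilities
#' of tables as or less probable than the observed one.  The Monte Carlo
#' mode instead shuffles the 2n alleles into n random genotype pairings `K`
#' times and reports the empirical P
#' `(1 + #{prob(table) <= prob(observed)}) / (K + 1)`.
#'
#' @param nAA,nAa,naa observed genotype counts.
#' @param method `"enumeration"` (exact, default) or `"montecarlo"`.
#' @param K Monte Carlo permutations (default 20000).
#' @param seed optional seed for the Monte Carlo draw.
#' @return the P-value in (0, 1\].
#' @examples
#' hweExact(3, 5, 2)
#' hweExact(0, 10, 0)          # all heterozygotes
#' hweExact(10, 0, 0)          # monomorphic: single possible table, P = 1
#' @export
hweExact <- function(nAA, nAa, naa, method = c("enumeration", "montecarlo"),
                     K = 20000L, seed = NULL) {
    method <- match.arg(method)
    stopifnot(nAA >= 0, nAa >= 0, naa >= 0, nAA + nAa + naa >= 1)
    n1 <- 2L * nAA + nAa
    n2 <- 2L * naa + nAa
    rare <- min(n1, n2)
    hets <- seq(rare %% 2L, rare, by = 2L)
    lp <- .hweLogProb((n1 - hets) / 2L, hets, (n2 - hets) / 2L)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    obs <- p[match(nAa, hets)]
    if (method == "enumeration")
        return(min(1, sum(p[p <= obs * (1 + 1e-12)])))
    draw <- function() {
        al <- sample(rep(c(1L, 0L), c(n1, n2)))
        sum(al[seq(1L, length(al), 2L)] != al[seq(2L, length(al), 2L)])
    }
    sim <- if (is.null(seed)) replicate(K, draw())
           else withSeed(seed, replicate(K, draw()))
    psim <- p[match(sim, hets)]
    (1 + sum(psim <= obs * (1 + 1e-12))) / (K + 1)
}

#' Check genotypes for Mendelian inconsistencies
#'
#' For nuclear markers, an offspring genotype is a violation when it cannot
#' be formed from one allele of each parent; for mitochondrial markers the
#' offspring allele must equal the dam's (maternal inheritance).  Trios
#' with a missing required parent genotype are skipped and counted.
#'
#' @param gm a [GenotypeMatrix-class] object.
#' @param ped a pedigree data.frame (see [readPedigree()]).
#' @param checkMito also apply the maternal-inheritance check to
#'   mitochondrial markers (default TRUE).
#' @return a data.frame of violations (offspring, marker, type), with a
#'   `"skipped"` attribute counting (trio, marker) pairs lacking parental
#'   genotypes.
#' @export
mendelianCheck <- function(gm, ped, checkMito = TRUE) {
    calls <- genoCalls(gm)
    m <- markerInfo(gm)
    ids <- rownames(calls)
    off <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
               ped$sample %in% ids, , drop = FALSE]
    ## possible offspring dosages for each (sire, dam) dosage pair
    gam <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
    viol <- list(); skipped <- 0L
    for (i in seq_len(nrow(off))) {
        o <- match(off$sample[i], ids)
        s <- match(off$sire[i], ids)
        d <- match(off$dam[i], ids)
        for (k in seq_len(ncol(calls))) {
            go <- calls[o, k]
            if (is.na(go)) next
            if (m$genome[k] == "mito") {
                if (!checkMito) next
                if (is.na(d) || is.na(calls[d, k])) {
                    skipped <- skipped + 1L; next
                }
                if (go != calls[d, k])
                    viol[[length(viol) + 1L]] <- data.frame(
                        offspring = off$sample[i], marker = m$marker[k],
                        type = "maternal_mismatch")
            } else {
                if (is.na(s) || is.na(d) ||
                    is.na(calls[s, k]) || is.na(calls[d, k])) {
                    skipped <- skipped + 1L; next
                }
                possible <- outer(gam[[calls[s, k] + 1L]],
                                  gam[[calls[d, k] + 1L]], `+`)
                if (!(go %in% possible))
                    viol[[length(viol) + 1L]] <- data.frame(
                        offspring = off$sample[i], marker = m$marker[k],
                        type = "impossible_genotype")
            }
        }
    }
    out <- if (length(viol)) do.call(rbind, viol)
           else data.frame(offspring = character(), marker = character(),
                           type = character())
    attr(out, "skipped") <- skipped
    out
}

#' Per-population polymorphism summary
#'
#' For each population: the number of markers polymorphic among its called
#' samples, the mean minor allele frequency over those markers, and the
#' identity of the minor allele per marker.  Markers whose minor allele
#' differs between populations are reported as flips.
#'
#' @param gm a [GenotypeMatrix-class] object.
#' @param populations character vector of population labels, one per sample.
#' @return a list: `perPopulation` (data.frame with nPolymorphic, meanMAF),
#'   `minorAlleles` (markers x populations character matrix, NA where a
#'   population is monomorphic or uncalled, `"tie"` at 0.5) and `flips`
#'   (marker ids with differing minor alleles between populations).
#' @export
polymorphismSummary <- function(gm, populations) {
    calls <- genoCalls(gm)
    m <- markerInfo(gm)
    stopifnot(length(populations) == nrow(calls))
    pops <- unique(populations)
    if (any(table(factor(populations, pops)) == 0L))
        stop("population with zero samples")
    minor <- matrix(NA_character_, nrow(m), length(pops),
                    dimnames = list(m$marker, pops))
    perPop <- data.frame(population = pops, nPolymorphic = 0L,
                         meanMAF = NA_real_)
    for (j in seq_along(pops)) {
        sub <- calls[populations == pops[j], , drop = FALSE]
        mafs <- rep(NA_real_, nrow(m))
        for (k in seq_len(ncol(sub))) {
            v <- sub[, k][!is.na(sub[, k])]
            if (length(v) == 0L) next
            f2 <- sum(v) / (2 * length(v))
            mafs[k] <- min(f2, 1 - f2)
            minor[k, j] <- if (mafs[k] == 0) NA_character_
                           else if (f2 < 0.5) m$a2[k]
                           else if (f2 > 0.5) m$a1[k]
                           else "tie"
        }
        poly <- !is.na(mafs) & mafs > 0
        perPop$nPolymorphic[j] <- sum(poly)
        perPop$meanMAF[j] <- if (any(poly)) mean(mafs[poly]) else NA_real_
    }
    flip <- apply(minor, 1L, function(r) {
        r <- r[!is.na(r) & r != "tie"]
        length(unique(r)) > 1L
    })
    list(perPopulation = perPop, minorAlleles = minor,
         flips = m$marker[flip])
}
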