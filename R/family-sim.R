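#' Simulate a multi-family genotyping panel with growth phenotypes
#'
#' Generates the downstream study design: `nFamilies` full-sib families of
#' `nOffspring` fish each, genotyped at a panel of nuclear SNPs plus a set
#' of mitochondrial SNPs forming three haplotypes, with body weights
#' recorded at four evaluation ages.  Nuclear founder genotypes are drawn
#' under Hardy-Weinberg at per-marker founder allele frequencies and
#' offspring by Mendelian segregation; mitochondrial haplotypes are drawn
#' for dams at the supplied haplotype frequencies and passed maternally.
#' Two of the three mitochondrial haplotypes differ only at two designated
#' marker positions.
#'
#' Weights follow a multiplicative growth model
#' `w = mu_t * exp(u_family + u_fish + tankEffect + eps)` with additive
#' marker and haplotype effects scaled by `mu_t / mu_T`, so an effect given
#' in grams applies at the final evaluation age.  Missing genotype calls are
#' introduced at `missingRate` per call.
#'
#' @param nFamilies number of full-sib families.
#' @param nOffspring offspring genotyped per family.
#' @param nNuclear,nMito panel sizes.
#' @param times evaluation ages, days post-hatch.
#' @param meanWeights mean body weight (g) at each evaluation age.
#' @param founderMafRange range of nuclear founder minor-allele frequencies.
#' @param hapFreqs frequencies of the three mitochondrial haplotypes.
#' @param nuclearEffects named numeric, grams per alternate-allele copy at
#'   the final age, names are nuclear marker ids.
#' @param hapEffect grams added at the final age for carriers of the third
#'   haplotype.
#' @param missingRate per-call missing probability.
#' @param sdFamily,sdFish,sdResidual log-scale standard deviations of the
#'   family, fish and residual effects.
#' @param seed mandatory integer seed.
#' @return a list with elements `genotypes` ([GenotypeMatrix-class], offspring
#'   and parents), `pedigree`, `phenotypes` (offspring only), `mitoOrder`
#'   (marker ids by position) and `hapAssign` (true dam haplotype index per
#'   offspring).
#' @examples
#' panel <- simulateFamilyPanel(nFamilies = 8, nOffspring = 5, seed = 3)
#' dim(genoCalls(panel$genotypes))
#' @export
simulateFamilyPanel <- function(nFamilies = 40L, nOffspring = 17L,
                                nNuclear = 30L, nMito = 24L,
                                times = c(170L, 218L, 282L, 372L),
                                meanWeights = c(60, 150, 400, 850),
                                founderMafRange = c(0.05, 0.5),
                                hapFreqs = c(0.49, 0.26, 0.25),
                                nuclearEffects = c(nuSNP05 = -30, nuSNP12 = 25),
                                hapEffect = c(Hap3 = -45),
                                missingRate = 0.03,
                                sdFamily = 0.10, sdFish = 0.15,
                                sdResidual = 0.05, seed) {
    if (missing(seed)) stop("an integer seed is mandatory")
    stopifnot(nMito >= 22L, length(times) == length(meanWeights),
              all(diff(times) > 0), abs(sum(hapFreqs) - 1) < 1e-8)
    withSeed(subSeed(seed, "panel"), {
        nuIds <- sprintf("nuSNP%02d", seq_len(nNuclear))
        mtIds <- sprintf("mtSNP%02d", seq_len(nMito))
        alleles <- t(vapply(seq_len(nNuclear + nMito),
                            function(i) sample(BASES, 2L), character(2L)))
        markers <- data.frame(
            marker = c(nuIds, mtIds),
            a1 = alleles[, 1L], a2 = alleles[, 2L],
            genome = rep(c("nuclear", "mito"), c(nNuclear, nMito)),
            contig = c(sprintf("tc%06d", seq_len(nNuclear)),
                       rep("mt", nMito)),
            pos = c(rep(100L, nNuclear),
                    sort(sample(seq_len(16000L), nMito))))
        founderFreq <- stats::runif(nNuclear, founderMafRange[1L],
                                    founderMafRange[2L])

        ## three mitochondrial haplotypes over the a1/a2 alleles (0 = a1,
        ## 1 = a2): every marker segregates, and haplotypes 2 and 3 are
        ## identical except at two distinguishing markers
        hap1 <- integer(nMito)
        hap3 <- rep(1L, nMito)
        hap2 <- hap3; hap2[c(8L, 21L)] <- 0L
        haps <- rbind(hap1, hap2, hap3)

        sires <- sprintf("S%02d", seq_len(nFamilies))
        dams <- sprintf("D%02d", seq_len(nFamilies))
        famIds <- sprintf("F%02d", seq_len(nFamilies))
        offIds <- unlist(lapply(seq_len(nFamilies), function(f)
            sprintf("%s_O%02d", famIds[f], seq_len(nOffspring))))
        nOff <- length(offIds)

        ## nuclear genotypes: founders HWE, offspring Mendelian
        sireG <- vapply(founderFreq, function(p)
            stats::rbinom(nFamilies, 2L, p), integer(nFamilies))
        damG <- vapply(founderFreq, function(p)
            stats::rbinom(nFamilies, 2L, p), integer(nFamilies))
        fam <- rep(seq_len(nFamilies), each = nOffspring)
        gamete <- function(g) stats::rbinom(length(g), 1L, g / 2)
        offNuc <- vapply(seq_len(nNuclear), function(m)
            gamete(sireG[fam, m]) + gamete(damG[fam, m]), integer(nOff))

        ## mitochondrial: dam haplotype passed to all her offspring
        damHap <- sample(1:3, nFamilies, replace = TRUE, prob = hapFreqs)
        sireHap <- sample(1:3, nFamilies, replace = TRUE, prob = hapFreqs)
        offMito <- haps[damHap[fam], , drop = FALSE] * 2L
        sireMito <- haps[sireHap, , drop = FALSE] * 2L
        damMito <- haps[damHap, , drop = FALSE] * 2L

        calls <- rbind(
            cbind(offNuc, offMito),
            cbind(sireG, sireMito),
            cbind(damG, damMito))
        rownames(calls) <- c(offIds, sires, dams)
        colnames(calls) <- markers$marker
        calls[stats::runif(length(calls)) < missingRate] <- NA_integer_
        storage.mode(calls) <- "integer"

        pedigree <- data.frame(
            sample = c(offIds, sires, dams),
            sire = c(sires[fam], rep(NA_character_, 2L * nFamilies)),
            dam = c(dams[fam], rep(NA_character_, 2L * nFamilies)),
            family = c(famIds[fam], famIds, famIds),
            generation = rep(c("offspring", "parent"),
                             c(nOff, 2L * nFamilies)))

        ## growth phenotypes for offspring
        uFam <- stats::rnorm(nFamilies, 0, sdFamily)
        uFish <- stats::rnorm(nOff, 0, sdFish)
        tank <- sample(c("T1", "T2"), nOff, replace = TRUE)
        tankEff <- ifelse(tank == "T1", 0.02, -0.02)
        age <- round(stats::rnorm(nOff, 0, 5))   # spawning-date offset, days
        muT <- meanWeights[length(meanWeights)]
        genEff <- rep(0, nOff)
        for (m in intersect(names(nuclearEffects), nuIds)) {
            d <- offNuc[, match(m, nuIds)]
            genEff <- genEff + nuclearEffects[[m]] * d
        }
        genEff <- genEff + hapEffect[[1L]] * (damHap[fam] == 3L)
        weights <- sapply(seq_along(times), function(t) {
            base <- meanWeights[t] *
                exp(uFam[fam] + uFish + tankEff +
                    stats::rnorm(nOff, 0, sdResidual)) +
                genEff * meanWeights[t] / muT
            ## older fish at a given measuring date are slightly heavier
            pmax(1, base * exp(age * 0.004))
        })
        colnames(weights) <- sprintf("weight_%d", times)
        phenotypes <- data.frame(sample = offIds, tank = tank,
                                 age = age, round(weights, 2))

        gm <- new("GenotypeMatrix", calls = calls, markers = markers)
        list(genotypes = gm, pedigree = pedigree, phenotypes = phenotypes,
             mitoOrder = mtIds, hapAssign = damHap[fam])
    })
}
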