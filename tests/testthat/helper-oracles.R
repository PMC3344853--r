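## Build a one-site or multi-site SiteEvidence from count/quality vectors.
## counts/quals are named vectors over a subset of A,C,G,T.
makeSite <- function(ref, countsFast, qualFast = NULL,
                     countsSlow = countsFast, qualSlow = qualFast,
                     contig = "tc1", pos = 100L) {
    toRow <- function(x, default = 0) {
        v <- stats::setNames(rep(default, 4L), c("A", "C", "G", "T"))
        if (!is.null(x)) v[names(x)] <- x
        matrix(v, 1L, dimnames = list(NULL, names(v)))
    }
    qf <- if (is.null(qualFast)) toRow(NULL) else toRow(qualFast)
    qs <- if (is.null(qualSlow)) toRow(NULL) else toRow(qualSlow)
    SiteEvidence(contig, pos, ref,
                 countsFast = toRow(countsFast), qualFast = qf,
                 countsSlow = toRow(countsSlow), qualSlow = qs)
}

## Stack many single-allele variant sites into one SiteEvidence: ref A,
## variant T with `varCount` reads of quality `qual`, total counted depth
## `depth` in the fast pool; slow pool all-reference at depth 10.
makeVariantGrid <- function(depth, varCount, qual) {
    n <- length(depth)
    cf <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    qf <- matrix(0, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    cf[, "A"] <- depth - varCount
    cf[, "T"] <- varCount
    qf[, "A"] <- 30
    qf[, "T"] <- ifelse(varCount > 0, qual, 0)
    cs <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    cs[, "A"] <- 10L
    qs <- qf * 0; qs[, "A"] <- 30
    SiteEvidence(sprintf("tc%06d", seq_len(n)), rep(100L, n),
                 rep("A", n), countsFast = cf, qualFast = qf,
                 countsSlow = cs, qualSlow = qs)
}

## Brute-force reference of the three stringency criteria, written directly
## from the printed rules: >= 4 reads calling the variant, > 20% of reads
## calling the variant, variant base quality > 20.
bruteStringency <- function(depth, varCount, qual,
                            minReads = 4, minFrac = 0.2, minQual = 20) {
    varCount > 0 & varCount >= minReads &
        (varCount / depth) > minFrac & qual > minQual
}

## Independent exact-HWE oracle: enumerate every genotype table with the
## same allele counts and sum the probabilities of tables no more probable
## than the observed one.  Probabilities are computed from first principles
## by counting allele pairings with choose(), a different route from the
## package's log-factorial recurrence.
hweOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    na <- 2 * naa + nAa
    tables <- list()
    for (h in 0:min(nA, na)) {
        if ((nA - h) %% 2 != 0) next
        aa <- (nA - h) / 2
        bb <- (na - h) / 2
        if (aa < 0 || bb < 0) next
        tables[[length(tables) + 1L]] <- c(aa, h, bb)
    }
    ## unnormalised weight: multinomial ways to place genotypes * 2^het
    w <- vapply(tables, function(tb)
        exp(lchoose(n, tb[1L]) + lchoose(n - tb[1L], tb[2L]) +
            tb[2L] * log(2)), 0)
    p <- w / sum(w)
    obs <- p[vapply(tables, function(tb) tb[2L] == nAa, TRUE)]
    sum(p[p <= obs + 1e-12 * obs])
}

## Closed-form simple OLS oracle.
olsOracle <- function(y, x) {
    n <- length(y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    b <- sxy / sxx
    a <- mean(y) - b * mean(x)
    res <- y - a - b * x
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    t <- b / se
    list(b = b, se = se, t = t,
         p = 2 * stats::pt(-abs(t), n - 2),
         r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
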