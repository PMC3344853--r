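#' Specific growth rate
#'
#' Log-ratio weight change per day, expressed as percent:
#' `100 * (ln(bwB) - ln(bwA)) / (tB - tA)`.
#'
#' @param bwA,bwB body weights (g) at the earlier and later evaluation.
#' @param tA,tB evaluation times (days post-hatch), `tB > tA`.
#' @return SGR in percent per day (vectorised).
#' @examples
#' sgr(100, 200, 170, 218)   # 100 * ln(2) / 48
#' @export
sgr <- function(bwA, bwB, tA, tB) {
    if (any(bwA <= 0 | bwB <= 0, na.rm = TRUE))
        stop("body weights must be positive")
    if (any(tB <= tA))
        stop("evaluation times must be strictly increasing")
    100 * (log(bwB) - log(bwA)) / (tB - tA)
}

#' Phenotypic coefficient of variation
#'
#' Sample standard deviation over the mean, returned as a proportion
#' (multiply by 100 to report as percent).
#'
#' @param values numeric vector, `n >= 2`.
#' @return SD / mean.
#' @examples
#' cv(c(90, 100, 110))
#' @export
cv <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 2L) stop("need at least two values")
    m <- mean(values)
    if (m == 0) stop("undefined CV: mean is zero")
    stats::sd(values) / m
}

#' Regression of phenotype on allele count
#'
#' Ordinary least squares of a trait on the per-sample allele dosage, with
#' optional covariates in the observed-statistic model.  Reports the slope
#' `b` (phenotype units per allele copy), its t-statistic, the two-sided
#' asymptotic P from the t distribution with residual degrees of freedom,
#' and R^2.  For the simple (covariate-free) regression,
#' `R^2 = t^2 / (t^2 + df)` holds as an internal identity.
#'
#' Incomplete pairs are dropped listwise.  A constant trait returns
#' `b = 0, t = 0, P = 1`; a constant dosage is a degenerate design and an
#' error; a trait perfectly collinear with dosage returns `R^2 = 1` with
#' `degenerateSE = TRUE`.
#'
#' @param y numeric trait values.
#' @param dosage numeric allele counts (0/1/2 for diploid markers, 0/1 for
#'   haplotype carriage).  The slope's sign flips if the counted allele is
#'   relabelled.
#' @param covariates optional data.frame of covariates.
#' @return a list of class `"pooldiffAssoc"`: `b`, `se`, `t`, `p`, `r2`,
#'   `n`, `df`, `degenerateSE`.
#' @examples
#' res <- alleleCountRegression(c(10, 11, 13, 14, 16, 17),
#'                              c(0, 0, 1, 1, 2, 2))
#' res$b
#' @export
alleleCountRegression <- function(y, dosage, covariates = NULL) {
    dat <- data.frame(y = y, dosage = dosage)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n <- nrow(dat)
    if (n < 3L) stop("need at least 3 complete cases")
    if (stats::var(dat$dosage) == 0)
        stop("degenerate design: dosage is constant")
    out <- list(b = 0, se = NA_real_, t = 0, p = 1, r2 = 0, n = n,
                df = NA_integer_, degenerateSE = FALSE)
    class(out) <- "pooldiffAssoc"
    if (stats::var(dat$y) == 0) {
        out$df <- n - 2L
        return(out)
    }
    fit <- stats::lm(y ~ ., data = dat)
    sm <- summary(fit)
    co <- sm$coefficients["dosage", ]
    out$b <- unname(co[1L])
    out$se <- unname(co[2L])
    out$df <- fit$df.residual
    out$r2 <- sm$r.squared
    if (out$se == 0 || !is.finite(co[3L])) {
        out$degenerateSE <- TRUE
        out$t <- sign(out$b) * Inf
        out$p <- 0
    } else {
        out$t <- unname(co[3L])
        out$p <- unname(co[4L])
    }
    out
}

#' @export
print.pooldiffAssoc <- function(x, ...) {
    cat(sprintf(
        "allele-count regression: b = %.4g, t = %.3f, P = %.4g, R2 = %.3f (n = %d)\n",
        x$b, x$t, x$p, x$r2, x$n))
    invisible(x)
}

## |t| of the dosage coefficient in a simple regression, from the
## correlation; vectorised over the columns of Y.
.absTfromCor <- function(xc, sx, Y, n) {
    sy <- sqrt(colSums(scale(Y, scale = FALSE)^2) / (n - 1))
    r <- colSums(xc * scale(Y, scale = FALSE)) / ((n - 1) * sx * sy)
    r <- pmin(pmax(r, -1), 1)
    ifelse(sy == 0, 0, abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300)))
}

#' Permutation empirical P-value for an allele-count regression
#'
#' Permutes the trait and recomputes the simple-regression t-statistic,
#' reporting `P = (1 + #{|t*| >= |t|}) / (K + 1)`.  The `pooled` scheme
#' permutes the trait over all samples; `within_family` permutes it only
#' among siblings of the same family, preserving the family structure
#' under the null.  Covariates are not part of the permutation model (the
#' observed-statistic regression may include them; the permuted statistic
#' is the covariate-free t).
#'
#' @param y numeric trait values.
#' @param dosage numeric allele counts.
#' @param K number of permutations (default 20000).
#' @param scheme `"pooled"` or `"within_family"`.
#' @param family family labels per sample (required for `within_family`).
#' @param seed integer seed; same seed gives an identical empirical P.
#' @return a list: `empiricalP`, `observedT` (absolute), `K`, `n`.
#' @examples
#' set.seed(1)
#' d <- rbinom(60, 2, 0.4)
#' y <- 2 * d + rnorm(60)
#' empiricalP(y, d, K = 999, seed = 5)$empiricalP
#' @export
empiricalP <- function(y, dosage, K = 20000L,
                       scheme = c("pooled", "within_family"),
                       family = NULL, seed = NULL) {
    scheme <- match.arg(scheme)
    keep <- stats::complete.cases(y, dosage,
                                  if (is.null(family)) rep(0, length(y))
                                  else family)
    y <- y[keep]; dosage <- dosage[keep]
    if (!is.null(family)) family <- family[keep]
    if (scheme == "within_family" && is.null(family))
        stop("within_family permutation requires family labels")
    n <- length(y)
    if (n < 3L) stop("need at least 3 complete cases")
    sx <- stats::sd(dosage)
    if (sx == 0) stop("degenerate design: dosage is constant")
    xc <- dosage - mean(dosage)
    if (stats::sd(y) == 0)
        return(list(empiricalP = 1, observedT = 0, K = K, n = n))
    r0 <- stats::cor(dosage, y)
    tObs <- abs(r0) * sqrt((n - 2) / max(1 - r0^2, 1e-300))
    blocks <- if (scheme == "within_family") split(seq_len(n), family)
    permute <- function(k) {
        idx <- matrix(0L, n, k)
        for (j in seq_len(k)) {
            if (scheme == "pooled") idx[, j] <- sample.int(n)
            else for (b in blocks)
                idx[b, j] <- if (length(b) == 1L) b else sample(b)
        }
        idx
    }
    doPerm <- function() {
        exceed <- 0L
        left <- as.integer(K)
        while (left > 0L) {
            k <- min(left, 2000L)
            Y <- matrix(y[permute(k)], n, k)
            tStar <- .absTfromCor(xc, sx, Y, n)
            exceed <- exceed + sum(tStar >= tObs - 1e-12)
            left <- left - k
        }
        exceed
    }
    exceed <- if (is.null(seed)) doPerm() else withSeed(seed, doPerm())
    list(empiricalP = (1 + exceed) / (K + 1), observedT = tObs,
         K = as.integer(K), n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted P-values with enforced monotonicity; each adjusted
#' value lies in `[p_i, 1]`.
#'
#' @param p numeric vector of P-values in \[0, 1\].
#' @return adjusted values in the input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.04))   # 0.03 0.03 0.04
#' @export
bhFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("P-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Sample sets of unrelated individuals from a pedigree
#'
#' Draws `nSets` population-based samples by picking one genotyped
#' offspring at random from each family, mirroring the design of repeated
#' unrelated-subset analyses (e.g. 3 sets of n = 40 from 40 families).
#'
#' @param ped a pedigree data.frame (see [readPedigree()]).
#' @param genotyped character vector of genotyped sample ids.
#' @param nSets number of independent sets to draw.
#' @param seed integer seed.
#' @return a list of character vectors, each with exactly one offspring per
#'   family.
#' @export
sampleUnrelated <- function(ped, genotyped = ped$sample, nSets = 3L, seed) {
    if (missing(seed)) stop("an integer seed is mandatory")
    off <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
               ped$sample %in% genotyped, , drop = FALSE]
    fams <- split(off$sample, off$family)
    if (length(fams) == 0L || any(lengths(fams) == 0L))
        stop("every family needs at least one genotyped offspring")
    withSeed(subSeed(seed, "sampling"), {
        lapply(seq_len(nSets), function(s)
            unname(vapply(fams, function(f)
                if (length(f) == 1L) f else sample(f, 1L), "")))
    })
}

#' Collapse mitochondrial genotypes into haplotypes
#'
#' Orders the mitochondrial markers by physical position (or an explicit
#' order), builds the per-sample allele string, and collapses identical
#' strings into haplotypes numbered by decreasing frequency.  Samples with
#' at most `maxMissing` missing calls are assigned to the unique haplotype
#' consistent with their called alleles; ambiguous or over-missing samples
#' stay unassigned.
#'
#' @param gm a [GenotypeMatrix-class]; only its mitochondrial markers are
#'   used.  Haploid calls must be homozygous (0 or 2; use [qcFilter()]
#'   first).
#' @param markerOrder optional character vector giving the marker order.
#' @param maxMissing maximum missing calls for rescue assignment.
#' @return a list of class `"haplotypeTable"`: `markers`, `haplotypes`
#'   (data.frame: haplotype, string, count, frequency over assigned
#'   samples), `assignment` (named integer, NA = unassigned).
#' @export
buildMtHaplotypes <- function(gm, markerOrder = NULL, maxMissing = 2L) {
    m <- markerInfo(gm)
    mito <- m[m$genome == "mito", , drop = FALSE]
    if (nrow(mito) == 0L) stop("no mitochondrial markers")
    if (is.null(markerOrder)) {
        markerOrder <- if ("pos" %in% names(mito))
            mito$marker[order(mito$pos)] else mito$marker
    }
    stopifnot(all(markerOrder %in% mito$marker))
    calls <- genoCalls(gm)[, markerOrder, drop = FALSE]
    if (any(calls == 1L, na.rm = TRUE))
        stop("heterozygous calls at haploid markers; run qcFilter() first")
    alleles <- ifelse(is.na(calls), NA_character_,
                      ifelse(calls == 0L,
                             mito$a1[match(markerOrder, mito$marker)][col(calls)],
                             mito$a2[match(markerOrder, mito$marker)][col(calls)]))
    dim(alleles) <- dim(calls)
    nMiss <- rowSums(is.na(alleles))
    strings <- apply(alleles, 1L, paste, collapse = "")
    complete <- nMiss == 0L
    tab <- sort(table(strings[complete]), decreasing = TRUE)
    if (length(tab) == 0L) stop("no sample has a complete haplotype string")
    hapStrings <- names(tab)
    assignment <- rep(NA_integer_, nrow(calls))
    names(assignment) <- rownames(calls)
    assignment[complete] <- match(strings[complete], hapStrings)
    rescue <- which(!complete & nMiss <= maxMissing)
    hapMat <- do.call(rbind, strsplit(hapStrings, ""))
    for (i in rescue) {
        called <- which(!is.na(alleles[i, ]))
        hits <- which(apply(hapMat[, called, drop = FALSE], 1L,
                            function(h) all(h == alleles[i, called])))
        if (length(hits) == 1L) assignment[i] <- hits
    }
    counts <- tabulate(assignment, nbins = length(hapStrings))
    out <- list(markers = markerOrder,
                haplotypes = data.frame(
                    haplotype = sprintf("Hap%d", seq_along(hapStrings)),
                    string = hapStrings, count = counts,
                    frequency = counts / sum(counts)),
                assignment = assignment)
    class(out) <- "haplotypeTable"
    out
}

#' @export
print.haplotypeTable <- function(x, ...) {
    cat(sprintf("%d distinct (%d-SNP long) haplotype%s; %d of %d samples assigned\n",
                nrow(x$haplotypes), length(x$markers),
                if (nrow(x$haplotypes) == 1) "" else "s",
                sum(!is.na(x$assignment)), length(x$assignment)))
    print(x$haplotypes[, c("haplotype", "count", "frequency")],
          row.names = FALSE)
    invisible(x)
}

#' Association of a haplotype with a trait
#'
#' Regression of phenotype on haplotype carriage (0/1 per sample, haploid)
#' with a permutation empirical P-value (default K = 10000 for haplotype
#' data).
#'
#' @param y numeric trait values.
#' @param carrier 0/1 haplotype carriage per sample.
#' @param K permutations for the empirical P.
#' @param scheme,family,seed passed to [empiricalP()].
#' @return a `"pooldiffAssoc"` list with `empiricalP` and `K` added.
#' @export
haplotypeAssociation <- function(y, carrier, K = 10000L,
                                 scheme = c("pooled", "within_family"),
                                 family = NULL, seed = NULL) {
    scheme <- match.arg(scheme)
    res <- alleleCountRegression(y, carrier)
    ep <- empiricalP(y, carrier, K = K, scheme = scheme, family = family,
                     seed = seed)
    res$empiricalP <- ep$empiricalP
    res$K <- ep$K
    res
}

#' Marker-by-marker association scan
#'
#' Runs [alleleCountRegression()] (plus [empiricalP()] when `K > 0`) for
#' every marker of a genotype matrix against one trait column, and appends
#' the Benjamini-Hochberg adjusted asymptotic P-values.
#'
#' @param gm a [GenotypeMatrix-class] object.
#' @param phenotypes a phenotype data.frame (see [readPhenotypes()]).
#' @param trait name of the trait column.
#' @param covariates optional character vector of covariate column names
#'   (observed-statistic model only).
#' @param K permutations per marker (0 disables the empirical P).
#' @param scheme,ped permutation scheme and pedigree (family labels come
#'   from the pedigree for `within_family`).
#' @param samples optional subset of sample ids.
#' @param seed integer seed for the permutations.
#' @return a data.frame with one row per marker: b, t, p, r2, n,
#'   empiricalP, fdrBH.
#' @export
associationScan <- function(gm, phenotypes, trait, covariates = NULL,
                            K = 0L, scheme = c("pooled", "within_family"),
                            ped = NULL, samples = NULL, seed = 1L) {
    scheme <- match.arg(scheme)
    if (is.null(samples))
        samples <- intersect(sampleIds(gm), phenotypes$sample)
    calls <- genoCalls(gm)[samples, , drop = FALSE]
    phen <- phenotypes[match(samples, phenotypes$sample), , drop = FALSE]
    y <- phen[[trait]]
    covs <- if (!is.null(covariates))
        phen[, covariates, drop = FALSE]
    family <- if (!is.null(ped)) ped$family[match(samples, ped$sample)]
    if (ncol(calls) == 0L)
        return(data.frame(marker = character(), b = numeric(),
                          t = numeric(), p = numeric(), r2 = numeric(),
                          n = integer(), empiricalP = numeric(),
                          fdrBH = numeric()))
    rows <- lapply(seq_len(ncol(calls)), function(k) {
        d <- calls[, k]
        res <- tryCatch(alleleCountRegression(y, d, covs),
                        error = function(e) NULL)
        if (is.null(res))
            return(data.frame(marker = colnames(calls)[k], b = NA, t = NA,
                              p = NA, r2 = NA, n = sum(!is.na(d) & !is.na(y)),
                              empiricalP = NA))
        ep <- if (K > 0L)
            empiricalP(y, d, K = K, scheme = scheme, family = family,
                       seed = seed + k)$empiricalP
        else NA_real_
        data.frame(marker = colnames(calls)[k], b = res$b, t = res$t,
                   p = res$p, r2 = res$r2, n = res$n, empiricalP = ep)
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p)
    out$fdrBH <- NA_real_
    out$fdrBH[ok] <- bhFdr(out$p[ok])
    out
}
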