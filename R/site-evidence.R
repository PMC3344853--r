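#' Construct a SiteEvidence object
#'
#' Low-level constructor used by the parsers and the simulator.  Count and
#' quality matrices must have columns A, C, G, T; depths default to the
#' counted reads per pool.
#'
#' @param contig character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases.
#' @param countsFast,countsSlow integer matrices (sites x 4) of per-base read
#'   counts.
#' @param qualFast,qualSlow numeric matrices (sites x 4) of aggregated Phred
#'   base qualities; default 0 everywhere.
#' @param depthFast,depthSlow integer vectors of raw pileup depths; default
#'   to the row sums of the count matrices.
#' @return a [SiteEvidence-class] object.
#' @examples
#' cf <- matrix(c(6L, 0L, 0L, 4L), 1, dimnames = list(NULL, c("A","C","G","T")))
#' qf <- matrix(c(35, 0, 0, 30), 1, dimnames = list(NULL, c("A","C","G","T")))
#' SiteEvidence("tc1", 10L, "A", countsFast = cf, qualFast = qf,
#'              countsSlow = cf, qualSlow = qf)
#' @export
SiteEvidence <- function(contig, pos, ref, countsFast, qualFast,
                         countsSlow, qualSlow,
                         depthFast = as.integer(rowSums(countsFast)),
                         depthSlow = as.integer(rowSums(countsSlow))) {
    fix <- function(m) {
        m <- as.matrix(m)
        colnames(m) <- BASES
        m
    }
    new("SiteEvidence",
        contig = as.character(contig), pos = as.integer(pos),
        ref = toupper(as.character(ref)),
        countsFast = fix(countsFast), qualFast = fix(qualFast),
        countsSlow = fix(countsSlow), qualSlow = fix(qualSlow),
        depthFast = as.integer(depthFast), depthSlow = as.integer(depthSlow))
}

.poolSlot <- function(pool, what) {
    pool <- match.arg(pool, c("fast", "slow"))
    paste0(what, if (pool == "fast") "Fast" else "Slow")
}

#' @rdname SiteEvidence-class
#' @export
setMethod("poolCounts", "SiteEvidence", function(x, pool)
    slot(x, .poolSlot(pool, "counts")))

#' @rdname SiteEvidence-class
#' @export
setMethod("poolQuals", "SiteEvidence", function(x, pool)
    slot(x, .poolSlot(pool, "qual")))

#' @rdname SiteEvidence-class
#' @export
setMethod("poolDepth", "SiteEvidence", function(x, pool)
    slot(x, .poolSlot(pool, "depth")))

#' @rdname SiteEvidence-class
#' @export
setMethod("refAllele", "SiteEvidence", function(x) x@ref)

#' @rdname SiteEvidence-class
#' @export
setMethod("siteKeys", "SiteEvidence", function(x)
    paste(x@contig, x@pos, sep = ":"))

#' @rdname SiteEvidence-class
#' @export
setMethod("length", "SiteEvidence", function(x) length(x@pos))

#' @rdname SiteEvidence-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SiteEvidence", function(x, i, j, ..., drop = FALSE) {
    new("SiteEvidence",
        contig = x@contig[i], pos = x@pos[i], ref = x@ref[i],
        countsFast = x@countsFast[i, , drop = FALSE],
        qualFast = x@qualFast[i, , drop = FALSE],
        countsSlow = x@countsSlow[i, , drop = FALSE],
        qualSlow = x@qualSlow[i, , drop = FALSE],
        depthFast = x@depthFast[i], depthSlow = x@depthSlow[i])
})

setMethod("show", "SiteEvidence", function(object) {
    n <- length(object)
    cat(sprintf("SiteEvidence with %d site%s\n", n, if (n == 1) "" else "s"))
    if (n > 0) {
        cat(sprintf("  mean depth: fast %.1f, slow %.1f\n",
                    mean(object@depthFast), mean(object@depthSlow)))
        k <- min(n, 3L)
        for (i in seq_len(k))
            cat(sprintf("  %s:%d ref=%s fast[%s] slow[%s]\n",
                        object@contig[i], object@pos[i], object@ref[i],
                        .fmtCounts(object@countsFast[i, ]),
                        .fmtCounts(object@countsSlow[i, ])))
        if (n > k) cat(sprintf("  ... and %d more\n", n - k))
    }
    invisible(NULL)
})

.fmtCounts <- function(cnt) {
    nz <- cnt > 0
    if (!any(nz)) return(".")
    paste(sprintf("%s:%d", names(cnt)[nz], cnt[nz]), collapse = ",")
}

#' Concatenate SiteEvidence objects
#'
#' @param x,... `SiteEvidence` objects.
#' @return a single [SiteEvidence-class] object.
#' @export
setMethod("c", "SiteEvidence", function(x, ...) {
    xs <- c(list(x), list(...))
    new("SiteEvidence",
        contig = unlist(lapply(xs, slot, "contig")),
        pos = unlist(lapply(xs, slot, "pos")),
        ref = unlist(lapply(xs, slot, "ref")),
        countsFast = do.call(rbind, lapply(xs, slot, "countsFast")),
        qualFast = do.call(rbind, lapply(xs, slot, "qualFast")),
        countsSlow = do.call(rbind, lapply(xs, slot, "countsSlow")),
        qualSlow = do.call(rbind, lapply(xs, slot, "qualSlow")),
        depthFast = unlist(lapply(xs, slot, "depthFast")),
        depthSlow = unlist(lapply(xs, slot, "depthSlow")))
})
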