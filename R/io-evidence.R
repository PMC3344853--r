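#' Parse per-site read evidence for two pools
#'
#' Reads site evidence in one of two dialects:
#' \describe{
#'   \item{`mpileup2`}{samtools mpileup text with exactly two sample blocks
#'     (fast pool first, slow pool second): columns contig, pos, ref, then
#'     depth / read-bases / base-qualities per pool.  Read-base strings are
#'     decoded per the pileup convention: `.` and `,` are the reference,
#'     `ACGTacgt` alternate bases (case, i.e. strand, is merged), `^X` and
#'     `$` read start/end marks are consumed, `+n`/`-n` indel sequences are
#'     skipped, and `*`, `>`, `<`, `N` consume a quality but contribute no
#'     counted base.  Per-base qualities (Phred+33) are aggregated per base
#'     with `qualityAggregation`.}
#'   \item{`native_tsv`}{the package's alignment-free tab-separated dialect
#'     with header `contig pos ref depth_fast bases_fast depth_slow
#'     bases_slow`, where a bases field is `.` (no counted reads) or a
#'     comma-separated list of `base:count:meanq` triples.}
#' }
#'
#' @param file path to the evidence file, or a character vector of lines.
#' @param dialect `"native_tsv"` or `"mpileup2"`.
#' @param qualityAggregation how per-read base qualities are summarised per
#'   base for the mpileup dialect: `"mean"` (default) or `"min"`.
#' @return a [SiteEvidence-class] object (zero-length for empty input).
#' @examples
#' lines <- "tc1\t5\tA\t10\t..,,TTTT..\tIIIIIIIIII\t8\t........\tIIIIIIII"
#' se <- parseSiteEvidence(lines, dialect = "mpileup2")
#' poolCounts(se, "fast")
#' @export
parseSiteEvidence <- function(file, dialect = c("native_tsv", "mpileup2"),
                              qualityAggregation = c("mean", "min")) {
    dialect <- match.arg(dialect)
    qualityAggregation <- match.arg(qualityAggregation)
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file) else as.character(file)
    lines <- lines[nzchar(lines)]
    if (dialect == "native_tsv" && length(lines) > 0 &&
        startsWith(lines[[1L]], "contig\t"))
        lines <- lines[-1L]
    if (length(lines) == 0L)
        return(.emptyEvidence())
    if (dialect == "mpileup2")
        .parseMpileup(lines, qualityAggregation)
    else
        .parseNativeTsv(lines)
}

.emptyEvidence <- function() {
    z <- matrix(0L, 0L, 4L, dimnames = list(NULL, BASES))
    SiteEvidence(character(), integer(), character(),
                 countsFast = z, qualFast = z + 0,
                 countsSlow = z, qualSlow = z + 0)
}

## Decode one pileup read-base string + quality string into per-base counts
## and a per-base quality summary. Returns list(counts, quals, used).
.decodePileup <- function(bases, quals, ref, lineno, agg) {
    ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
    qv <- utf8ToInt(quals) - 33L
    counts <- stats::setNames(integer(4L), BASES)
    qsum <- stats::setNames(numeric(4L), BASES)
    qmin <- stats::setNames(rep(Inf, 4L), BASES)
    i <- 1L; qi <- 0L
    n <- length(ch)
    while (i <= n) {
        c0 <- ch[i]
        if (c0 == "^") {
            i <- i + 2L            # caret + mapping quality char
        } else if (c0 == "$") {
            i <- i + 1L
        } else if (c0 == "+" || c0 == "-") {
            j <- i + 1L
            while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
            len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
            if (is.na(len))
                stop(sprintf("line %d: malformed indel in read bases", lineno))
            i <- j + len
        } else {
            qi <- qi + 1L
            if (qi > length(qv))
                stop(sprintf(
                    "line %d: quality string shorter than read bases", lineno))
            q <- qv[qi]
            base <- if (c0 == "." || c0 == ",") ref else toupper(c0)
            if (base %in% BASES) {
                counts[base] <- counts[base] + 1L
                qsum[base] <- qsum[base] + q
                qmin[base] <- min(qmin[base], q)
            }        # '*', '>', '<', 'N' consume a quality, count nothing
            i <- i + 1L
        }
    }
    if (qi != length(qv))
        stop(sprintf("line %d: depth/quality-string length mismatch", lineno))
    quals <- if (agg == "mean") ifelse(counts > 0, qsum / pmax(counts, 1L), 0)
             else ifelse(counts > 0, qmin, 0)
    list(counts = counts, quals = quals)
}

.parseMpileup <- function(lines, agg) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 9L)
    if (length(bad))
        stop(sprintf(
            "line %d: expected 9 mpileup columns (two sample blocks), got %d",
            bad[1L], length(parts[[bad[1L]]])))
    n <- length(parts)
    cf <- matrix(0L, n, 4L, dimnames = list(NULL, BASES)); cs <- cf
    qf <- matrix(0, n, 4L, dimnames = list(NULL, BASES)); qs <- qf
    contig <- character(n); pos <- integer(n); ref <- character(n)
    df <- integer(n); ds <- integer(n)
    for (i in seq_len(n)) {
        p <- parts[[i]]
        contig[i] <- p[1L]
        pos[i] <- suppressWarnings(as.integer(p[2L]))
        if (is.na(pos[i]))
            stop(sprintf("line %d: malformed position '%s'", i, p[2L]))
        ref[i] <- toupper(p[3L])
        df[i] <- as.integer(p[4L]); ds[i] <- as.integer(p[7L])
        fast <- .decodePileup(p[5L], p[6L], ref[i], i, agg)
        slow <- .decodePileup(p[8L], p[9L], ref[i], i, agg)
        cf[i, ] <- fast$counts; qf[i, ] <- fast$quals
        cs[i, ] <- slow$counts; qs[i, ] <- slow$quals
        if (nchar(p[6L]) != df[i])
            stop(sprintf(
                "line %d: fast-pool quality string length %d != depth %d",
                i, nchar(p[6L]), df[i]))
        if (nchar(p[9L]) != ds[i])
            stop(sprintf(
                "line %d: slow-pool quality string length %d != depth %d",
                i, nchar(p[9L]), ds[i]))
    }
    SiteEvidence(contig, pos, ref, countsFast = cf, qualFast = qf,
                 countsSlow = cs, qualSlow = qs,
                 depthFast = df, depthSlow = ds)
}

.parseTriples <- function(field, lineno) {
    counts <- stats::setNames(integer(4L), BASES)
    quals <- stats::setNames(numeric(4L), BASES)
    if (field != ".") {
        for (trip in strsplit(field, ",", fixed = TRUE)[[1L]]) {
            kv <- strsplit(trip, ":", fixed = TRUE)[[1L]]
            if (length(kv) != 3L || !(kv[1L] %in% BASES))
                stop(sprintf(
                    "line %d: malformed base:count:meanq triple '%s'",
                    lineno, trip))
            counts[kv[1L]] <- as.integer(kv[2L])
            quals[kv[1L]] <- as.numeric(kv[3L])
        }
    }
    list(counts = counts, quals = quals)
}

.parseNativeTsv <- function(lines) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 7L)
    if (length(bad))
        stop(sprintf("line %d: expected 7 tab-separated fields, got %d",
                     bad[1L], length(parts[[bad[1L]]])))
    n <- length(parts)
    cf <- matrix(0L, n, 4L, dimnames = list(NULL, BASES)); cs <- cf
    qf <- matrix(0, n, 4L, dimnames = list(NULL, BASES)); qs <- qf
    contig <- character(n); pos <- integer(n); ref <- character(n)
    df <- integer(n); ds <- integer(n)
    for (i in seq_len(n)) {
        p <- parts[[i]]
        contig[i] <- p[1L]
        pos[i] <- suppressWarnings(as.integer(p[2L]))
        if (is.na(pos[i]))
            stop(sprintf("line %d: malformed position '%s'", i, p[2L]))
        ref[i] <- toupper(p[3L])
        df[i] <- as.integer(p[4L]); ds[i] <- as.integer(p[6L])
        fast <- .parseTriples(p[5L], i); slow <- .parseTriples(p[7L], i)
        cf[i, ] <- fast$counts; qf[i, ] <- fast$quals
        cs[i, ] <- slow$counts; qs[i, ] <- slow$quals
        if (sum(cf[i, ]) > df[i] || sum(cs[i, ]) > ds[i])
            stop(sprintf("line %d: base counts exceed declared depth", i))
    }
    SiteEvidence(contig, pos, ref, countsFast = cf, qualFast = qf,
                 countsSlow = cs, qualSlow = qs,
                 depthFast = df, depthSlow = ds)
}

#' Write site evidence in the native TSV dialect
#'
#' Inverse of [parseSiteEvidence()] for the `native_tsv` dialect; writing
#' then re-reading reproduces all fields (qualities at 4 decimal places).
#'
#' @param se a [SiteEvidence-class] object.
#' @param file output path, or `NULL` to return the lines invisibly.
#' @return the character vector of lines, invisibly.
#' @export
writeSiteEvidence <- function(se, file = NULL) {
    fmtPool <- function(cnt, qual) {
        apply(cbind(cnt, qual), 1L, function(r) {
            nz <- which(r[1:4] > 0)
            if (!length(nz)) return(".")
            paste(sprintf("%s:%d:%.4f", BASES[nz], as.integer(r[nz]),
                          r[4L + nz]), collapse = ",")
        })
    }
    lines <- c("contig\tpos\tref\tdepth_fast\tbases_fast\tdepth_slow\tbases_slow",
        if (length(se) > 0)
            sprintf("%s\t%d\t%s\t%d\t%s\t%d\t%s",
                    se@contig, se@pos, se@ref,
                    se@depthFast, fmtPool(se@countsFast, se@qualFast),
                    se@depthSlow, fmtPool(se@countsSlow, se@qualSlow)))
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}
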