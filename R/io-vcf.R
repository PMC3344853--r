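#' Write discovery records as VCF v4.2
#'
#' Each retained or excluded record becomes one VCF line with INFO keys
#' `AFF` (fast-pool variant-allele frequency), `AFS` (slow-pool), `AIS`
#' (allelic imbalance score, `inf` allowed) and `AIC` (imbalance class);
#' the FILTER column is `PASS` for retained records and the stage flag
#' (`paralog_suspect`, `discordant_allele`, `no_coverage_other_pool`) for
#' excluded ones.  Records must be sorted by (contig, pos).
#'
#' @param x a [PoolDiscovery-class] object, or a record data.frame as
#'   returned by [imbalanceRecords()].
#' @param file output path, or `NULL` to return the lines.
#' @param includeExcluded when `x` is a `PoolDiscovery`, also write the
#'   excluded records with their FILTER flags (default TRUE).
#' @return the character vector of VCF lines, invisibly.
#' @seealso [readDiscoveryVcf()]
#' @export
writeDiscoveryVcf <- function(x, file = NULL, includeExcluded = TRUE) {
    if (is(x, "PoolDiscovery")) {
        recs <- if (includeExcluded)
            rbind(imbalanceRecords(x), paralogRecords(x))
        else imbalanceRecords(x)
        recs <- recs[order(recs$contig, recs$pos), , drop = FALSE]
    } else {
        recs <- x
        if (nrow(recs) > 0 &&
            !identical(order(recs$contig, recs$pos), seq_len(nrow(recs))))
            stop("records must be sorted by (contig, pos)")
    }
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=pooldiff",
        "##INFO=<ID=AFF,Number=1,Type=Float,Description=\"Fast-pool variant allele frequency\">",
        "##INFO=<ID=AFS,Number=1,Type=Float,Description=\"Slow-pool variant allele frequency\">",
        "##INFO=<ID=AIS,Number=1,Type=Float,Description=\"Allelic imbalance score (fast/slow)\">",
        "##INFO=<ID=AIC,Number=1,Type=String,Description=\"Imbalance class\">",
        "##FILTER=<ID=paralog_suspect,Description=\"Flagged by the paralog filter\">",
        "##FILTER=<ID=discordant_allele,Description=\"Pools pass on different variant alleles\">",
        "##FILTER=<ID=no_coverage_other_pool,Description=\"Contrasting pool has no usable reads\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    fmtNum <- function(v) ifelse(is.na(v), ".",
                          ifelse(is.infinite(v), "inf", sprintf("%.6g", v)))
    body <- if (nrow(recs) == 0L) character() else {
        filt <- ifelse(recs$flags == "", "PASS", recs$flags)
        info <- sprintf("AFF=%s;AFS=%s;AIS=%s;AIC=%s",
                        fmtNum(recs$fFast), fmtNum(recs$fSlow),
                        fmtNum(recs$score),
                        ifelse(is.na(recs$class), ".", recs$class))
        sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                recs$contig, recs$pos, recs$ref, recs$variantAllele,
                filt, info)
    }
    lines <- c(hdr, body)
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}

#' Read a discovery VCF back into a record table
#'
#' Parses a VCF written by [writeDiscoveryVcf()]; the AFF/AFS/AIS/AIC INFO
#' keys are restored to numeric/character columns (`inf` to `Inf`, `.` to
#' `NA`).
#'
#' @param file path to the VCF, or a character vector of lines.
#' @return a data.frame with columns contig, pos, ref, variantAllele,
#'   fFast, fSlow, score, class, flags, key.
#' @export
readDiscoveryVcf <- function(file) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file) else as.character(file)
    body <- lines[!startsWith(lines, "#")]
    empty <- data.frame(contig = character(), pos = integer(),
                        ref = character(), variantAllele = character(),
                        fFast = numeric(), fSlow = numeric(),
                        score = numeric(), class = character(),
                        flags = character(), key = character())
    if (length(body) == 0L) return(empty)
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 8L)) stop("malformed VCF body line")
    getInfo <- function(info, key) {
        m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"),
                                      info))
        vapply(m, function(x) if (length(x) == 2L) x[2L] else ".", "")
    }
    num <- function(v) ifelse(v == ".", NA_real_,
                       ifelse(v == "inf", Inf, suppressWarnings(as.numeric(v))))
    info <- vapply(parts, `[`, "", 8L)
    filt <- vapply(parts, `[`, "", 7L)
    klass <- getInfo(info, "AIC")
    out <- data.frame(
        contig = vapply(parts, `[`, "", 1L),
        pos = as.integer(vapply(parts, `[`, "", 2L)),
        ref = vapply(parts, `[`, "", 4L),
        variantAllele = vapply(parts, `[`, "", 5L),
        fFast = num(getInfo(info, "AFF")),
        fSlow = num(getInfo(info, "AFS")),
        score = num(getInfo(info, "AIS")),
        class = ifelse(klass == ".", NA_character_, klass),
        flags = ifelse(filt == "PASS", "", filt))
    out$key <- paste(out$contig, out$pos, sep = ":")
    out
}
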