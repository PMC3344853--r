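#' @rdname GenotypeMatrix-class
#' @export
setMethod("genoCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) x@markers$marker)

#' @rdname GenotypeMatrix-class
#' @param i sample index, j marker index.
#' @param ...,drop ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@calls))
    if (missing(j)) j <- seq_len(ncol(x@calls))
    if (is.character(j)) j <- match(j, x@markers$marker)
    new("GenotypeMatrix", calls = x@calls[i, j, drop = FALSE],
        markers = x@markers[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
    tab <- table(object@markers$genome)
    cat(sprintf("GenotypeMatrix: %d samples x %d markers (%s)\n",
                nrow(object@calls), ncol(object@calls),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    cat(sprintf("  completion %.3f\n", mean(!is.na(object@calls))))
    invisible(NULL)
})

#' Read a genotype matrix from TSV
#'
#' The genotype file has a `sample` column then one column per marker with
#' genotypes written as allele pairs (`A/G`) or the missing token `NA`; the
#' marker file has columns `marker`, `a1`, `a2`, `genome` and optional
#' `contig`, `pos`.  Calls are coded as the count of the `a2` allele.
#' Heterozygous calls at mitochondrial (haploid) markers raise a warning and
#' are flagged in the `"mitoHet"` attribute; [qcFilter()] rejects them.
#'
#' @param genoFile path to the genotype TSV.
#' @param markerFile path to the marker metadata TSV.
#' @return a [GenotypeMatrix-class] object.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(genoFile, markerFile) {
    g <- utils::read.delim(genoFile, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
    m <- utils::read.delim(markerFile, colClasses = "character")
    if (anyDuplicated(g$sample)) stop("duplicate sample ids")
    if (anyDuplicated(m$marker)) stop("duplicate marker ids")
    if (!identical(sort(setdiff(names(g), "sample")), sort(m$marker)))
        stop("genotype columns do not match the marker table")
    if ("pos" %in% names(m)) m$pos <- as.integer(m$pos)
    calls <- matrix(NA_integer_, nrow(g), nrow(m),
                    dimnames = list(g$sample, m$marker))
    mitoHet <- character()
    for (k in seq_len(nrow(m))) {
        v <- g[[m$marker[k]]]
        known <- v != "NA"
        al <- strsplit(v[known], "/", fixed = TRUE)
        bad <- vapply(al, function(a)
            length(a) != 2L || !all(a %in% c(m$a1[k], m$a2[k])), TRUE)
        if (any(bad))
            stop(sprintf("marker %s: unparseable genotype '%s'",
                         m$marker[k], v[known][bad][1L]))
        dos <- vapply(al, function(a) sum(a == m$a2[k]), 0L)
        if (m$genome[k] == "mito" && any(dos == 1L)) {
            mitoHet <- c(mitoHet, m$marker[k])
            warning(sprintf(
                "heterozygous call(s) at mitochondrial marker %s flagged",
                m$marker[k]))
        }
        calls[known, k] <- dos
    }
    gm <- new("GenotypeMatrix", calls = calls, markers = m)
    attr(gm, "mitoHet") <- mitoHet
    gm
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [readGenotypes()]: writes the genotype file (allele-pair
#' genotypes, `NA` for missing) and the marker metadata file.
#'
#' @param gm a [GenotypeMatrix-class] object.
#' @param genoFile,markerFile output paths.
#' @return invisibly, the genotype file path.
#' @export
writeGenotypes <- function(gm, genoFile, markerFile) {
    m <- markerInfo(gm)
    calls <- genoCalls(gm)
    out <- data.frame(sample = rownames(calls), check.names = FALSE)
    for (k in seq_len(nrow(m))) {
        gstr <- c(paste(m$a1[k], m$a1[k], sep = "/"),
                  paste(m$a1[k], m$a2[k], sep = "/"),
                  paste(m$a2[k], m$a2[k], sep = "/"))[calls[, k] + 1L]
        out[[m$marker[k]]] <- ifelse(is.na(gstr), "NA", gstr)
    }
    utils::write.table(out, genoFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(m, markerFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(genoFile)
}

#' Read a pedigree from TSV
#'
#' Columns: `sample`, `sire`, `dam`, `family`, `generation`; `NA` marks
#' unknown parents.  Rejects duplicate samples and any sample appearing in
#' its own ancestry.
#'
#' @param file path to the pedigree TSV, or a data.frame with the same
#'   columns (validated and returned).
#' @return a validated data.frame.
#' @export
readPedigree <- function(file) {
    ped <- if (is.data.frame(file)) file
           else utils::read.delim(file, colClasses = "character")
    need <- c("sample", "sire", "dam", "family")
    if (!all(need %in% names(ped)))
        stop("pedigree needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(ped$sample)) stop("duplicate sample ids in pedigree")
    parent <- function(ids, col) ped[[col]][match(ids, ped$sample)]
    for (s in ped$sample) {
        seen <- character(); frontier <- s
        while (length(frontier)) {
            anc <- stats::na.omit(c(parent(frontier, "sire"),
                                    parent(frontier, "dam")))
            anc <- setdiff(anc, seen)
            if (s %in% anc)
                stop(sprintf("sample %s is its own ancestor", s))
            seen <- c(seen, anc); frontier <- anc
        }
    }
    ped
}

#' Read a phenotype table from TSV
#'
#' Columns: `sample`, optional covariates (e.g. `tank`, `age`), and body
#' weights in columns named `weight_<days>` with strictly increasing
#' evaluation ages.  Weights must be positive.
#'
#' @param file path to the phenotype TSV, or a data.frame.
#' @return a validated data.frame with a `"times"` attribute (days
#'   post-hatch of the weight columns).
#' @export
readPhenotypes <- function(file) {
    ph <- if (is.data.frame(file)) file else utils::read.delim(file)
    if (!"sample" %in% names(ph)) stop("phenotype table needs a sample column")
    if (anyDuplicated(ph$sample)) stop("duplicate sample ids in phenotypes")
    wcols <- grep("^weight_\\d+$", names(ph), value = TRUE)
    if (length(wcols) == 0L) stop("no weight_<days> columns found")
    times <- as.integer(sub("weight_", "", wcols))
    ord <- order(times)
    if (any(diff(times[ord]) <= 0))
        stop("evaluation times must be strictly increasing")
    for (w in wcols)
        if (any(ph[[w]] <= 0, na.rm = TRUE))
            stop(sprintf("non-positive body weight in %s", w))
    attr(ph, "times") <- times[ord]
    attr(ph, "weightCols") <- wcols[ord]
    ph
}

#' @rdname readPedigree
#' @param ped a pedigree data.frame (for `writePedigree`, written to `file`).
#' @export
writePedigree <- function(ped, file) {
    utils::write.table(ped, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname readPhenotypes
#' @param ph a phenotype data.frame.
#' @export
writePhenotypes <- function(ph, file) {
    utils::write.table(ph, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
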