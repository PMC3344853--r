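#' Run the full pooled-discovery study pipeline
#'
#' Chains every stage on synthetic data: simulate pooled evidence with
#' ground truth, run the discovery funnel, validate the discovered sites
#' against the individually-genotyped discovery panel, then simulate the
#' multi-family genotyping panel and run marker QC, the association scan
#' with permutation empirical P-values, and the mitochondrial haplotype
#' analysis.  All outputs are plain text and, for a fixed seed,
#' byte-identical across runs.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param simCfg optional [SimConfig-class]; default `simConfig(seed = seed)`
#'   (its own seed is replaced by `seed`).
#' @param assayFailRate fraction of panel assays failing (assay design plus
#'   multiplexing losses).
#' @param nFamilies,nOffspring family-panel design.
#' @param trait trait column for the association scan.
#' @param K permutations per marker in the association scan.
#' @return invisibly, a list with the stage objects and a `metrics` list
#'   (funnel counts, discovery evaluation, panel validation rate, haplotype
#'   frequencies, top associated marker).
#' @examples
#' \donttest{
#' res <- runPipeline(tempfile("pd"), seed = 1,
#'                    simCfg = simConfig(nSites = 500, seed = 1),
#'                    nFamilies = 8, nOffspring = 5, K = 99)
#' res$metrics$panelValidationRate
#' }
#' @export
runPipeline <- function(outDir, seed, simCfg = NULL, assayFailRate = 0.25,
                        nFamilies = 40L, nOffspring = 17L,
                        trait = "weight_372", K = 500L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    if (is.null(simCfg)) simCfg <- simConfig(seed = seed)
    else simCfg@seed <- as.integer(seed)

    ## discovery on pooled evidence
    truth <- simulateTruth(simCfg)
    se <- simulateEvidence(truth)
    writeSiteEvidence(se, p("evidence.tsv"))
    utils::write.table(truthTable(truth), p("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dsc <- discoverSNPs(se, dhHetSites = dhHetSiteKeys(truth))
    writeDiscoveryVcf(dsc, p("calls.vcf"))
    jsonlite::write_json(as.list(funnelReport(dsc)), p("funnel.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    evalMetrics <- evaluateDiscovery(truth, dsc)

    ## panel validation of the discovered sites
    recs <- imbalanceRecords(dsc)
    valRate <- NA_real_
    if (nrow(recs) > 0) {
        panel <- panelFromTruth(truth, keys = recs$key,
                                assayFailRate = assayFailRate, seed = seed)
        vrep <- validationReport(dsc, panel)
        utils::write.table(vrep$table, p("validation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        valRate <- vrep$validationRate
    }

    ## family panel: QC, association, haplotypes
    fp <- simulateFamilyPanel(nFamilies = nFamilies,
                              nOffspring = nOffspring, seed = seed)
    writeGenotypes(fp$genotypes, p("genotypes.tsv"), p("markers.tsv"))
    writePedigree(fp$pedigree, p("pedigree.tsv"))
    writePhenotypes(fp$phenotypes, p("phenotypes.tsv"))
    qc <- qcFilter(fp$genotypes)
    utils::write.table(qc$dropped, p("qc_dropped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    offspring <- fp$pedigree$sample[fp$pedigree$generation == "offspring"]
    offspring <- intersect(offspring, sampleIds(qc$kept))
    mk <- markerInfo(qc$kept)
    ## nuclear markers: family-based, permuting the trait within families;
    ## mitochondrial markers are maternally inherited (constant within a
    ## family), so they are tested population-based on an unrelated subset
    scanNuc <- associationScan(qc$kept[, mk$marker[mk$genome == "nuclear"]],
                               fp$phenotypes, trait, K = K,
                               scheme = "within_family", ped = fp$pedigree,
                               samples = offspring, seed = seed)
    unrel <- sampleUnrelated(fp$pedigree, offspring, nSets = 3L,
                             seed = seed)
    scanMito <- associationScan(qc$kept[, mk$marker[mk$genome == "mito"]],
                                fp$phenotypes, trait, K = K,
                                scheme = "pooled",
                                samples = unrel[[1L]], seed = seed)
    scanNuc$scheme <- "within_family"; scanMito$scheme <- "pooled_unrelated"
    scan <- rbind(scanNuc, scanMito)
    utils::write.table(scan, p("assoc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    haps <- buildMtHaplotypes(qc$kept)
    utils::write.table(haps$haplotypes, p("haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    top <- scan[which.min(scan$p), , drop = FALSE]
    metrics <- list(
        funnel = as.list(funnelReport(dsc)),
        discovery = evalMetrics,
        panelValidationRate = valRate,
        haplotypeFrequencies = haps$haplotypes$frequency,
        nMarkersKept = length(markerIds(qc$kept)),
        topMarker = top$marker, topMarkerP = top$p)
    jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(truth = truth, evidence = se, discovery = dsc,
                   familyPanel = fp, qc = qc, scan = scan,
                   haplotypes = haps, metrics = metrics, dir = outDir))
}
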