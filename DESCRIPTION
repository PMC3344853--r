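Package: pooldiff
Title: SNP Discovery by Allelic Imbalance Between Pooled Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery of candidate trait-associated SNPs from low-coverage
    RNA-Seq of two phenotypically divergent pools (e.g. fast- versus
    slow-growing fish), using per-pool stringency filtering of read
    evidence, read-count allele-frequency estimation and an allelic
    imbalance score (the ratio of variant-allele frequencies between
    pools), with paralog-artifact removal against a doubled-haploid
    reference. Includes a pooled-sequencing simulator with ground truth,
    a genotype-panel validation stage, and downstream marker statistics:
    genotype QC, exact Hardy-Weinberg tests, regression of phenotype on
    allele count with permutation empirical P-values, Benjamini-Hochberg
    FDR, unrelated-subset sampling from pedigrees, and mitochondrial
    haplotype construction and association.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SNPDiscovery, Genetics, Sequencing, StatisticalMethod
RoxygenNote: 7.3.3
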