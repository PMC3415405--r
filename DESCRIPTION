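Package: chdsig
Title: Transcriptome Signatures of Congenital Heart Defects in Trisomy 21
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for distinguishing Down-syndrome heart-defect
    subgroups (atrioventricular septal defect, atrial plus ventricular septal
    defect, no defect) from expression profiles of lymphoblastoid cell lines.
    Provides detection-p-value expression calls, quantile normalization,
    probe-to-gene collapsing, pairwise t-tests with a global common variance,
    one-way ANOVA, a p-value-uniformity group-merge rule, a four-class gene
    dosage classification, positional (chromosomal) cluster statistics for
    runs of contiguous differentially expressed genes, and hypergeometric
    gene-set enrichment with GOrilla-style enrichment factors. A synthetic
    data generator with planted ground truth stands in for the original
    microarray cohort and drives calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
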