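Package: SomaticSubtyper
Title: Multi-Caller Somatic Consensus, Tumor Mutational Burden, and
    Rule-Based Molecular Subtyping of Pediatric CNS Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream somatic-genomics toolkit for pediatric cancer
    cohorts. Merges small-variant calls from four callers (Strelka2,
    Mutect2, Lancet, VarDict) into consensus calls with multi-nucleotide
    variant reconstruction, hotspot rescue and germline-leakage
    filtering; builds multi-caller copy-number consensus regions by
    reciprocal overlap and containment and resolves gene-level focal
    copy-number status; computes tumor mutational burden with
    BED-intersection denominators; prioritizes putative oncogenic RNA
    fusions; annotates TP53 activated/lost status from multi-channel
    evidence; and assigns WHO 2021 research-grade molecular subtypes to
    pediatric CNS tumor events with a rule engine integrating mutation,
    copy-number, fusion, expression and DNA-methylation-classifier
    evidence. Ships a seeded synthetic-cohort generator with labeled
    ground truth so every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CopyNumberVariation, SNP, Sequencing, Classification
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SomaticSubtyper-package.R'
    'intervals.R'
    'containers.R'
    'consensus-cnv.R'
    'arm-events.R'
    'consensus-snv.R'
    'expression.R'
    'focal-cn.R'
    'fusions.R'
    'independent-samples.R'
    'io-maf.R'
    'io-seg.R'
    'tmb.R'
    'tp53.R'
    'subtype-rules.R'
    'subtype-engine.R'
    'run-subtyping.R'
    'pipeline.R'
    'synthetic-cohort.R'
    'thresholds.R'
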