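#' @include run-subtyping.R tmb.R focal-cn.R arm-events.R fusions.R
NULL

.maybe <- function(path) if (file.exists(path)) path else NULL

#' Run the full downstream pipeline on a cohort directory
#'
#' Executes every stage in dependency order on a directory laid out like
#' [generateCohort()] output: SNV consensus (MNP reconstruction, two-of-
#' four consensus, germline-leakage filter), CNV consensus (de-noising,
#' pairwise consensus, merging, blacklist/size filter), gene-level focal
#' status with duplicate resolution, arm events, TMB, fusion
#' prioritization, TP53 status, and molecular subtyping. Missing evidence
#' files degrade gracefully: the corresponding channel is empty and
#' subtype predicates on it evaluate false (with a warning). Writes all
#' stage outputs plus a run manifest (input checksums and per-stage row
#' counts; no timestamps, so identical inputs give identical manifests).
#'
#' @param dir input directory.
#' @param outDir output directory (created).
#' @param thresholds see [defaultThresholds()].
#' @param rules see [subtypeRules()].
#' @return invisibly, a named list of the in-memory stage results.
#' @export
runPipeline <- function(dir, outDir, thresholds = defaultThresholds(),
                        rules = subtypeRules()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  o <- function(...) file.path(outDir, ...)
  counts <- list()

  hist <- readTsv(p("histologies.tsv"))
  wgs <- hist$sample_id[grepl("WGS", hist$experimental_strategy)]

  ## ---- SNV consensus ----
  mafs <- list(
    strelka2 = readMaf(p("strelka2.maf.tsv"), "strelka2",
                       gnomad_af_col = "gnomad_3_1_1_AF"),
    mutect2 = readMaf(p("mutect2.maf.tsv"), "mutect2"),
    lancet = readMaf(p("lancet.maf.tsv"), "lancet"),
    vardict = readMaf(p("vardict.maf.tsv"), "vardict")
  )
  others <- variantSet(do.call(rbind, lapply(
    mafs[c("mutect2", "lancet", "vardict")], records)))
  mafs$strelka2 <- reconstructMnp(mafs$strelka2, others)
  consensus <- callConsensus(mafs, thresholds)
  consensus <- filterGermlineLeakage(consensus, thresholds)
  writeMaf(consensus, o("consensus.maf.tsv"))
  counts$consensus_snv <- length(consensus)

  ## ---- CNV consensus ----
  segs <- list(
    controlfreec = readSeg(p("controlfreec.seg.tsv"), "controlfreec",
                           ploidy = thresholds$ploidy),
    cnvkit = readSeg(p("cnvkit.seg.tsv"), "cnvkit",
                     ploidy = thresholds$ploidy),
    gatk = readSeg(p("gatk.seg.tsv"), "gatk", ploidy = thresholds$ploidy)
  )
  segs <- denoiseCallerFiles(segs, thresholds)
  regions <- pairwiseConsensus(segs, thresholds)
  regions <- mergeAdjacent(regions, thresholds)
  blacklist <- if (file.exists(p("blacklist.bed"))) {
    readBed(p("blacklist.bed"))
  } else NULL
  regions <- blacklistSizeFilter(regions, blacklist, thresholds)
  regions <- neutralToNA(regions)
  writeSeg(regions, o("consensus_cnv.tsv"))
  counts$consensus_cnv <- nrow(regions)

  ## ---- gene status + arm events ----
  geneModel <- readGeneBed(p("genes.bed"))
  geneCalls <- assignGeneStatus(regions, geneModel, samples = wgs)
  geneStatus <- resolveDuplicateStatus(geneCalls)
  writeTsv(geneStatus, o("gene_status.tsv"))
  counts$gene_status <- nrow(geneStatus)
  arms <- readArmTable(p("arms.tsv"))
  armEvents <- callArmEvents(regions, arms, thresholds)
  writeTsv(armEvents, o("arm_events.tsv"))
  counts$arm_events <- nrow(armEvents)

  ## ---- TMB ----
  surveyed <- Reduce(intersectSets, list(
    readBed(p("surveyed_strelka2.bed")),
    readBed(p("surveyed_mutect2.bed")),
    readBed(p("surveyed_vardict.bed"))
  ))
  cds <- readBed(p("cds.bed"))
  tmb <- computeTmb(splitMnv(consensus), "WGS", surveyed, cds,
                    samples = wgs)
  writeTsv(tmb, o("tmb.tsv"))
  counts$tmb <- nrow(tmb)

  ## ---- fusions ----
  fus <- if (file.exists(p("fusions.tsv"))) {
    fusionSet(readTsv(p("fusions.tsv")))
  } else {
    warning("no fusions.tsv; fusion channel empty")
    fusionSet()
  }
  lists <- list(
    kinase = .maybe(p("genes_kinase.txt")),
    oncogene = .maybe(p("genes_oncogene.txt")),
    tumor_suppressor = .maybe(p("genes_tumor_suppressor.txt")),
    transcription_factor = .maybe(p("genes_transcription_factor.txt")),
    cosmic_census = .maybe(p("genes_cosmic_census.txt")),
    tcga_observed = .maybe(p("genes_tcga_observed.txt"))
  )
  lists <- lists[!vapply(lists, is.null, TRUE)]
  if (length(lists)) fus <- annotateOncogenic(fus, lists)
  pri <- retainFusions(fus, thresholds)
  writeTsv(records(pri$retained), o("fusions_prioritized.tsv"))
  counts$fusions_retained <- length(pri$retained)

  ## ---- TP53 ----
  germline <- hist[, intersect(c("sample_id", "germline_flags"),
                               names(hist)), drop = FALSE]
  scores <- if (file.exists(p("tp53_scores.tsv"))) {
    readTsv(p("tp53_scores.tsv"))
  } else data.frame()
  tp53ev <- assembleTp53Evidence(consensus, geneStatus,
                                 germline = germline, scores = scores,
                                 samples = hist$sample_id)
  tp53 <- classifyTp53(tp53ev, thresholds)
  writeTsv(tp53, o("tp53_status.tsv"))
  counts$tp53 <- nrow(tp53)

  ## ---- expression flags ----
  exprFlags <- data.frame()
  exprTpm <- data.frame()
  if (file.exists(p("expression.tsv"))) {
    ex <- readExpression(p("expression.tsv"))
    mat <- collapseToSymbol(ex$mat, ex$ensembl, ex$symbol)
    grouping <- hist$cancer_group[match(colnames(mat), hist$sample_id)]
    grouping[is.na(grouping)] <- "unknown"
    z <- cohortZscore(mat, grouping)
    over <- z >= thresholds$zscore_high
    under <- z < thresholds$zscore_low
    exprFlags <- data.frame(
      sample_id = rep(colnames(mat), each = nrow(mat)),
      gene = rep(rownames(mat), times = ncol(mat)),
      over = as.vector(over), under = as.vector(under),
      stringsAsFactors = FALSE
    )
    exprTpm <- data.frame(
      sample_id = rep(colnames(mat), each = nrow(mat)),
      gene = rep(rownames(mat), times = ncol(mat)),
      tpm = as.vector(mat), stringsAsFactors = FALSE
    )
  } else {
    warning("no expression.tsv; expression predicates will be FALSE")
  }

  ## ---- subtyping ----
  methyl <- if (file.exists(p("methylation.tsv"))) {
    readTsv(p("methylation.tsv"))
  } else {
    warning("no methylation.tsv; methylation predicates will be FALSE")
    data.frame()
  }
  bundles <- buildEvidenceBundles(
    hist, variants = consensus, geneStatus = geneStatus,
    armEvents = armEvents, fusions = pri$retained,
    exprFlags = exprFlags, exprTpm = exprTpm, methyl = methyl,
    tp53 = tp53
  )
  subtypes <- runSubtyping(bundles, rules, thresholds)
  writeTsv(subtypes, o("subtypes.tsv"))
  counts$subtypes <- nrow(subtypes)

  ## ---- manifest ----
  inputs <- sort(list.files(dir, full.names = TRUE))
  manifest <- data.frame(
    file = basename(inputs),
    md5 = as.character(tools::md5sum(inputs)),
    stringsAsFactors = FALSE
  )
  stage <- data.frame(file = paste0("rows:", names(counts)),
                      md5 = as.character(unlist(counts)),
                      stringsAsFactors = FALSE)
  writeTsv(rbind(manifest, stage), o("manifest.tsv"))

  invisible(list(consensus = consensus, regions = regions,
                 geneStatus = geneStatus, armEvents = armEvents,
                 tmb = tmb, fusions = pri, tp53 = tp53,
                 subtypes = subtypes, counts = counts))
}
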