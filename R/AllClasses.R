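#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importClassesFrom GenomicRanges GRanges
NULL

## Column contracts for the tabular containers. Optional columns are filled
## with NA by the constructors so downstream code can rely on their presence.
.VARIANT_COLS <- c(
  "sample_id", "chrom", "start", "end", "ref", "alt", "gene",
  "variant_class", "variant_type", "protein_change", "callers",
  "t_depth", "alt_depth", "n_depth", "gnomad_af", "hotspot"
)
.SEGMENT_COLS <- c(
  "sample_id", "chrom", "start", "end", "copy_number", "status", "caller"
)
.FUSION_COLS <- c(
  "sample_id", "gene5", "gene3", "caller", "cancer_group", "annotations"
)

.CNV_STATUSES <- c("gain", "loss", "amplification", "deep deletion", "neutral")
.SNV_CALLERS <- c("strelka2", "mutect2", "lancet", "vardict")
.CNV_CALLERS <- c("controlfreec", "cnvkit", "gatk", "mantasv")

#' Disjoint genomic interval set
#'
#' An `IntervalSet` is a `GRanges` whose ranges are sorted, strictly
#' disjoint and non-abutting within each chromosome (i.e. fully reduced).
#' It backs all region arithmetic in the package: CNV-consensus geometry,
#' TMB denominators and chromosome-arm coverage. Construct with
#' [intervalSet()], which merges and sorts arbitrary input ranges.
#'
#' @seealso [intervalSet()], [totalBp()], [intersectSets()], [readBed()]
#' @export
setClass("IntervalSet", contains = "GRanges")

setValidity("IntervalSet", function(object) {
  red <- GenomicRanges::reduce(GenomicRanges::sort(object))
  if (length(red) != length(object) ||
      (length(red) && !identical(
        as.data.frame(GenomicRanges::granges(GenomicRanges::sort(object))),
        as.data.frame(GenomicRanges::granges(red))
      ))) {
    return("intervals must be sorted, disjoint and non-abutting (reduced)")
  }
  TRUE
})

#' Somatic small-variant call set
#'
#' Holds one row per somatic small-variant call in MAF coordinates
#' (1-based, inclusive), with caller provenance, tumor/normal depths,
#' gnomAD population allele frequency and the hotspot flag. Multiple
#' supporting callers are recorded as a comma-separated `callers` field.
#'
#' @slot records `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `ref`, `alt`, `gene`, `variant_class`, `variant_type`,
#'   `protein_change`, `callers`, `t_depth`, `alt_depth`, `n_depth`,
#'   `gnomad_af`, `hotspot` (and, after consensus, `consensus_reason`).
#' @seealso [variantSet()], [readMaf()], [callConsensus()]
#' @export
setClass("VariantSet", representation(records = "data.frame"))

setValidity("VariantSet", function(object) {
  df <- object@records
  miss <- setdiff(.VARIANT_COLS, names(df))
  if (length(miss)) {
    return(paste("missing variant columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(df$end < df$start)) return("variant end < start")
    bad <- !is.na(df$alt_depth) & !is.na(df$t_depth) & df$alt_depth > df$t_depth
    if (any(bad)) return("alt_depth exceeds t_depth")
    if (any(is.na(df$callers) | !nzchar(df$callers))) {
      return("every variant needs at least one caller")
    }
    af <- df$gnomad_af[!is.na(df$gnomad_af)]
    if (length(af) && (any(af < 0) || any(af > 1))) {
      return("gnomad_af outside [0, 1]")
    }
  }
  TRUE
})

#' Copy-number segment set
#'
#' One row per copy-number segment from a single caller: a genomic interval
#' (1-based, inclusive), an integer copy number (possibly `NA`), a direction
#' status (`gain`, `loss`, `amplification`, `deep deletion`, `neutral`) and
#' the caller label.
#'
#' @slot records `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `copy_number`, `status`, `caller`.
#' @seealso [segmentSet()], [readSeg()], [pairwiseConsensus()]
#' @export
setClass("SegmentSet", representation(records = "data.frame"))

setValidity("SegmentSet", function(object) {
  df <- object@records
  miss <- setdiff(.SEGMENT_COLS, names(df))
  if (length(miss)) {
    return(paste("missing segment columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(df$end < df$start)) return("segment end < start")
    if (any(!df$status %in% .CNV_STATUSES)) {
      return(paste("unknown status token; allowed:",
                   paste(.CNV_STATUSES, collapse = ", ")))
    }
  }
  TRUE
})

#' RNA fusion call set
#'
#' One row per gene-fusion call: 5' and 3' partner HGNC symbols, the caller
#' (`arriba`, `starfusion` or `dgd_panel`), the cohort's cancer-group label
#' and any annotation flags (comma-separated subset of `kinase`, `oncogene`,
#' `tumor_suppressor`, `transcription_factor`, `cosmic_census`,
#' `tcga_observed`).
#'
#' @slot records `data.frame` with columns `sample_id`, `gene5`, `gene3`,
#'   `caller`, `cancer_group`, `annotations`.
#' @seealso [fusionSet()], [annotateOncogenic()], [retainFusions()]
#' @export
setClass("FusionSet", representation(records = "data.frame"))

setValidity("FusionSet", function(object) {
  df <- object@records
  miss <- setdiff(.FUSION_COLS, names(df))
  if (length(miss)) {
    return(paste("missing fusion columns:", paste(miss, collapse = ", ")))
  }
  TRUE
})

#' Per-event multi-omic evidence bundle
#'
#' Collects every evidence channel the subtyping engine can consult for one
#' tumor event. All channels except the specimen metadata are optional;
#' predicates on absent channels evaluate to `FALSE`.
#'
#' @slot specimen one-row `data.frame` of specimen/clinical metadata
#'   (pathology diagnosis, free-text diagnosis, age, anatomical site,
#'   germline flags, ...).
#' @slot variants consensus small-variant `data.frame` (VariantSet records).
#' @slot geneStatus resolved gene-level focal copy-number `data.frame`.
#' @slot armEvents `data.frame` with columns `arm`, `direction`.
#' @slot fusions prioritized fusion `data.frame`.
#' @slot exprFlags `data.frame` with columns `gene`, `over`, `under`
#'   (z-score derived expression flags).
#' @slot exprTpm named numeric of raw collapsed TPM values (used for the
#'   MYCN cutoff in neuroblastoma).
#' @slot methyl methylation-classifier prediction `data.frame`
#'   (`classifier`, `subclass`, `score`).
#' @slot tp53 one-row `data.frame` with `status` and `evidence_trace`, or
#'   empty.
#' @slot rnaSubtype external transcriptomic medulloblastoma classifier
#'   label (`character(0)` when absent).
#' @seealso [evidenceBundle()], [runSubtyping()]
#' @export
setClass("EvidenceBundle", representation(
  specimen   = "data.frame",
  variants   = "data.frame",
  geneStatus = "data.frame",
  armEvents  = "data.frame",
  fusions    = "data.frame",
  exprFlags  = "data.frame",
  exprTpm    = "numeric",
  methyl     = "data.frame",
  tp53       = "data.frame",
  rnaSubtype = "character"
))

setValidity("EvidenceBundle", function(object) {
  if (nrow(object@specimen) != 1L) return("specimen must be a one-row data.frame")
  if (nrow(object@methyl) && (any(object@methyl$score < 0, na.rm = TRUE) ||
                              any(object@methyl$score > 1, na.rm = TRUE))) {
    return("methylation scores must lie in [0, 1]")
  }
  TRUE
})
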