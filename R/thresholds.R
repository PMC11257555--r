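#' Pipeline thresholds
#'
#' Returns the full set of numeric thresholds used across the pipeline,
#' optionally overridden from a YAML file or by named arguments. Every
#' stage takes a `thresholds` list so no cutoff is hard-coded at a call
#' site.
#'
#' Defaults (units in parentheses):
#' \describe{
#'   \item{normal_depth_max = 7 (reads)}{germline-leakage filter: maximum
#'     matched-normal depth at which a non-hotspot variant with elevated
#'     population frequency is considered germline leakage.}
#'   \item{gnomad_af_min = 0.001}{germline-leakage filter: gnomAD allele
#'     frequency above which such a variant is removed.}
#'   \item{tumor_only_min_t_depth = 4 (reads)}{tumor-only filter: variants
#'     below this tumor depth (or with zero alt reads) are removed.}
#'   \item{min_callers = 2}{callers required for non-hotspot consensus.}
#'   \item{recip_overlap = 0.50}{reciprocal-overlap fraction both segments
#'     must reach for CNV consensus rule 1.}
#'   \item{containment = 0.90}{fraction of a smaller segment that must be
#'     covered by another caller for CNV consensus rule 2 (strict >).}
#'   \item{max_cnv_per_file = 2500 (segments)}{per-sample/per-caller
#'     de-noising cap; files above it are dropped.}
#'   \item{merge_gap = 10000 (bp)}{same-direction consensus regions at most
#'     this far apart are merged.}
#'   \item{min_cnv_len = 3000 (bp)}{consensus regions shorter than this are
#'     filtered out.}
#'   \item{blacklist_overlap = 0.50}{regions overlapping the blacklist by
#'     at least this fraction of their length are filtered out.}
#'   \item{methyl_confidence = 0.80}{methylation classifier score at or
#'     above which a prediction is high-confidence.}
#'   \item{mycn_tpm_cutoff = 140.83 (TPM)}{MYCN expression cutoff for
#'     neuroblastoma subtyping when DNA evidence is absent/conflicting.}
#'   \item{tp53_score_cutoff = 0.5}{TP53 inactivation classifier score
#'     (strict >) used by lost-condition (iv).}
#'   \item{zscore_high = 2}{over-expression flag: z >= zscore_high.}
#'   \item{zscore_low = -2}{under-expression flag: z < zscore_low (strict).}
#'   \item{arm_fraction = 0.5}{fraction of a chromosome arm that must be
#'     covered by same-direction consensus regions to call an arm event.}
#'   \item{fusion_recurrence_min = 3 (samples)}{gene pairs seen in at least
#'     this many samples of one cancer group count as recurrent.}
#'   \item{mb_age_alpha = 2, mb_age_beta_gamma = 5, mb_age_delta = 10 (y)}{
#'     age gates for the MB SHH alpha / beta+gamma / delta criteria.}
#'   \item{ploidy = 2}{assumed ploidy for copy-number status derivation.}
#' }
#'
#' @param file optional YAML file of overrides (flat key: value map).
#' @param ... named scalar overrides applied after the file.
#' @return named list of thresholds.
#' @export
defaultThresholds <- function(file = NULL, ...) {
  th <- list(
    normal_depth_max = 7,
    gnomad_af_min = 0.001,
    tumor_only_min_t_depth = 4,
    min_callers = 2,
    recip_overlap = 0.50,
    containment = 0.90,
    max_cnv_per_file = 2500,
    merge_gap = 10000,
    min_cnv_len = 3000,
    blacklist_overlap = 0.50,
    methyl_confidence = 0.80,
    mycn_tpm_cutoff = 140.83,
    tp53_score_cutoff = 0.5,
    zscore_high = 2,
    zscore_low = -2,
    arm_fraction = 0.5,
    fusion_recurrence_min = 3,
    mb_age_alpha = 2,
    mb_age_beta_gamma = 5,
    mb_age_delta = 10,
    ploidy = 2
  )
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    th[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(th))
    if (length(unknown)) {
      stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
    }
    th[names(dots)] <- dots
  }
  stopifnot(
    th$recip_overlap >= 0, th$recip_overlap <= 1,
    th$containment >= 0, th$containment <= 1,
    th$blacklist_overlap >= 0, th$blacklist_overlap <= 1,
    th$methyl_confidence >= 0, th$methyl_confidence <= 1,
    th$min_callers >= 1, th$min_cnv_len > 0, th$merge_gap >= 0,
    th$max_cnv_per_file > 0, th$ploidy >= 1
  )
  th
}

#' Nonsynonymous Variant_Classification sets for TMB
#'
#' `"default"` is the high/moderate-consequence list used for coding TMB;
#' `"focr"` is an editable alternate list following the Friends of Cancer
#' Research TMB-harmonization recommendations (shipped as a config file in
#' `inst/extdata/nonsyn_focr.txt`; edit it to change the set).
#'
#' @param which `"default"` or `"focr"`.
#' @return character vector of Variant_Classification values.
#' @export
nonsynClassifications <- function(which = c("default", "focr")) {
  which <- match.arg(which)
  if (which == "default") {
    c("Missense_Mutation", "Frame_Shift_Del", "In_Frame_Ins",
      "Frame_Shift_Ins", "Splice_Site", "Nonsense_Mutation",
      "In_Frame_Del", "Nonstop_Mutation", "Translation_Start_Site")
  } else {
    path <- system.file("extdata", "nonsyn_focr.txt",
                        package = "SomaticSubtyper", mustWork = TRUE)
    scan(path, what = character(), quiet = TRUE, comment.char = "#")
  }
}
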