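#' @include containers.R
NULL

.TP53_GOF <- c("p.R273C", "p.R248W")

#' Assemble TP53 evidence per sample
#'
#' Collects, per sample, the somatic TP53 small variants (protein change
#' and hotspot flag), whether the gene carries a focal copy-number loss or
#' deep deletion, whether a structural variant disrupts it, the germline
#' Li-Fraumeni flag, and the RNA inactivation-classifier score.
#'
#' @param variants consensus [VariantSet-class] (or its records).
#' @param geneStatus resolved gene-status `data.frame`
#'   ([resolveDuplicateStatus()]).
#' @param svTable `data.frame` with `sample_id`, `gene` of SV-disrupted
#'   genes (optional).
#' @param germline `data.frame` with `sample_id`, `germline_flags`
#'   (comma-separated; `TP53_LFS` marks a pathogenic LFS variant).
#' @param scores `data.frame` with `sample_id`, `classifier_score`.
#' @param samples sample ids to assemble; default union over channels.
#' @return `data.frame`, one row per sample, with columns `sample_id`,
#'   `gof_variant`, `hotspot_variant`, `n_somatic_snv`, `cnv_loss`, `sv`,
#'   `germline_lfs`, `classifier_score`.
#' @export
assembleTp53Evidence <- function(variants = variantSet(),
                                 geneStatus = data.frame(),
                                 svTable = data.frame(),
                                 germline = data.frame(),
                                 scores = data.frame(),
                                 samples = NULL) {
  vdf <- if (is(variants, "VariantSet")) records(variants)
         else as.data.frame(variants)
  tp53 <- vdf[!is.na(vdf$gene) & vdf$gene == "TP53", , drop = FALSE]
  if (is.null(samples)) {
    samples <- sort(unique(c(
      tp53$sample_id,
      if (nrow(geneStatus)) geneStatus$sample_id,
      if (nrow(svTable)) svTable$sample_id,
      if (nrow(germline)) germline$sample_id,
      if (nrow(scores)) scores$sample_id
    )))
  }
  do.call(rbind, lapply(samples, function(s) {
    v <- tp53[tp53$sample_id == s, , drop = FALSE]
    gs <- if (nrow(geneStatus)) {
      geneStatus[geneStatus$sample_id == s & geneStatus$gene == "TP53", ,
                 drop = FALSE]
    } else data.frame()
    gl <- if (nrow(germline)) {
      germline[germline$sample_id == s, , drop = FALSE]
    } else data.frame()
    sc <- if (nrow(scores)) {
      scores[scores$sample_id == s, , drop = FALSE]
    } else data.frame()
    data.frame(
      sample_id = s,
      gof_variant = any(!is.na(v$protein_change) &
                          v$protein_change %in% .TP53_GOF),
      hotspot_variant = any(v$hotspot),
      n_somatic_snv = nrow(v),
      cnv_loss = nrow(gs) > 0 &&
        any(gs$status %in% c("loss", "deep deletion")),
      sv = nrow(svTable) > 0 &&
        any(svTable$sample_id == s &
              !is.na(svTable$gene) & svTable$gene == "TP53"),
      germline_lfs = nrow(gl) > 0 &&
        any(grepl("TP53_LFS", gl$germline_flags)),
      classifier_score = if (nrow(sc)) sc$classifier_score[1] else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Classify TP53 status
#'
#' Status is `activated` iff a somatic gain-of-function variant p.R273C or
#' p.R248W is present (activation takes precedence: those residues are
#' also database hotspots). Otherwise status is `lost` iff any of:
#' (i) a hotspot TP53 mutation; (ii) at least two distinct TP53 alteration
#' channels among SNV / CNV / SV (biallelic-inactivation pattern);
#' (iii) a single somatic TP53 variant, or a pathogenic germline LFS
#' variant; (iv) a germline LFS variant together with an inactivation
#' classifier score strictly above `tp53_score_cutoff` (default 0.5).
#' Otherwise `other` (wild-type-consistent).
#'
#' @param evidence `data.frame` from [assembleTp53Evidence()].
#' @param thresholds see [defaultThresholds()].
#' @return `data.frame`: `sample_id`, `status`
#'   (`activated`/`lost`/`other`), `evidence_trace` (fired conditions,
#'   comma-separated).
#' @export
classifyTp53 <- function(evidence, thresholds = defaultThresholds()) {
  if (!nrow(evidence)) {
    return(data.frame(sample_id = character(), status = character(),
                      evidence_trace = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(evidence)), function(i) {
    e <- evidence[i, ]
    trace <- character()
    if (isTRUE(e$gof_variant)) {
      return(data.frame(sample_id = e$sample_id, status = "activated",
                        evidence_trace = "gain_of_function_variant",
                        stringsAsFactors = FALSE))
    }
    n_channels <- sum(e$n_somatic_snv > 0, isTRUE(e$cnv_loss), isTRUE(e$sv))
    if (isTRUE(e$hotspot_variant)) trace <- c(trace, "hotspot")
    if (n_channels >= 2) trace <- c(trace, "two_alterations")
    if (e$n_somatic_snv > 0) trace <- c(trace, "single_somatic_variant")
    if (isTRUE(e$germline_lfs)) trace <- c(trace, "germline_lfs")
    if (isTRUE(e$germline_lfs) && !is.na(e$classifier_score) &&
        e$classifier_score > thresholds$tp53_score_cutoff) {
      trace <- c(trace, "germline_lfs_plus_classifier")
    }
    data.frame(
      sample_id = e$sample_id,
      status = if (length(trace)) "lost" else "other",
      evidence_trace = paste(trace, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
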