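#' @include subtype-engine.R
NULL

.sub_rows <- function(df, s) {
  if (!nrow(df)) df else df[df$sample_id == s, , drop = FALSE]
}

#' Assemble per-event evidence bundles from channel tables
#'
#' Joins every evidence channel to the specimen table by `sample_id`.
#' Missing channels simply yield empty slots; subtyping predicates on
#' absent channels evaluate to `FALSE`.
#'
#' @param histologies specimen/clinical `data.frame`; must carry
#'   `sample_id`, `tumor_event_id`, `pathology_diagnosis`; consulted when
#'   present: `pathology_free_text_diagnosis`, `age_at_diagnosis_years`,
#'   `anatomical_site`, `germline_flags`, `precomputed_subtype`,
#'   `rna_subtype_label`.
#' @param variants consensus [VariantSet-class] (or records).
#' @param geneStatus resolved gene-status `data.frame`.
#' @param armEvents arm-event `data.frame` from [callArmEvents()].
#' @param fusions prioritized [FusionSet-class] (or records).
#' @param exprFlags long `data.frame`: `sample_id`, `gene`, `over`,
#'   `under`.
#' @param exprTpm long `data.frame`: `sample_id`, `gene`, `tpm`.
#' @param methyl `data.frame`: `sample_id`, `classifier`, `subclass`,
#'   `score`.
#' @param tp53 `data.frame` from [classifyTp53()].
#' @return named list of [EvidenceBundle-class], one per histology row.
#' @export
buildEvidenceBundles <- function(histologies,
                                 variants = variantSet(),
                                 geneStatus = data.frame(),
                                 armEvents = data.frame(),
                                 fusions = fusionSet(),
                                 exprFlags = data.frame(),
                                 exprTpm = data.frame(),
                                 methyl = data.frame(),
                                 tp53 = data.frame()) {
  vdf <- if (is(variants, "VariantSet")) records(variants)
         else as.data.frame(variants)
  fdf <- if (is(fusions, "FusionSet")) records(fusions)
         else as.data.frame(fusions)
  out <- lapply(seq_len(nrow(histologies)), function(i) {
    spec <- histologies[i, , drop = FALSE]
    s <- spec$sample_id
    tpm_rows <- .sub_rows(as.data.frame(exprTpm), s)
    tpm <- if (nrow(tpm_rows)) {
      stats::setNames(as.numeric(tpm_rows$tpm), tpm_rows$gene)
    } else numeric()
    rna <- if ("rna_subtype_label" %in% names(spec) &&
               !is.na(spec$rna_subtype_label) &&
               nzchar(spec$rna_subtype_label)) {
      as.character(spec$rna_subtype_label)
    } else character()
    evidenceBundle(
      specimen = spec,
      variants = .sub_rows(vdf, s),
      geneStatus = .sub_rows(as.data.frame(geneStatus), s),
      armEvents = .sub_rows(as.data.frame(armEvents), s),
      fusions = .sub_rows(fdf, s),
      exprFlags = .sub_rows(as.data.frame(exprFlags), s),
      exprTpm = tpm,
      methyl = .sub_rows(as.data.frame(methyl), s),
      tp53 = .sub_rows(as.data.frame(tp53), s),
      rnaSubtype = rna
    )
  })
  names(out) <- histologies$sample_id
  out
}

.RULESET_FUN <- list(
  hgg = subtypeHgg, atrt = subtypeAtrt, nbl = subtypeNbl,
  cranio = subtypeCranio, epn = subtypeEpn, lgg = subtypeLgg,
  mb = subtypeMb, pb = subtypePb, etmr = subtypeEtmr
)

#' Run molecular subtyping over a cohort
#'
#' Dispatches each tumor event to its histology rule set via the
#' pathology diagnosis (case-insensitive match against the config's
#' dispatch map), evaluates the rules and returns one row per event with
#' the assigned subtype and an auditable trace of fired rules. Events
#' whose diagnosis is outside the covered histologies get an `NA`
#' subtype. The review flag marks events a molecular pathologist should
#' look at: conflicting methylation/RNA labels, free-text conflicts, or a
#' high-confidence methylation call left unused by a fall-through label.
#'
#' @param bundles list of [EvidenceBundle-class] from
#'   [buildEvidenceBundles()].
#' @param rules config from [subtypeRules()].
#' @param thresholds see [defaultThresholds()].
#' @return `data.frame`: `tumor_event_id`, `sample_id`,
#'   `molecular_subtype`, `fired_rules` (semicolon-separated),
#'   `review_flag`.
#' @export
runSubtyping <- function(bundles, rules = subtypeRules(),
                         thresholds = defaultThresholds()) {
  rows <- lapply(bundles, function(b) {
    spec <- b@specimen
    diag <- tolower(as.character(spec$pathology_diagnosis[1]))
    set <- if (!is.na(diag) && diag %in% names(rules$dispatch)) {
      rules$dispatch[[diag]]
    } else NA_character_
    if (is.na(set)) {
      return(data.frame(
        tumor_event_id = as.character(spec$tumor_event_id[1]),
        sample_id = as.character(spec$sample_id[1]),
        molecular_subtype = NA_character_,
        fired_rules = "uncovered_histology",
        review_flag = FALSE, stringsAsFactors = FALSE
      ))
    }
    res <- .RULESET_FUN[[set]](b, rules, thresholds)
    review <- isTRUE(res$review)
    ## unused high-confidence methylation call + fall-through label
    if (!review && grepl("To be classified", res$label) &&
        length(.hc_subclasses(b, thresholds))) {
      review <- TRUE
    }
    data.frame(
      tumor_event_id = as.character(spec$tumor_event_id[1]),
      sample_id = as.character(spec$sample_id[1]),
      molecular_subtype = res$label,
      fired_rules = paste(res$fired, collapse = ";"),
      review_flag = review, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
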