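#' @include containers.R
NULL

#' Annotate putative oncogenic fusions
#'
#' A fusion is flagged putative oncogenic when either partner gene appears
#' in any supplied reference list (known kinases, oncogenes, tumor
#' suppressors, curated transcription factors, COSMIC Cancer Gene Census,
#' genes with fusions observed in TCGA). Existing `annotations` flags are
#' augmented with the matched list names.
#'
#' @param x a [FusionSet-class].
#' @param geneLists named list of character vectors; conventional names:
#'   `kinase`, `oncogene`, `tumor_suppressor`, `transcription_factor`,
#'   `cosmic_census`, `tcga_observed`. Each may be a file path (gene per
#'   line) or a character vector.
#' @return A [FusionSet-class] whose records gain a logical
#'   `putative_oncogenic` column and augmented `annotations`.
#' @export
annotateOncogenic <- function(x, geneLists) {
  lists <- lapply(geneLists, function(g) {
    if (length(g) == 1L && is.character(g) && file.exists(g)) {
      scan(g, what = character(), quiet = TRUE, comment.char = "#")
    } else as.character(g)
  })
  df <- records(x)
  if (!nrow(df)) {
    df$putative_oncogenic <- logical()
    return(fusionSet(df))
  }
  flags <- vapply(seq_len(nrow(df)), function(i) {
    hit <- names(lists)[vapply(lists, function(g) {
      df$gene5[i] %in% g || df$gene3[i] %in% g
    }, TRUE)]
    paste(hit, collapse = ",")
  }, character(1))
  prior <- ifelse(is.na(df$annotations), "", df$annotations)
  merged <- mapply(function(a, b) {
    paste(sort(unique(setdiff(c(strsplit(a, ",")[[1]],
                                strsplit(b, ",")[[1]]), ""))),
          collapse = ",")
  }, prior, flags, USE.NAMES = FALSE)
  df$annotations <- merged
  df$putative_oncogenic <- nzchar(flags) | nzchar(prior)
  fusionSet(df)
}

#' Retain prioritized fusions
#'
#' A fusion call is retained when any of the following holds for its
#' (sample, gene pair): called by both RNA callers (arriba and
#' starfusion); the gene pair is recurrent (seen in at least
#' `fusion_recurrence_min` samples of one cancer group); the gene pair is
#' specific to a single cancer group cohort-wide; or the call is annotated
#' putative oncogenic. DGD clinical panel calls bypass filtering and are
#' returned separately.
#'
#' @param x a [FusionSet-class], ideally after [annotateOncogenic()].
#' @param thresholds see [defaultThresholds()] (`fusion_recurrence_min`).
#' @return list with elements `retained` (a [FusionSet-class] whose
#'   records carry `retained_reason`) and `dgd` (pass-through panel
#'   calls).
#' @export
retainFusions <- function(x, thresholds = defaultThresholds()) {
  df <- records(x)
  if (!"putative_oncogenic" %in% names(df)) {
    df$putative_oncogenic <- FALSE
  }
  dgd <- df[df$caller == "dgd_panel", , drop = FALSE]
  df <- df[df$caller != "dgd_panel", , drop = FALSE]
  if (!nrow(df)) {
    df$retained_reason <- character()
    return(list(retained = fusionSet(df), dgd = fusionSet(dgd)))
  }
  pair <- paste(df$gene5, df$gene3, sep = "::")
  sample_pair <- paste(df$sample_id, pair, sep = "\r")

  ## both callers on the same sample + pair
  callers_by_sp <- tapply(df$caller, sample_pair,
                          function(x) length(unique(
                            intersect(x, c("arriba", "starfusion")))))
  both <- callers_by_sp[sample_pair] >= 2L

  ## recurrence: distinct samples per (pair, cancer_group)
  pg <- paste(pair, df$cancer_group, sep = "\r")
  uniq <- !duplicated(paste(pg, df$sample_id, sep = "\r"))
  n_by_pg <- tapply(uniq, pg, sum)
  recurrent <- n_by_pg[pg] >= thresholds$fusion_recurrence_min

  ## specificity: pair seen in exactly one cancer group cohort-wide
  groups_by_pair <- tapply(df$cancer_group, pair,
                           function(x) length(unique(x)))
  specific <- groups_by_pair[pair] == 1L

  reason <- mapply(function(b, r, s, o) {
    paste(c(if (b) "both_callers", if (r) "recurrent",
            if (s) "cancer_group_specific",
            if (o) "oncogenic_annotation"), collapse = ",")
  }, both, recurrent, specific, df$putative_oncogenic, USE.NAMES = FALSE)
  keep <- nzchar(reason)
  out <- df[keep, , drop = FALSE]
  out$retained_reason <- reason[keep]
  out <- out[order(out$sample_id, out$gene5, out$gene3, out$caller,
                   method = "radix"), , drop = FALSE]
  list(retained = fusionSet(out), dgd = fusionSet(dgd))
}
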