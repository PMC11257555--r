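#' @include containers.R
NULL

#' Load the subtyping rule configuration
#'
#' The declarative part of the rule engine — pathology-diagnosis dispatch
#' map, methylation-subclass matchers, output label strings, marker gene
#' groups and the loss-of-function classification set — ships as YAML so
#' label strings and class tokens can be corrected without code changes.
#'
#' @param path YAML file; default the packaged
#'   `extdata/subtype_rules.yaml`.
#' @return named list (the parsed config).
#' @export
subtypeRules <- function(path = system.file("extdata", "subtype_rules.yaml",
                                            package = "SomaticSubtyper",
                                            mustWork = TRUE)) {
  yaml::read_yaml(path)
}

#' Is a methylation prediction high-confidence?
#'
#' @param score classifier score(s) in [0, 1] (`NA` allowed).
#' @param thresholds see [defaultThresholds()] (`methyl_confidence`,
#'   default 0.80; the boundary counts as high-confidence).
#' @return logical vector; `NA` scores give `FALSE`.
#' @export
highConfidence <- function(score, thresholds = defaultThresholds()) {
  !is.na(score) & score >= thresholds$methyl_confidence
}

## ---- bundle predicates (internal) -----------------------------------

## high-confidence methylation subclasses of a bundle
.hc_subclasses <- function(bundle, th) {
  m <- bundle@methyl
  if (!nrow(m)) return(character())
  unique(m$subclass[highConfidence(m$score, th)])
}

.match_one <- function(subclasses, matcher) {
  if (matcher$type == "exact") {
    matcher$match %in% subclasses
  } else if (matcher$type == "prefix") {
    any(startsWith(subclasses, matcher$match))
  } else {
    any(grepl(matcher$match, subclasses, fixed = TRUE))
  }
}

## TRUE iff any high-confidence subclass matches the named rule's matchers
.methyl_hit <- function(bundle, rules, key, th) {
  matchers <- rules$methylation[[key]]
  if (is.null(matchers)) return(FALSE)
  sub <- .hc_subclasses(bundle, th)
  if (!length(sub)) return(FALSE)
  any(vapply(matchers, function(m) .match_one(sub, m), TRUE))
}

.has_variant <- function(bundle, genes, protein = NULL, classes = NULL,
                         hotspot = NA) {
  v <- bundle@variants
  if (!nrow(v)) return(FALSE)
  hit <- v$gene %in% genes
  if (!is.null(protein)) {
    hit <- hit & !is.na(v$protein_change) & v$protein_change %in% protein
  }
  if (!is.null(classes)) hit <- hit & v$variant_class %in% classes
  if (!is.na(hotspot)) hit <- hit & v$hotspot == hotspot
  any(hit)
}

.gene_status <- function(bundle, gene) {
  gs <- bundle@geneStatus
  if (!nrow(gs)) return(NA_character_)
  row <- gs[gs$gene == gene, , drop = FALSE]
  if (!nrow(row)) NA_character_ else row$status[1]
}

.has_arm <- function(bundle, arm, direction) {
  a <- bundle@armEvents
  nrow(a) > 0 && any(a$arm == arm & a$direction == direction)
}

.has_fusion_pair <- function(bundle, gene5, partners) {
  f <- bundle@fusions
  if (!nrow(f)) return(FALSE)
  any((f$gene5 == gene5 & f$gene3 %in% partners) |
        (f$gene3 == gene5 & f$gene5 %in% partners))
}

.has_fusion_partner <- function(bundle, genes) {
  f <- bundle@fusions
  nrow(f) > 0 && any(f$gene5 %in% genes | f$gene3 %in% genes)
}

.expr_over <- function(bundle, gene) {
  e <- bundle@exprFlags
  nrow(e) > 0 && any(e$gene == gene & e$over)
}

.expr_under <- function(bundle, gene) {
  e <- bundle@exprFlags
  nrow(e) > 0 && any(e$gene == gene & e$under)
}

.free_text <- function(bundle) {
  tolower(as.character(bundle@specimen$pathology_free_text_diagnosis[1]))
}

.free_text_contains <- function(bundle, patterns) {
  tx <- .free_text(bundle)
  if (is.na(tx)) return(FALSE)
  any(vapply(patterns, function(p) grepl(p, tx, fixed = TRUE), TRUE))
}

.site <- function(bundle) {
  s <- bundle@specimen
  if (!"anatomical_site" %in% names(s)) return(NA_character_)
  tolower(as.character(s$anatomical_site[1]))
}

.age <- function(bundle) {
  a <- bundle@specimen$age_at_diagnosis_years[1]
  if (is.null(a)) NA_real_ else as.numeric(a)
}

.germline_has <- function(bundle, flag) {
  g <- bundle@specimen$germline_flags[1]
  !is.null(g) && !is.na(g) && grepl(flag, g, fixed = TRUE)
}

.precomputed <- function(bundle) {
  s <- bundle@specimen
  if (!"precomputed_subtype" %in% names(s)) return(NA_character_)
  v <- as.character(s$precomputed_subtype[1])
  if (!is.na(v) && nzchar(v)) v else NA_character_
}
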