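#' @include AllClasses.R AllGenerics.R
NULL

.fill_cols <- function(df, cols, fills = list()) {
  for (cl in cols) {
    if (!cl %in% names(df)) {
      df[[cl]] <- if (cl %in% names(fills)) fills[[cl]] else NA
    }
  }
  df[, union(cols, names(df)), drop = FALSE]
}

#' Construct a VariantSet
#'
#' Missing optional columns (`gene`, `protein_change`, depths, `gnomad_af`)
#' are filled with `NA`; `hotspot` defaults to `FALSE`. Coordinates are
#' MAF-style 1-based inclusive.
#'
#' @param records `data.frame` of variant calls.
#' @return A [VariantSet-class].
#' @export
variantSet <- function(records = data.frame()) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df <- data.frame(
      sample_id = character(), chrom = character(), start = integer(),
      end = integer(), ref = character(), alt = character(),
      gene = character(), variant_class = character(),
      variant_type = character(), protein_change = character(),
      callers = character(), t_depth = integer(), alt_depth = integer(),
      n_depth = integer(), gnomad_af = numeric(), hotspot = logical(),
      stringsAsFactors = FALSE
    )
  } else {
    df <- .fill_cols(df, .VARIANT_COLS, fills = list(hotspot = FALSE))
    df$hotspot <- isTRUE_vec(df$hotspot)
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  rownames(df) <- NULL
  new("VariantSet", records = df)
}

## tolerant logical coercion (NA -> FALSE)
isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' Construct a SegmentSet
#'
#' When `status` is absent it is derived from `copy_number` against the
#' assumed ploidy: 0 is a deep deletion, below ploidy a loss, at ploidy
#' neutral, up to two copies above ploidy a gain, three or more above an
#' amplification. This copy-number-to-status map is a package convention
#' (the upstream callers' own status columns take precedence when present)
#' and the ploidy is configurable per call.
#'
#' @param records `data.frame` of segments (1-based inclusive coordinates).
#' @param ploidy assumed sample ploidy used when deriving `status` from
#'   `copy_number` (default 2).
#' @return A [SegmentSet-class].
#' @export
segmentSet <- function(records = data.frame(), ploidy = 2L) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df <- data.frame(
      sample_id = character(), chrom = character(), start = integer(),
      end = integer(), copy_number = integer(), status = character(),
      caller = character(), stringsAsFactors = FALSE
    )
  } else {
    if (!"status" %in% names(df) || all(is.na(df$status))) {
      df$status <- cnToStatus(df$copy_number, ploidy = ploidy)
    }
    df <- .fill_cols(df, .SEGMENT_COLS)
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    df$copy_number <- suppressWarnings(as.integer(df$copy_number))
  }
  rownames(df) <- NULL
  new("SegmentSet", records = df)
}

#' Copy-number to status map
#'
#' @param cn integer copy numbers (NA allowed).
#' @param ploidy assumed ploidy (default 2).
#' @return character vector of status tokens.
#' @export
cnToStatus <- function(cn, ploidy = 2L) {
  cn <- suppressWarnings(as.integer(cn))
  out <- rep(NA_character_, length(cn))
  out[!is.na(cn) & cn == 0L] <- "deep deletion"
  out[!is.na(cn) & cn > 0L & cn < ploidy] <- "loss"
  out[!is.na(cn) & cn == ploidy] <- "neutral"
  out[!is.na(cn) & cn > ploidy & cn < ploidy + 3L] <- "gain"
  out[!is.na(cn) & cn >= ploidy + 3L] <- "amplification"
  out
}

#' Construct a FusionSet
#'
#' @param records `data.frame` of fusion calls.
#' @return A [FusionSet-class].
#' @export
fusionSet <- function(records = data.frame()) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df <- data.frame(
      sample_id = character(), gene5 = character(), gene3 = character(),
      caller = character(), cancer_group = character(),
      annotations = character(), stringsAsFactors = FALSE
    )
  } else {
    df <- .fill_cols(df, .FUSION_COLS, fills = list(annotations = ""))
    df$annotations[is.na(df$annotations)] <- ""
  }
  rownames(df) <- NULL
  new("FusionSet", records = df)
}

#' Construct an EvidenceBundle
#'
#' @param specimen one-row `data.frame` of specimen metadata (mandatory).
#' @param variants,geneStatus,armEvents,fusions,exprFlags,methyl,tp53
#'   optional evidence-channel `data.frame`s (default empty).
#' @param exprTpm named numeric of raw TPM values (default empty).
#' @param rnaSubtype external MB transcriptomic label (default absent).
#' @return An [EvidenceBundle-class].
#' @export
evidenceBundle <- function(specimen,
                           variants = data.frame(),
                           geneStatus = data.frame(),
                           armEvents = data.frame(),
                           fusions = data.frame(),
                           exprFlags = data.frame(),
                           exprTpm = numeric(),
                           methyl = data.frame(),
                           tp53 = data.frame(),
                           rnaSubtype = character()) {
  new("EvidenceBundle",
      specimen = as.data.frame(specimen),
      variants = as.data.frame(variants),
      geneStatus = as.data.frame(geneStatus),
      armEvents = as.data.frame(armEvents),
      fusions = as.data.frame(fusions),
      exprFlags = as.data.frame(exprFlags),
      exprTpm = exprTpm,
      methyl = as.data.frame(methyl),
      tp53 = as.data.frame(tp53),
      rnaSubtype = as.character(rnaSubtype))
}

#' @rdname records
#' @export
setMethod("records", "VariantSet", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "SegmentSet", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "FusionSet", function(x) x@records)

#' @describeIn VariantSet-class number of variant records
#' @param x a `VariantSet`
#' @export
setMethod("length", "VariantSet", function(x) nrow(x@records))

#' @describeIn SegmentSet-class number of segments
#' @param x a `SegmentSet`
#' @export
setMethod("length", "SegmentSet", function(x) nrow(x@records))

#' @describeIn FusionSet-class number of fusion calls
#' @param x a `FusionSet`
#' @export
setMethod("length", "FusionSet", function(x) nrow(x@records))

setMethod("show", "VariantSet", function(object) {
  df <- object@records
  cat("VariantSet with", nrow(df), "calls across",
      length(unique(df$sample_id)), "sample(s)\n")
  if (nrow(df)) {
    tab <- sort(table(unlist(strsplit(df$callers, ","))), decreasing = TRUE)
    cat("  caller support:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "SegmentSet", function(object) {
  df <- object@records
  cat("SegmentSet with", nrow(df), "segments across",
      length(unique(df$sample_id)), "sample(s)\n")
  if (nrow(df)) {
    tab <- table(df$status)
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "FusionSet", function(object) {
  df <- object@records
  cat("FusionSet with", nrow(df), "calls across",
      length(unique(df$sample_id)), "sample(s)\n")
})

setMethod("show", "EvidenceBundle", function(object) {
  cat("EvidenceBundle for sample",
      as.character(object@specimen$sample_id[1]), "\n")
  cat("  channels:",
      paste(c(
        sprintf("variants[%d]", nrow(object@variants)),
        sprintf("geneStatus[%d]", nrow(object@geneStatus)),
        sprintf("armEvents[%d]", nrow(object@armEvents)),
        sprintf("fusions[%d]", nrow(object@fusions)),
        sprintf("exprFlags[%d]", nrow(object@exprFlags)),
        sprintf("methyl[%d]", nrow(object@methyl))
      ), collapse = " "), "\n")
})
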