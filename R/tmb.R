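#' @include containers.R intervals.R
NULL

#' Split multi-nucleotide variants into per-base SNVs
#'
#' Every DNP/TNP/ONP becomes one SNV per substituted base, inheriting the
#' record's sample, classification, depths and flags; calls made redundant
#' by the split (same sample and variant key) are removed. Used upstream
#' of TMB so each substituted base counts once.
#'
#' @param x a [VariantSet-class].
#' @return A [VariantSet-class] of SNVs and indels (no DNP/TNP/ONP rows).
#' @export
splitMnv <- function(x) {
  df <- records(x)
  if (!nrow(df)) return(x)
  is_mnv <- df$variant_type %in% c("DNP", "TNP", "ONP")
  keep <- df[!is_mnv, , drop = FALSE]
  mnv <- df[is_mnv, , drop = FALSE]
  if (nrow(mnv)) {
    len <- mnv$end - mnv$start + 1L
    bad <- nchar(mnv$ref) != len | nchar(mnv$alt) != len
    if (any(bad)) {
      stop(sprintf("MNV ref/alt length mismatch at %s:%d",
                   mnv$chrom[which(bad)[1]], mnv$start[which(bad)[1]]))
    }
    idx <- rep(seq_len(nrow(mnv)), len)
    off <- sequence(len) - 1L
    snv <- mnv[idx, , drop = FALSE]
    snv$start <- snv$start + off
    snv$end <- snv$start
    snv$ref <- substring(mnv$ref[idx], off + 1L, off + 1L)
    snv$alt <- substring(mnv$alt[idx], off + 1L, off + 1L)
    snv$variant_type <- "SNP"
    keep <- rbind(keep, snv)
  }
  keep <- keep[!duplicated(.variant_key(keep)), , drop = FALSE]
  keep <- keep[order(keep$sample_id, keep$chrom, keep$start, keep$end,
                     method = "radix"), , drop = FALSE]
  variantSet(keep)
}

#' Coding denominator for TMB
#'
#' Intersection, in bp, of the effectively surveyed region with the coding
#' sequence ranges.
#'
#' @param surveyed,cds [IntervalSet-class] objects.
#' @return Number of bp in the intersection.
#' @export
codingDenominator <- function(surveyed, cds) {
  totalBp(intersectSets(surveyed, cds))
}

#' Keep only nonsynonymous variants
#'
#' @param x a [VariantSet-class].
#' @param which classification set: `"default"` (high/moderate
#'   consequence) or `"focr"` (TMB-harmonization style, configurable); see
#'   [nonsynClassifications()].
#' @return Filtered [VariantSet-class].
#' @export
filterNonsynonymous <- function(x, which = c("default", "focr")) {
  classes <- nonsynClassifications(match.arg(which))
  df <- records(x)
  variantSet(df[df$variant_class %in% classes, , drop = FALSE])
}

.variants_in_set <- function(df, iset) {
  if (!nrow(df)) return(logical())
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end)
  )
  suppressWarnings(IRanges::overlapsAny(gr, as(iset, "GRanges")))
}

#' Tumor mutational burden
#'
#' For each sample: `tmb_all` counts every consensus mutation falling in
#' the surveyed region, divided by the surveyed size; `tmb_coding` counts
#' only nonsynonymous classifications falling in the coding denominator
#' region (surveyed intersected with CDS), divided by that region's size.
#' Both are reported in mutations per megabase alongside the raw
#' numerators and denominators. Apply [splitMnv()] first so MNVs count
#' per substituted base.
#'
#' For WGS the surveyed region is the intersection of the callers'
#' effectively surveyed BEDs; for WXS it is the capture BED (and the
#' coding denominator its intersection with the CDS).
#'
#' @param x a [VariantSet-class] of consensus calls (post [splitMnv()]).
#' @param strategy `"WGS"` or `"WXS"` (recorded on the result).
#' @param surveyed [IntervalSet-class]: the all-mutation denominator
#'   region.
#' @param cds [IntervalSet-class] of coding sequence ranges.
#' @param nonsynFilter classification set for the coding numerator
#'   (default [nonsynClassifications()]`("default")`).
#' @param samples sample ids to report; default those present in `x`.
#' @return `data.frame`: `sample_id`, `strategy`, `numerator_all`,
#'   `denominator_all`, `tmb_all`, `numerator_coding`,
#'   `denominator_coding`, `tmb_coding`.
#' @export
computeTmb <- function(x, strategy = c("WGS", "WXS"), surveyed, cds,
                       nonsynFilter = nonsynClassifications("default"),
                       samples = NULL) {
  strategy <- match.arg(strategy)
  df <- records(x)
  if (is.null(samples)) samples <- sort(unique(df$sample_id))
  denom_all <- totalBp(surveyed)
  coding_set <- intersectSets(surveyed, cds)
  denom_coding <- totalBp(coding_set)
  if (denom_all <= 0) stop("empty surveyed region (zero denominator)")
  if (denom_coding <= 0) stop("surveyed and CDS regions do not intersect ",
                              "(zero coding denominator)")
  in_all <- .variants_in_set(df, surveyed)
  in_coding <- .variants_in_set(df, coding_set) &
    df$variant_class %in% nonsynFilter
  n_all <- vapply(samples, function(s) sum(in_all & df$sample_id == s), 0)
  n_cod <- vapply(samples, function(s) sum(in_coding & df$sample_id == s), 0)
  data.frame(
    sample_id = samples,
    strategy = strategy,
    numerator_all = as.integer(n_all),
    denominator_all = denom_all,
    tmb_all = n_all / (denom_all / 1e6),
    numerator_coding = as.integer(n_cod),
    denominator_coding = denom_coding,
    tmb_coding = n_cod / (denom_coding / 1e6),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
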