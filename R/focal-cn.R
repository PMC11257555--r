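#' @include consensus-cnv.R
NULL

.status_rank <- c("amplification" = 1L, "deep deletion" = 2L,
                  "gain" = 3L, "loss" = 4L, "neutral" = 5L)

#' Read a gene-model BED (gene -> interval)
#'
#' BED4: chrom, start, end (0-based half-open), gene symbol. One interval
#' per gene expected.
#'
#' @param path BED file.
#' @return `data.frame` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
readGeneBed <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE, showProgress = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  data.frame(gene = as.character(df$gene),
             chrom = .norm_chrom(df$chrom),
             start = as.integer(df$start) + 1L,
             end = as.integer(df$end),
             stringsAsFactors = FALSE)
}

#' Assign per-gene focal copy-number calls (pre-resolution)
#'
#' Every (gene, overlapping consensus region) pair yields one status call
#' annotated with the overlap in bp and the segment coordinates. Genes a
#' sample has no overlapping region for get a `neutral` call (absence of a
#' consensus region is absence of evidence for change).
#'
#' @param regions consensus-region `data.frame` (WXS rows included).
#' @param geneModel `data.frame` from [readGeneBed()].
#' @param samples sample ids to emit calls for; default all samples in
#'   `regions`.
#' @return `data.frame`: `sample_id`, `gene`, `status`, `copy_number`,
#'   `overlap_bp`, `seg_start`, `seg_end`. Possibly several rows per
#'   (sample, gene); resolve with [resolveDuplicateStatus()].
#' @export
assignGeneStatus <- function(regions, geneModel,
                             samples = unique(regions$sample_id)) {
  base <- data.frame(
    sample_id = rep(samples, each = nrow(geneModel)),
    gene = rep(geneModel$gene, times = length(samples)),
    status = "neutral", copy_number = NA_integer_,
    overlap_bp = 0, seg_start = NA_integer_, seg_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!nrow(regions) || !length(samples)) return(base)

  gg <- GenomicRanges::GRanges(
    seqnames = geneModel$chrom,
    ranges = IRanges::IRanges(geneModel$start, geneModel$end)
  )
  rg <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(regions$start, regions$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gg, rg))
  if (length(hits)) {
    g <- S4Vectors::queryHits(hits)
    r <- S4Vectors::subjectHits(hits)
    ov <- pmin(geneModel$end[g], regions$end[r]) -
      pmax(geneModel$start[g], regions$start[r]) + 1
    calls <- data.frame(
      sample_id = regions$sample_id[r],
      gene = geneModel$gene[g],
      status = regions$status[r],
      copy_number = regions$copy_number[r],
      overlap_bp = ov,
      seg_start = regions$start[r],
      seg_end = regions$end[r],
      stringsAsFactors = FALSE
    )
    calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
    covered <- paste(calls$sample_id, calls$gene)
    base <- base[!paste(base$sample_id, base$gene) %in% covered, ,
                 drop = FALSE]
    base <- rbind(calls, base)
  }
  base <- base[order(base$sample_id, base$gene, method = "radix"), ,
               drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Resolve duplicated gene-level status calls
#'
#' Selects exactly one status per (sample, gene) by, in order:
#' (1) non-neutral calls beat neutral; (2) the call from the dominant
#' segment — largest overlap with the gene in bp — wins; (3) amplification
#' beats gain and deep deletion beats loss; residual ties break
#' deterministically on (status rank, segment start).
#'
#' @param calls `data.frame` from [assignGeneStatus()].
#' @return `data.frame` with exactly one row per (sample, gene).
#' @export
resolveDuplicateStatus <- function(calls) {
  if (!nrow(calls)) return(calls)
  rank <- .status_rank[calls$status]
  ord <- order(calls$sample_id, calls$gene,
               calls$status == "neutral",      # non-neutral first
               -calls$overlap_bp,              # dominant segment
               rank,                           # extreme over mild
               calls$seg_start,                # final deterministic key
               method = "radix")
  out <- calls[ord, , drop = FALSE]
  out <- out[!duplicated(paste(out$sample_id, out$gene, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
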