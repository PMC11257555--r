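#' @include consensus-cnv.R
NULL

#' Read a cytoband-style arm coordinate table
#'
#' TSV with columns `chrom`, `arm` (`p`/`q`), `start`, `end` (0-based
#' half-open, as in UCSC cytoband files collapsed to arms).
#'
#' @param path TSV file.
#' @return `data.frame` with `chrom`, `arm`, `start`, `end` (1-based
#'   inclusive).
#' @export
readArmTable <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  data.frame(chrom = .norm_chrom(df$chrom), arm = as.character(df$arm),
             start = as.integer(df$start) + 1L, end = as.integer(df$end),
             stringsAsFactors = FALSE)
}

#' Call chromosome-arm gain/loss events
#'
#' An arm is flagged gained (lost) for a sample when the same-direction
#' consensus regions cover at least `arm_fraction` (default 0.5) of the
#' arm's length. Coverage is computed on the merged footprint, so
#' overlapping regions do not double count. Regions on chromosomes absent
#' from the arm table are ignored with a warning.
#'
#' @param regions consensus-region `data.frame`.
#' @param arms `data.frame` from [readArmTable()].
#' @param thresholds see [defaultThresholds()].
#' @return `data.frame`: `sample_id`, `arm` (e.g. `"9p"`), `direction`,
#'   `fraction`.
#' @export
callArmEvents <- function(regions, arms, thresholds = defaultThresholds()) {
  empty <- data.frame(sample_id = character(), arm = character(),
                      direction = character(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions)) return(empty)
  df <- regions[!is.na(regions$direction), , drop = FALSE]
  unknown <- setdiff(unique(df$chrom), unique(arms$chrom))
  if (length(unknown)) {
    warning("regions on chromosome(s) absent from arm table ignored: ",
            paste(unknown, collapse = ", "))
    df <- df[!df$chrom %in% unknown, , drop = FALSE]
  }
  if (!nrow(df)) return(empty)

  ## merge same-direction footprints per sample in one reduce() by keying
  ## the seqnames on (sample | direction | chrom), then overlap the merged
  ## pieces against arms with plain interval arithmetic
  red <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = paste(df$sample_id, df$direction, df$chrom, sep = "|"),
    ranges = IRanges::IRanges(df$start, df$end)
  ))
  key <- strsplit(as.character(GenomeInfoDb::seqnames(red)), "|",
                  fixed = TRUE)
  piece <- data.frame(
    sample_id = vapply(key, `[`, "", 1L),
    direction = vapply(key, `[`, "", 2L),
    chrom = vapply(key, `[`, "", 3L),
    start = GenomicRanges::start(red), end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  hit <- merge(piece, arms, by = "chrom", suffixes = c("", ".arm"))
  hit$ov <- pmax(0, pmin(hit$end, hit$end.arm) -
                   pmax(hit$start, hit$start.arm) + 1)
  hit$arm_len <- hit$end.arm - hit$start.arm + 1
  hit$arm_name <- paste0(sub("^chr", "", hit$chrom), hit$arm)
  grp <- paste(hit$sample_id, hit$arm_name, hit$direction, sep = "\r")
  grpf <- factor(grp, levels = unique(grp))
  cov <- tapply(hit$ov, grpf, sum)
  first <- hit[!duplicated(grp), , drop = FALSE]
  frac <- as.numeric(cov) / first$arm_len
  keep <- frac >= thresholds$arm_fraction
  if (!any(keep)) return(empty)
  res <- data.frame(sample_id = first$sample_id[keep],
                    arm = first$arm_name[keep],
                    direction = first$direction[keep],
                    fraction = frac[keep], stringsAsFactors = FALSE)
  res <- res[order(res$sample_id, res$arm, res$direction,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
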