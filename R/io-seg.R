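#' @include containers.R
NULL

#' Read a SEG-like copy-number segment table
#'
#' Tab-delimited with columns `sample_id` (or `ID`), `chrom`, `start`,
#' `end` in 0-based half-open (BED-style) coordinates, and `copy_number`
#' and/or `status`. When only `copy_number` is present the status is
#' derived with [cnToStatus()] against the assumed ploidy. Internally
#' segments are stored 1-based inclusive.
#'
#' @param path SEG file.
#' @param caller caller label (`controlfreec`, `cnvkit`, `gatk`,
#'   `mantasv`).
#' @param ploidy assumed ploidy for status derivation (default 2).
#' @return A [SegmentSet-class].
#' @export
readSeg <- function(path, caller, ploidy = 2L) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA", "."),
                          data.table = FALSE, showProgress = FALSE)
  names(df)[names(df) == "ID"] <- "sample_id"
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("SEG missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!any(c("copy_number", "status") %in% names(df))) {
    stop("SEG needs a copy_number and/or status column")
  }
  if (nrow(df)) {
    bad <- which(df$end <= df$start)
    if (length(bad)) {
      stop(sprintf("segment end <= start at row %d", bad[1]))
    }
    if ("status" %in% names(df)) {
      tok <- df$status[!is.na(df$status)]
      unknown <- setdiff(unique(tok), .CNV_STATUSES)
      if (length(unknown)) {
        stop("unknown status token(s): ", paste(unknown, collapse = ", "))
      }
    }
    df$chrom <- .norm_chrom(df$chrom)
    df$start <- as.integer(df$start) + 1L  # to 1-based inclusive
    df$end <- as.integer(df$end)
  }
  df$caller <- rep(caller, nrow(df))
  if (!"sample_id" %in% names(df)) df$sample_id <- character(nrow(df))
  segmentSet(df, ploidy = ploidy)
}

#' Write a SegmentSet (or consensus region table) as SEG-like TSV
#'
#' Coordinates are written back in 0-based half-open convention.
#'
#' @param x a [SegmentSet-class] or a `data.frame` with 1-based inclusive
#'   `start`/`end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSeg <- function(x, path) {
  df <- if (is(x, "SegmentSet")) records(x) else as.data.frame(x)
  if (nrow(df)) {
    df$start <- df$start - 1L
  }
  ord <- if (nrow(df)) {
    order(df$sample_id, df$chrom, df$start, df$end, method = "radix")
  } else integer()
  data.table::fwrite(df[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a simple TSV with fread defaults used across the package
#' @param path file
#' @return data.frame
#' @export
readTsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE,
                    na.strings = c("", "NA"),
                    data.table = FALSE, showProgress = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame
#' @param path file
#' @return `path`, invisibly
#' @export
writeTsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
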