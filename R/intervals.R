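#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomicRanges GRanges reduce sort intersect granges
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Build an IntervalSet from ranges
#'
#' Sorts and merges (reduces) the input so that overlapping or abutting
#' ranges collapse into single intervals per chromosome.
#'
#' @param x a `GRanges`, or a `data.frame` with columns `chrom`, `start`,
#'   `end` in 0-based half-open (BED) coordinates.
#' @return An [IntervalSet-class].
#' @export
intervalSet <- function(x = GenomicRanges::GRanges()) {
  if (is.data.frame(x)) {
    if (nrow(x) && any(x$start < 0)) stop("negative interval coordinates")
    x <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
    )
  }
  gr <- GenomicRanges::reduce(GenomicRanges::sort(GenomicRanges::granges(x)))
  new("IntervalSet", gr)
}

#' @rdname totalBp
#' @export
setMethod("totalBp", "GRanges", function(x) {
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(x))))
})

#' @rdname totalBp
#' @export
setMethod("totalBp", "IntervalSet", function(x) {
  sum(as.numeric(IRanges::width(x)))
})

setMethod("show", "IntervalSet", function(object) {
  cat("IntervalSet:", length(object), "intervals on",
      length(unique(as.character(GenomeInfoDb::seqnames(object)))),
      "chromosome(s),", format(totalBp(object), big.mark = ","), "bp\n")
})

#' Read a BED file into an IntervalSet
#'
#' BED is 0-based half-open; the result is merged and sorted, with abutting
#' records collapsed.
#'
#' @param path BED3+ file.
#' @return An [IntervalSet-class].
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  intervalSet(gr)
}

#' Write an IntervalSet as BED3
#'
#' @param x an [IntervalSet-class] (or `GRanges`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reciprocal overlap of two intervals
#'
#' Fraction of each interval covered by the other. Intervals on different
#' chromosomes have reciprocal overlap (0, 0). Symmetric under swapping
#' (the pair reverses) and invariant under translation.
#'
#' @param a,b single-range `GRanges` (1-based inclusive), or `data.frame`s
#'   with `chrom`, `start`, `end` in 0-based half-open coordinates.
#' @return numeric length-2 vector `c(overlap/|a|, overlap/|b|)`.
#' @export
reciprocalOverlap <- function(a, b) {
  a <- .as_single_range(a)
  b <- .as_single_range(b)
  if (a$chrom != b$chrom) return(c(0, 0))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
  c(ov / (a$end - a$start + 1), ov / (b$end - b$start + 1))
}

.as_single_range <- function(x) {
  if (is(x, "GRanges")) {
    stopifnot(length(x) == 1L)
    list(chrom = as.character(GenomeInfoDb::seqnames(x)),
         start = GenomicRanges::start(x), end = GenomicRanges::end(x))
  } else if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(chrom = x$chrom, start = x$start + 1, end = x$end)
  } else {
    ## plain list with 1-based inclusive start/end
    x
  }
}

#' Intersect two interval sets
#'
#' @param a,b [IntervalSet-class] objects.
#' @return An [IntervalSet-class]: regions present in both.
#' @export
intersectSets <- function(a, b) {
  gr <- suppressWarnings(GenomicRanges::intersect(
    GenomicRanges::granges(as(a, "GRanges")),
    GenomicRanges::granges(as(b, "GRanges"))
  ))
  intervalSet(gr)
}
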