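#' @include AllClasses.R
NULL

#' Total bases covered by an interval set
#'
#' @param x An [IntervalSet-class] (or `GRanges`).
#' @return Integer scalar: the number of distinct base pairs covered.
#' @export
setGeneric("totalBp", function(x) standardGeneric("totalBp"))

#' Extract the record table from a set object
#'
#' All tabular containers in the package (variants, copy-number segments,
#' fusion calls) store their rows in a single `data.frame` slot; `records()`
#' is the accessor.
#'
#' @param x A `VariantSet`, `SegmentSet` or `FusionSet`.
#' @return A `data.frame`, one row per record.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
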