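#' @include containers.R
NULL

.MAF_REQUIRED <- c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
  "Variant_Type", "t_depth", "t_alt_count", "n_depth"
)

## normalize chromosome names to the chr-prefixed GRCh38 convention;
## refuse files mixing prefixed and unprefixed naming
.norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  has <- startsWith(chrom, "chr")
  if (any(has) && any(!has)) {
    stop("mixed chromosome naming (chr-prefixed and bare) in one file")
  }
  ifelse(has, chrom, paste0("chr", chrom))
}

.parse_depth <- function(x, col, rows) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & x != "" & x != "." & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row %d: '%s'",
                 col, rows[bad[1]], x[bad[1]]))
  }
  out
}

#' Read a MAF-dialect variant table
#'
#' Reads a tab-delimited MAF ('#' comment lines skipped) into a
#' [VariantSet-class], stamping every record with `caller` provenance.
#' Coordinates stay 1-based inclusive (MAF native). Optional columns
#' consumed when present: `Tumor_Sample_Barcode`, `HGVSp_Short`, a gnomAD
#' allele-frequency column (`gnomad_af_col`) and a hotspot flag column
#' (`hotspot_col`, truthy values `TRUE`/`1`/`Yes`/`Y`).
#'
#' @param path MAF file.
#' @param caller caller label recorded on every row (one of `strelka2`,
#'   `mutect2`, `lancet`, `vardict`, or any label for pre-merged files).
#' @param gnomad_af_col,hotspot_col column names holding population AF and
#'   the hotspot flag.
#' @return A [VariantSet-class].
#' @export
readMaf <- function(path, caller,
                    gnomad_af_col = "gnomad_3_1_1_AF",
                    hotspot_col = "HotSpotAllele") {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA", "."),
                          colClasses = list(character = "Chromosome"),
                          data.table = FALSE, showProgress = FALSE)
  miss <- setdiff(.MAF_REQUIRED, names(df))
  if (length(miss)) {
    stop("MAF missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(df)
  rows <- seq_len(n)
  out <- data.frame(
    sample_id = if ("Tumor_Sample_Barcode" %in% names(df)) {
      as.character(df$Tumor_Sample_Barcode)
    } else rep(NA_character_, n),
    chrom = if (n) .norm_chrom(df$Chromosome) else character(),
    start = as.integer(df$Start_Position),
    end = as.integer(df$End_Position),
    ref = as.character(df$Reference_Allele),
    alt = as.character(df$Tumor_Seq_Allele2),
    gene = as.character(df$Hugo_Symbol),
    variant_class = as.character(df$Variant_Classification),
    variant_type = as.character(df$Variant_Type),
    protein_change = if ("HGVSp_Short" %in% names(df)) {
      as.character(df$HGVSp_Short)
    } else rep(NA_character_, n),
    callers = rep(caller, n),
    t_depth = .parse_depth(df$t_depth, "t_depth", rows),
    alt_depth = .parse_depth(df$t_alt_count, "t_alt_count", rows),
    n_depth = .parse_depth(df$n_depth, "n_depth", rows),
    gnomad_af = if (gnomad_af_col %in% names(df)) {
      as.numeric(df[[gnomad_af_col]])
    } else rep(NA_real_, n),
    hotspot = if (hotspot_col %in% names(df)) {
      tolower(as.character(df[[hotspot_col]])) %in% c("true", "1", "yes", "y")
    } else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  variantSet(out)
}

#' Write a VariantSet as a MAF-dialect TSV
#'
#' Emits the consumed MAF columns plus provenance columns (`callers` and,
#' when present, `consensus_reason`). Rows are written in canonical order
#' (sample, chrom, start, end, ref, alt) so that write/read round-trips are
#' byte-comparable.
#'
#' @param x a [VariantSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(x, path) {
  df <- records(x)
  out <- data.frame(
    Hugo_Symbol = df$gene,
    Chromosome = df$chrom,
    Start_Position = df$start,
    End_Position = df$end,
    Reference_Allele = df$ref,
    Tumor_Seq_Allele2 = df$alt,
    Variant_Classification = df$variant_class,
    Variant_Type = df$variant_type,
    HGVSp_Short = df$protein_change,
    Tumor_Sample_Barcode = df$sample_id,
    t_depth = df$t_depth,
    t_alt_count = df$alt_depth,
    n_depth = df$n_depth,
    gnomad_3_1_1_AF = df$gnomad_af,
    HotSpotAllele = ifelse(df$hotspot, "Yes", "No"),
    callers = df$callers,
    stringsAsFactors = FALSE
  )
  if ("consensus_reason" %in% names(df)) {
    out$consensus_reason <- df$consensus_reason
  }
  ord <- order(out$Tumor_Sample_Barcode, out$Chromosome,
               out$Start_Position, out$End_Position,
               out$Reference_Allele, out$Tumor_Seq_Allele2,
               method = "radix")
  data.table::fwrite(out[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}
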