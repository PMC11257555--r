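#' @include containers.R
NULL

.variant_key <- function(df) {
  paste(df$sample_id, df$chrom, df$start, df$end, df$ref, df$alt, sep = "\r")
}

.caller_priority <- c(strelka2 = 1L, mutect2 = 2L, lancet = 3L, vardict = 4L)

#' Reconstruct Strelka2 multi-nucleotide variants
#'
#' Strelka2 reports multi-nucleotide substitutions as runs of consecutive
#' SNPs. For every DNP/TNP/ONP reported by another caller whose every
#' constituent position/ref/alt base is matched by a Strelka2 SNP in the
#' same sample, those SNPs are replaced by a single Strelka2 MNP record
#' with the candidate's span and alleles, so that the merged call keeps
#' the predicted protein consequence intact. Unmatched SNPs pass through
#' unchanged. When overlapping candidates claim the same SNP, the longest
#' candidate wins, ties broken leftmost.
#'
#' @param strelka a [VariantSet-class] of Strelka2 calls for one or more
#'   samples.
#' @param otherMnps a [VariantSet-class] holding DNP/TNP/ONP calls from the
#'   other callers.
#' @return A [VariantSet-class] of Strelka2 calls with MNPs reconstructed;
#'   an `mnp_members` column lists the constituent SNP keys of each
#'   emitted MNP (semicolon-separated), `NA` elsewhere.
#' @export
reconstructMnp <- function(strelka, otherMnps) {
  sdf <- records(strelka)
  mdf <- records(otherMnps)
  if (!nrow(sdf)) return(strelka)
  sdf$mnp_members <- NA_character_
  mdf <- mdf[mdf$variant_type %in% c("DNP", "TNP", "ONP"), , drop = FALSE]
  if (!nrow(mdf)) return(variantSet(sdf))

  ## unique candidates, longest first then leftmost
  mdf <- mdf[!duplicated(.variant_key(mdf)), , drop = FALSE]
  mdf <- mdf[order(-(mdf$end - mdf$start), mdf$sample_id, mdf$chrom,
                   mdf$start, method = "radix"), , drop = FALSE]

  is_snp <- sdf$variant_type == "SNP"
  snp_pos_key <- ifelse(is_snp,
                        paste(sdf$sample_id, sdf$chrom, sdf$start,
                              sdf$ref, sdf$alt, sep = "\r"),
                        NA_character_)
  claimed <- rep(FALSE, nrow(sdf))
  emitted <- list()

  for (i in seq_len(nrow(mdf))) {
    cand <- mdf[i, ]
    len <- cand$end - cand$start + 1L
    if (is.na(cand$ref) || is.na(cand$alt) ||
        nchar(cand$ref) != len || nchar(cand$alt) != len) next
    want <- paste(cand$sample_id, cand$chrom, cand$start + seq_len(len) - 1L,
                  substring(cand$ref, seq_len(len), seq_len(len)),
                  substring(cand$alt, seq_len(len), seq_len(len)),
                  sep = "\r")
    idx <- match(want, ifelse(claimed, NA_character_, snp_pos_key))
    if (anyNA(idx)) next
    claimed[idx] <- TRUE
    donor <- sdf[idx[1], ]
    mnp <- donor
    mnp$start <- cand$start
    mnp$end <- cand$end
    mnp$ref <- cand$ref
    mnp$alt <- cand$alt
    mnp$variant_type <- cand$variant_type
    mnp$variant_class <- cand$variant_class
    mnp$protein_change <- cand$protein_change
    mnp$hotspot <- any(sdf$hotspot[idx])
    mnp$callers <- "strelka2"
    mnp$mnp_members <- paste(
      gsub("\r", ":", snp_pos_key[idx], fixed = TRUE), collapse = ";")
    emitted[[length(emitted) + 1L]] <- mnp
  }

  out <- sdf[!claimed, , drop = FALSE]
  if (length(emitted)) out <- rbind(out, do.call(rbind, emitted))
  out <- out[order(out$sample_id, out$chrom, out$start, out$end,
                   method = "radix"), , drop = FALSE]
  variantSet(out)
}

#' Call consensus across variant callers
#'
#' A variant keyed by (sample, chrom, start, end, ref, alt) is retained if
#' it was detected by at least `min_callers` callers, or if it carries the
#' hotspot flag in at least one caller (hotspot rescue). The output record
#' takes depths and annotations from the highest-priority supporting
#' caller (strelka2 > mutect2 > lancet > vardict); `callers` is the union
#' of supporting callers and `consensus_reason` is `multi_caller` or
#' `hotspot_rescue`.
#'
#' @param perCaller named list of [VariantSet-class], names are caller
#'   labels. Strelka2 input is expected to have MNP reconstruction already
#'   applied ([reconstructMnp()]).
#' @param thresholds see [defaultThresholds()].
#' @return A [VariantSet-class] with `consensus_reason` column.
#' @export
callConsensus <- function(perCaller, thresholds = defaultThresholds()) {
  dfs <- lapply(names(perCaller), function(cl) {
    df <- records(perCaller[[cl]])
    if (nrow(df)) df$callers <- cl
    df
  })
  dfs <- dfs[vapply(dfs, nrow, 0L) > 0]
  if (!length(dfs)) {
    out <- records(variantSet())
    out$consensus_reason <- character()
    return(variantSet(out))
  }
  cols <- Reduce(intersect, lapply(dfs, names))
  all <- do.call(rbind, lapply(dfs, function(d) d[, cols, drop = FALSE]))
  key <- .variant_key(all)
  prio <- .caller_priority[all$callers]
  prio[is.na(prio)] <- 99L

  ord <- order(key, prio, method = "radix")
  all <- all[ord, , drop = FALSE]
  key <- key[ord]
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  grpf <- factor(grp, levels = seq_len(max(grp)))

  n_callers <- as.integer(tapply(all$callers, grpf,
                                 function(x) length(unique(x))))
  any_hot <- as.logical(tapply(all$hotspot, grpf, any))
  callers_union <- tapply(all$callers, grpf, function(x) {
    paste(sort(unique(x)), collapse = ",")
  })

  out <- all[first, , drop = FALSE]
  out$callers <- as.character(callers_union)
  out$hotspot <- any_hot
  keep <- n_callers >= thresholds$min_callers | any_hot
  out$consensus_reason <- ifelse(n_callers >= thresholds$min_callers,
                                 "multi_caller", "hotspot_rescue")
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$start, out$end, out$ref,
                   out$alt, method = "radix"), , drop = FALSE]
  variantSet(out)
}

#' Remove likely germline leakage from consensus calls
#'
#' A call is removed iff it is not a hotspot, its matched-normal depth is
#' at most `normal_depth_max` (default 7 reads) and its gnomAD allele
#' frequency exceeds `gnomad_af_min` (default 0.001). Records missing
#' either value are never removed (tumor-only samples carry no normal
#' depth, so the filter does not apply to them).
#'
#' @param x a [VariantSet-class].
#' @param thresholds see [defaultThresholds()].
#' @return Filtered [VariantSet-class].
#' @export
filterGermlineLeakage <- function(x, thresholds = defaultThresholds()) {
  df <- records(x)
  if (!nrow(df)) return(x)
  drop <- !df$hotspot &
    !is.na(df$n_depth) & df$n_depth <= thresholds$normal_depth_max &
    !is.na(df$gnomad_af) & df$gnomad_af > thresholds$gnomad_af_min
  variantSet(df[!drop, , drop = FALSE])
}

#' Depth filter for tumor-only calls
#'
#' Removes records with zero alt-allele reads or tumor depth below
#' `tumor_only_min_t_depth` (default 4 reads). Records with absent depths
#' are retained.
#'
#' @param x a [VariantSet-class] of tumor-only calls.
#' @param thresholds see [defaultThresholds()].
#' @return Filtered [VariantSet-class].
#' @export
filterTumorOnly <- function(x, thresholds = defaultThresholds()) {
  df <- records(x)
  if (!nrow(df)) return(x)
  drop <- (!is.na(df$alt_depth) & df$alt_depth == 0L) |
    (!is.na(df$t_depth) & df$t_depth < thresholds$tumor_only_min_t_depth)
  variantSet(df[!drop, , drop = FALSE])
}
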