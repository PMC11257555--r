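#' @include containers.R intervals.R
NULL

.cnv_caller_priority <- c(controlfreec = 1L, cnvkit = 2L, gatk = 3L,
                          mantasv = 4L)

.status_direction <- function(status) {
  out <- rep(NA_character_, length(status))
  out[status %in% c("gain", "amplification")] <- "gain"
  out[status %in% c("loss", "deep deletion")] <- "loss"
  out
}

.bind_caller_segments <- function(perCaller) {
  if (is(perCaller, "SegmentSet")) return(records(perCaller))
  dfs <- lapply(perCaller, function(x) {
    if (is(x, "SegmentSet")) records(x) else as.data.frame(x)
  })
  dfs <- dfs[vapply(dfs, nrow, 0L) > 0]
  if (!length(dfs)) return(records(segmentSet()))
  do.call(rbind, dfs)
}

#' Drop noisy per-sample caller files
#'
#' Any (sample, caller) group with more than `max_cnv_per_file` (default
#' 2,500) non-neutral segments is dropped entirely, mirroring the
#' GISTIC-style de-noising cutoff. Groups at exactly the cap are kept.
#'
#' @param segments a [SegmentSet-class] (or list of them, one per caller).
#' @param thresholds see [defaultThresholds()].
#' @return A [SegmentSet-class] with noisy groups removed; dropped groups
#'   are reported via `message()`.
#' @export
denoiseCallerFiles <- function(segments, thresholds = defaultThresholds()) {
  df <- .bind_caller_segments(segments)
  if (!nrow(df)) return(segmentSet(df))
  grp <- paste(df$sample_id, df$caller, sep = "\r")
  nn <- tapply(df$status != "neutral", factor(grp, levels = unique(grp)), sum)
  bad <- names(nn)[nn > thresholds$max_cnv_per_file]
  if (length(bad)) {
    message("de-noising dropped ", length(bad), " (sample, caller) file(s): ",
            paste(gsub("\r", "/", bad, fixed = TRUE), collapse = ", "))
    df <- df[!grp %in% bad, , drop = FALSE]
  }
  segmentSet(df)
}

## segments -> GRanges keyed on (sample | direction | chrom) so overlap
## queries stay per-sample and same-direction by construction
.seg_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = paste(df$sample_id, df$direction, df$chrom, sep = "|"),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Multi-caller CNV consensus (overlap + containment rules)
#'
#' Per sample and direction (gain/amplification vs loss/deep deletion),
#' compares each caller pair's segments and emits: (rule 1) the
#' intersection interval of every pair with reciprocal overlap of at least
#' `recip_overlap` (default 50%) in both directions, and (rule 2) any
#' smaller segment more than `containment` (default 90%) covered by
#' another caller's same-direction segment. Identical emitted regions are
#' collapsed with supporter union. The output copy number comes from the
#' highest-priority supporting caller (controlfreec > cnvkit > gatk >
#' mantasv); amplification / deep deletion is preserved on the region when
#' any supporter carried it.
#'
#' @param segments a [SegmentSet-class] (non-neutral rows are used), or a
#'   list of per-caller `SegmentSet`s.
#' @param thresholds see [defaultThresholds()].
#' @return `data.frame` of consensus regions: `sample_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `direction`, `status`,
#'   `copy_number`, `supporting_callers`, `n_callers`, `in_consensus`.
#' @export
pairwiseConsensus <- function(segments, thresholds = defaultThresholds()) {
  df <- .bind_caller_segments(segments)
  empty <- data.frame(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), direction = character(), status = character(),
    copy_number = integer(), supporting_callers = character(),
    n_callers = integer(), in_consensus = logical(),
    stringsAsFactors = FALSE
  )
  if (!nrow(df)) return(empty)
  df$direction <- .status_direction(df$status)
  df <- df[!is.na(df$direction), , drop = FALSE]
  if (!nrow(df)) return(empty)

  callers <- sort(unique(df$caller))
  pieces <- list()
  for (i in seq_along(callers)) {
    for (j in seq_along(callers)) {
      if (j <= i) next
      a <- df[df$caller == callers[i], , drop = FALSE]
      b <- df[df$caller == callers[j], , drop = FALSE]
      if (!nrow(a) || !nrow(b)) next
      gra <- .seg_granges(a)
      grb <- .seg_granges(b)
      hits <- suppressWarnings(GenomicRanges::findOverlaps(gra, grb))
      if (!length(hits)) next
      qa <- a[S4Vectors::queryHits(hits), , drop = FALSE]
      qb <- b[S4Vectors::subjectHits(hits), , drop = FALSE]
      ov <- pmin(qa$end, qb$end) - pmax(qa$start, qb$start) + 1L
      wa <- qa$end - qa$start + 1L
      wb <- qb$end - qb$start + 1L
      rule1 <- ov / wa >= thresholds$recip_overlap &
        ov / wb >= thresholds$recip_overlap
      smaller_is_a <- wa <= wb
      cov_small <- ifelse(smaller_is_a, ov / wa, ov / wb)
      rule2 <- cov_small > thresholds$containment

      emit <- function(keep, start, end) {
        if (!any(keep)) return(NULL)
        data.frame(
          sample_id = qa$sample_id[keep], chrom = qa$chrom[keep],
          start = start[keep], end = end[keep],
          direction = qa$direction[keep],
          status_a = qa$status[keep], status_b = qb$status[keep],
          caller_a = qa$caller[keep], caller_b = qb$caller[keep],
          cn_a = qa$copy_number[keep], cn_b = qb$copy_number[keep],
          stringsAsFactors = FALSE
        )
      }
      pieces[[length(pieces) + 1L]] <-
        emit(rule1, pmax(qa$start, qb$start), pmin(qa$end, qb$end))
      pieces[[length(pieces) + 1L]] <-
        emit(rule2,
             ifelse(smaller_is_a, qa$start, qb$start),
             ifelse(smaller_is_a, qa$end, qb$end))
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty)
  long <- do.call(rbind, pieces)

  ## one row per (region, caller) with that caller's status and cn
  per_caller <- rbind(
    data.frame(long[c("sample_id", "chrom", "start", "end", "direction")],
               caller = long$caller_a, status = long$status_a,
               cn = long$cn_a, stringsAsFactors = FALSE),
    data.frame(long[c("sample_id", "chrom", "start", "end", "direction")],
               caller = long$caller_b, status = long$status_b,
               cn = long$cn_b, stringsAsFactors = FALSE)
  )
  key <- paste(per_caller$sample_id, per_caller$chrom, per_caller$start,
               per_caller$end, per_caller$direction, sep = "\r")
  prio <- .cnv_caller_priority[per_caller$caller]
  prio[is.na(prio)] <- 99L
  ord <- order(key, prio, method = "radix")
  per_caller <- per_caller[ord, , drop = FALSE]
  key <- key[ord]
  grpf <- factor(key, levels = unique(key))

  first <- !duplicated(key)
  out <- per_caller[first, c("sample_id", "chrom", "start", "end",
                             "direction"), drop = FALSE]
  out$status <- as.character(tapply(per_caller$status, grpf, function(s) {
    if ("amplification" %in% s) "amplification"
    else if ("deep deletion" %in% s) "deep deletion"
    else s[1]
  }))
  ## extreme statuses label the direction; normalize mild label to direction
  mild <- !(out$status %in% c("amplification", "deep deletion"))
  out$status[mild] <- out$direction[mild]
  out$copy_number <- as.integer(tapply(per_caller$cn, grpf, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_integer_
  }))
  out$supporting_callers <- as.character(
    tapply(per_caller$caller, grpf,
           function(x) paste(sort(unique(x)), collapse = ","))
  )
  out$n_callers <- as.integer(
    tapply(per_caller$caller, grpf, function(x) length(unique(x)))
  )
  out$in_consensus <- TRUE
  out <- out[order(out$sample_id, out$chrom, out$start, out$end,
                   out$direction, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CNV consensus with the MantaSV fallback trio
#'
#' When a GATK panel of normals is unavailable, consensus for the sample
#' runs on the Control-FREEC / CNVkit / MantaSV trio instead; consensus
#' semantics are unchanged.
#'
#' @param perCaller named list of [SegmentSet-class] (expects
#'   `controlfreec`, `cnvkit`, and `gatk` when available).
#' @param gatkAvailable logical: is the GATK callset usable?
#' @param mantaSegments [SegmentSet-class] of MantaSV-derived segments,
#'   used when `gatkAvailable` is `FALSE`.
#' @param thresholds see [defaultThresholds()].
#' @return As [pairwiseConsensus()].
#' @export
consensusWithFallback <- function(perCaller, gatkAvailable = TRUE,
                                  mantaSegments = segmentSet(),
                                  thresholds = defaultThresholds()) {
  trio <- perCaller[setdiff(names(perCaller), if (gatkAvailable) "mantasv"
                            else "gatk")]
  if (!gatkAvailable) trio$mantasv <- mantaSegments
  with_data <- sum(vapply(trio, function(x) length(x) > 0, TRUE))
  if (with_data < 2L) {
    warning("fewer than 2 callers with segments; empty consensus")
    return(pairwiseConsensus(segmentSet(), thresholds))
  }
  pairwiseConsensus(trio, thresholds)
}

#' Merge nearby same-direction consensus regions
#'
#' Per sample, same-direction regions separated by at most `merge_gap`
#' (default 10,000 bp) are merged into one spanning region; supporters are
#' unioned, the extreme status is preserved if any constituent carried it,
#' and the copy number comes from the highest-priority supporting caller's
#' constituent value.
#'
#' @param regions consensus-region `data.frame` from
#'   [pairwiseConsensus()].
#' @param thresholds see [defaultThresholds()].
#' @return Merged consensus-region `data.frame`.
#' @export
mergeAdjacent <- function(regions, thresholds = defaultThresholds()) {
  if (!nrow(regions)) return(regions)
  df <- regions[order(regions$sample_id, regions$direction, regions$chrom,
                      regions$start, regions$end, method = "radix"), ,
                drop = FALSE]
  grp_key <- paste(df$sample_id, df$direction, df$chrom, sep = "\r")
  out <- list()
  cur <- NULL
  cur_key <- ""
  flush <- function(cur) {
    cur$supporting_callers <- paste(sort(unique(cur$sup)), collapse = ",")
    cur$n_callers <- length(unique(cur$sup))
    cur$sup <- NULL
    as.data.frame(cur, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    sup <- strsplit(row$supporting_callers, ",")[[1]]
    if (!is.null(cur) && grp_key[i] == cur_key &&
        row$start - cur$end - 1L <= thresholds$merge_gap) {
      cur$end <- max(cur$end, row$end)
      cur$sup <- c(cur$sup, sup)
      if (row$status %in% c("amplification", "deep deletion")) {
        cur$status <- row$status
      }
      if (is.na(cur$copy_number)) cur$copy_number <- row$copy_number
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(sample_id = row$sample_id, chrom = row$chrom,
                  start = row$start, end = row$end,
                  direction = row$direction, status = row$status,
                  copy_number = row$copy_number, sup = sup,
                  in_consensus = TRUE)
      cur_key <- grp_key[i]
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
  out <- do.call(rbind, out)
  out <- out[, names(regions), drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$start, out$end,
                   out$direction, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Blacklist and minimum-size filter
#'
#' Removes regions shorter than `min_cnv_len` (default 3,000 bp) or whose
#' overlap with the blacklist (immunoglobulin, telomeric, centromeric and
#' segmental-duplication regions, supplied as one merged BED) is at least
#' `blacklist_overlap` (default 50%) of the region's own length. With no
#' blacklist, only the size filter applies (with a warning).
#'
#' @param regions consensus-region `data.frame`.
#' @param blacklist an [IntervalSet-class], or `NULL`.
#' @param thresholds see [defaultThresholds()].
#' @return Filtered consensus-region `data.frame`.
#' @export
blacklistSizeFilter <- function(regions, blacklist = NULL,
                                thresholds = defaultThresholds()) {
  if (!nrow(regions)) return(regions)
  len <- regions$end - regions$start + 1
  keep <- len >= thresholds$min_cnv_len
  if (is.null(blacklist)) {
    warning("no blacklist supplied; applying size filter only")
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start, end = regions$end)
    )
    bl <- GenomicRanges::reduce(GenomicRanges::granges(as(blacklist, "GRanges")))
    ovbp <- rep(0, nrow(regions))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, bl))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      w <- pmin(GenomicRanges::end(gr)[q], GenomicRanges::end(bl)[s]) -
        pmax(GenomicRanges::start(gr)[q], GenomicRanges::start(bl)[s]) + 1
      ovbp <- as.numeric(tapply(w, factor(q, levels = seq_len(nrow(regions))),
                                sum))
      ovbp[is.na(ovbp)] <- 0
    }
    keep <- keep & (ovbp / len < thresholds$blacklist_overlap)
  }
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Set copy number to NA on neutral rows
#'
#' The released consensus table carries `NA` copy number for neutral calls
#' of samples included in the consensus (neutral rows enter the table only
#' via the appended WXS calls).
#'
#' @param regions consensus-region `data.frame` (a `status` column is
#'   required).
#' @param samplesInConsensus sample ids included in the consensus set;
#'   default all samples present.
#' @return `data.frame` with `copy_number` masked on neutral rows.
#' @export
neutralToNA <- function(regions,
                        samplesInConsensus = unique(regions$sample_id)) {
  if (!nrow(regions)) return(regions)
  hit <- regions$status == "neutral" &
    regions$sample_id %in% samplesInConsensus
  regions$copy_number[hit] <- NA_integer_
  regions
}

#' Append WXS CNVkit calls to a consensus table
#'
#' WXS samples do not enter the WGS consensus; their CNVkit segments are
#' appended verbatim, flagged `in_consensus = FALSE` with caller `cnvkit`.
#'
#' @param consensus consensus-region `data.frame`.
#' @param wxsSegments [SegmentSet-class] of WXS CNVkit segments.
#' @return Combined `data.frame` with identical column schema.
#' @export
appendWxsCalls <- function(consensus, wxsSegments) {
  df <- if (is(wxsSegments, "SegmentSet")) records(wxsSegments)
        else as.data.frame(wxsSegments)
  if (!nrow(df)) return(consensus)
  add <- data.frame(
    sample_id = df$sample_id, chrom = df$chrom, start = df$start,
    end = df$end, direction = .status_direction(df$status),
    status = df$status, copy_number = df$copy_number,
    supporting_callers = "cnvkit", n_callers = 1L, in_consensus = FALSE,
    stringsAsFactors = FALSE
  )
  out <- rbind(consensus, add[, names(consensus), drop = FALSE])
  rownames(out) <- NULL
  out
}
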