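# Independent brute-force oracles and row constructors shared across the
# suite. The oracles restate the published predicates with naive set
# algebra / all-pairs loops and never call the implementation under test.

mk_var <- function(sample = "S1", chrom = "chr1", start = 100L,
                   end = start, ref = "C", alt = "A", gene = "GENE",
                   variant_class = "Missense_Mutation",
                   variant_type = "SNP", protein_change = NA_character_,
                   callers = "strelka2", t_depth = 50L, alt_depth = 10L,
                   n_depth = 30L, gnomad_af = NA_real_, hotspot = FALSE) {
  data.frame(sample_id = sample, chrom = chrom, start = as.integer(start),
             end = as.integer(end), ref = ref, alt = alt, gene = gene,
             variant_class = variant_class, variant_type = variant_type,
             protein_change = protein_change, callers = callers,
             t_depth = t_depth, alt_depth = alt_depth, n_depth = n_depth,
             gnomad_af = gnomad_af, hotspot = hotspot,
             stringsAsFactors = FALSE)
}

mk_seg <- function(sample = "S1", chrom = "chr1", start = 1e5L,
                   end = 2e5L, copy_number = 3L, status = NULL,
                   caller = "controlfreec") {
  if (is.null(status)) status <- cnToStatus(copy_number)
  data.frame(sample_id = sample, chrom = chrom, start = as.integer(start),
             end = as.integer(end), copy_number = as.integer(copy_number),
             status = status, caller = caller, stringsAsFactors = FALSE)
}

var_key <- function(df) {
  paste(df$sample_id, df$chrom, df$start, df$end, df$ref, df$alt)
}

# set-algebra restatement of the two-of-four / hotspot-rescue rule
oracle_consensus_keys <- function(per_caller, min_callers = 2) {
  all <- do.call(rbind, lapply(names(per_caller), function(cl) {
    df <- per_caller[[cl]]
    df$..caller <- cl
    df
  }))
  key <- var_key(all)
  n <- tapply(all$..caller, key, function(x) length(unique(x)))
  hot <- tapply(all$hotspot, key, any)
  sort(names(n)[n >= min_callers | hot])
}

# O(n^2) all-pairs restatement of CNV consensus rules 1 and 2; returns a
# sorted character vector of emitted region keys
oracle_cnv_keys <- function(df, recip = 0.5, contain = 0.9) {
  dir <- ifelse(df$status %in% c("gain", "amplification"), "gain",
                ifelse(df$status %in% c("loss", "deep deletion"), "loss",
                       NA))
  df$dir <- dir
  df <- df[!is.na(df$dir), , drop = FALSE]
  keys <- character()
  callers <- sort(unique(df$caller))
  for (s in unique(df$sample_id)) {
    for (i in seq_along(callers)) for (j in seq_along(callers)) {
      if (j <= i) next
      A <- df[df$sample_id == s & df$caller == callers[i], , drop = FALSE]
      B <- df[df$sample_id == s & df$caller == callers[j], , drop = FALSE]
      if (!nrow(A) || !nrow(B)) next
      idx <- expand.grid(a = seq_len(nrow(A)), b = seq_len(nrow(B)))
      a <- A[idx$a, ]; b <- B[idx$b, ]
      same <- a$chrom == b$chrom & a$dir == b$dir
      ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start) + 1)
      wa <- a$end - a$start + 1; wb <- b$end - b$start + 1
      r1 <- same & ov / wa >= recip & ov / wb >= recip
      small_a <- wa <= wb
      r2 <- same & ifelse(small_a, ov / wa, ov / wb) > contain
      if (any(r1)) {
        keys <- c(keys, paste(s, a$chrom[r1], pmax(a$start, b$start)[r1],
                              pmin(a$end, b$end)[r1], a$dir[r1]))
      }
      if (any(r2)) {
        keys <- c(keys, paste(s, a$chrom[r2],
                              ifelse(small_a, a$start, b$start)[r2],
                              ifelse(small_a, a$end, b$end)[r2],
                              a$dir[r2]))
      }
    }
  }
  sort(unique(keys))
}

# per-bp membership count on a toy genome (brute-force totalBp oracle)
oracle_total_bp <- function(df0based, chrom_len = 1e5) {
  total <- 0
  for (chr in unique(df0based$chrom)) {
    covered <- rep(FALSE, chrom_len)
    rows <- df0based[df0based$chrom == chr, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      covered[(rows$start[k] + 1):rows$end[k]] <- TRUE
    }
    total <- total + sum(covered)
  }
  total
}

random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             chrom_len = 1e5, max_len = 5000) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
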