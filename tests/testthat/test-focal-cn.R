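genes <- data.frame(gene = c("GENE_A", "GENE_B"),
                    chrom = c("chr1", "chr2"),
                    start = c(100001L, 100001L), end = c(120000L, 120000L),
                    stringsAsFactors = FALSE)

reg <- function(start, end, status, sample = "S1", chrom = "chr1") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             direction = ifelse(status %in% c("gain", "amplification"),
                                "gain", "loss"),
             status = status, copy_number = 3L,
             supporting_callers = "cnvkit,controlfreec", n_callers = 2L,
             in_consensus = TRUE, stringsAsFactors = FALSE)
}

test_that("gene status calls annotate every overlapping region", {
  r <- rbind(reg(90001, 130000, "gain"),        # covers GENE_A fully
             reg(110001, 200000, "loss"))       # overlaps GENE_A partially
  calls <- assignGeneStatus(r, genes, samples = "S1")
  a <- calls[calls$gene == "GENE_A", ]
  expect_equal(sort(a$status), c("gain", "loss"))
  expect_equal(a$overlap_bp[a$status == "gain"], 20000)
  expect_equal(a$overlap_bp[a$status == "loss"], 10000)
  # gene with no region at all: neutral default
  b <- calls[calls$gene == "GENE_B", ]
  expect_equal(b$status, "neutral")
  expect_equal(b$overlap_bp, 0)
})

test_that("duplicate resolution applies the three priority rules in order", {
  # rule 1: non-neutral beats neutral
  c1 <- rbind(
    data.frame(sample_id = "S1", gene = "G", status = "neutral",
               copy_number = NA_integer_, overlap_bp = 20000,
               seg_start = NA_integer_, seg_end = NA_integer_),
    data.frame(sample_id = "S1", gene = "G", status = "gain",
               copy_number = 3L, overlap_bp = 100,
               seg_start = 1L, seg_end = 5000L)
  )
  expect_equal(resolveDuplicateStatus(c1)$status, "gain")

  # rule 2: dominant segment (larger gene overlap) wins
  c2 <- rbind(
    data.frame(sample_id = "S1", gene = "G", status = "gain",
               copy_number = 3L, overlap_bp = 16000,
               seg_start = 1L, seg_end = 5e4L),
    data.frame(sample_id = "S1", gene = "G", status = "loss",
               copy_number = 1L, overlap_bp = 4000,
               seg_start = 6e4L, seg_end = 9e4L)
  )
  expect_equal(resolveDuplicateStatus(c2)$status, "gain")

  # rule 3: amplification beats gain at equal overlap
  c3 <- rbind(
    data.frame(sample_id = "S1", gene = "G", status = "gain",
               copy_number = 3L, overlap_bp = 10000,
               seg_start = 1L, seg_end = 5e4L),
    data.frame(sample_id = "S1", gene = "G", status = "amplification",
               copy_number = 10L, overlap_bp = 10000,
               seg_start = 2L, seg_end = 5e4L)
  )
  expect_equal(resolveDuplicateStatus(c3)$status, "amplification")
})

test_that("resolution always leaves exactly one call per (sample, gene)", {
  set.seed(21)
  statuses <- c("amplification", "gain", "neutral", "loss", "deep deletion")
  calls <- do.call(rbind, lapply(1:300, function(i) {
    data.frame(
      sample_id = sample(sprintf("S%d", 1:5), 1),
      gene = sample(sprintf("G%d", 1:10), 1),
      status = sample(statuses, 1),
      copy_number = 2L,
      overlap_bp = sample(c(100, 5000, 5000, 20000), 1),
      seg_start = sample.int(1e6, 1), seg_end = 2e6L,
      stringsAsFactors = FALSE
    )
  }))
  out <- resolveDuplicateStatus(calls)
  expect_false(any(duplicated(paste(out$sample_id, out$gene))))
  expect_setequal(paste(out$sample_id, out$gene),
                  unique(paste(calls$sample_id, calls$gene)))
  # determinism regardless of row order
  out2 <- resolveDuplicateStatus(calls[sample.int(nrow(calls)), ])
  expect_identical(out[order(out$sample_id, out$gene), ],
                   out2[order(out2$sample_id, out2$gene), ])
})
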