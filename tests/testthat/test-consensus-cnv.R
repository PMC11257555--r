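test_that("de-noising drops caller files only above 2,500 segments", {
  at_cap <- do.call(rbind, lapply(seq_len(2500), function(i) {
    mk_seg(start = i * 10000L, end = i * 10000L + 5000L)
  }))
  over_cap <- rbind(at_cap, mk_seg(start = 9e7, end = 9e7 + 5000))
  expect_equal(length(denoiseCallerFiles(segmentSet(at_cap))), 2500L)
  expect_message(
    kept <- denoiseCallerFiles(segmentSet(over_cap)),
    "de-noising")
  expect_equal(length(kept), 0L)
  expect_equal(length(denoiseCallerFiles(segmentSet())), 0L)
})

test_that("reciprocal-overlap rule emits the pair intersection", {
  segs <- rbind(
    mk_seg(start = 100001, end = 200000, caller = "controlfreec"),
    mk_seg(start = 150001, end = 250000, caller = "cnvkit")
  )
  out <- pairwiseConsensus(segmentSet(segs))
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 150001)
  expect_equal(out$end, 200000)
  expect_equal(out$supporting_callers, "cnvkit,controlfreec")
  expect_equal(out$direction, "gain")
})

test_that("containment rule emits the >90%-covered smaller segment", {
  segs <- rbind(
    mk_seg(start = 1, end = 100000, caller = "controlfreec"),
    mk_seg(start = 10001, end = 20000, caller = "cnvkit")
  )
  out <- pairwiseConsensus(segmentSet(segs))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(10001, 20000))
})

test_that("opposite directions never reach consensus", {
  segs <- rbind(
    mk_seg(start = 100001, end = 200000, copy_number = 3,
           caller = "controlfreec"),
    mk_seg(start = 100001, end = 200000, copy_number = 1,
           caller = "cnvkit")
  )
  expect_equal(nrow(pairwiseConsensus(segmentSet(segs))), 0L)
})

test_that("extreme status and priority-donor copy number survive", {
  segs <- rbind(
    mk_seg(start = 100001, end = 200000, copy_number = 10,
           caller = "cnvkit"),   # amplification
    mk_seg(start = 100001, end = 200000, copy_number = 3,
           caller = "controlfreec")
  )
  out <- pairwiseConsensus(segmentSet(segs))
  expect_equal(out$status, "amplification")
  expect_equal(out$copy_number, 3L)  # controlfreec outranks cnvkit
})

test_that("MantaSV substitutes for GATK in the fallback trio", {
  freec <- segmentSet(mk_seg(start = 100001, end = 200000,
                             caller = "controlfreec"))
  manta <- segmentSet(mk_seg(start = 150001, end = 250000,
                             caller = "mantasv"))
  out <- consensusWithFallback(
    list(controlfreec = freec, cnvkit = segmentSet(), gatk = segmentSet()),
    gatkAvailable = FALSE, mantaSegments = manta)
  expect_equal(out$supporting_callers, "controlfreec,mantasv")
  expect_warning(
    empty <- consensusWithFallback(
      list(controlfreec = freec, cnvkit = segmentSet(),
           gatk = segmentSet()),
      gatkAvailable = TRUE),
    "fewer than 2")
  expect_equal(nrow(empty), 0L)
})

region_row <- function(start, end, direction = "gain", status = direction,
                       sample = "S1", chrom = "chr1", cn = 3L,
                       sup = "cnvkit,controlfreec") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             direction = direction, status = status, copy_number = cn,
             supporting_callers = sup, n_callers = 2L, in_consensus = TRUE,
             stringsAsFactors = FALSE)
}

test_that("merging joins same-direction regions within 10 kb only", {
  r <- rbind(region_row(1, 5000), region_row(15001, 20000))  # gap 10000
  m <- mergeAdjacent(r)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1, 20000))

  r2 <- rbind(region_row(1, 5000), region_row(15002, 20000))  # gap 10001
  expect_equal(nrow(mergeAdjacent(r2)), 2L)

  r3 <- rbind(region_row(1, 5000),
              region_row(5002, 20000, direction = "loss", status = "loss"))
  expect_equal(nrow(mergeAdjacent(r3)), 2L)
})

test_that("merged regions leave no same-direction neighbors within 10 kb", {
  set.seed(5)
  st <- sort(sample.int(5e6, 80))
  r <- do.call(rbind, lapply(st, function(s) {
    region_row(s, s + sample.int(20000, 1),
               direction = sample(c("gain", "loss"), 1))
  }))
  r$status <- r$direction
  m <- mergeAdjacent(r)
  for (dir in c("gain", "loss")) {
    sub <- m[m$direction == dir, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      gaps <- sub$start[-1] - sub$end[-nrow(sub)] - 1
      expect_true(all(gaps > 10000))
    }
  }
})

test_that("blacklist and size filters use the published boundaries", {
  bl <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  r <- rbind(
    region_row(2e6, 2e6 + 2998),          # 2,999 bp, no overlap: drop
    region_row(995001, 1005000),          # 10,000 bp, 5,000 in blacklist: drop
    region_row(998502, 1001501),          # 3,000 bp, 1,499 in blacklist: keep
    region_row(3e6, 3e6 + 2999)           # exactly 3,000 bp: keep
  )
  out <- blacklistSizeFilter(r, bl)
  expect_equal(out$start, c(998502, 3e6))
  expect_true(all(out$end - out$start + 1 >= 3000))
  expect_warning(blacklistSizeFilter(r, NULL), "size filter only")
})

test_that("neutral rows get NA copy number; WXS rows append verbatim", {
  r <- rbind(region_row(1e5, 2e5),
             region_row(3e5, 4e5, direction = NA, status = "neutral",
                        cn = 2L))
  out <- neutralToNA(r)
  expect_true(is.na(out$copy_number[2]))
  expect_equal(out$copy_number[1], 3L)

  wxs <- segmentSet(mk_seg(sample = "WX1", start = 1e5, end = 2e5,
                           caller = "cnvkit"))
  comb <- appendWxsCalls(r, wxs)
  expect_equal(nrow(comb), 3L)
  expect_identical(names(comb), names(r))
  expect_false(comb$in_consensus[3])
  expect_identical(appendWxsCalls(r, segmentSet()), r)
})

test_that("pairwise consensus reproduces the all-pairs brute force", {
  set.seed(13)
  segs <- NULL
  for (s in sprintf("S%02d", 1:6)) {
    for (cl in c("controlfreec", "cnvkit", "gatk")) {
      n <- 40
      st <- sample.int(9e6, n)
      segs <- rbind(segs, data.frame(
        sample_id = s, chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        start = st, end = st + sample.int(2e5, n),
        copy_number = sample(c(0L, 1L, 3L, 10L), n, replace = TRUE),
        status = NA_character_, caller = cl, stringsAsFactors = FALSE
      ))
    }
  }
  segs$status <- cnToStatus(segs$copy_number)
  got <- pairwiseConsensus(segmentSet(segs))
  got_keys <- sort(unique(paste(got$sample_id, got$chrom, got$start,
                                got$end, got$direction)))
  expect_identical(got_keys, oracle_cnv_keys(segs))
})
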