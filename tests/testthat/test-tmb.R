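test_that("MNV splitting emits per-base SNVs and removes redundancy", {
  vs <- variantSet(rbind(
    mk_var(start = 100, end = 101, ref = "CG", alt = "AT",
           variant_type = "DNP"),
    mk_var(start = 100, ref = "C", alt = "A")   # duplicate of first split base
  ))
  out <- records(splitMnv(vs))
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(100L, 101L))
  expect_equal(out$ref, c("C", "G"))
  expect_equal(out$alt, c("A", "T"))
  expect_true(all(out$variant_type == "SNP"))

  pure <- variantSet(rbind(mk_var(start = 5), mk_var(start = 9)))
  expect_equal(records(splitMnv(pure))[, c("start", "ref", "alt")],
               records(pure)[, c("start", "ref", "alt")])

  bad <- variantSet(mk_var(start = 100, end = 102, ref = "CG", alt = "AT",
                           variant_type = "TNP"))
  expect_error(splitMnv(bad), "length mismatch")
})

test_that("MNV splitting conserves the substituted base count", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 40
    starts <- sample.int(1e6, n) * 10L  # spaced, so no accidental dedup
    len <- sample(1:3, n, replace = TRUE)
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_var(start = starts[i], end = starts[i] + len[i] - 1L,
             ref = paste(rep("C", len[i]), collapse = ""),
             alt = paste(rep("T", len[i]), collapse = ""),
             variant_type = c("SNP", "DNP", "TNP")[len[i]])
    }))
    out <- records(splitMnv(variantSet(df)))
    expect_equal(nrow(out), sum(len))
    expect_equal(sum(out$end - out$start + 1), sum(len))
  }
})

test_that("coding denominator is the surveyed/CDS intersection size", {
  surveyed <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  cds <- intervalSet(data.frame(chrom = "chr1", start = 4e5, end = 6e5))
  expect_equal(codingDenominator(surveyed, cds), 2e5)
  disjoint <- intervalSet(data.frame(chrom = "chr2", start = 0, end = 1e5))
  vs <- variantSet(mk_var())
  expect_error(computeTmb(vs, "WGS", surveyed, disjoint),
               "zero coding denominator")
})

test_that("12 coding nonsynonymous mutations over 2 Mb give 6.0 per Mb", {
  surveyed <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 4e6))
  cds <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 2e6))
  df <- do.call(rbind, lapply(1:12, function(i) {
    mk_var(start = i * 1000L)
  }))
  out <- computeTmb(variantSet(df), "WGS", surveyed, cds)
  expect_equal(out$tmb_coding, 6.0)
  expect_equal(out$numerator_coding, 12L)
  expect_equal(out$denominator_coding, 2e6)
  expect_equal(out$tmb_all, 3.0)

  none <- computeTmb(variantSet(mk_var(start = 3.5e6)), "WGS",
                     surveyed, cds)
  expect_equal(none$tmb_coding, 0)
})

test_that("silent calls count for all-mutation but not coding TMB", {
  surveyed <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 2e6))
  cds <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  df <- rbind(mk_var(start = 100, variant_class = "Silent"),
              mk_var(start = 200, variant_class = "Missense_Mutation"))
  out <- computeTmb(variantSet(df), "WGS", surveyed, cds)
  expect_equal(out$numerator_all, 2L)
  expect_equal(out$numerator_coding, 1L)
  expect_true(out$numerator_coding <= out$numerator_all)
})

test_that("doubling the denominator halves TMB exactly", {
  cds <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  s1 <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  s2 <- intervalSet(data.frame(chrom = c("chr1", "chr1"),
                               start = c(0, 1e6), end = c(1e6, 2e6)))
  df <- do.call(rbind, lapply(1:8, function(i) mk_var(start = i * 100L)))
  t1 <- computeTmb(variantSet(df), "WGS", s1, cds)
  t2 <- computeTmb(variantSet(df), "WGS", s2, cds)
  expect_equal(t2$tmb_all, t1$tmb_all / 2)
})

test_that("alternate nonsynonymous sets behave as configured", {
  default_set <- nonsynClassifications("default")
  focr_set <- nonsynClassifications("focr")
  expect_true("Translation_Start_Site" %in% default_set)
  expect_false("Translation_Start_Site" %in% focr_set)
  vs <- variantSet(rbind(
    mk_var(start = 100, variant_class = "Translation_Start_Site"),
    mk_var(start = 200, variant_class = "Missense_Mutation"),
    mk_var(start = 300, variant_class = "Silent")
  ))
  expect_equal(nrow(records(filterNonsynonymous(vs, "default"))), 2L)
  expect_equal(nrow(records(filterNonsynonymous(vs, "focr"))), 1L)
  surveyed <- intervalSet(data.frame(chrom = "chr1", start = 0, end = 1e6))
  same <- computeTmb(vs, "WGS", surveyed, surveyed,
                     nonsynFilter = default_set)
  again <- computeTmb(vs, "WGS", surveyed, surveyed,
                      nonsynFilter = default_set)
  expect_identical(same, again)
})
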