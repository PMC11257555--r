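test_that("fully supported MNPs replace their constituent SNPs", {
  strelka <- variantSet(rbind(
    mk_var(start = 100, ref = "C", alt = "A"),
    mk_var(start = 101, ref = "G", alt = "T")
  ))
  mnp <- variantSet(mk_var(start = 100, end = 101, ref = "CG", alt = "AT",
                           variant_type = "DNP", callers = "mutect2"))
  out <- records(reconstructMnp(strelka, mnp))
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref, "CG")
  expect_equal(out$alt, "AT")
  expect_equal(out$variant_type, "DNP")
  expect_equal(out$callers, "strelka2")
  expect_match(out$mnp_members, "100.*;.*101")
})

test_that("partial support and absent candidates leave SNPs untouched", {
  one <- variantSet(mk_var(start = 100, ref = "C", alt = "A"))
  mnp <- variantSet(mk_var(start = 100, end = 101, ref = "CG", alt = "AT",
                           variant_type = "DNP", callers = "mutect2"))
  out <- records(reconstructMnp(one, mnp))
  expect_equal(nrow(out), 1L)
  expect_equal(out$variant_type, "SNP")

  two <- variantSet(rbind(mk_var(start = 100, ref = "C", alt = "A"),
                          mk_var(start = 101, ref = "G", alt = "T")))
  out2 <- records(reconstructMnp(two, variantSet()))
  expect_equal(out2$variant_type, c("SNP", "SNP"))
})

test_that("overlapping candidates resolve longest-first then leftmost", {
  strelka <- variantSet(rbind(
    mk_var(start = 100, ref = "C", alt = "A"),
    mk_var(start = 101, ref = "G", alt = "T"),
    mk_var(start = 102, ref = "A", alt = "C")
  ))
  cands <- variantSet(rbind(
    mk_var(start = 100, end = 101, ref = "CG", alt = "AT",
           variant_type = "DNP", callers = "mutect2"),
    mk_var(start = 100, end = 102, ref = "CGA", alt = "ATC",
           variant_type = "TNP", callers = "lancet"),
    mk_var(start = 101, end = 102, ref = "GA", alt = "TC",
           variant_type = "DNP", callers = "vardict")
  ))
  out <- records(reconstructMnp(strelka, cands))
  expect_equal(nrow(out), 1L)          # the TNP claims all three SNPs
  expect_equal(out$variant_type, "TNP")
  expect_equal(out$ref, "CGA")
})

test_that("MNP reconstruction conserves substituted bases over random cases", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 50
    pos <- sort(sample.int(5000, n))
    strelka_df <- do.call(rbind, lapply(pos, function(p) {
      mk_var(start = p, ref = sample(c("A", "C", "G", "T"), 1), alt = "T")
    }))
    # candidates built from random adjacent runs of the SNPs themselves
    cand <- NULL
    for (k in 1:10) {
      i <- sample.int(n - 2, 1)
      if (strelka_df$start[i + 1] == strelka_df$start[i] + 1) {
        cand <- rbind(cand, mk_var(
          start = strelka_df$start[i], end = strelka_df$start[i] + 1,
          ref = paste0(strelka_df$ref[i], strelka_df$ref[i + 1]),
          alt = "TT", variant_type = "DNP", callers = "mutect2"))
      }
    }
    base_count <- function(df) sum(df$end - df$start + 1)
    out <- records(reconstructMnp(
      variantSet(strelka_df),
      if (is.null(cand)) variantSet() else variantSet(cand)))
    expect_equal(base_count(out), base_count(strelka_df))
  }
})

test_that("two-caller support or hotspot rescue admits a variant", {
  per <- list(
    strelka2 = variantSet(rbind(
      mk_var(start = 100),                       # strelka2+mutect2
      mk_var(start = 300, hotspot = TRUE)        # strelka2 only, hotspot
    )),
    mutect2 = variantSet(mk_var(start = 100, callers = "mutect2")),
    lancet = variantSet(mk_var(start = 200, callers = "lancet")),
    vardict = variantSet()
  )
  out <- records(callConsensus(per))
  expect_equal(nrow(out), 2L)
  expect_equal(out$consensus_reason[out$start == 100], "multi_caller")
  expect_equal(out$callers[out$start == 100], "mutect2,strelka2")
  expect_equal(out$consensus_reason[out$start == 300], "hotspot_rescue")
})

test_that("depths come from the highest-priority supporting caller", {
  per <- list(
    vardict = variantSet(mk_var(start = 100, callers = "vardict",
                                t_depth = 99L, alt_depth = 40L)),
    mutect2 = variantSet(mk_var(start = 100, callers = "mutect2",
                                t_depth = 60L, alt_depth = 20L))
  )
  out <- records(callConsensus(per))
  expect_equal(out$t_depth, 60L)  # mutect2 outranks vardict
})

test_that("adding a caller never removes a variant (monotonicity)", {
  set.seed(3)
  base <- list(
    strelka2 = variantSet(do.call(rbind, lapply(
      sample.int(1e4, 50), function(p) mk_var(start = p)))),
    mutect2 = variantSet(do.call(rbind, lapply(
      sample.int(1e4, 50), function(p) mk_var(start = p,
                                              callers = "mutect2"))))
  )
  before <- var_key(records(callConsensus(base)))
  extra <- base
  extra$lancet <- variantSet(mk_var(start = 1L, callers = "lancet"))
  after <- var_key(records(callConsensus(extra)))
  expect_true(all(before %in% after))
})

test_that("germline-leakage removal follows the published predicate grid", {
  grid <- expand.grid(n_depth = c(6L, 7L, 8L),
                      gnomad_af = c(0.0009, 0.001, 0.0011, 0.01),
                      hotspot = c(TRUE, FALSE))
  df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    mk_var(start = i, n_depth = grid$n_depth[i],
           gnomad_af = grid$gnomad_af[i], hotspot = grid$hotspot[i])
  }))
  kept <- records(filterGermlineLeakage(variantSet(df)))$start
  expect_removed <- !grid$hotspot & grid$n_depth <= 7 & grid$gnomad_af > 0.001
  expect_setequal(kept, which(!expect_removed))

  # absent values never trigger removal
  na_df <- rbind(mk_var(start = 1, n_depth = NA_integer_, gnomad_af = 0.5),
                 mk_var(start = 2, n_depth = 3L, gnomad_af = NA_real_))
  expect_equal(nrow(records(filterGermlineLeakage(variantSet(na_df)))), 2L)
})

test_that("tumor-only depth filter matches its boundary grid", {
  grid <- expand.grid(alt_depth = c(0L, 1L, 2L), t_depth = c(3L, 4L, 50L))
  df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    mk_var(start = i, alt_depth = grid$alt_depth[i],
           t_depth = grid$t_depth[i], n_depth = NA_integer_)
  }))
  kept <- records(filterTumorOnly(variantSet(df)))$start
  expect_removed <- grid$alt_depth == 0 | grid$t_depth < 4
  expect_setequal(kept, which(!expect_removed))

  na_df <- mk_var(start = 1, alt_depth = NA_integer_,
                  t_depth = NA_integer_)
  expect_equal(nrow(records(filterTumorOnly(variantSet(na_df)))), 1L)
})
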