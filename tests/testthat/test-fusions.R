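mk_fus <- function(sample = "S1", gene5 = "AAA", gene3 = "BBB",
                   caller = "arriba", group = "HGG", annotations = "") {
  data.frame(sample_id = sample, gene5 = gene5, gene3 = gene3,
             caller = caller, cancer_group = group,
             annotations = annotations, stringsAsFactors = FALSE)
}

lists <- list(kinase = c("ALK", "ROS1"), oncogene = "MYCN",
              tcga_observed = "TTYH1")

test_that("oncogenic annotation fires on either partner in any list", {
  fs <- fusionSet(rbind(
    mk_fus(gene5 = "ALK", gene3 = "XXX"),
    mk_fus(gene5 = "XXX", gene3 = "TTYH1"),
    mk_fus(gene5 = "XXX", gene3 = "YYY")
  ))
  out <- records(annotateOncogenic(fs, lists))
  expect_equal(out$putative_oncogenic, c(TRUE, TRUE, FALSE))
  expect_match(out$annotations[1], "kinase")
  expect_match(out$annotations[2], "tcga_observed")
})

test_that("retention reasons cover both callers, recurrence, specificity", {
  df <- rbind(
    # called by both callers in one sample
    mk_fus("S1", "P1", "Q1", caller = "arriba", group = "A"),
    mk_fus("S1", "P1", "Q1", caller = "starfusion", group = "A"),
    # recurrent: 3 samples of one cancer group, single caller
    mk_fus("S2", "P2", "Q2", group = "B"),
    mk_fus("S3", "P2", "Q2", group = "B"),
    mk_fus("S4", "P2", "Q2", group = "B"),
    # seen once in each of two groups, one caller, no annotation: dropped
    mk_fus("S5", "P3", "Q3", group = "A"),
    mk_fus("S6", "P3", "Q3", group = "B")
  )
  out <- retainFusions(annotateOncogenic(fusionSet(df), lists))
  ret <- records(out$retained)
  pairs <- paste(ret$gene5, ret$gene3)
  expect_true(all(c("P1 Q1", "P2 Q2") %in% pairs))
  expect_false("P3 Q3" %in% pairs)
  expect_match(ret$retained_reason[ret$gene5 == "P1"][1], "both_callers")
  expect_match(ret$retained_reason[ret$gene5 == "P2"][1], "recurrent")
  # P1::Q1 occurs in exactly one cancer group, so it is also specific
  expect_match(ret$retained_reason[ret$gene5 == "P1"][1],
               "cancer_group_specific")
})

test_that("oncogenic annotation alone rescues a singleton call", {
  df <- rbind(mk_fus("S5", "P3", "Q3", group = "A"),
              mk_fus("S6", "P3", "Q3", group = "B"),
              mk_fus("S7", "ALK", "Q4", group = "A"),
              mk_fus("S8", "ALK", "Q4", group = "B"))
  out <- records(retainFusions(
    annotateOncogenic(fusionSet(df), lists))$retained)
  expect_setequal(unique(out$gene5), "ALK")
  expect_match(out$retained_reason[1], "oncogenic_annotation")
})

test_that("adding an annotation flag never drops a retained fusion", {
  df <- rbind(mk_fus("S1", "P1", "Q1", caller = "arriba"),
              mk_fus("S1", "P1", "Q1", caller = "starfusion"))
  plain <- records(retainFusions(annotateOncogenic(
    fusionSet(df), list()))$retained)
  flagged <- records(retainFusions(annotateOncogenic(
    fusionSet(df), list(kinase = "P1")))$retained)
  expect_true(all(paste(plain$sample_id, plain$gene5, plain$gene3) %in%
                    paste(flagged$sample_id, flagged$gene5,
                          flagged$gene3)))
})

test_that("retention is independent of input row order", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:40, function(i) {
    mk_fus(sample = sprintf("S%d", sample(1:8, 1)),
           gene5 = sample(c("P1", "P2", "ALK"), 1),
           gene3 = sample(c("Q1", "Q2"), 1),
           caller = sample(c("arriba", "starfusion"), 1),
           group = sample(c("A", "B"), 1))
  }))
  a <- records(retainFusions(annotateOncogenic(fusionSet(df),
                                               lists))$retained)
  b <- records(retainFusions(annotateOncogenic(
    fusionSet(df[sample.int(nrow(df)), ]), lists))$retained)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[do.call(order, a), ], b[do.call(order, b), ],
               ignore_attr = TRUE)
})

test_that("DGD panel calls bypass filtering into their own output", {
  df <- rbind(mk_fus("S1", "P1", "Q1", caller = "dgd_panel"),
              mk_fus("S2", "P9", "Q9", caller = "arriba", group = "A"),
              mk_fus("S3", "P9", "Q9", caller = "arriba", group = "B"))
  out <- retainFusions(annotateOncogenic(fusionSet(df), list()))
  expect_equal(length(out$dgd), 1L)
  expect_equal(records(out$dgd)$caller, "dgd_panel")
  expect_equal(length(out$retained), 0L)
})
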