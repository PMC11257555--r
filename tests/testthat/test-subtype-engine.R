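rules <- subtypeRules()
th <- defaultThresholds()

spec_row <- function(diagnosis = "Medulloblastoma", age = 8,
                     site = "hemispheric", free_text = NA_character_,
                     germline = NA_character_, sample = "S1") {
  data.frame(sample_id = sample, tumor_event_id = "EV1",
             pathology_diagnosis = diagnosis,
             pathology_free_text_diagnosis = free_text,
             age_at_diagnosis_years = age, anatomical_site = site,
             germline_flags = germline, stringsAsFactors = FALSE)
}

bndl <- function(diagnosis = "Medulloblastoma", age = 8, site = "hemispheric",
                 free_text = NA_character_, germline = NA_character_, ...) {
  evidenceBundle(spec_row(diagnosis, age, site, free_text, germline), ...)
}

methyl_df <- function(subclass, score = 0.9) {
  data.frame(sample_id = "S1", classifier = "dkfz_v12",
             subclass = subclass, score = score, stringsAsFactors = FALSE)
}

test_that("methylation confidence boundary sits exactly at 0.80", {
  expect_true(highConfidence(0.80))
  expect_false(highConfidence(0.79))
  expect_false(highConfidence(NA_real_))
})

test_that("histone H3 K28 mutations define DMG regardless of methylation", {
  b <- bndl("High-grade glioma",
            variants = mk_var(gene = "H3F3A", protein_change = "p.K28M"))
  expect_equal(subtypeHgg(b, rules, th)$label, "DMG, H3 K28")
  b2 <- bndl("High-grade glioma", methyl = methyl_df("DMG_K27"))
  expect_equal(subtypeHgg(b2, rules, th)$label, "DMG, H3 K28")
  expect_equal(subtypeHgg(bndl("High-grade glioma"), rules, th)$label,
               "HGG, To be classified")
})

test_that("PXA needs the gate plus BRAF V600E plus CDKN2A/B deep deletion", {
  gs <- data.frame(sample_id = "S1", gene = "CDKN2A",
                   status = "deep deletion", stringsAsFactors = FALSE)
  braf <- mk_var(gene = "BRAF", protein_change = "p.V600E")
  full <- bndl("High-grade glioma", methyl = methyl_df("PXA"),
               variants = braf, geneStatus = gs)
  expect_equal(subtypeHgg(full, rules, th)$label, "PXA")
  # free-text gate works too
  ft <- bndl("High-grade glioma", free_text = "c/w pxa", variants = braf,
             geneStatus = gs)
  expect_equal(subtypeHgg(ft, rules, th)$label, "PXA")
  # missing the deletion: not PXA
  no_del <- bndl("High-grade glioma", methyl = methyl_df("PXA"),
                 variants = braf)
  expect_false(subtypeHgg(no_del, rules, th)$label == "PXA")
})

test_that("TP53 status is appended to HGG labels", {
  tp53 <- data.frame(sample_id = "S1", status = "lost",
                     evidence_trace = "hotspot", stringsAsFactors = FALSE)
  b <- bndl("High-grade glioma",
            variants = mk_var(gene = "H3F3A", protein_change = "p.K28M"),
            tp53 = tp53)
  expect_equal(subtypeHgg(b, rules, th)$label, "DMG, H3 K28, TP53 lost")
})

test_that("IHG suffix follows the RTK fusion partner", {
  fus <- function(g5, g3) data.frame(sample_id = "S1", gene5 = g5,
                                     gene3 = g3, caller = "arriba",
                                     cancer_group = "HGG",
                                     annotations = "",
                                     stringsAsFactors = FALSE)
  gate <- methyl_df("IHG")
  expect_equal(subtypeHgg(bndl("High-grade glioma", methyl = gate,
                               fusions = fus("PPP1CB", "ALK")),
                          rules, th)$label, "IHG, ALK-altered")
  expect_equal(subtypeHgg(bndl("High-grade glioma", methyl = gate,
                               fusions = fus("NTRK3", "X")),
                          rules, th)$label, "IHG, NTRK-altered")
  expect_equal(subtypeHgg(bndl("High-grade glioma", methyl = gate),
                          rules, th)$label, "IHG, To be classified")
})

test_that("ATRT subtyping is methylation-only with a confidence gate", {
  expect_equal(subtypeAtrt(bndl("Atypical Teratoid Rhabdoid Tumor",
                                methyl = methyl_df("ATRT_MYC", 0.9)),
                           rules, th)$label, "ATRT, MYC")
  expect_equal(subtypeAtrt(bndl("Atypical Teratoid Rhabdoid Tumor",
                                methyl = methyl_df("ATRT_MYC", 0.79)),
                           rules, th)$label, "ATRT, To be classified")
})

test_that("NBL precedence: DNA, then free-text conflict via TPM cutoff", {
  gs_amp <- data.frame(sample_id = "S1", gene = "MYCN",
                       status = "amplification", stringsAsFactors = FALSE)
  gs_neu <- data.frame(sample_id = "S1", gene = "MYCN",
                       status = "neutral", stringsAsFactors = FALSE)
  expect_equal(subtypeNbl(bndl("Neuroblastoma", geneStatus = gs_amp),
                          rules, th)$label, "NBL, MYCN amplified")
  # free text claims amplified, genetics says no: TPM decides, boundary in
  conflict <- bndl("Neuroblastoma", free_text = "nbl, mycn amplified",
                   geneStatus = gs_neu,
                   exprTpm = c(MYCN = 140.83))
  expect_equal(subtypeNbl(conflict, rules, th)$label,
               "NBL, MYCN amplified")
  below <- bndl("Neuroblastoma", free_text = "nbl, mycn amplified",
                geneStatus = gs_neu, exprTpm = c(MYCN = 140.82))
  expect_equal(subtypeNbl(below, rules, th)$label,
               "NBL, MYCN non-amplified")
  # no DNA at all: cutoff alone
  expect_equal(subtypeNbl(bndl("Neuroblastoma",
                               exprTpm = c(MYCN = 200)),
                          rules, th)$label, "NBL, MYCN amplified")
  expect_equal(subtypeNbl(bndl("Neuroblastoma"), rules, th)$label,
               "NBL, To be classified")
})

test_that("EPN criteria apply in their listed order", {
  gs_amp <- data.frame(sample_id = "S1", gene = "MYCN",
                       status = "amplification", stringsAsFactors = FALSE)
  fus <- data.frame(sample_id = "S1", gene5 = "YAP1", gene3 = "MAMLD1",
                    caller = "arriba", cancer_group = "EPN",
                    annotations = "", stringsAsFactors = FALSE)
  # spinal MYCN outranks a YAP1 fusion that also matches
  b <- bndl("Ependymoma", site = "spinal", geneStatus = gs_amp,
            fusions = fus)
  expect_equal(subtypeEpn(b, rules, th)$label, "EPN, SP-MYCN")
  expect_equal(subtypeEpn(bndl("Ependymoma", fusions = fus),
                          rules, th)$label, "EPN, ST YAP1")
  # 1q gain + TKTL1 over-expression
  arm <- data.frame(sample_id = "S1", arm = "1q", direction = "gain",
                    fraction = 0.8, stringsAsFactors = FALSE)
  flags <- data.frame(sample_id = "S1", gene = "TKTL1", over = TRUE,
                      under = FALSE, stringsAsFactors = FALSE)
  expect_equal(subtypeEpn(bndl("Ependymoma", armEvents = arm,
                               exprFlags = flags), rules, th)$label,
               "EPN, PF A")
  # the generic EPN_SP class must not be confused with EPN_SP_SE
  expect_equal(subtypeEpn(bndl("Ependymoma",
                               methyl = methyl_df("EPN_SP_SE")),
                          rules, th)$label, "EPN, SP SE")
})

test_that("MB SHH tie-break sends a young 2p-gain tumor to gamma", {
  arm2p <- data.frame(sample_id = "S1", arm = "2p", direction = "gain",
                      fraction = 0.9, stringsAsFactors = FALSE)
  b <- bndl("Medulloblastoma", age = 3, methyl = methyl_df("MB_SHH"),
            armEvents = arm2p)
  expect_equal(subtypeMb(b, rules, th)$label, "MB, SHH gamma")
  # with an additional beta-specific lesion, beta wins the fixed order
  kmt2d <- mk_var(gene = "KMT2D", variant_class = "Nonsense_Mutation")
  b2 <- bndl("Medulloblastoma", age = 3, methyl = methyl_df("MB_SHH"),
             armEvents = arm2p, variants = kmt2d)
  expect_equal(subtypeMb(b2, rules, th)$label, "MB, SHH beta")
})

test_that("MB falls back to the RNA classifier and flags disagreement", {
  b <- bndl("Medulloblastoma")
  b_rna <- evidenceBundle(cbind(spec_row(), rna_subtype_label = "Group4"),
                          rnaSubtype = "Group4")
  expect_equal(subtypeMb(b_rna, rules, th)$label, "MB, Group4")
  expect_equal(subtypeMb(b, rules, th)$label, "MB, To be classified")
  disagree <- evidenceBundle(spec_row(), methyl = methyl_df("MB_WNT"),
                             rnaSubtype = "Group3")
  res <- subtypeMb(disagree, rules, th)
  expect_equal(res$label, "MB, WNT")   # methylation wins
  expect_true(res$review)
})

test_that("perturbing one methylation score across 0.80 flips only its rule", {
  b_hi <- bndl("Pineoblastoma", methyl = methyl_df("PB_FOXR2", 0.80))
  b_lo <- bndl("Pineoblastoma", methyl = methyl_df("PB_FOXR2", 0.79))
  expect_equal(subtypePb(b_hi, rules, th)$label,
               "Pineoblastoma, MYC/FOXR2-activated")
  expect_equal(subtypePb(b_lo, rules, th)$label, "PB, To be classified")
  # a rule not citing methylation is untouched by the same perturbation
  fus <- data.frame(sample_id = "S1", gene5 = "ZFTA", gene3 = "RELA",
                    caller = "arriba", cancer_group = "EPN",
                    annotations = "", stringsAsFactors = FALSE)
  e_hi <- bndl("Ependymoma", fusions = fus,
               methyl = methyl_df("PB_FOXR2", 0.80))
  e_lo <- bndl("Ependymoma", fusions = fus,
               methyl = methyl_df("PB_FOXR2", 0.79))
  expect_equal(subtypeEpn(e_hi, rules, th)$label,
               subtypeEpn(e_lo, rules, th)$label)
})

test_that("ETMR logic distinguishes C19MC-altered from NOS", {
  fus <- data.frame(sample_id = "S1", gene5 = "TTYH1", gene3 = "LRRC4B",
                    caller = "arriba", cancer_group = "EMB",
                    annotations = "", stringsAsFactors = FALSE)
  lin <- data.frame(sample_id = "S1", gene = "LIN28A", over = TRUE,
                    under = FALSE, stringsAsFactors = FALSE)
  expect_equal(subtypeEtmr(bndl("Embryonal tumor", fusions = fus,
                                exprFlags = lin), rules, th)$label,
               "ETMR, C19MC-altered")
  expect_equal(subtypeEtmr(bndl("Embryonal tumor", exprFlags = lin),
                           rules, th)$label, "ETMR, NOS")
  expect_equal(subtypeEtmr(bndl("Embryonal tumor"), rules, th)$label,
               "EMB, To be classified")
})

test_that("uncovered histologies pass through without a subtype", {
  bundles <- buildEvidenceBundles(spec_row(diagnosis = "Osteosarcoma"))
  out <- runSubtyping(bundles, rules, th)
  expect_true(is.na(out$molecular_subtype))
  expect_equal(out$fired_rules, "uncovered_histology")
})
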