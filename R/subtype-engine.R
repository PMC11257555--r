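#' @include subtype-rules.R tp53.R
NULL

.result <- function(label, fired, review = FALSE) {
  list(label = label, fired = fired, review = review)
}

#' High-grade glioma subtyping
#'
#' Ordered criteria, first match wins: H3 K28-altered diffuse midline
#' glioma (p.K28M/p.K28I in a histone H3 gene, or high-confidence DMG
#' methylation class); oligodendroglioma IDH-mutant; oligosarcoma
#' IDH-mutant; PXA (methylation or free-text gate AND BRAF V600E AND
#' CDKN2A/CDKN2B deep deletion); DHG H3 G35; HGG IDH; HGG H3 wild type
#' (methylation families); the infant-type hemispheric glioma branch
#' ([subtypeIhg()]); else to-be-classified. When the sample's TP53 status
#' is lost or activated, the status is appended to the label as a suffix.
#'
#' @param bundle an [EvidenceBundle-class].
#' @param rules config from [subtypeRules()].
#' @param thresholds see [defaultThresholds()].
#' @return list with `label`, `fired` (rule ids), `review`.
#' @export
subtypeHgg <- function(bundle, rules = subtypeRules(),
                       thresholds = defaultThresholds()) {
  lb <- rules$labels
  res <- NULL
  h3 <- rules$genes$histone_h3
  if (.has_variant(bundle, h3, protein = c("p.K28M", "p.K28I"))) {
    res <- .result(lb$hgg_dmg, "hgg_dmg_h3_mutation")
  } else if (.methyl_hit(bundle, rules, "hgg_dmg", thresholds)) {
    res <- .result(lb$hgg_dmg, "hgg_dmg_methylation")
  } else if (.methyl_hit(bundle, rules, "hgg_oligo_idh", thresholds)) {
    res <- .result(lb$hgg_oligo_idh, "hgg_oligo_idh_methylation")
  } else if (.methyl_hit(bundle, rules, "hgg_oligosarc_idh", thresholds)) {
    res <- .result(lb$hgg_oligosarc_idh, "hgg_oligosarc_methylation")
  } else if ((.methyl_hit(bundle, rules, "hgg_pxa", thresholds) ||
              .free_text_contains(bundle,
                c("pleomorphic xanthoastrocytoma", "pxa"))) &&
             .has_variant(bundle, "BRAF", protein = "p.V600E") &&
             (.gene_status(bundle, "CDKN2A") %in% "deep deletion" ||
              .gene_status(bundle, "CDKN2B") %in% "deep deletion")) {
    res <- .result(lb$hgg_pxa, "hgg_pxa")
  } else if (.methyl_hit(bundle, rules, "hgg_dhg_g35", thresholds)) {
    res <- .result(lb$hgg_dhg_g35, "hgg_dhg_g35_methylation")
  } else if (.methyl_hit(bundle, rules, "hgg_idh", thresholds)) {
    res <- .result(lb$hgg_idh, "hgg_idh_methylation")
  } else if (.methyl_hit(bundle, rules, "hgg_h3wt", thresholds)) {
    res <- .result(lb$hgg_h3wt, "hgg_h3wt_methylation")
  } else if (.methyl_hit(bundle, rules, "ihg_gate", thresholds) ||
             .free_text_contains(bundle, "infant type hemispheric glioma") ||
             .free_text_contains(bundle, "infant-type hemispheric glioma")) {
    res <- subtypeIhg(bundle, rules, thresholds)
  } else {
    res <- .result(lb$hgg_tbc, "hgg_fallthrough")
  }
  ## TP53 status suffix, part of the HGG subtype framework
  if (nrow(bundle@tp53)) {
    st <- bundle@tp53$status[1]
    if (identical(st, "lost")) {
      res$label <- paste0(res$label, lb$tp53_lost_suffix)
      res$fired <- c(res$fired, "tp53_lost_suffix")
    } else if (identical(st, "activated")) {
      res$label <- paste0(res$label, lb$tp53_activated_suffix)
      res$fired <- c(res$fired, "tp53_activated_suffix")
    }
  }
  res
}

#' Infant-type hemispheric glioma branch
#'
#' Assumes the IHG gate (methylation class "IHG" or free-text diagnosis)
#' already passed; the RTK fusion partner determines the suffix, with no
#' observed fusion giving the to-be-classified label.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeIhg <- function(bundle, rules = subtypeRules(),
                       thresholds = defaultThresholds()) {
  lb <- rules$labels
  g <- rules$genes
  if (.has_fusion_partner(bundle, g$ihg_rtk_alk)) {
    .result(lb$ihg_alk, "ihg_alk_fusion")
  } else if (.has_fusion_partner(bundle, g$ihg_rtk_ntrk)) {
    .result(lb$ihg_ntrk, "ihg_ntrk_fusion")
  } else if (.has_fusion_partner(bundle, g$ihg_rtk_ros1)) {
    .result(lb$ihg_ros1, "ihg_ros1_fusion")
  } else if (.has_fusion_partner(bundle, g$ihg_rtk_met)) {
    .result(lb$ihg_met, "ihg_met_fusion")
  } else {
    .result(lb$ihg_tbc, "ihg_no_fusion")
  }
}

#' Atypical teratoid rhabdoid tumor subtyping
#'
#' Based solely on the DNA methylation classifier: a high-confidence
#' ATRT_MYC / ATRT_SHH / ATRT_TYR subclass maps to the corresponding
#' subtype; low-confidence or absent predictions are to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeAtrt <- function(bundle, rules = subtypeRules(),
                        thresholds = defaultThresholds()) {
  lb <- rules$labels
  if (.methyl_hit(bundle, rules, "atrt_myc", thresholds)) {
    .result("ATRT, MYC", "atrt_myc_methylation")
  } else if (.methyl_hit(bundle, rules, "atrt_shh", thresholds)) {
    .result("ATRT, SHH", "atrt_shh_methylation")
  } else if (.methyl_hit(bundle, rules, "atrt_tyr", thresholds)) {
    .result("ATRT, TYR", "atrt_tyr_methylation")
  } else {
    .result(lb$atrt_tbc, "atrt_low_confidence")
  }
}

#' Neuroblastoma subtyping (MYCN amplification status)
#'
#' Precedence: genomic MYCN amplification wins outright (including over a
#' contradicting free-text diagnosis); a free-text "amplified" claim with
#' non-amplified genetics falls to the MYCN expression cutoff (TPM >=
#' `mycn_tpm_cutoff`, default 140.83, boundary amplified); samples with no
#' DNA are decided by the cutoff alone; with neither DNA nor RNA the tumor
#' is to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeNbl <- function(bundle, rules = subtypeRules(),
                       thresholds = defaultThresholds()) {
  lb <- rules$labels
  status <- .gene_status(bundle, "MYCN")
  tpm <- unname(bundle@exprTpm["MYCN"])
  has_dna <- nrow(bundle@geneStatus) > 0
  has_rna <- !is.na(tpm) && length(tpm) == 1
  by_tpm <- function(fired) {
    if (!has_rna) return(.result(lb$nbl_tbc, c(fired, "nbl_no_rna"),
                                 review = TRUE))
    if (tpm >= thresholds$mycn_tpm_cutoff) {
      .result(lb$nbl_amp, c(fired, "nbl_tpm_above_cutoff"))
    } else {
      .result(lb$nbl_nonamp, c(fired, "nbl_tpm_below_cutoff"))
    }
  }
  if (has_dna) {
    if (identical(status, "amplification")) {
      review <- .free_text_contains(bundle, "mycn non-amplified")
      return(.result(lb$nbl_amp, "nbl_mycn_amplification", review))
    }
    if (.free_text_contains(bundle, "mycn amplified")) {
      return(by_tpm("nbl_freetext_conflict"))
    }
    return(.result(lb$nbl_nonamp, "nbl_mycn_not_amplified"))
  }
  if (has_rna) return(by_tpm("nbl_no_dna"))
  .result(lb$nbl_tbc, "nbl_no_evidence")
}

#' Craniopharyngioma subtyping
#'
#' High-confidence methylation subclass containing CPH_PAP gives the
#' papillary subtype, CPH_ADM the adamantinomatous subtype; otherwise a
#' pre-computed molecular-criteria label supplied on the specimen record
#' is retained; else to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeCranio <- function(bundle, rules = subtypeRules(),
                          thresholds = defaultThresholds()) {
  lb <- rules$labels
  if (.methyl_hit(bundle, rules, "cranio_pap", thresholds)) {
    .result(lb$cranio_pap, "cranio_pap_methylation")
  } else if (.methyl_hit(bundle, rules, "cranio_adam", thresholds)) {
    .result(lb$cranio_adam, "cranio_adam_methylation")
  } else if (!is.na(.precomputed(bundle))) {
    .result(.precomputed(bundle), "cranio_precomputed")
  } else {
    .result(lb$cranio_tbc, "cranio_fallthrough")
  }
}

#' Ependymoma subtyping
#'
#' Ordered criteria, first match wins: spinal MYCN-amplified; ST YAP1
#' (YAP1 fusions); ST ZFTA (ZFTA fusions); PF A (1q gain with TKTL1
#' over-expression, EZHIP over-expression, posterior-fossa H3 K28
#' mutation, or methylation); PF B (6p/6q loss with GPBP1 or IFT46
#' over-expression, or methylation); then the methylation-only MPE,
#' PF SE, SP SE and SP classes; else to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeEpn <- function(bundle, rules = subtypeRules(),
                       thresholds = defaultThresholds()) {
  lb <- rules$labels
  g <- rules$genes
  spinal <- identical(.site(bundle), "spinal")
  pf <- identical(.site(bundle), "posterior fossa")
  if ((spinal && identical(.gene_status(bundle, "MYCN"), "amplification")) ||
      .methyl_hit(bundle, rules, "epn_sp_mycn", thresholds)) {
    return(.result(lb$epn_sp_mycn, "epn_sp_mycn"))
  }
  if (.has_fusion_pair(bundle, "YAP1", g$yap1_partners) ||
      .methyl_hit(bundle, rules, "epn_st_yap1", thresholds)) {
    return(.result(lb$epn_st_yap1, "epn_st_yap1"))
  }
  if (.has_fusion_pair(bundle, "ZFTA", g$zfta_partners) ||
      .methyl_hit(bundle, rules, "epn_st_zfta", thresholds)) {
    return(.result(lb$epn_st_zfta, "epn_st_zfta"))
  }
  if ((.has_arm(bundle, "1q", "gain") && .expr_over(bundle, "TKTL1")) ||
      .expr_over(bundle, "EZHIP") ||
      (pf && .has_variant(bundle, g$histone_h3,
                          protein = c("p.K28M", "p.K28I"))) ||
      .methyl_hit(bundle, rules, "epn_pf_a", thresholds)) {
    return(.result(lb$epn_pf_a, "epn_pf_a"))
  }
  if (((.has_arm(bundle, "6p", "loss") || .has_arm(bundle, "6q", "loss")) &&
       (.expr_over(bundle, "GPBP1") || .expr_over(bundle, "IFT46"))) ||
      .methyl_hit(bundle, rules, "epn_pf_b", thresholds)) {
    return(.result(lb$epn_pf_b, "epn_pf_b"))
  }
  for (key in c("epn_mpe", "epn_pf_se", "epn_sp_se", "epn_sp")) {
    if (.methyl_hit(bundle, rules, key, thresholds)) {
      return(.result(lb[[key]], paste0(key, "_methylation")))
    }
  }
  .result(lb$epn_tbc, "epn_fallthrough")
}

#' Low-grade glioma subtyping
#'
#' High-confidence methylation subclasses map to the seven LGG labels;
#' otherwise a pre-computed molecular-criteria label on the specimen
#' record is retained; else to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeLgg <- function(bundle, rules = subtypeRules(),
                       thresholds = defaultThresholds()) {
  for (key in names(rules$lgg_labels)) {
    if (.methyl_hit(bundle, rules, key, thresholds)) {
      return(.result(rules$lgg_labels[[key]], paste0(key, "_methylation")))
    }
  }
  if (!is.na(.precomputed(bundle))) {
    return(.result(.precomputed(bundle), "lgg_precomputed"))
  }
  .result(rules$labels$lgg_tbc, "lgg_fallthrough")
}

#' Medulloblastoma subtyping (major groups + SHH subgroups)
#'
#' High-confidence methylation classes map to the major groups first
#' (MB_SHH* to SHH, MB_G34 I-IV to Group3, V-VIII to Group4, MB_WNT,
#' MB_MYO); without methylation the external transcriptomic classifier
#' label is used. SHH tumors are refined by [subtypeMbShh()]. A
#' disagreement between methylation and RNA labels sets the review flag
#' (methylation wins).
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeMb <- function(bundle, rules = subtypeRules(),
                      thresholds = defaultThresholds()) {
  lb <- rules$labels
  meth_group <- NULL
  for (key in c("mb_shh", "mb_g3", "mb_g4", "mb_wnt", "mb_myo")) {
    if (.methyl_hit(bundle, rules, key, thresholds)) {
      meth_group <- key
      break
    }
  }
  rna <- if (length(bundle@rnaSubtype)) bundle@rnaSubtype[1] else NA_character_
  rna_key <- switch(if (is.na(rna)) "none" else rna,
                    SHH = "mb_shh", Group3 = "mb_g3", Group4 = "mb_g4",
                    WNT = "mb_wnt", "none")
  review <- !is.null(meth_group) && rna_key != "none" &&
    meth_group != rna_key
  group <- if (!is.null(meth_group)) meth_group
           else if (rna_key != "none") rna_key else NA_character_
  if (is.na(group)) return(.result(lb$mb_tbc, "mb_no_classification"))
  fired <- if (!is.null(meth_group)) paste0(group, "_methylation")
           else paste0(group, "_rna_classifier")
  if (group == "mb_shh") {
    res <- subtypeMbShh(bundle, rules, thresholds)
    res$fired <- c(fired, res$fired)
    res$review <- res$review || review
    return(res)
  }
  .result(lb[[group]], fired, review)
}

## evaluate the molecular (non-methylation) criteria for one SHH subgroup;
## returns a character vector of fired criterion ids (empty = no match)
.mb_shh_criteria <- function(bundle, subgroup, rules, th) {
  g <- rules$genes
  age <- .age(bundle)
  lof <- rules$lof_classes
  fired <- character()
  if (subgroup == "alpha" && !is.na(age) && age >= th$mb_age_alpha) {
    amp <- any(vapply(g$mb_shh_alpha_amp, function(gn) {
      identical(.gene_status(bundle, gn), "amplification") ||
        .expr_over(bundle, gn)
    }, TRUE))
    if (amp) fired <- c(fired, "mycn_gli2_ccnd2_amp_or_over")
    if (.germline_has(bundle, "ELP1") || .germline_has(bundle, "TP53_LFS")) {
      fired <- c(fired, "germline_elp1_tp53")
    }
    if (.has_variant(bundle, "TP53", hotspot = TRUE)) {
      fired <- c(fired, "tp53_hotspot")
    }
    if (.has_arm(bundle, "9p", "gain") || .has_arm(bundle, "17p", "loss")) {
      fired <- c(fired, "chr9p_gain_or_17p_loss")
    }
  }
  if (subgroup == "beta" && !is.na(age) && age < th$mb_age_beta_gamma) {
    if (.has_variant(bundle, "KMT2D", classes = lof)) {
      fired <- c(fired, "kmt2d_lof")
    }
    if (.gene_status(bundle, "PTEN") %in% c("loss", "deep deletion") ||
        .expr_under(bundle, "PTEN")) {
      fired <- c(fired, "pten_loss_or_under")
    }
    if (.has_arm(bundle, "2p", "gain") || .has_arm(bundle, "2q", "gain")) {
      fired <- c(fired, "chr2_gain")
    }
  }
  if (subgroup == "gamma" && !is.na(age) && age < th$mb_age_beta_gamma) {
    if (.has_arm(bundle, "2p", "gain")) fired <- c(fired, "chr2p_gain")
  }
  if (subgroup == "delta" && !is.na(age) && age >= th$mb_age_delta) {
    if (.has_variant(bundle, c("DDX3X", "SMO"), classes = lof)) {
      fired <- c(fired, "ddx3x_smo_lof")
    }
    if (.has_variant(bundle, g$tert_u1, hotspot = TRUE)) {
      fired <- c(fired, "tert_u1_hotspot")
    }
    if (.has_arm(bundle, "14q", "loss")) fired <- c(fired, "chr14q_loss")
  }
  fired
}

#' SHH-activated medulloblastoma subgroup refinement
#'
#' The methylation shortcut decides first (high-confidence MB_SHH_3 ->
#' alpha, MB_SHH_1 -> beta, MB_SHH_2 -> gamma, MB_SHH_4 -> delta);
#' otherwise the age-gated molecular criteria are evaluated. When several
#' subgroups match, precedence is by specificity: the chromosome-2p
#' collision (a young patient's 2p gain satisfies both beta and gamma)
#' resolves to gamma when the gain is beta's only fired criterion, since
#' gamma's condition is the stricter subset; residual ties break
#' alpha > beta > gamma > delta. No match leaves the unrefined SHH label.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeMbShh <- function(bundle, rules = subtypeRules(),
                         thresholds = defaultThresholds()) {
  lb <- rules$labels
  for (sg in c("alpha", "beta", "gamma", "delta")) {
    key <- paste0("mb_shh_", sg)
    if (.methyl_hit(bundle, rules, key, thresholds)) {
      return(.result(lb[[key]], paste0(key, "_methylation")))
    }
  }
  fired <- lapply(c(alpha = "alpha", beta = "beta", gamma = "gamma",
                    delta = "delta"), function(sg) {
    .mb_shh_criteria(bundle, sg, rules, thresholds)
  })
  matched <- names(fired)[vapply(fired, length, 0L) > 0]
  if (!length(matched)) return(.result(lb$mb_shh, "mb_shh_unrefined"))
  if (setequal(matched, c("beta", "gamma")) &&
      identical(fired$beta, "chr2_gain")) {
    pick <- "gamma"
  } else {
    pick <- matched[order(match(matched,
                                c("alpha", "beta", "gamma", "delta")))][1]
  }
  .result(lb[[paste0("mb_shh_", pick)]],
          paste0("mb_shh_", pick, "_", fired[[pick]]))
}

#' Pineoblastoma subtyping
#'
#' High-confidence methylation classes map PB_FOXR2, PB_RB1, PB_GRP1A/B
#' and PB_GRP2 to their subtypes; everything else is to-be-classified.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypePb <- function(bundle, rules = subtypeRules(),
                      thresholds = defaultThresholds()) {
  lb <- rules$labels
  for (key in c("pb_foxr2", "pb_rb1", "pb_grp1", "pb_grp2")) {
    if (.methyl_hit(bundle, rules, key, thresholds)) {
      return(.result(lb[[key]], paste0(key, "_methylation")))
    }
  }
  .result(lb$pb_tbc, "pb_fallthrough")
}

#' Embryonal tumor (non-MB, non-ATRT) subtyping
#'
#' ETMR C19MC-altered: high-confidence ETMR_C19MC methylation class, or a
#' TTYH1 fusion together with chromosome 19 amplification (arm-level gain)
#' or LIN28A over-expression; takes precedence over ETMR NOS (LIN28A
#' over-expression without a TTYH1 fusion). Otherwise the embryonal
#' rule set falls through to its to-be-classified label.
#'
#' @inheritParams subtypeHgg
#' @return list with `label`, `fired`, `review`.
#' @export
subtypeEtmr <- function(bundle, rules = subtypeRules(),
                        thresholds = defaultThresholds()) {
  lb <- rules$labels
  ttyh1 <- .has_fusion_partner(bundle, "TTYH1")
  chr19_amp <- .has_arm(bundle, "19p", "gain") ||
    .has_arm(bundle, "19q", "gain")
  lin28a <- .expr_over(bundle, "LIN28A")
  if (.methyl_hit(bundle, rules, "etmr_c19mc", thresholds)) {
    return(.result(lb$etmr_c19mc, "etmr_c19mc_methylation"))
  }
  if (ttyh1 && (chr19_amp || lin28a)) {
    return(.result(lb$etmr_c19mc, "etmr_ttyh1_fusion"))
  }
  if (lin28a && !ttyh1) {
    return(.result(lb$etmr_nos, "etmr_nos_lin28a"))
  }
  .result(lb$emb_tbc, "emb_fallthrough")
}
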