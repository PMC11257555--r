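#' @include containers.R io-maf.R io-seg.R
NULL

## ---- toy genome ------------------------------------------------------
## Nine miniature 10-Mb chromosomes named after the real chromosomes the
## subtyping rules cite, so arm events (1q, 2p/2q, 6q, 9p, 14q, 17p, 19q)
## exist at desk scale. p arm = [1, 4.5e6], q arm = [5.5e6, 1e7].

.TOY_CHROM_LEN <- 1e7
.TOY_CHROMS <- paste0("chr", c(1, 2, 3, 6, 9, 14, 17, 19))

#' Toy genome arm table
#'
#' @return `data.frame` with `chrom`, `arm`, `start`, `end` (1-based
#'   inclusive).
#' @export
toyArms <- function() {
  data.frame(
    chrom = rep(.TOY_CHROMS, each = 2),
    arm = rep(c("p", "q"), times = length(.TOY_CHROMS)),
    start = rep(c(1L, 5500001L), times = length(.TOY_CHROMS)),
    end = rep(c(4500000L, as.integer(.TOY_CHROM_LEN)),
              times = length(.TOY_CHROMS)),
    stringsAsFactors = FALSE
  )
}

#' Toy gene model
#'
#' Synthetic placement of the genes the rule engine consults, on the toy
#' genome (positions bear no relation to the real loci). 20-kb genes.
#'
#' @return `data.frame` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
toyGeneModel <- function() {
  g <- function(gene, chrom, start) {
    data.frame(gene = gene, chrom = chrom, start = as.integer(start),
               end = as.integer(start + 19999), stringsAsFactors = FALSE)
  }
  rbind(
    g("RNU1-1", "chr1", 1.0e6), g("TKTL1", "chr1", 1.1e6),
    g("EZHIP", "chr1", 1.2e6), g("GPBP1", "chr1", 1.3e6),
    g("IFT46", "chr1", 1.4e6), g("LIN28A", "chr1", 1.5e6),
    g("ALK", "chr2", 1.0e6), g("MYCN", "chr2", 2.0e6),
    g("GLI2", "chr2", 7.0e6),
    g("CCND2", "chr3", 1.0e6), g("BRAF", "chr3", 1.2e6),
    g("KMT2D", "chr3", 1.4e6), g("DDX3X", "chr3", 1.6e6),
    g("PTEN", "chr3", 1.8e6), g("TERT", "chr3", 2.0e6),
    g("YAP1", "chr3", 2.2e6), g("MAMLD1", "chr3", 2.4e6),
    g("MAML2", "chr3", 2.6e6), g("FAM118B", "chr3", 2.8e6),
    g("ZFTA", "chr3", 3.0e6), g("RELA", "chr3", 3.2e6),
    g("TTYH1", "chr3", 3.4e6), g("NTRK1", "chr3", 3.6e6),
    g("NTRK2", "chr3", 3.8e6), g("ROS1", "chr3", 4.0e6),
    g("MET", "chr3", 4.2e6), g("SMO", "chr3", 4.4e6),
    g("LRRC4B", "chr3", 4.6e6),
    g("HIST1H3B", "chr6", 1.0e6), g("HIST1H3C", "chr6", 1.1e6),
    g("H3F3A", "chr6", 1.2e6), g("HIST2H3C", "chr6", 1.3e6),
    g("CDKN2A", "chr9", 1.5e6), g("CDKN2B", "chr9", 1.6e6),
    g("TP53", "chr17", 1.0e6)
  )
}

## surveyed footprint (all on chr3 q, away from genes and the CNV noise
## zone): per-caller effectively surveyed regions differ slightly so the
## intersection is a proper subset
.SURVEYED <- list(
  strelka2 = c(8000001L, 9000000L),
  mutect2 = c(8000001L, 8980000L),
  vardict = c(8020001L, 9000000L)
)
## CDS: 50 blocks of 2 kb inside the intersection
.toy_cds <- function() {
  starts <- as.integer(seq(8050001, by = 18000, length.out = 50))
  data.frame(chrom = "chr3", start = starts, end = starts + 1999L,
             stringsAsFactors = FALSE)
}
.CNV_NOISE_ZONE <- c(6000001L, 7400000L)   # chr3
.BLACKLIST_ZONE <- c(7600001L, 7800000L)   # chr3

## ---- lesion catalog --------------------------------------------------

#' Default lesion plan: one tumor event per subtyping rule
#'
#' Each row plans one synthetic tumor event: its histology, the injected
#' subtype-defining lesion, the clinical fields the rules consult and the
#' expected molecular subtype. Covers every rule of every histology rule
#' set, plus to-be-classified fall-throughs and padding events.
#'
#' @return `data.frame`, one row per event.
#' @export
defaultLesionPlan <- function() {
  r <- function(histology, lesion, expected, age = 8, site = "hemispheric",
                free_text = NA_character_, germline = NA_character_,
                strategy = "WGS;RNA-Seq", rna_label = NA_character_,
                precomputed = NA_character_) {
    data.frame(histology = histology, lesion = lesion, expected = expected,
               age = age, site = site, free_text = free_text,
               germline = germline, strategy = strategy,
               rna_label = rna_label, precomputed = precomputed,
               stringsAsFactors = FALSE)
  }
  plan <- rbind(
    ## --- high-grade glioma ---
    r("High-grade glioma", "hgg_dmg_mut", "DMG, H3 K28"),
    r("High-grade glioma", "hgg_dmg_meth", "DMG, H3 K28"),
    r("High-grade glioma", "hgg_dmg_tp53",
      "DMG, H3 K28, TP53 lost"),
    r("High-grade glioma", "hgg_oligo_idh", "Oligodendroglioma, IDH-mutant"),
    r("High-grade glioma", "hgg_oligosarc", "Oligosarcoma, IDH-mutant"),
    r("High-grade glioma", "hgg_pxa", "PXA",
      free_text = "consistent with pxa"),
    r("High-grade glioma", "hgg_dhg", "DHG, H3 G35"),
    r("High-grade glioma", "hgg_idh", "HGG, IDH"),
    r("High-grade glioma", "hgg_h3wt", "HGG, H3 wild type"),
    r("High-grade glioma", "ihg_alk", "IHG, ALK-altered", age = 0.5),
    r("High-grade glioma", "ihg_ntrk", "IHG, NTRK-altered", age = 0.7),
    r("High-grade glioma", "ihg_ros1", "IHG, ROS1-altered", age = 0.4),
    r("High-grade glioma", "ihg_met", "IHG, MET-altered", age = 0.6),
    r("High-grade glioma", "ihg_none", "IHG, To be classified", age = 0.9),
    r("High-grade glioma", "none", "HGG, To be classified"),
    ## --- ATRT ---
    r("Atypical Teratoid Rhabdoid Tumor", "atrt_myc", "ATRT, MYC", age = 2),
    r("Atypical Teratoid Rhabdoid Tumor", "atrt_shh", "ATRT, SHH", age = 1),
    r("Atypical Teratoid Rhabdoid Tumor", "atrt_tyr", "ATRT, TYR", age = 3),
    r("Atypical Teratoid Rhabdoid Tumor", "atrt_lowconf",
      "ATRT, To be classified", age = 2),
    ## --- neuroblastoma ---
    r("Neuroblastoma", "nbl_amp_cnv", "NBL, MYCN amplified", age = 3),
    r("Ganglioneuroblastoma", "nbl_nonamp", "NBL, MYCN non-amplified",
      age = 4),
    r("Neuroblastoma", "nbl_tpm", "NBL, MYCN amplified", age = 2,
      strategy = "RNA-Seq"),
    r("Neuroblastoma", "nbl_freetext_conflict", "NBL, MYCN amplified",
      age = 5, free_text = "nbl, mycn amplified"),
    r("Ganglioneuroma", "nbl_none", "NBL, To be classified", age = 6,
      strategy = "Methylation"),
    ## --- craniopharyngioma ---
    r("Craniopharyngioma", "cranio_pap", "CRANIO, PAP", age = 12),
    r("Craniopharyngioma", "cranio_adam", "CRANIO, ADAM", age = 7),
    r("Craniopharyngioma", "cranio_lowconf", "CRANIO, To be classified",
      age = 9),
    r("Craniopharyngioma", "cranio_precomp", "CRANIO, ADAM", age = 8,
      precomputed = "CRANIO, ADAM"),
    ## --- ependymoma ---
    r("Ependymoma", "epn_sp_mycn_site", "EPN, SP-MYCN", site = "spinal"),
    r("Ependymoma", "epn_sp_mycn_meth", "EPN, SP-MYCN"),
    r("Ependymoma", "epn_yap1", "EPN, ST YAP1"),
    r("Ependymoma", "epn_zfta", "EPN, ST ZFTA"),
    r("Ependymoma", "epn_pfa_1q", "EPN, PF A"),
    r("Ependymoma", "epn_pfa_ezhip", "EPN, PF A"),
    r("Ependymoma", "epn_pfa_h3", "EPN, PF A", site = "posterior fossa"),
    r("Ependymoma", "epn_pfa_meth", "EPN, PF A"),
    r("Ependymoma", "epn_pfb_6q", "EPN, PF B"),
    r("Ependymoma", "epn_pfb_meth", "EPN, PF B"),
    r("Ependymoma", "epn_mpe", "EPN, MPE"),
    r("Ependymoma", "epn_pf_se", "EPN, PF SE"),
    r("Ependymoma", "epn_sp_se", "EPN, SP SE"),
    r("Ependymoma", "epn_sp", "EPN, SP", site = "spinal"),
    r("Ependymoma", "none", "EPN, To be classified"),
    ## --- low-grade glioma ---
    r("Low-grade glioma", "lgg_other_mapk", "LGG, other MAPK-altered"),
    r("Low-grade glioma", "lgg_fgfr", "LGG, FGFR-altered"),
    r("Low-grade glioma", "lgg_idh", "LGG, IDH-altered"),
    r("Low-grade glioma", "lgg_myb", "LGG, MYB/MYBL1 fusion"),
    r("Low-grade glioma", "lgg_mapk", "LGG, MAPK-altered"),
    r("Low-grade glioma", "lgg_braf_mapk", "LGG, BRAF- and MAPK-altered"),
    r("Low-grade glioma", "lgg_sega", "SEGA, to be classified"),
    r("Pilocytic astrocytoma", "lgg_precomp", "LGG, BRAF fusion",
      precomputed = "LGG, BRAF fusion"),
    r("Low-grade glioma", "none", "LGG, To be classified"),
    ## --- medulloblastoma ---
    r("Medulloblastoma", "mb_wnt", "MB, WNT", age = 9),
    r("Medulloblastoma", "mb_g3", "MB, Group3", age = 4),
    r("Medulloblastoma", "mb_g4", "MB, Group4", age = 8),
    r("Medulloblastoma", "mb_myo", "MB, MYO", age = 3),
    r("Medulloblastoma", "mb_rna_shh", "MB, SHH", age = 7,
      rna_label = "SHH"),
    r("Medulloblastoma", "mb_shh_alpha_meth", "MB, SHH alpha", age = 6),
    r("Medulloblastoma", "mb_shh_beta_meth", "MB, SHH beta", age = 2),
    r("Medulloblastoma", "mb_shh_gamma_meth", "MB, SHH gamma", age = 1),
    r("Medulloblastoma", "mb_shh_delta_meth", "MB, SHH delta", age = 14),
    r("Medulloblastoma", "mb_shh_alpha_amp", "MB, SHH alpha", age = 8),
    r("Medulloblastoma", "mb_shh_alpha_germline", "MB, SHH alpha", age = 4,
      germline = "ELP1"),
    r("Medulloblastoma", "mb_shh_alpha_tp53hot", "MB, SHH alpha", age = 6),
    r("Medulloblastoma", "mb_shh_alpha_17p", "MB, SHH alpha", age = 3),
    r("Medulloblastoma", "mb_shh_beta_kmt2d", "MB, SHH beta", age = 2),
    r("Medulloblastoma", "mb_shh_beta_pten", "MB, SHH beta", age = 1),
    r("Medulloblastoma", "mb_shh_beta_2q", "MB, SHH beta", age = 4),
    r("Medulloblastoma", "mb_shh_gamma_2p", "MB, SHH gamma", age = 3),
    r("Medulloblastoma", "mb_shh_delta_ddx3x", "MB, SHH delta", age = 12),
    r("Medulloblastoma", "mb_shh_delta_tert", "MB, SHH delta", age = 15),
    r("Medulloblastoma", "mb_shh_delta_14q", "MB, SHH delta", age = 11),
    r("Medulloblastoma", "none", "MB, To be classified", age = 5),
    ## --- pineoblastoma ---
    r("Pineoblastoma", "pb_foxr2", "Pineoblastoma, MYC/FOXR2-activated"),
    r("Pineoblastoma", "pb_rb1", "Pineoblastoma, RB1-altered"),
    r("Pineoblastoma", "pb_grp1", "Pineoblastoma, group 1"),
    r("Pineoblastoma", "pb_grp2", "Pineoblastoma, group 2"),
    r("Pineoblastoma", "pb_lowconf", "PB, To be classified"),
    ## --- embryonal (non-MB, non-ATRT) ---
    r("Embryonal tumor", "etmr_meth", "ETMR, C19MC-altered", age = 2),
    r("Embryonal tumor", "etmr_ttyh1_19", "ETMR, C19MC-altered", age = 1),
    r("Embryonal tumor", "etmr_ttyh1_lin28a", "ETMR, C19MC-altered",
      age = 2),
    r("Embryonal tumor", "etmr_nos", "ETMR, NOS", age = 3),
    r("Embryonal tumor", "none", "EMB, To be classified", age = 4)
  )
  ## padding so every expression cohort is large enough for stable z-scores
  pad <- do.call(rbind, lapply(seq_len(6), function(i) {
    r("Embryonal tumor", "none", "EMB, To be classified", age = 5)
  }))
  plan <- rbind(plan, pad)
  plan$sample_id <- sprintf("BS_%04d", seq_len(nrow(plan)))
  plan$participant_id <- sprintf("PT_%04d", seq_len(nrow(plan)))
  plan$tumor_event_id <- sprintf("EV_%04d", seq_len(nrow(plan)))
  plan
}

## ---- injection helpers ----------------------------------------------

.gene_loc <- function(gene) {
  gm <- toyGeneModel()
  gm[gm$gene == gene, , drop = FALSE]
}

.mk_variant <- function(sample, gene, protein, class = "Missense_Mutation",
                        hotspot = FALSE, offset = 100L) {
  loc <- .gene_loc(gene)
  data.frame(
    sample_id = sample, chrom = loc$chrom, start = loc$start + offset,
    end = loc$start + offset, ref = "C", alt = "T", gene = gene,
    variant_class = class, variant_type = "SNP", protein_change = protein,
    t_depth = 80L, alt_depth = 30L, n_depth = 40L, gnomad_af = NA_real_,
    hotspot = hotspot, stringsAsFactors = FALSE
  )
}

.mk_gene_seg <- function(sample, gene, cn) {
  loc <- .gene_loc(gene)
  data.frame(sample_id = sample, chrom = loc$chrom,
             start = loc$start - 5000L, end = loc$end + 5000L,
             copy_number = as.integer(cn),
             status = cnToStatus(cn), stringsAsFactors = FALSE)
}

.mk_arm_seg <- function(sample, chrom, arm, cn) {
  a <- toyArms()
  a <- a[a$chrom == chrom & a$arm == arm, ]
  data.frame(sample_id = sample, chrom = chrom, start = a$start,
             end = a$end, copy_number = as.integer(cn),
             status = cnToStatus(cn), stringsAsFactors = FALSE)
}

.mk_fusion <- function(sample, gene5, gene3, group,
                       callers = c("arriba", "starfusion")) {
  data.frame(sample_id = sample, gene5 = gene5, gene3 = gene3,
             caller = callers, cancer_group = group, annotations = "",
             stringsAsFactors = FALSE)
}

.mk_methyl <- function(sample, subclass, score) {
  data.frame(sample_id = sample, classifier = "dkfz_v12",
             subclass = subclass, score = score, stringsAsFactors = FALSE)
}

## returns list(variants=, segments=, fusions=, methyl=, expr_over=,
## expr_under=, mycn_tpm=) injected for one event
.inject_lesion <- function(lesion, sample, group) {
  v <- NULL; s <- NULL; f <- NULL; m <- NULL
  over <- character(); under <- character(); mycn <- NA_real_
  add_v <- function(...) v <<- rbind(v, .mk_variant(sample, ...))
  add_s <- function(...) s <<- rbind(s, .mk_gene_seg(sample, ...))
  add_a <- function(...) s <<- rbind(s, .mk_arm_seg(sample, ...))
  add_f <- function(...) f <<- rbind(f, .mk_fusion(sample, ..., group = group))
  add_m <- function(...) m <<- rbind(m, .mk_methyl(sample, ...))
  switch(lesion,
    none = NULL,
    hgg_dmg_mut = add_v("H3F3A", "p.K28M"),
    hgg_dmg_meth = add_m("DMG_K27", 0.92),
    hgg_dmg_tp53 = {
      add_v("H3F3A", "p.K28M")
      add_v("TP53", "p.R175H", hotspot = TRUE, offset = 200L)
    },
    hgg_oligo_idh = add_m("O_IDH", 0.9),
    hgg_oligosarc = add_m("OLIGOSARC_IDH", 0.88),
    hgg_pxa = {
      add_m("PXA", 0.95)
      add_v("BRAF", "p.V600E")
      add_s("CDKN2A", 0)
    },
    hgg_dhg = add_m("DHG_G34", 0.9),
    hgg_idh = add_m("GBM_IDH", 0.9),
    hgg_h3wt = add_m("GBM_MES_TYP", 0.9),
    ihg_alk = { add_m("IHG", 0.9); add_f("PPP1CB", "ALK") },
    ihg_ntrk = { add_m("IHG", 0.9); add_f("NTRK2", "LRRC4B") },
    ihg_ros1 = { add_m("IHG", 0.9); add_f("ROS1", "LRRC4B") },
    ihg_met = { add_m("IHG", 0.9); add_f("MET", "LRRC4B") },
    ihg_none = add_m("IHG", 0.9),
    atrt_myc = add_m("ATRT_MYC", 0.9),
    atrt_shh = add_m("ATRT_SHH", 0.95),
    atrt_tyr = add_m("ATRT_TYR", 0.85),
    atrt_lowconf = add_m("ATRT_MYC", 0.7),
    nbl_amp_cnv = add_s("MYCN", 10),
    nbl_nonamp = { mycn <- 20 },
    nbl_tpm = { mycn <- 500 },
    nbl_freetext_conflict = { mycn <- 500 },
    nbl_none = NULL,
    cranio_pap = add_m("CPH_PAP", 0.9),
    cranio_adam = add_m("CPH_ADM", 0.92),
    cranio_lowconf = add_m("CPH_PAP", 0.5),
    cranio_precomp = NULL,
    epn_sp_mycn_site = add_s("MYCN", 12),
    epn_sp_mycn_meth = add_m("EPN_SP_MYCN", 0.9),
    epn_yap1 = add_f("YAP1", "MAMLD1"),
    epn_zfta = add_f("ZFTA", "RELA"),
    epn_pfa_1q = { add_a("chr1", "q", 3); over <- "TKTL1" },
    epn_pfa_ezhip = { over <- "EZHIP" },
    epn_pfa_h3 = add_v("H3F3A", "p.K28M"),
    epn_pfa_meth = add_m("EPN_PF_A", 0.9),
    epn_pfb_6q = { add_a("chr6", "q", 1); over <- "GPBP1" },
    epn_pfb_meth = add_m("EPN_PF_B", 0.9),
    epn_mpe = add_m("EPN_MPE", 0.9),
    epn_pf_se = add_m("EPN_PF_SE", 0.9),
    epn_sp_se = add_m("EPN_SP_SE", 0.9),
    epn_sp = add_m("EPN_SP", 0.9),
    lgg_other_mapk = add_m("PA_MID", 0.9),
    lgg_fgfr = add_m("PA_INF_FGFR", 0.9),
    lgg_idh = add_m("A_IDH_LG", 0.9),
    lgg_myb = add_m("AG_MYB", 0.9),
    lgg_mapk = add_m("LGG, MAPK", 0.9),
    lgg_braf_mapk = add_m("LGG, BRAF/MAPK", 0.9),
    lgg_sega = add_m("SEGA, To be classified", 0.9),
    lgg_precomp = NULL,
    mb_wnt = add_m("MB_WNT", 0.9),
    mb_g3 = add_m("MB_G34_II", 0.9),
    mb_g4 = add_m("MB_G34_VII", 0.9),
    mb_myo = add_m("MB_MYO", 0.9),
    mb_rna_shh = NULL,
    mb_shh_alpha_meth = add_m("MB_SHH_3", 0.9),
    mb_shh_beta_meth = add_m("MB_SHH_1", 0.9),
    mb_shh_gamma_meth = add_m("MB_SHH_2", 0.9),
    mb_shh_delta_meth = add_m("MB_SHH_4", 0.9),
    mb_shh_alpha_amp = { add_m("MB_SHH", 0.9); add_s("GLI2", 10) },
    mb_shh_alpha_germline = add_m("MB_SHH", 0.9),
    mb_shh_alpha_tp53hot = {
      add_m("MB_SHH", 0.9)
      add_v("TP53", "p.R175H", hotspot = TRUE)
    },
    mb_shh_alpha_17p = { add_m("MB_SHH", 0.9); add_a("chr17", "p", 1) },
    mb_shh_beta_kmt2d = {
      add_m("MB_SHH", 0.9)
      add_v("KMT2D", "p.Q100*", class = "Nonsense_Mutation")
    },
    mb_shh_beta_pten = { add_m("MB_SHH", 0.9); add_s("PTEN", 0) },
    mb_shh_beta_2q = { add_m("MB_SHH", 0.9); add_a("chr2", "q", 3) },
    mb_shh_gamma_2p = { add_m("MB_SHH", 0.9); add_a("chr2", "p", 3) },
    mb_shh_delta_ddx3x = {
      add_m("MB_SHH", 0.9)
      add_v("DDX3X", "p.L50fs", class = "Frame_Shift_Del")
    },
    mb_shh_delta_tert = {
      add_m("MB_SHH", 0.9)
      add_v("TERT", "p.=", class = "5'Flank", hotspot = TRUE)
    },
    mb_shh_delta_14q = { add_m("MB_SHH", 0.9); add_a("chr14", "q", 1) },
    pb_foxr2 = add_m("PB_FOXR2", 0.9),
    pb_rb1 = add_m("PB_RB1", 0.9),
    pb_grp1 = add_m("PB_GRP1B", 0.85),
    pb_grp2 = add_m("PB_GRP2", 0.9),
    pb_lowconf = add_m("PB_RB1", 0.7),
    etmr_meth = add_m("ETMR_C19MC", 0.9),
    etmr_ttyh1_19 = { add_f("TTYH1", "LRRC4B"); add_a("chr19", "q", 10) },
    etmr_ttyh1_lin28a = { add_f("TTYH1", "LRRC4B"); over <- "LIN28A" },
    etmr_nos = { over <- "LIN28A" },
    stop("unknown lesion id: ", lesion)
  )
  list(variants = v, segments = s, fusions = f, methyl = m,
       expr_over = over, expr_under = under, mycn_tpm = mycn)
}

## ---- generator -------------------------------------------------------

## brute-force consensus restatement used for truth values (set algebra
## over keys; deliberately independent of callConsensus)
.truth_consensus <- function(caller_dfs) {
  all <- do.call(rbind, lapply(names(caller_dfs), function(cl) {
    df <- caller_dfs[[cl]]
    if (is.null(df) || !nrow(df)) return(NULL)
    df$caller <- cl
    df
  }))
  if (is.null(all)) return(NULL)
  all$key <- paste(all$sample_id, all$chrom, all$start, all$end,
                   all$ref, all$alt)
  kept <- NULL
  for (k in unique(all$key)) {
    rows <- all[all$key == k, , drop = FALSE]
    n <- length(unique(rows$caller))
    hot <- any(rows$hotspot)
    if (!(n >= 2 || hot)) next
    rec <- rows[1, , drop = FALSE]
    ## germline-leakage restatement
    if (!hot && !is.na(rec$n_depth) && rec$n_depth <= 7 &&
        !is.na(rec$gnomad_af) && rec$gnomad_af > 0.001) next
    kept <- rbind(kept, rec)
  }
  kept
}

## per-bp denominator + numerator tally for truth TMB (chr3-only surveyed
## footprint keeps the enumeration small)
.truth_tmb <- function(consensus, samples, cds) {
  pos_sets <- lapply(.SURVEYED, function(iv) seq.int(iv[1], iv[2]))
  surveyed <- Reduce(intersect, pos_sets)
  cds_pos <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE))
  cds_surv <- intersect(surveyed, cds_pos)
  nonsyn <- nonsynClassifications("default")
  do.call(rbind, lapply(samples, function(s) {
    rows <- consensus[consensus$sample_id == s & consensus$chrom == "chr3", ,
                      drop = FALSE]
    in_all <- rows$start %in% surveyed
    in_cds <- rows$start %in% cds_surv & rows$variant_class %in% nonsyn
    data.frame(
      sample_id = s,
      expected_tmb_all = sum(in_all) / (length(surveyed) / 1e6),
      expected_tmb_coding = sum(in_cds) / (length(cds_surv) / 1e6),
      stringsAsFactors = FALSE
    )
  }))
}

#' Generate a synthetic multi-omic cohort with labeled ground truth
#'
#' Writes, under `dir`, every input file the pipeline consumes: four
#' per-caller MAFs, three per-caller SEG files, a fusion table, an
#' expression matrix, a methylation-prediction table, a histologies
#' table, surveyed/CDS/blacklist/gene BEDs, the arm table, reference gene
#' lists, and a `truth.tsv` with the expected subtype and brute-force
#' expected consensus count and TMB per event. Deterministic for a given
#' seed. Truth values are computed by naive set algebra and per-bp
#' counting inside the generator, never by the pipeline under test.
#'
#' @param dir output directory (created).
#' @param seed RNG seed.
#' @param plan lesion plan from [defaultLesionPlan()] (or a subset).
#' @param passengerMean mean passenger SNVs per WGS sample (Poisson).
#' @param noiseSegs random non-consensus segments per caller per sample.
#' @return invisibly, a list with `dir`, `truth` (`data.frame`) and the
#'   file paths.
#' @export
generateCohort <- function(dir, seed = 1L, plan = defaultLesionPlan(),
                           passengerMean = 30, noiseSegs = 5) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snv_callers <- c("strelka2", "mutect2", "lancet", "vardict")
  cnv_callers <- c("controlfreec", "cnvkit", "gatk")

  caller_variants <- stats::setNames(vector("list", 4), snv_callers)
  caller_segments <- stats::setNames(vector("list", 3), cnv_callers)
  fusions <- NULL
  methyl <- NULL
  expr_over <- list()
  mycn_tpm <- stats::setNames(rep(NA_real_, nrow(plan)), plan$sample_id)

  has_wgs <- grepl("WGS", plan$strategy)
  has_rna <- grepl("RNA-Seq", plan$strategy)

  for (i in seq_len(nrow(plan))) {
    s <- plan$sample_id[i]
    inj <- .inject_lesion(plan$lesion[i], s, plan$histology[i])
    if (!is.null(inj$variants) && has_wgs[i]) {
      for (cl in c("strelka2", "mutect2")) {
        caller_variants[[cl]] <- rbind(caller_variants[[cl]], inj$variants)
      }
    }
    if (!is.null(inj$segments) && has_wgs[i]) {
      for (cl in c("controlfreec", "cnvkit")) {
        caller_segments[[cl]] <- rbind(caller_segments[[cl]], inj$segments)
      }
    }
    if (!is.null(inj$fusions) && has_rna[i]) {
      fusions <- rbind(fusions, inj$fusions)
    }
    if (!is.null(inj$methyl)) methyl <- rbind(methyl, inj$methyl)
    if (length(inj$expr_over)) expr_over[[s]] <- inj$expr_over
    if (!is.na(inj$mycn_tpm)) mycn_tpm[s] <- inj$mycn_tpm

    ## passenger SNVs inside the surveyed footprint
    if (has_wgs[i]) {
      n_pass <- stats::rpois(1, passengerMean)
      if (n_pass > 0) {
        pos <- sample(seq.int(8020001L, 8970000L), n_pass)
        for (p in pos) {
          n_call <- sample(1:4, 1, prob = c(0.35, 0.35, 0.2, 0.1))
          who <- sample(snv_callers, n_call)
          hot <- n_call == 1 && stats::runif(1) < 0.10
          leak <- stats::runif(1) < 0.08
          row <- data.frame(
            sample_id = s, chrom = "chr3", start = p, end = p,
            ref = sample(c("A", "C", "G", "T"), 1), alt = "T",
            gene = sprintf("PSG%02d", sample(1:20, 1)),
            variant_class = sample(c("Missense_Mutation", "Silent",
                                     "Nonsense_Mutation"), 1,
                                   prob = c(0.6, 0.3, 0.1)),
            variant_type = "SNP", protein_change = NA_character_,
            t_depth = sample(30:100, 1), alt_depth = sample(5:25, 1),
            n_depth = if (leak) sample(2:7, 1) else sample(20:60, 1),
            gnomad_af = if (leak) stats::runif(1, 0.002, 0.05)
                        else NA_real_,
            hotspot = hot, stringsAsFactors = FALSE
          )
          for (cl in who) {
            caller_variants[[cl]] <- rbind(caller_variants[[cl]], row)
          }
        }
      }
      ## random non-recurrent CNV noise, confined to a gene-free zone
      for (cl in cnv_callers) {
        k <- noiseSegs
        st <- sample(seq.int(.CNV_NOISE_ZONE[1],
                             .CNV_NOISE_ZONE[2] - 50000L), k)
        caller_segments[[cl]] <- rbind(caller_segments[[cl]], data.frame(
          sample_id = s, chrom = "chr3", start = st,
          end = st + sample(5000:40000, k, replace = TRUE),
          copy_number = sample(c(1L, 3L), k, replace = TRUE),
          status = NA_character_, stringsAsFactors = FALSE
        ))
      }
    }
  }
  for (cl in cnv_callers) {
    if (!is.null(caller_segments[[cl]])) {
      na_st <- is.na(caller_segments[[cl]]$status)
      caller_segments[[cl]]$status[na_st] <-
        cnToStatus(caller_segments[[cl]]$copy_number[na_st])
    }
  }

  ## spurious fusion noise: one caller, seen in two cancer groups
  rna_ids <- plan$sample_id[has_rna]
  noise_samples <- c(rna_ids[1], rna_ids[length(rna_ids)])
  noise_groups <- plan$histology[match(noise_samples, plan$sample_id)]
  fusions <- rbind(fusions,
                   .mk_fusion(noise_samples[1], "NOISE1", "NOISE2",
                              noise_groups[1], callers = "arriba"),
                   .mk_fusion(noise_samples[2], "NOISE1", "NOISE2",
                              noise_groups[2], callers = "arriba"))

  ## ---- expression matrix (marker genes + noise genes) ----
  rna_samples <- plan$sample_id[has_rna]
  marker <- c("TKTL1", "EZHIP", "GPBP1", "IFT46", "LIN28A", "MYCN", "PTEN",
              "GLI2", "CCND2")
  base <- c(TKTL1 = 10, EZHIP = 10, GPBP1 = 10, IFT46 = 10, LIN28A = 10,
            MYCN = 20, PTEN = 100, GLI2 = 15, CCND2 = 15)
  emat <- matrix(rep(base[marker], length(rna_samples)),
                 nrow = length(marker),
                 dimnames = list(marker, rna_samples))
  for (s in names(expr_over)) {
    if (s %in% rna_samples) emat[expr_over[[s]], s] <- 5000
  }
  ok <- !is.na(mycn_tpm[rna_samples])
  emat["MYCN", rna_samples[ok]] <- mycn_tpm[rna_samples[ok]]
  noise_genes <- matrix(round(stats::rlnorm(20 * length(rna_samples), 2, 1), 3),
                        nrow = 20,
                        dimnames = list(sprintf("NSG%02d", 1:20),
                                        rna_samples))
  emat <- rbind(emat, noise_genes)
  ## duplicate-symbol rows exercising the collapse rule
  dup <- matrix(c(rep(1, length(rna_samples)), rep(0, length(rna_samples))),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("NSG01", "NSG02"), rna_samples))
  full <- rbind(emat, dup)
  expr_df <- data.frame(
    ensembl_id = c(sprintf("ENSG%05d", seq_len(nrow(emat))),
                   "ENSG99998", "ENSG99999"),
    gene_symbol = rownames(full),
    full, check.names = FALSE, stringsAsFactors = FALSE,
    row.names = NULL
  )

  ## ---- histologies ----
  hist <- data.frame(
    sample_id = plan$sample_id, participant_id = plan$participant_id,
    tumor_event_id = plan$tumor_event_id,
    experimental_strategy = plan$strategy,
    tumor_descriptor = "Initial CNS Tumor",
    pathology_diagnosis = plan$histology,
    pathology_free_text_diagnosis = plan$free_text,
    age_at_diagnosis_years = plan$age,
    anatomical_site = plan$site,
    germline_flags = plan$germline,
    cancer_group = plan$histology,
    rna_library = "polyA",
    rna_subtype_label = plan$rna_label,
    precomputed_subtype = plan$precomputed,
    stringsAsFactors = FALSE
  )

  ## ---- truth (brute force, generator-side) ----
  cons <- .truth_consensus(caller_variants)
  n_cons <- vapply(plan$sample_id, function(s) {
    if (is.null(cons)) 0L else sum(cons$sample_id == s)
  }, 0L)
  tmb <- .truth_tmb(if (is.null(cons)) {
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), variant_class = character())
  } else cons, plan$sample_id[has_wgs], .toy_cds())
  truth <- data.frame(
    sample_id = plan$sample_id, tumor_event_id = plan$tumor_event_id,
    lesion = plan$lesion, expected_subtype = plan$expected,
    expected_consensus_n = n_cons, stringsAsFactors = FALSE
  )
  truth <- merge(truth, tmb, by = "sample_id", all.x = TRUE, sort = FALSE)
  truth <- truth[order(truth$sample_id), , drop = FALSE]

  ## ---- write everything ----
  paths <- list()
  for (cl in snv_callers) {
    df <- caller_variants[[cl]]
    vs <- variantSet(if (is.null(df)) data.frame() else
      cbind(df, callers = cl, stringsAsFactors = FALSE))
    paths[[paste0("maf_", cl)]] <-
      writeMaf(vs, file.path(dir, paste0(cl, ".maf.tsv")))
  }
  for (cl in cnv_callers) {
    df <- caller_segments[[cl]]
    if (is.null(df)) df <- records(segmentSet())
    df$caller <- cl
    paths[[paste0("seg_", cl)]] <-
      writeSeg(segmentSet(df), file.path(dir, paste0(cl, ".seg.tsv")))
  }
  paths$fusions <- writeTsv(fusions, file.path(dir, "fusions.tsv"))
  paths$methyl <- writeTsv(methyl, file.path(dir, "methylation.tsv"))
  paths$expression <- writeTsv(expr_df, file.path(dir, "expression.tsv"))
  paths$histologies <- writeTsv(hist, file.path(dir, "histologies.tsv"))
  paths$truth <- writeTsv(truth, file.path(dir, "truth.tsv"))

  bed <- function(df1based, file) {
    utils::write.table(
      data.frame(df1based$chrom, df1based$start - 1L, df1based$end),
      file.path(dir, file), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    file.path(dir, file)
  }
  for (cl in names(.SURVEYED)) {
    iv <- .SURVEYED[[cl]]
    paths[[paste0("surveyed_", cl)]] <- bed(
      data.frame(chrom = "chr3", start = iv[1], end = iv[2]),
      paste0("surveyed_", cl, ".bed"))
  }
  paths$cds <- bed(.toy_cds(), "cds.bed")
  paths$blacklist <- bed(
    data.frame(chrom = "chr3", start = .BLACKLIST_ZONE[1],
               end = .BLACKLIST_ZONE[2]), "blacklist.bed")
  gm <- toyGeneModel()
  utils::write.table(
    data.frame(gm$chrom, gm$start - 1L, gm$end, gm$gene),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  paths$genes <- file.path(dir, "genes.bed")
  arms <- toyArms()
  arms$start <- arms$start - 1L
  paths$arms <- writeTsv(arms, file.path(dir, "arms.tsv"))

  ## reference gene lists for fusion annotation
  lists <- list(
    kinase = c("ALK", "NTRK1", "NTRK2", "NTRK3", "ROS1", "MET", "BRAF"),
    oncogene = c("MYCN", "YAP1", "GLI2", "CCND2", "LIN28A"),
    tumor_suppressor = c("TP53", "PTEN", "CDKN2A", "CDKN2B"),
    transcription_factor = c("RELA", "FOXR2"),
    cosmic_census = c("TP53", "BRAF", "ALK", "MYCN", "MAML2"),
    tcga_observed = c("TTYH1", "ZFTA", "MAMLD1")
  )
  for (nm in names(lists)) {
    writeLines(lists[[nm]], file.path(dir, paste0("genes_", nm, ".txt")))
    paths[[paste0("list_", nm)]] <- file.path(dir, paste0("genes_", nm, ".txt"))
  }
  invisible(list(dir = dir, truth = truth, paths = paths))
}
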