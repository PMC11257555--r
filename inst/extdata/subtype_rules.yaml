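# Declarative part of the molecular subtyping engine: pathology-diagnosis
# dispatch, methylation-subclass -> label maps, and output label strings.
# Matching against methylation subclasses is case-sensitive; "type" is one
# of exact / contains / prefix. Edit labels here, not in code.
version: 1

dispatch:
  high-grade glioma: hgg
  glioblastoma: hgg
  diffuse midline glioma: hgg
  diffuse hemispheric glioma: hgg
  infant-type hemispheric glioma: hgg
  atypical teratoid rhabdoid tumor: atrt
  neuroblastoma: nbl
  ganglioneuroblastoma: nbl
  ganglioneuroma: nbl
  craniopharyngioma: cranio
  ependymoma: epn
  low-grade glioma: lgg
  pilocytic astrocytoma: lgg
  medulloblastoma: mb
  pineoblastoma: pb
  embryonal tumor: etmr
  embryonal tumor with multilayered rosettes: etmr

labels:
  hgg_dmg: "DMG, H3 K28"
  hgg_oligo_idh: "Oligodendroglioma, IDH-mutant"
  hgg_oligosarc_idh: "Oligosarcoma, IDH-mutant"
  hgg_pxa: "PXA"
  hgg_dhg_g35: "DHG, H3 G35"
  hgg_idh: "HGG, IDH"
  hgg_h3wt: "HGG, H3 wild type"
  hgg_tbc: "HGG, To be classified"
  ihg_alk: "IHG, ALK-altered"
  ihg_ntrk: "IHG, NTRK-altered"
  ihg_ros1: "IHG, ROS1-altered"
  ihg_met: "IHG, MET-altered"
  ihg_tbc: "IHG, To be classified"
  atrt_tbc: "ATRT, To be classified"
  nbl_amp: "NBL, MYCN amplified"
  nbl_nonamp: "NBL, MYCN non-amplified"
  nbl_tbc: "NBL, To be classified"
  cranio_pap: "CRANIO, PAP"
  cranio_adam: "CRANIO, ADAM"
  cranio_tbc: "CRANIO, To be classified"
  epn_sp_mycn: "EPN, SP-MYCN"
  epn_st_yap1: "EPN, ST YAP1"
  epn_st_zfta: "EPN, ST ZFTA"
  epn_pf_a: "EPN, PF A"
  epn_pf_b: "EPN, PF B"
  epn_mpe: "EPN, MPE"
  epn_pf_se: "EPN, PF SE"
  epn_sp_se: "EPN, SP SE"
  epn_sp: "EPN, SP"
  epn_tbc: "EPN, To be classified"
  lgg_tbc: "LGG, To be classified"
  mb_shh: "MB, SHH"
  mb_g3: "MB, Group3"
  mb_g4: "MB, Group4"
  mb_wnt: "MB, WNT"
  mb_myo: "MB, MYO"
  mb_tbc: "MB, To be classified"
  mb_shh_alpha: "MB, SHH alpha"
  mb_shh_beta: "MB, SHH beta"
  mb_shh_gamma: "MB, SHH gamma"
  mb_shh_delta: "MB, SHH delta"
  pb_foxr2: "Pineoblastoma, MYC/FOXR2-activated"
  pb_rb1: "Pineoblastoma, RB1-altered"
  pb_grp1: "Pineoblastoma, group 1"
  pb_grp2: "Pineoblastoma, group 2"
  pb_tbc: "PB, To be classified"
  etmr_c19mc: "ETMR, C19MC-altered"
  etmr_nos: "ETMR, NOS"
  emb_tbc: "EMB, To be classified"
  tp53_lost_suffix: ", TP53 lost"
  tp53_activated_suffix: ", TP53 activated"

methylation:
  hgg_dmg:        [{match: "DMG", type: contains}]
  hgg_oligo_idh:  [{match: "O_IDH", type: exact}]
  hgg_oligosarc_idh: [{match: "OLIGOSARC_IDH", type: exact}]
  hgg_pxa:        [{match: "PXA", type: exact}]
  hgg_dhg_g35:    [{match: "DHG_G34", type: contains},
                   {match: "GBM_G34", type: contains}]
  hgg_idh:        [{match: "A_IDH_HG", type: contains},
                   {match: "GBM_IDH", type: contains}]
  hgg_h3wt:       [{match: "GBM_MES", type: contains},
                   {match: "GBM_RTK", type: contains},
                   {match: "HGG_", type: contains},
                   {match: "HGAP", type: contains},
                   {match: "AAP", type: contains},
                   {match: "ped_", type: contains}]
  ihg_gate:       [{match: "IHG", type: exact}]
  atrt_myc:       [{match: "ATRT_MYC", type: exact}]
  atrt_shh:       [{match: "ATRT_SHH", type: exact}]
  atrt_tyr:       [{match: "ATRT_TYR", type: exact}]
  cranio_pap:     [{match: "CPH_PAP", type: contains}]
  cranio_adam:    [{match: "CPH_ADM", type: contains}]
  epn_sp_mycn:    [{match: "EPN_SP_MYCN", type: exact}]
  epn_st_yap1:    [{match: "EPN_ST_YAP1", type: exact}]
  epn_st_zfta:    [{match: "EPN_ST_ZFTA", type: exact}]
  epn_pf_a:       [{match: "EPN_PF_A", type: exact}]
  epn_pf_b:       [{match: "EPN_PF_B", type: exact}]
  epn_mpe:        [{match: "EPN_MPE", type: exact}]
  epn_pf_se:      [{match: "EPN_PF_SE", type: exact}]
  epn_sp_se:      [{match: "EPN_SP_SE", type: exact}]
  epn_sp:         [{match: "EPN_SP", type: exact}]
  lgg_other_mapk: [{match: "PA_MID", type: exact},
                   {match: "PLNTY", type: exact}]
  lgg_fgfr:       [{match: "PA_INF_FGFR", type: exact}]
  lgg_idh:        [{match: "A_IDH_LG", type: exact}]
  lgg_myb:        [{match: "AG_MYB", type: exact},
                   {match: "LGG_MYB", type: exact}]
  lgg_mapk:       [{match: "LGG, MAPK", type: exact}]
  lgg_braf_mapk:  [{match: "LGG, BRAF/MAPK", type: exact}]
  lgg_sega:       [{match: "SEGA, To be classified", type: exact}]
  mb_shh:         [{match: "MB_SHH", type: contains}]
  mb_g3:          [{match: "MB_G34_I", type: exact},
                   {match: "MB_G34_II", type: exact},
                   {match: "MB_G34_III", type: exact},
                   {match: "MB_G34_IV", type: exact}]
  mb_g4:          [{match: "MB_G34_V", type: exact},
                   {match: "MB_G34_VI", type: exact},
                   {match: "MB_G34_VII", type: exact},
                   {match: "MB_G34_VIII", type: exact}]
  mb_wnt:         [{match: "MB_WNT", type: exact}]
  mb_myo:         [{match: "MB_MYO", type: exact}]
  mb_shh_alpha:   [{match: "MB_SHH_3", type: exact}]
  mb_shh_beta:    [{match: "MB_SHH_1", type: exact}]
  mb_shh_gamma:   [{match: "MB_SHH_2", type: exact}]
  mb_shh_delta:   [{match: "MB_SHH_4", type: exact}]
  pb_foxr2:       [{match: "PB_FOXR2", type: exact}]
  pb_rb1:         [{match: "PB_RB1", type: exact}]
  pb_grp1:        [{match: "PB_GRP1A", type: exact},
                   {match: "PB_GRP1B", type: exact}]
  pb_grp2:        [{match: "PB_GRP2", type: exact}]
  etmr_c19mc:     [{match: "ETMR_C19MC", type: exact}]

lgg_labels:
  lgg_other_mapk: "LGG, other MAPK-altered"
  lgg_fgfr: "LGG, FGFR-altered"
  lgg_idh: "LGG, IDH-altered"
  lgg_myb: "LGG, MYB/MYBL1 fusion"
  lgg_mapk: "LGG, MAPK-altered"
  lgg_braf_mapk: "LGG, BRAF- and MAPK-altered"
  lgg_sega: "SEGA, to be classified"

genes:
  histone_h3: [H3F3A, HIST1H3B, HIST1H3C, HIST2H3C]
  ihg_rtk_alk: [ALK]
  ihg_rtk_ntrk: [NTRK1, NTRK2, NTRK3]
  ihg_rtk_ros1: [ROS1]
  ihg_rtk_met: [MET]
  yap1_partners: [MAMLD1, MAML2, FAM118B]
  zfta_partners: [RELA, MAML2]
  mb_shh_alpha_amp: [MYCN, GLI2, CCND2]
  tert_u1: [TERT, RNU1-1]

lof_classes: [Nonsense_Mutation, Frame_Shift_Del, Frame_Shift_Ins,
              Splice_Site, Nonstop_Mutation, Translation_Start_Site]
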