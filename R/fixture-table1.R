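## A deterministic, hand-allocated synthetic cohort of 2,002 patients whose
## route tallies reproduce the published cohort summary exactly: 430
## diagnosed patients (21.5% yield); 378 unique (L)P variants in 369
## patients on the case-excess/EF route, 354 of them concordant (94%), 15
## founder-flagged among the 24 discordant (4% of 378); 22 (L)Ps on the
## gnomAD route, 12 concordant (55%); 92 unique selected VUSs in 143
## patients on the CE/EF route (113 undiagnosed, 5.6%); 37 unique gnomAD-
## route VUSs in 42 patients (19 undiagnosed, 1%); 23 unique VUSs
## reclassified to LP in 28 patients, 25 of whom gain a first diagnosis
## (+1.2% yield); 106 unique VUSs prioritized (5.3%); 132 undiagnosed
## patients selected in total (6.6%).
##
## The allocation is explicit tally bookkeeping, not simulation, so that
## end-to-end pipeline tests are exact. Patient/variant identifiers and the
## gene symbols are synthetic; the per-gene EF values are plausible
## stand-ins, chosen only to drive each variant through the intended
## decision branch.

#' Packaged cohort fixture reproducing the published summary statistics
#'
#' Builds (in code, deterministically) a cohort of 2,002 patients and the
#' matching constraint table such that [validate_lp_concordance()],
#' [triage_vus()] and [build_report()] reproduce every cell of the
#' published cohort summary table and the headline results (see the
#' package vignette for the full list). Useful as an end-to-end regression
#' anchor and as a worked example of the expected input formats.
#'
#' @return a list with elements `variants` (2,002-patient variant table)
#'   and `constraints` (the constraint table), both validated.
#' @examples
#' \donttest{
#' fx <- table1_fixture()
#' summary(triage_cohort(fx$variants, fx$constraints))
#' }
#' @export
table1_fixture <- function() {
  ## ---- constraint table ----
  ce <- function(gene, subtype, cls, has_ce, ef = NA_real_,
                 cil = NA_real_, cih = NA_real_,
                 rs = NA_integer_, re = NA_integer_,
                 pli = NA_real_, misz = NA_real_) {
    data.frame(gene = gene, subtype = subtype, variant_class = cls,
               has_case_excess = has_ce, ef = ef,
               ef_ci_low = cil, ef_ci_high = cih,
               region_start = as.integer(rs), region_end = as.integer(re),
               pli = pli, mis_z = misz, stringsAsFactors = FALSE)
  }
  tr <- "truncating"; nt <- "non_truncating"
  constraints <- rbind(
    ## HCM: 14 genes with case excess
    ce("MYBPC3", "HCM", tr, TRUE, 0.97, 0.94, 0.99),
    ce("MYH7", "HCM", nt, TRUE, 0.97, 0.95, 0.98, rs = 181, re = 937),
    ce("MYH7", "HCM", nt, TRUE, 0.85),
    ce("TNNT2", "HCM", nt, TRUE, 0.92),
    ce("TNNI3", "HCM", nt, TRUE, 0.93),
    ce("TPM1", "HCM", nt, TRUE, 0.91),
    ce("MYL2", "HCM", nt, TRUE, 0.85),
    ce("MYL3", "HCM", nt, TRUE, 0.84),
    ce("ACTC1", "HCM", nt, TRUE, 0.88),
    ce("CSRP3", "HCM", nt, TRUE, 0.82),
    ce("TNNC1", "HCM", nt, TRUE, 0.81),
    ce("PLN", "HCM", nt, TRUE, 0.87),
    ce("FLNC", "HCM", nt, TRUE, 0.56),
    ce("JPH2", "HCM", nt, TRUE, 0.83),
    ce("ALPK3", "HCM", tr, TRUE, 0.86),
    ce("MYH7", "HCM", tr, FALSE),   # analysed, no excess
    ce("TNNT2", "HCM", tr, FALSE),
    ## DCM: 14 genes with case excess
    ce("TTN", "DCM", tr, TRUE, 0.93, 0.90, 0.95),
    ce("LMNA", "DCM", tr, TRUE, 0.97),
    ce("LMNA", "DCM", nt, TRUE, 0.91),
    ce("DSP", "DCM", tr, TRUE, 0.94),
    ce("FLNC", "DCM", tr, TRUE, 0.92),
    ce("RBM20", "DCM", nt, TRUE, 0.91),
    ce("BAG3", "DCM", tr, TRUE, 0.95),
    ce("TNNT2", "DCM", nt, TRUE, 0.86),
    ce("SCN5A", "DCM", nt, TRUE, 0.75),
    ce("DES", "DCM", nt, TRUE, 0.80),
    ce("PLN", "DCM", nt, TRUE, 0.82),
    ce("TNNC1", "DCM", nt, TRUE, 0.88),
    ce("ACTN2", "DCM", nt, TRUE, 0.65),
    ce("NEXN", "DCM", tr, TRUE, 0.70),
    ce("VCL", "DCM", tr, TRUE, 0.72),
    ce("TTN", "DCM", nt, FALSE),
    ce("SCN5A", "DCM", tr, FALSE),
    ## ACM: 5 genes with case excess
    ce("PKP2", "ACM", tr, TRUE, 0.98),
    ce("DSG2", "ACM", tr, TRUE, 0.95),
    ce("DSC2", "ACM", tr, TRUE, 0.93),
    ce("JUP", "ACM", tr, TRUE, 0.88),
    ce("DSP", "ACM", tr, TRUE, 0.94),
    ce("PKP2", "ACM", nt, FALSE),
    ce("DSG2", "ACM", nt, FALSE),
    ## gnomAD-only genes (never burden-analysed)
    ce("MYH6", "ANY", nt, NA, misz = 3.5),
    ce("TMEM43", "ANY", nt, NA, misz = 3.2),
    ce("CASQ2", "ANY", tr, NA, pli = 0.95),
    ce("LAMP2", "ANY", tr, NA, pli = 0.97),
    ce("CRYAB", "ANY", nt, NA, misz = 3.4),
    ce("PRDM16", "LVNC", tr, NA, pli = 0.99),
    ce("MIB1", "LVNC", tr, NA, pli = 0.93),
    ce("HCN4", "LVNC", nt, NA, misz = 3.1),
    ce("TCAP", "ANY", nt, NA, misz = 1.2),
    ce("ANKRD1", "ANY", tr, NA, pli = 0.30),
    ce("LDB3", "ANY", nt, NA, misz = 0.8),
    ce("MYPN", "ANY", tr, NA, pli = 0.10))

  ## ---- bookkeeping ----
  npat <- 0L; nfam <- 0L; last_fam <- ""
  pat_sub <- character(0)
  new_patient <- function(subtype) {
    npat <<- npat + 1L
    if (npat %% 57L == 0L) {           # 35 multi-patient families -> 1967
      fam <- last_fam
    } else {
      nfam <<- nfam + 1L
      fam <- sprintf("FA%04d", nfam)
    }
    last_fam <<- fam
    id <- sprintf("PT%04d", npat)
    pat_sub[id] <<- subtype
    attr(id, "family") <- fam
    pat_fam[id] <<- fam
    id
  }
  pat_fam <- character(0)
  new_patients <- function(n, subtype)
    vapply(seq_len(n), function(i) new_patient(subtype), "")

  vid_ct <- new.env(parent = emptyenv())
  vid <- function(gene) {
    k <- (get0(gene, vid_ct) %||% 0L) + 1L
    assign(gene, k, vid_ct)
    sprintf("%s.c%04d", gene, k)
  }

  rows <- vector("list", 4096L); nr <- 0L
  add <- function(pid, gene, variant_id, cls, prior, af = NA_real_,
                  pos = NA_integer_, insil = TRUE, pheno = TRUE,
                  founder = FALSE) {
    nr <<- nr + 1L
    rows[[nr]] <<- data.frame(
      patient_id = pid, family_id = pat_fam[[pid]],
      subtype = pat_sub[[pid]], gene = gene, variant_id = variant_id,
      variant_class = cls, popmax_af = af,
      protein_position = as.integer(pos),
      insilico_support = insil, phenotype_specific = pheno,
      proband_count = 0L, segregating_meioses = 0L,
      prior_class = prior, founder_flag = founder,
      stringsAsFactors = FALSE)
  }
  lp_class <- function(i) if (i %% 3L == 0L) 5L else 4L  # mix of P and LP

  ## ---- (A) CE/EF-route prior (L)Ps ----
  ## HCM: 169 patients, 172 unique variants, 160 concordant (158 patients)
  hcm <- new_patients(169L, "HCM")
  conc_gene <- rep(c("MYBPC3", "MYH7", "TNNT2", "TNNI3", "TPM1"),
                   c(60L, 50L, 20L, 15L, 15L))
  conc_cls <- ifelse(conc_gene == "MYBPC3", tr, nt)
  conc_pos <- ifelse(conc_gene == "MYH7", 200L + seq_along(conc_gene), NA)
  conc_vid <- vapply(conc_gene, vid, "")
  carrier <- c(hcm[1], hcm[1], hcm[2], hcm[2], hcm[3:158])
  for (k in seq_len(160L))
    add(carrier[k], conc_gene[k], conc_vid[k], conc_cls[k], lp_class(k),
        pos = conc_pos[k])
  disc_gene <- c(rep("MYH7", 7L), rep("TNNT2", 5L))   # truncating: no CE
  disc_pat <- c(hcm[1], hcm[159:169])
  for (k in seq_len(12L))
    add(disc_pat[k], disc_gene[k], vid(disc_gene[k]), tr, lp_class(k),
        founder = k <= 8L)

  ## DCM: 181 patients, 186 unique variants, 177 concordant (178 patients:
  ## one concordant variant is shared by two patients)
  dcm <- new_patients(181L, "DCM")
  spec <- list(c("TTN", tr, 80L), c("LMNA", tr, 20L), c("LMNA", nt, 20L),
               c("DSP", tr, 25L), c("FLNC", tr, 12L), c("RBM20", nt, 20L))
  dg <- unlist(lapply(spec, function(s) rep(s[1], as.integer(s[3]))))
  dc <- unlist(lapply(spec, function(s) rep(s[2], as.integer(s[3]))))
  dv <- vapply(dg, vid, "")
  add(dcm[1], dg[1], dv[1], dc[1], 4L)        # shared concordant variant
  add(dcm[2], dg[1], dv[1], dc[1], 4L)
  for (k in 2:177) add(dcm[k + 1L], dg[k], dv[k], dc[k], lp_class(k))
  e_gene <- c(rep("TTN", 5L), rep("SCN5A", 4L))
  e_cls <- c(rep(nt, 5L), rep(tr, 4L))        # classes without CE
  e_pat <- c(dcm[179:181], dcm[1:6])
  for (k in seq_len(9L))
    add(e_pat[k], e_gene[k], vid(e_gene[k]), e_cls[k], lp_class(k),
        founder = k <= 5L)

  ## ACM: 19 patients, 20 unique variants, 17 concordant
  acm <- new_patients(19L, "ACM")
  ag <- rep(c("PKP2", "DSG2", "DSC2"), c(10L, 4L, 3L))
  for (k in seq_len(17L)) add(acm[k], ag[k], vid(ag[k]), tr, lp_class(k))
  f_gene <- c("PKP2", "PKP2", "DSG2")          # non-truncating: no CE
  f_pat <- c(acm[18], acm[19], acm[1])
  for (k in seq_len(3L))
    add(f_pat[k], f_gene[k], vid(f_gene[k]), nt, lp_class(k),
        founder = k <= 2L)

  ## ---- (B) gnomAD-route prior (L)Ps: 22 patients/variants, 12 concordant
  gn_lp <- list(
    list("HCM", "MYH6", nt, 4L),   # mis_z 3.5 -> concordant
    list("HCM", "TCAP", nt, 2L),   # mis_z 1.2 -> discordant
    list("DCM", "CASQ2", tr, 3L),  # pli 0.95 -> concordant
    list("DCM", "CRYAB", nt, 1L),  # concordant
    list("DCM", "ANKRD1", tr, 2L), # pli 0.30 -> discordant
    list("CM_unclassified", "LAMP2", tr, 2L),  # concordant
    list("CM_unclassified", "LDB3", nt, 3L),   # discordant
    list("LVNC", "PRDM16", tr, 2L),            # concordant
    list("LVNC", "MYPN", tr, 3L))              # discordant
  for (g in gn_lp)
    for (k in seq_len(g[[4]]))
      add(new_patient(g[[1]]), g[[2]], vid(g[[2]]), g[[3]], 4L,
          pheno = g[[1]] != "CM_unclassified")

  ## ---- other diagnosed patients: (L)P in genes outside the table ----
  oth_sub <- rep(c("HCM", "DCM", "ACM", "CM_unclassified", "LVNC"),
                 c(15L, 15L, 2L, 4L, 3L))
  oth_genes <- c("OBSCN", "MYOM1", "NKX25", "TBX20")
  oth <- character(39L)
  for (k in seq_len(39L)) {
    oth[k] <- new_patient(oth_sub[k])
    g <- oth_genes[1L + (k - 1L) %% 4L]
    add(oth[k], g, vid(g), nt, lp_class(k),
        pheno = oth_sub[k] != "CM_unclassified")
  }
  cm_dx <- oth[oth_sub == "CM_unclassified"]   # 4 diagnosed CM patients

  ## ---- (C) reclassified VUSs: 23 unique in 28 patients, 25 undiagnosed
  ## HCM: 17 unique / 21 patients (19 new + hcm[3], hcm[4])
  rg <- rep(c("MYH7", "TNNT2", "TNNI3", "TPM1"), c(6L, 4L, 4L, 3L))
  rp <- ifelse(rg == "MYH7", 300L + seq_along(rg), NA)
  rv <- vapply(rg, vid, "")
  rn <- new_patients(19L, "HCM")
  rc_carrier <- list(c(rn[1], rn[2]), c(rn[3], rn[4]), c(rn[5], rn[6]),
                     c(rn[7], hcm[3]))
  rc_singles <- c(rn[8:19], hcm[4])
  for (k in seq_len(4L)) for (p in rc_carrier[[k]])
    add(p, rg[k], rv[k], nt, 3L, pos = rp[k])
  for (k in seq_len(13L))
    add(rc_singles[k], rg[k + 4L], rv[k + 4L], nt, 3L, pos = rp[k + 4L],
        af = if (k == 1L) 1e-5 else NA_real_)   # PM2 also met when < 0.004%
  ## DCM: 6 unique / 7 patients (6 new + dcm[3])
  rg2 <- c("TTN", "TTN", "LMNA", "LMNA", "BAG3", "RBM20")
  rc2 <- c(tr, tr, tr, tr, tr, nt)
  rv2 <- vapply(rg2, vid, "")
  rn2 <- new_patients(6L, "DCM")
  add(rn2[1], rg2[1], rv2[1], rc2[1], 3L)
  add(rn2[2], rg2[1], rv2[1], rc2[1], 3L)
  for (k in 2:5) add(rn2[k + 1L], rg2[k], rv2[k], rc2[k], 3L)
  add(dcm[3], rg2[6], rv2[6], rc2[6], 3L)

  ## ---- (D) prioritized VUSs on the CE/EF route: 69 unique ----
  ## HCM: 24 unique / 40 patients (25 new + hcm[5..19])
  pg <- list(
    list("MYL2", nt, NA_real_, NA), list("MYL2", nt, NA_real_, NA),
    list("MYL2", nt, NA_real_, NA), list("MYL2", nt, NA_real_, NA),
    list("MYL2", nt, NA_real_, NA),
    list("MYL3", nt, NA_real_, NA), list("MYL3", nt, NA_real_, NA),
    list("MYL3", nt, NA_real_, NA), list("MYL3", nt, NA_real_, NA),
    list("ACTC1", nt, NA_real_, NA), list("ACTC1", nt, NA_real_, NA),
    list("ACTC1", nt, NA_real_, NA), list("ACTC1", nt, NA_real_, NA),
    list("CSRP3", nt, NA_real_, NA), list("CSRP3", nt, NA_real_, NA),
    list("CSRP3", nt, NA_real_, NA),
    list("FLNC", nt, NA_real_, NA), list("FLNC", nt, NA_real_, NA),
    list("FLNC", nt, NA_real_, NA),
    ## outside the high-EF residue cluster -> gene-wide EF 0.85
    list("MYH7", nt, NA_real_, 50L), list("MYH7", nt, NA_real_, 60L),
    list("MYH7", nt, NA_real_, 70L),
    ## inside the cluster but too frequent for PM2 (> 0.004%)
    list("MYH7", nt, 1e-4, 400L), list("MYH7", nt, 1e-4, 410L))
  pv <- vapply(pg, function(s) vid(s[[1]]), "")
  pr_obs <- list()
  for (k in 1:16) pr_obs <- c(pr_obs, list(k), list(k))  # shared pairs
  for (k in 17:24) pr_obs <- c(pr_obs, list(k))          # singles
  pn <- new_patients(25L, "HCM")
  pr_pat <- c(pn, hcm[5:19])
  for (j in seq_along(pr_obs)) {
    k <- pr_obs[[j]]
    add(pr_pat[j], pg[[k]][[1]], pv[k], pg[[k]][[2]], 3L,
        af = pg[[k]][[3]], pos = pg[[k]][[4]])
  }
  ## DCM: 26 unique / 48 patients (40 new + dcm[4..11])
  qg <- rep(c("TNNT2", "SCN5A", "DES", "PLN", "TNNC1", "ACTN2", "NEXN",
              "VCL"), c(4L, 4L, 4L, 3L, 3L, 3L, 3L, 2L))
  qc <- ifelse(qg %in% c("NEXN", "VCL"), tr, nt)
  qv <- vapply(qg, vid, "")
  q_obs <- c(unlist(lapply(1:22, function(k) c(k, k))), 23:26)
  qn <- new_patients(40L, "DCM")
  q_pat <- c(qn, dcm[4:11])
  for (j in seq_along(q_obs)) {
    k <- q_obs[[j]]
    add(q_pat[j], qg[k], qv[k], qc[k], 3L)
  }
  ## ACM: 1 unique / 1 patient
  add(new_patient("ACM"), "JUP", vid("JUP"), tr, 3L)
  ## unclassified CM: 18 unique / 26 patients (22 new + 4 diagnosed);
  ## PP4 cannot hold without a definite subtype, so none reclassify
  ug <- rep(c("TTN", "MYBPC3", "LMNA", "DSP", "TNNT2", "RBM20"),
            c(4L, 3L, 3L, 3L, 3L, 2L))
  uc <- ifelse(ug %in% c("TNNT2", "RBM20"), nt, tr)
  uv <- vapply(ug, vid, "")
  u_obs <- c(unlist(lapply(1:8, function(k) c(k, k))), 9:18)
  un <- new_patients(22L, "CM_unclassified")
  u_pat <- c(un, cm_dx)
  for (j in seq_along(u_obs)) {
    k <- u_obs[[j]]
    add(u_pat[j], ug[k], uv[k], uc[k], 3L, pheno = FALSE)
  }

  ## ---- (E) gnomAD-route VUSs: 37 unique in 42 patients, 19 undiagnosed
  gdc <- new_patients(2L, "DCM")
  add(gdc[1], "MYH6", vid("MYH6"), nt, 3L)
  add(gdc[2], "TMEM43", vid("TMEM43"), nt, 3L)
  glv <- new_patients(6L, "LVNC")
  lv_spec <- list(c("PRDM16", tr), c("PRDM16", tr), c("MIB1", tr),
                  c("MIB1", tr), c("HCN4", nt), c("HCN4", nt))
  for (k in seq_len(6L))
    add(glv[k], lv_spec[[k]][1], vid(lv_spec[[k]][1]), lv_spec[[k]][2], 3L)
  gcm <- new_patients(11L, "CM_unclassified")
  cm_spec <- rep(c("LAMP2", "CASQ2", "CRYAB"), c(4L, 4L, 3L))
  cm_cls <- ifelse(cm_spec == "CRYAB", nt, tr)
  for (k in seq_len(11L))
    add(gcm[k], cm_spec[k], vid(cm_spec[k]), cm_cls[k], 3L, pheno = FALSE)
  ## 23 already-diagnosed patients also carry gnomAD-route VUSs
  hg <- rep(c("MYH6", "TMEM43"), c(5L, 3L))             # 8 unique, 10 obs
  hv <- vapply(hg, vid, "")
  h_obs <- c(1L, 1L, 2L, 2L, 3:8)
  h_pat <- hcm[20:29]
  for (j in seq_along(h_obs))
    add(h_pat[j], hg[h_obs[j]], hv[h_obs[j]], nt, 3L)
  dg2 <- rep(c("CASQ2", "LAMP2", "CRYAB"), c(4L, 3L, 3L)) # 10 unique, 13 obs
  dc2 <- ifelse(dg2 == "CRYAB", nt, tr)
  dv2 <- vapply(dg2, vid, "")
  d_obs <- c(1L, 1L, 2L, 2L, 3L, 3L, 4:10)
  d_pat <- dcm[12:24]
  for (j in seq_along(d_obs))
    add(d_pat[j], dg2[d_obs[j]], dv2[d_obs[j]], dc2[d_obs[j]], 3L)

  ## ---- (F) remaining referrals: no (L)P, no selectable VUS ----
  fill_sub <- rep(c("HCM", "DCM", "ACM", "CM_unclassified", "LVNC"),
                  c(500L, 500L, 40L, 200L, 200L))
  fill_genes <- c("MYOM2", "SYNPO2L", "TRIM63", "FHOD3", "KLHL24", "CTNNA3")
  for (k in seq_along(fill_sub)) {
    p <- new_patient(fill_sub[k])
    g <- fill_genes[1L + (k - 1L) %% 6L]
    add(p, g, vid(g), if (k %% 2L == 0L) nt else tr,
        prior = if (k %% 2L == 0L) 3L else 2L, af = 5e-4,
        insil = FALSE, pheno = FALSE)
  }

  variants <- do.call(rbind, rows[seq_len(nr)])
  rownames(variants) <- NULL
  validate_variant_table(variants)
  validate_constraint_table(constraints)
  list(variants = variants, constraints = constraints)
}
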