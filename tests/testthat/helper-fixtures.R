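# Small in-code fixtures shared across tests.

make_obs <- function(patient_id = "P1", family_id = "F1", subtype = "HCM",
                     gene = "MYH7", variant_id = "MYH7.c0001",
                     variant_class = "non_truncating",
                     popmax_af = NA_real_, protein_position = NA_integer_,
                     insilico_support = TRUE, phenotype_specific = TRUE,
                     proband_count = 0L, segregating_meioses = 0L,
                     prior_class = 3L, founder_flag = FALSE) {
  data.frame(patient_id = patient_id, family_id = family_id,
             subtype = subtype, gene = gene, variant_id = variant_id,
             variant_class = variant_class, popmax_af = popmax_af,
             protein_position = as.integer(protein_position),
             insilico_support = insilico_support,
             phenotype_specific = phenotype_specific,
             proband_count = as.integer(proband_count),
             segregating_meioses = as.integer(segregating_meioses),
             prior_class = as.integer(prior_class),
             founder_flag = founder_flag, stringsAsFactors = FALSE)
}

make_entry <- function(gene = "MYH7", subtype = "HCM",
                       variant_class = "non_truncating",
                       has_case_excess = TRUE, ef = NA_real_,
                       ef_ci_low = NA_real_, ef_ci_high = NA_real_,
                       region_start = NA_integer_, region_end = NA_integer_,
                       pli = NA_real_, mis_z = NA_real_) {
  data.frame(gene = gene, subtype = subtype, variant_class = variant_class,
             has_case_excess = has_case_excess, ef = ef,
             ef_ci_low = ef_ci_low, ef_ci_high = ef_ci_high,
             region_start = as.integer(region_start),
             region_end = as.integer(region_end),
             pli = pli, mis_z = mis_z, stringsAsFactors = FALSE)
}

# MYH7 with a high-EF residue cluster plus a gene-wide entry, a truncating
# gene, and a gnomAD-only gene: enough structure for lookup/triage tests.
toy_constraints <- function() rbind(
  make_entry("MYH7", "HCM", "non_truncating", TRUE, ef = 0.97,
             region_start = 181L, region_end = 937L),
  make_entry("MYH7", "HCM", "non_truncating", TRUE, ef = 0.85),
  make_entry("TTN", "DCM", "truncating", TRUE, ef = 0.93),
  make_entry("MYL2", "HCM", "non_truncating", TRUE, ef = 0.85),
  make_entry("ACTN2", "DCM", "non_truncating", FALSE, mis_z = 1.5),
  make_entry("CASQ2", "ANY", "truncating", NA, pli = 0.95),
  make_entry("MYH6", "ANY", "non_truncating", NA, mis_z = 3.5),
  make_entry("LDB3", "ANY", "non_truncating", NA, mis_z = 0.8))

evset <- function(...) {
  items <- do.call(rbind, list(...))
  evidence_set(items)
}
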