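toy_cohort <- function() rbind(
  # reclassifiable: DCM truncating, EF 0.93, af missing, PP3+PP4
  make_obs("P1", subtype = "DCM", gene = "TTN", variant_id = "TTN.v1",
           variant_class = "truncating"),
  # significant CE but EF 0.85: prioritize
  make_obs("P2", gene = "MYL2", variant_id = "MYL2.v1"),
  # EF 0.97 cluster but popmax 0.01% > 0.004%: PM2 gate fails
  make_obs("P3", gene = "MYH7", variant_id = "MYH7.v1",
           protein_position = 400L, popmax_af = 1e-4),
  # no CE/EF entry, truncating, pLI 0.95: gnomAD-route prioritization
  make_obs("P4", gene = "CASQ2", variant_id = "CASQ2.v1",
           variant_class = "truncating"),
  # gnomAD gene failing the screen
  make_obs("P5", gene = "LDB3", variant_id = "LDB3.v1"),
  # gene absent from the table entirely
  make_obs("P6", gene = "ZZZ9", variant_id = "ZZZ9.v1"),
  # analysed without case excess
  make_obs("P7", subtype = "DCM", gene = "ACTN2", variant_id = "ACTN2.v1"),
  # a prior (L)P: not triaged
  make_obs("P8", gene = "MYH7", variant_id = "MYH7.v2",
           protein_position = 300L, prior_class = 4L))

test_that("the decision flow routes VUSs as specified", {
  dec <- triage_vus(toy_cohort(), toy_constraints())
  expect_equal(nrow(dec), 7L)  # the (L)P row is not a VUS
  d <- function(p) dec[dec$patient_id == p, ]

  expect_equal(d("P1")$action, "reclassify_LP")
  expect_equal(d("P1")$route, "ce_ef_gene")
  expect_equal(d("P1")$new_class, "likely_pathogenic")

  expect_equal(d("P2")$action, "prioritize")
  expect_equal(d("P2")$route, "ce_ef_gene")
  expect_true(is.na(d("P2")$new_class))

  expect_equal(d("P3")$action, "prioritize")  # frequency blocks PM2
  expect_match(d("P3")$rationale, "PM2")

  expect_equal(d("P4")$action, "prioritize")
  expect_equal(d("P4")$route, "gnomad_gene")

  expect_equal(d("P5")$action, "none")
  expect_equal(d("P6")$action, "none")
  expect_equal(d("P6")$route, "unmatched")
  expect_equal(d("P7")$action, "none")
  expect_equal(d("P7")$route, "ce_ef_gene")
})

test_that("reclassification decisions carry a verifiable evidence trail", {
  dec <- triage_vus(toy_cohort(), toy_constraints())
  rec <- dec[dec$action == "reclassify_LP", ]
  for (i in seq_len(nrow(rec))) {
    # the recorded evidence independently re-combines to (likely) pathogenic
    ev <- parse_evidence_set(rec$evidence[i])
    expect_true(combine_acmg(ev) %in% c("likely_pathogenic", "pathogenic"))
    for (gate in c("PM2", "PP3", "PP4"))
      expect_true(gate %in% ev$items$criterion)
    # and the rationale records the EF threshold comparison and the gates
    expect_match(rec$rationale[i], "EF=.*>= 0\\.9")
    expect_match(rec$rationale[i], "PM2, PP3 and PP4 all met")
  }
})

test_that("no decision downgrades: actions are reclassify/prioritize/none", {
  dec <- triage_vus(toy_cohort(), toy_constraints())
  expect_true(all(dec$action %in% c("reclassify_LP", "prioritize", "none")))
  expect_true(all(is.na(dec$new_class) |
                    dec$new_class == "likely_pathogenic"))
  # reclassify only ever happens on the CE/EF route
  expect_true(all(dec$route[dec$action == "reclassify_LP"] == "ce_ef_gene"))
})

test_that("co-segregation evidence can upgrade a prioritized variant", {
  ct <- toy_constraints()
  obs <- make_obs("P2", gene = "MYL2", variant_id = "MYL2.v1")  # EF 0.85
  dec <- triage_vus(obs, ct)
  expect_equal(dec$action, "prioritize")

  # 5 meioses: PP1@moderate joins PM1@supporting, PM2, PP3, PP4
  # -> 2 moderate + 3 supporting -> likely pathogenic (rule-table oracle)
  expect_equal(
    oracle_combine_criteria(c("PM1", "PM2", "PP1", "PP3", "PP4"),
                            c(PM1 = "supporting", PP1 = "moderate")),
    "likely_pathogenic")
  up <- apply_pp1_upgrade(dec, obs, ct, meioses = 5L)
  expect_equal(up$action, "reclassify_LP")
  expect_equal(up$new_class, "likely_pathogenic")
  expect_match(up$rationale, "5 meioses")

  # below every tier: unchanged
  expect_equal(apply_pp1_upgrade(dec, obs, ct, meioses = 2L)$action,
               "prioritize")
  # an already-reclassified decision is idempotent
  obs2 <- make_obs("P1", subtype = "DCM", gene = "TTN",
                   variant_id = "TTN.v1", variant_class = "truncating")
  dec2 <- triage_vus(obs2, ct)
  expect_identical(apply_pp1_upgrade(dec2[1, ], obs2, ct, meioses = 7L),
                   dec2[1, ])
})

test_that("triage output is deterministic and byte-identical", {
  fx <- table1_fixture()
  sub <- fx$variants[300:900, ]  # spans (L)P, reclassified and prioritized rows
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_decisions(triage_vus(sub, fx$constraints), p1)
  write_decisions(triage_vus(sub, fx$constraints), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an empty cohort yields empty (but well-formed) results", {
  empty <- make_obs()[0, ]
  conc <- validate_lp_concordance(empty, toy_constraints())
  expect_true(all(conc$n_variants == 0))
  expect_true(all(is.na(conc$concordance_pct)))
  dec <- triage_vus(empty, toy_constraints())
  expect_equal(nrow(dec), 0L)
})

test_that("concordance distinguishes the two routes and founder variants", {
  cohort <- rbind(
    make_obs("P1", gene = "MYH7", variant_id = "M.v1", prior_class = 4L,
             protein_position = 300L),                      # CE: concordant
    make_obs("P2", subtype = "DCM", gene = "ACTN2", variant_id = "A.v1",
             prior_class = 5L, founder_flag = TRUE),        # CE: discordant
    make_obs("P3", gene = "CASQ2", variant_id = "C.v1", prior_class = 4L,
             variant_class = "truncating"),                 # gnomAD: conc.
    make_obs("P4", gene = "LDB3", variant_id = "L.v1", prior_class = 4L))
  conc <- as.data.frame(validate_lp_concordance(cohort, toy_constraints()))
  ce <- conc[conc$route == "ce_ef_gene" & conc$subtype == "TOTAL", ]
  gn <- conc[conc$route == "gnomad_gene" & conc$subtype == "TOTAL", ]
  expect_equal(ce$n_variants, 2L)
  expect_equal(ce$n_concordant_variants, 1L)
  expect_equal(ce$concordance_pct, 50)
  expect_equal(ce$founder_discordant_pct, 50)
  expect_equal(gn$n_variants, 2L)
  expect_equal(gn$n_concordant_variants, 1L)
})
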