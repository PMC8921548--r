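test_that("EF bands map to PM1 strengths with left-closed edges", {
  t <- cm_thresholds()
  band <- function(ef) {
    e <- ef_to_pm1(ef, t)
    if (is.null(e)) NA_character_ else e$strength
  }
  expect_equal(band(0.97), "strong")
  expect_equal(band(0.92), "moderate")
  expect_equal(band(0.85), "supporting")
  # exact edges: 0.95 / 0.90 / 0.80 belong to the upper band
  expect_equal(band(0.95), "strong")
  expect_equal(band(0.9499999), "moderate")
  expect_equal(band(0.90), "moderate")
  expect_equal(band(0.8999999), "supporting")
  expect_equal(band(0.80), "supporting")
  expect_true(is.na(band(0.7999)))
  expect_true(is.na(band(0)))
  expect_error(ef_to_pm1(NA), class = "vustriage_validation_error")
})

test_that("combining matches the enumerated rule-table oracle", {
  oracle <- read.delim(test_path("fixtures", "combining-oracle.tsv"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(oracle))) {
    crit <- strsplit(oracle$criteria[i], ",", fixed = TRUE)[[1]]
    ev <- if (length(crit)) evidence_set(do.call(rbind, lapply(crit, evidence)))
          else evidence_set()
    expect_equal(combine_acmg(ev), oracle$expected[i],
                 label = paste0("{", oracle$criteria[i], "}"))
  }
})

test_that("combining honours strength overrides in every rule", {
  # the pipeline's overrides: PM1 promoted by EF band, PP1 by meioses
  crit <- c("PVS1", "PS4", "PM1", "PM2", "PP1", "PP3")
  overrides <- list(
    character(0),
    c(PM1 = "strong"),
    c(PM1 = "supporting"),
    c(PP1 = "moderate"),
    c(PP1 = "strong"),
    c(PM1 = "strong", PP1 = "moderate"))
  for (ov in overrides) for (mask in 0:63) {
    sel <- crit[bitwAnd(mask, 2^(0:5)) > 0]
    items <- lapply(sel, function(cr)
      evidence(cr, if (cr %in% names(ov)) ov[[cr]] else NULL))
    ev <- if (length(items)) evidence_set(do.call(rbind, items))
          else evidence_set()
    expect_equal(combine_acmg(ev), oracle_combine_criteria(sel, ov))
  }
  # a PM1@strong is a strong criterion: strong + moderate + 2 supporting
  ev <- evset(evidence("PM1", "strong"), evidence("PM2"), evidence("PP3"),
              evidence("PP4"))
  expect_equal(combine_acmg(ev), "likely_pathogenic")
  ev <- evset(evidence("PM1", "moderate"), evidence("PM2"), evidence("PP3"),
              evidence("PP4"))
  expect_equal(combine_acmg(ev), "likely_pathogenic")  # 2 moderate + 2 supp
  expect_equal(combine_acmg(evidence_set()), "vus")
})

test_that("benign-side rules and conflicts resolve per the table", {
  expect_equal(combine_acmg(evset(evidence("BA1"))), "benign")
  expect_equal(combine_acmg(evset(evidence("BS1"), evidence("BS2"))),
               "benign")
  expect_equal(combine_acmg(evset(evidence("BS1"), evidence("BP4"))),
               "likely_benign")
  expect_equal(combine_acmg(evset(evidence("BP4"), evidence("BP7"))),
               "likely_benign")
  # conflicting pathogenic and benign evidence -> VUS
  expect_equal(combine_acmg(evset(evidence("PS1"), evidence("PM2"),
                                  evidence("BS1"), evidence("BS2"))),
               "vus")
})

test_that("adding pathogenic evidence never moves the class backwards", {
  rank <- c(vus = 0, likely_pathogenic = 1, pathogenic = 2)
  path_crit <- c("PVS1", "PS1", "PS4", "PM1", "PM2", "PM4", "PP1", "PP3",
                 "PP4")
  set.seed(5)
  for (i in 1:200) {
    base <- sample(path_crit, sample(0:5, 1))
    extra <- sample(setdiff(path_crit, base), 1)
    ev1 <- if (length(base)) evidence_set(do.call(rbind, lapply(base, evidence)))
           else evidence_set()
    ev2 <- evidence_set(do.call(rbind, lapply(c(base, extra), evidence)))
    expect_gte(rank[combine_acmg(ev2)], rank[combine_acmg(ev1)])
  }
})

test_that("combining is invariant under item permutation", {
  set.seed(9)
  crit <- c("PS4", "PM1", "PM2", "PP1", "PP3", "PP4")
  items <- do.call(rbind, lapply(crit, evidence))
  ref <- combine_acmg(evidence_set(items))
  for (i in 1:10)
    expect_equal(combine_acmg(evidence_set(items[sample(nrow(items)), ])),
                 ref)
})

test_that("evidence assignment activates criteria from the inputs", {
  t <- cm_thresholds()
  entry <- make_entry(ef = 0.93)
  ev <- assign_evidence(make_obs(), entry, t)
  expect_setequal(ev$items$criterion, c("PM1", "PM2", "PP3", "PP4"))
  expect_equal(ev$items$strength[ev$items$criterion == "PM1"], "moderate")

  # 0.005% popmax: PM2 not met
  ev <- assign_evidence(make_obs(popmax_af = 5e-5), entry, t)
  expect_false("PM2" %in% ev$items$criterion)
  # just under the 0.004% cutoff: met
  ev <- assign_evidence(make_obs(popmax_af = 3.9e-5), entry, t)
  expect_true("PM2" %in% ev$items$criterion)

  # tiered co-segregation: highest applicable tier only
  tier <- function(m) {
    ev <- assign_evidence(make_obs(segregating_meioses = m), entry, t)
    s <- ev$items$strength[ev$items$criterion == "PP1"]
    if (length(s)) s else NA_character_
  }
  expect_equal(tier(7L), "strong")
  expect_equal(tier(5L), "moderate")
  expect_equal(tier(3L), "supporting")
  expect_true(is.na(tier(2L)))
  expect_equal(sum(assign_evidence(
    make_obs(segregating_meioses = 9L), entry, t)$items$criterion == "PP1"),
    1L)

  # PS4 at >= 15 probands
  ev <- assign_evidence(make_obs(proband_count = 15L), entry, t)
  expect_true("PS4" %in% ev$items$criterion)
  ev <- assign_evidence(make_obs(proband_count = 14L), entry, t)
  expect_false("PS4" %in% ev$items$criterion)

  # no entry, no flags: only PM2 from the missing frequency
  ev <- assign_evidence(make_obs(insilico_support = FALSE,
                                 phenotype_specific = FALSE), NULL, t)
  expect_equal(ev$items$criterion, "PM2")
  expect_equal(length(ev$provenance), 1L)
})

test_that("evidence sets reject duplicates and round-trip their tokens", {
  expect_error(evset(evidence("PM2"), evidence("PM2")),
               class = "vustriage_validation_error")
  ev <- evset(evidence("PM1", "strong"), evidence("PM2"), evidence("PP3"))
  expect_equal(format_evidence_set(ev), "PM1:strong,PM2,PP3")
  back <- parse_evidence_set("PM1:strong,PM2,PP3")
  expect_equal(back$items, ev$items)
  expect_equal(format_evidence_set(evidence_set()), "")
})
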