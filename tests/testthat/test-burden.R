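test_that("CE and EF follow the carrier-frequency definitions", {
  r <- compute_burden(list(case_carriers = 20, case_n = 100,
                           control_carriers = 2, control_n = 1000))
  expect_equal(r$ce, 0.198)
  expect_equal(r$ef, 0.99)
  expect_true(r$significant)

  r <- compute_burden(list(case_carriers = 10, case_n = 100,
                           control_carriers = 100, control_n = 1000))
  expect_equal(r$ce, 0)
  expect_equal(r$ef, 0)
  expect_false(r$significant)

  r <- compute_burden(list(case_carriers = 5, case_n = 100,
                           control_carriers = 0, control_n = 60706))
  expect_equal(r$ef, 1)             # zero control frequency pins EF at 1
  expect_true(is.na(r$ef_ci_low))   # zero cell: no CI
})

test_that("EF is undefined (not zero) without case carriers", {
  r <- compute_burden(list(case_carriers = 0, case_n = 100,
                           control_carriers = 5, control_n = 1000))
  expect_false(r$ef_defined)
  expect_true(is.na(r$ef))
})

test_that("p-values match exhaustive hypergeometric enumeration (n <= 12)", {
  for (N in 2:12) for (cn in 1:(N - 1)) {
    kn <- N - cn
    for (a in 0:cn) for (c0 in 0:kn) {
      r <- compute_burden(list(case_carriers = a, case_n = cn,
                               control_carriers = c0, control_n = kn))
      expect_equal(r$p_value, oracle_fisher_p(a, cn - a, c0, kn - c0),
                   tolerance = 1e-12)
    }
  }
})

test_that("EF equals 1 - 1/RR for the carrier-frequency ratio", {
  set.seed(7)
  for (i in 1:200) {
    cn <- sample(20:2000, 1); kn <- sample(100:60706, 1)
    a <- sample(seq_len(cn), 1); c0 <- sample(seq_len(kn), 1)
    r <- compute_burden(list(case_carriers = a, case_n = cn,
                             control_carriers = c0, control_n = kn))
    rr <- (a / cn) / (c0 / kn)
    expect_equal(r$ef, 1 - 1 / rr, tolerance = 1e-12)
  }
})

test_that("EF never exceeds 1, shares sign with CE, and grows with f_case", {
  set.seed(11)
  for (i in 1:300) {
    cn <- sample(1:500, 1); kn <- sample(1:5000, 1)
    a <- sample(0:cn, 1); c0 <- sample(0:kn, 1)
    r <- compute_burden(list(case_carriers = a, case_n = cn,
                             control_carriers = c0, control_n = kn))
    if (r$ef_defined) {
      expect_lte(r$ef, 1)
      if (r$ce != 0) expect_equal(sign(r$ef), sign(r$ce))
    }
    if (!r$significant || r$ce > 0) succeed()  # significance requires excess
    else fail("significant with non-positive CE")
  }
  efs <- vapply(c(10, 20, 40, 80), function(a)
    compute_burden(list(case_carriers = a, case_n = 100,
                        control_carriers = 10, control_n = 1000))$ef, 0)
  expect_true(all(diff(efs) > 0))  # monotone in the case frequency
})

test_that("EF confidence interval is present iff all cells are positive", {
  r <- compute_burden(list(case_carriers = 20, case_n = 100,
                           control_carriers = 10, control_n = 1000))
  expect_false(is.na(r$ef_ci_low))
  expect_lt(r$ef_ci_low, r$ef_ci_high)
  expect_lte(r$ef_ci_high, 1)
  # the interval is the exact OR interval mapped through 1 - 1/OR
  ft <- fisher.test(matrix(c(20, 80, 10, 990), 2))
  expect_equal(r$ef_ci_low, 1 - 1 / ft$conf.int[1])
  expect_equal(r$ef_ci_high, 1 - 1 / ft$conf.int[2])
})

test_that("burden_table maps a counts table row-wise", {
  counts <- data.frame(
    gene = c("DSP", "TTN"), subtype = c("DCM", "DCM"),
    variant_class = c("truncating", "truncating"),
    case_carriers = c(20L, 5L), case_n = c(100L, 100L),
    control_carriers = c(2L, 0L), control_n = c(1000L, 60706L),
    stringsAsFactors = FALSE)
  bt <- burden_table(counts)
  expect_equal(bt$ef, c(0.99, 1))
  expect_equal(bt$gene, c("DSP", "TTN"))
})

test_that("gnomAD screen pairs metrics with classes strictly", {
  t <- cm_thresholds()
  expect_true(gnomad_screen(make_obs(variant_class = "truncating"),
                            make_entry(pli = 0.95), t))
  expect_false(gnomad_screen(make_obs(variant_class = "truncating"),
                             make_entry(pli = 0.90), t))  # strict >
  expect_false(gnomad_screen(make_obs(variant_class = "non_truncating"),
                             make_entry(mis_z = 2.5), t))
  expect_true(gnomad_screen(make_obs(variant_class = "non_truncating"),
                            make_entry(mis_z = 3.1), t))
  # pLI is never applied to missense variants, however extreme
  expect_false(gnomad_screen(make_obs(variant_class = "non_truncating"),
                             make_entry(pli = 0.99, mis_z = 1.0), t))
  # class-matched metric missing: FALSE with a warning, whatever the other
  expect_warning(
    res <- gnomad_screen(make_obs(variant_class = "truncating"),
                         make_entry(mis_z = 9)), "pLI missing")
  expect_false(res)
})

test_that("constraint lookup prefers containing regions, then case excess", {
  ct <- toy_constraints()
  hit <- lookup_constraint(make_obs(protein_position = 500L), ct)
  expect_equal(hit$ef, 0.97)        # inside the 181-937 cluster
  hit <- lookup_constraint(make_obs(protein_position = 50L), ct)
  expect_equal(hit$ef, 0.85)        # outside: gene-wide entry
  hit <- lookup_constraint(make_obs(protein_position = NA), ct)
  expect_equal(hit$ef, 0.85)        # unknown position: gene-wide
  # unclassified CM matches evidence from any subtype
  hit <- lookup_constraint(
    make_obs(subtype = "CM_unclassified", gene = "TTN",
             variant_class = "truncating"), ct)
  expect_equal(hit$ef, 0.93)
  # LVNC patients cannot borrow subtype-specific evidence
  expect_null(lookup_constraint(
    make_obs(subtype = "LVNC", gene = "TTN", variant_class = "truncating"),
    ct))
  # but ANY-subtype gnomAD entries match them
  hit <- lookup_constraint(
    make_obs(subtype = "LVNC", gene = "CASQ2", variant_class = "truncating"),
    ct)
  expect_equal(hit$pli, 0.95)
  # class mismatch finds nothing
  expect_null(lookup_constraint(
    make_obs(gene = "TTN", subtype = "DCM",
             variant_class = "non_truncating"), ct))
  # highest-EF region wins when several contain the position
  ct2 <- rbind(make_entry("MYH7", ef = 0.92, region_start = 100L,
                          region_end = 600L),
               make_entry("MYH7", ef = 0.97, region_start = 181L,
                          region_end = 937L))
  hit <- lookup_constraint(make_obs(protein_position = 500L), ct2)
  expect_equal(hit$ef, 0.97)
})
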