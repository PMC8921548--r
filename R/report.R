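## Cohort-level reporting: diagnostic yield, concordance, reclassification
## and prioritization tallies with the publication's rounding conventions
## (half-up at the displayed precision; integer percentages for
## concordance, one decimal for cohort-level yields).

REPORT_SUBTYPES <- c(HCM = "HCM", DCM = "DCM", ACM = "ACM",
                     CM = "CM_unclassified", LVNC = "LVNC")

#' Build the cohort report
#'
#' Aggregates the triage decisions and the (L)P concordance into the
#' standard cohort summary: per-subtype rows (plus a TOTAL row that is the
#' column-wise sum of the counts; percentages are always recomputed from
#' raw counts, never summed) and cohort-level yields.
#'
#' Counting conventions: a patient is counted once per tally regardless of
#' how many qualifying variants they carry; unique-variant tallies
#' deduplicate by `variant_id` across patients. A patient is "diagnosed"
#' when carrying at least one prior (L)P. The diagnostic yield is the
#' diagnosed fraction of the cohort; the yield increase is the fraction of
#' patients gaining a *first* (L)P through immediate reclassification. The
#' prioritized fraction counts undiagnosed patients holding at least one
#' selected CE/EF-route VUS; the gnomAD-route tally counts undiagnosed
#' patients selected only through the intolerance screen. A patient
#' selected on both routes is counted on the CE/EF route alone.
#'
#' @param cohort a variant table data.frame.
#' @param constraints a constraint table data.frame (for the per-subtype
#'   gene-with-case-excess counts).
#' @param decisions a [triage_vus()] decisions data.frame.
#' @param concordance a [validate_lp_concordance()] result.
#' @return an object of class `cohort_report`: a list with `subtypes` (the
#'   per-subtype table) and `overall` (named cohort-level metrics).
#' @export
build_report <- function(cohort, constraints, decisions, concordance) {
  pt_subtype <- tapply(cohort$subtype, cohort$patient_id, `[`, 1L)
  total_patients <- length(pt_subtype)
  diagnosed <- unique(cohort$patient_id[cohort$prior_class >= 4L])

  sel_ce <- decisions[decisions$route == "ce_ef_gene" &
                        decisions$action %in% c("reclassify_LP", "prioritize"),
                      , drop = FALSE]
  sel_gn <- decisions[decisions$route == "gnomad_gene" &
                        decisions$action == "prioritize", , drop = FALSE]
  recl <- decisions[decisions$action == "reclassify_LP", , drop = FALSE]

  ce_patients <- unique(sel_ce$patient_id)
  gn_patients <- setdiff(unique(sel_gn$patient_id), ce_patients)
  recl_patients <- unique(recl$patient_id)

  undiag <- function(p) setdiff(p, diagnosed)

  conc <- as.data.frame(concordance)
  conc_ce <- conc[conc$route == "ce_ef_gene", , drop = FALSE]
  conc_row <- function(sub) {
    r <- conc_ce[conc_ce$subtype == sub, , drop = FALSE]
    if (nrow(r) == 0L)
      r <- data.frame(n_variants = 0L, n_concordant_variants = 0L,
                      n_patients = 0L, n_concordant_patients = 0L,
                      concordance_pct = NA_real_)
    r
  }

  genes_ce <- function(sub) {
    k <- constraints$subtype == sub & !is.na(constraints$has_case_excess) &
      constraints$has_case_excess
    length(unique(constraints$gene[k]))
  }

  sub_rows <- lapply(names(REPORT_SUBTYPES), function(lbl) {
    sub <- REPORT_SUBTYPES[[lbl]]
    pts <- names(pt_subtype)[pt_subtype == sub]
    cr <- conc_row(sub)
    ce_s <- intersect(ce_patients, pts)
    gn_s <- intersect(gn_patients, pts)
    rc_s <- intersect(recl_patients, pts)
    data.frame(
      subtype = lbl,
      n_genes_ce = genes_ce(sub),
      n_patients_rdc_lp = cr$n_patients,
      n_variants_rdc_lp = cr$n_variants,
      n_patients_ce_lp = cr$n_concordant_patients,
      n_variants_ce_lp = cr$n_concordant_variants,
      concordance_pct = cr$concordance_pct,
      n_patients_selected_ce = length(ce_s),
      n_selected_no_dx = length(undiag(ce_s)),
      n_reclassified_no_dx = length(undiag(rc_s)),
      n_gnomad_no_dx = length(undiag(gn_s)),
      stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, sub_rows)
  cnt <- c("n_genes_ce", "n_patients_rdc_lp", "n_variants_rdc_lp",
           "n_patients_ce_lp", "n_variants_ce_lp", "n_patients_selected_ce",
           "n_selected_no_dx", "n_reclassified_no_dx", "n_gnomad_no_dx")
  total <- st[1, , drop = FALSE]
  total$subtype <- "TOTAL"
  for (cc in cnt) total[[cc]] <- sum(st[[cc]])
  total$concordance_pct <- if (total$n_variants_rdc_lp > 0)
    round_half_up(100 * total$n_variants_ce_lp / total$n_variants_rdc_lp)
  else NA_real_
  st <- rbind(st, total)
  rownames(st) <- NULL

  uniq_recl <- unique(recl$variant_id)
  uniq_prior <- setdiff(
    unique(decisions$variant_id[decisions$action == "prioritize"]), uniq_recl)
  n_sel_nd <- length(undiag(ce_patients))
  n_gn_nd <- length(undiag(gn_patients))
  n_comb_nd <- length(undiag(union(ce_patients, gn_patients)))
  n_recl_nd <- length(undiag(recl_patients))

  overall <- list(
    total_patients = total_patients,
    n_diagnosed = length(diagnosed),
    diagnostic_yield_pct = round_half_up(
      100 * length(diagnosed) / total_patients, 1),
    n_reclassified_patients = length(recl_patients),
    n_reclassified_no_dx = n_recl_nd,
    yield_increase_pct = round_half_up(100 * n_recl_nd / total_patients, 1),
    n_selected_ce_patients = length(ce_patients),
    n_selected_no_dx_ce = n_sel_nd,
    prioritized_pct = round_half_up(100 * n_sel_nd / total_patients, 1),
    n_gnomad_no_dx = n_gn_nd,
    gnomad_pct = round_half_up(100 * n_gn_nd / total_patients),
    n_combined_no_dx = n_comb_nd,
    combined_selected_pct = round_half_up(100 * n_comb_nd / total_patients, 1),
    n_unique_reclassified = length(uniq_recl),
    n_unique_prioritized = length(uniq_prior),
    prioritized_unique_pct = round_half_up(
      100 * length(uniq_prior) / total_patients, 1))

  structure(list(subtypes = st, overall = overall), class = "cohort_report")
}

#' Render a cohort report
#'
#' @param report a [build_report()] result.
#' @param format `"text"` for a human-readable layout mirroring the
#'   published summary table, `"tsv"` for machine-readable output (the
#'   subtype table followed by a `metric<TAB>value` block).
#' @return a character vector of lines.
#' @export
render_report <- function(report, format = c("text", "tsv")) {
  format <- match.arg(format)
  st <- report$subtypes
  ov <- report$overall
  if (format == "tsv") {
    lines <- paste(names(st), collapse = "\t")
    for (i in seq_len(nrow(st)))
      lines <- c(lines, paste(vapply(st[i, ], function(v)
        ifelse(is.na(v), "NA", as.character(v)), ""), collapse = "\t"))
    lines <- c(lines, "", "metric\tvalue")
    for (nm in names(ov))
      lines <- c(lines, paste0(nm, "\t", format(ov[[nm]])))
    return(lines)
  }
  dash <- function(v, fmt = "%d") ifelse(is.na(v) | v == 0, "-",
                                         sprintf(fmt, v))
  lines <- c(
    "Impact of constraint-metric reassessment of variant pathogenicity",
    sprintf("  %-6s %6s %12s %12s %6s %10s %8s %8s %8s",
            "CM", "genes", "RDC (L)P", "CE/EF (L)P", "conc.",
            "selected", "no-dx", "reclass", "gnomAD"))
  for (i in seq_len(nrow(st))) {
    r <- st[i, ]
    lines <- c(lines, sprintf(
      "  %-6s %6s %12s %12s %6s %10s %8s %8s %8s",
      r$subtype, dash(r$n_genes_ce),
      ifelse(r$n_patients_rdc_lp == 0, "-",
             sprintf("%d (%d)", r$n_patients_rdc_lp, r$n_variants_rdc_lp)),
      ifelse(r$n_patients_ce_lp == 0, "-",
             sprintf("%d (%d)", r$n_patients_ce_lp, r$n_variants_ce_lp)),
      ifelse(is.na(r$concordance_pct), "-",
             sprintf("%d%%", r$concordance_pct)),
      dash(r$n_patients_selected_ce), dash(r$n_selected_no_dx),
      dash(r$n_reclassified_no_dx), dash(r$n_gnomad_no_dx)))
  }
  lines <- c(lines, "",
    sprintf("  Diagnostic yield                 : %.1f%% (%d/%d)",
            ov$diagnostic_yield_pct, ov$n_diagnosed, ov$total_patients),
    sprintf("  Yield increase (reclassified)    : %.1f%% (%d patients, %d unique VUSs)",
            ov$yield_increase_pct, ov$n_reclassified_no_dx,
            ov$n_unique_reclassified),
    sprintf("  Prioritized, CE/EF route         : %.1f%% (%d patients)",
            ov$prioritized_pct, ov$n_selected_no_dx_ce),
    sprintf("  Prioritized, gnomAD route        : %g%% (%d patients)",
            ov$gnomad_pct, ov$n_gnomad_no_dx),
    sprintf("  Prioritized unique VUSs          : %.1f%% (%d/%d)",
            ov$prioritized_unique_pct, ov$n_unique_prioritized,
            ov$total_patients),
    sprintf("  Combined selection               : %.1f%% (%d patients)",
            ov$combined_selected_pct, ov$n_combined_no_dx))
  lines
}

#' @export
print.cohort_report <- function(x, ...) {
  writeLines(render_report(x, "text"))
  invisible(x)
}

#' Run the full pipeline on a cohort
#'
#' Convenience wrapper: validates (L)P concordance, triages every VUS and
#' builds the cohort report in one call.
#'
#' @param cohort a variant table data.frame.
#' @param constraints a constraint table data.frame.
#' @param thresholds a [cm_thresholds()] object.
#' @return an object of class `cm_triage`: a list with `concordance`,
#'   `decisions`, `report` and `thresholds`.
#' @export
triage_cohort <- function(cohort, constraints,
                          thresholds = cm_thresholds()) {
  validate_variant_table(cohort)
  validate_constraint_table(constraints)
  conc <- validate_lp_concordance(cohort, constraints, thresholds)
  dec <- triage_vus(cohort, constraints, thresholds)
  rep <- build_report(cohort, constraints, dec, conc)
  structure(list(concordance = conc, decisions = dec, report = rep,
                 thresholds = thresholds), class = "cm_triage")
}

#' @export
print.cm_triage <- function(x, ...) {
  print(x$decisions)
  cat(sprintf("Diagnostic yield %.1f%%; yield increase %.1f%%; combined selection %.1f%%\n",
              x$report$overall$diagnostic_yield_pct,
              x$report$overall$yield_increase_pct,
              x$report$overall$combined_selected_pct))
  invisible(x)
}

#' @export
summary.cm_triage <- function(object, ...) {
  print(object$concordance)
  cat("\n")
  print(object$report)
  invisible(object)
}
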