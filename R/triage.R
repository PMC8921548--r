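## VUS triage: immediate reclassification versus prioritization.

.decision_row <- function(obs, route, action, new_class, ev, rationale) {
  data.frame(
    patient_id = obs$patient_id, variant_id = obs$variant_id,
    route = route, action = action,
    new_class = new_class %||% NA_character_,
    evidence = if (is.null(ev)) NA_character_ else format_evidence_set(ev),
    rationale = paste(rationale, collapse = " | "),
    stringsAsFactors = FALSE)
}

.triage_one <- function(obs, constraints, t) {
  entry <- lookup_constraint(obs, constraints)
  if (is.null(entry))
    return(.decision_row(obs, "unmatched", "none", NULL, NULL,
      sprintf("no constraint entry for %s/%s/%s",
              obs$gene, obs$subtype, obs$variant_class)))

  analysed <- !is.na(entry$has_case_excess)
  if (analysed && isTRUE(entry$has_case_excess)) {
    ev <- assign_evidence(obs, entry, t)
    rat <- c(sprintf("gene %s has significant case excess (%s, %s)",
                     entry$gene, entry$subtype, entry$variant_class),
             ev$provenance)
    ef <- entry$ef
    ef_ok <- !is.na(ef) && ef >= t$ef_reclass
    rat <- c(rat, if (is.na(ef))
      "EF missing: not eligible for immediate reclassification"
    else sprintf("EF=%g %s %g (reclassification cutoff)", ef,
                 if (ef_ok) ">=" else "<", t$ef_reclass))
    gates <- c(PM2 = has_criterion(ev, "PM2"), PP3 = has_criterion(ev, "PP3"),
               PP4 = has_criterion(ev, "PP4"))
    cls <- combine_acmg(ev)
    if (ef_ok && all(gates) &&
        cls %in% c("likely_pathogenic", "pathogenic")) {
      rat <- c(rat, "PM2, PP3 and PP4 all met",
               sprintf("combining rules -> %s", cls),
               "action: immediate reclassification to LP")
      return(.decision_row(obs, "ce_ef_gene", "reclassify_LP",
                           "likely_pathogenic", ev, rat))
    }
    if (!all(gates))
      rat <- c(rat, sprintf("gate(s) not met: %s",
                            paste(names(gates)[!gates], collapse = ", ")))
    if (ef_ok && all(gates))
      rat <- c(rat, sprintf("combining rules -> %s (below LP)", cls))
    rat <- c(rat, "action: prioritize for co-segregation/functional studies")
    return(.decision_row(obs, "ce_ef_gene", "prioritize", NULL, ev, rat))
  }

  # gene in the constraint table without significant case excess (either
  # never burden-analysed, or analysed without excess): gnomAD screen only,
  # never an immediate reclassification on this route
  screened <- gnomad_screen(obs, entry, t)
  route <- if (analysed) "ce_ef_gene" else "gnomad_gene"
  if (!analysed && screened) {
    metric <- if (obs$variant_class == "truncating")
      sprintf("pLI=%g > %g", entry$pli, t$pli_cut)
    else sprintf("mis_z=%g > %g", entry$mis_z, t$mis_z_cut)
    return(.decision_row(obs, "gnomad_gene", "prioritize", NULL, NULL,
      c(sprintf("gene %s established for subtype (entry %s) without CE/EF data",
                entry$gene, entry$subtype),
        sprintf("gnomAD intolerance screen passed (%s)", metric),
        "action: prioritize only (constraint scores insufficient for (L)P)")))
  }
  .decision_row(obs, route, "none", NULL, NULL,
    if (analysed)
      sprintf("gene %s analysed for case excess but none found (%s, %s)",
              entry$gene, entry$subtype, entry$variant_class)
    else "gnomAD intolerance screen not passed")
}

#' Triage variants of uncertain significance
#'
#' Applies the constraint-metric decision flow to every prior-VUS
#' observation in the cohort:
#'
#' 1. resolve the constraint entry via [lookup_constraint()];
#' 2. if the gene/class/subtype has significant case excess, assign ACMG
#'    evidence; with `EF >= ef_reclass` (default 0.90) **and** PM2, PP3 and
#'    PP4 all met **and** the combining rules reaching (likely) pathogenic,
#'    the variant is immediately reclassified to LP; otherwise it is
#'    prioritized for co-segregation or functional follow-up;
#' 3. without case-excess evidence, a variant passing the gnomAD
#'    intolerance screen in a gene whose constraint entry establishes it
#'    for the patient's subtype is prioritized (never reclassified: these
#'    scores alone are insufficient to support (L)P);
#' 4. anything else gets no action.
#'
#' Every threshold comparison is recorded in the rationale trail. Identical
#' inputs produce byte-identical decision tables.
#'
#' @param cohort a variant table data.frame.
#' @param constraints a constraint table data.frame.
#' @param thresholds a [cm_thresholds()] object.
#' @return an object of class `triage_decisions` (a data.frame with one row
#'   per prior-VUS observation): `patient_id`, `variant_id`, `route`,
#'   `action`, `new_class`, `evidence`, `rationale`.
#' @export
triage_vus <- function(cohort, constraints, thresholds = cm_thresholds()) {
  vus <- cohort[cohort$prior_class == 3L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(vus)),
                 function(i) .triage_one(vus[i, ], constraints, thresholds))
  out <- if (length(rows)) do.call(rbind, rows) else
    .decision_row(list(patient_id = "x", variant_id = "x"), "unmatched",
                  "none", NULL, NULL, "")[0, ]
  rownames(out) <- NULL
  structure(out, class = c("triage_decisions", "data.frame"))
}

#' @export
print.triage_decisions <- function(x, ...) {
  cat(sprintf(
    "Triage decisions: %d VUS observations (%d reclassified to LP, %d prioritized, %d no action)\n",
    nrow(x), sum(x$action == "reclassify_LP"), sum(x$action == "prioritize"),
    sum(x$action == "none")))
  invisible(x)
}

#' Re-evaluate a prioritized decision with co-segregation evidence
#'
#' Re-runs evidence assignment for the observation with the given number of
#' segregating meioses (activating the tiered PP1 criterion) and
#' re-combines. The action is upgraded to `reclassify_LP` only when the
#' combined class reaches likely pathogenic or pathogenic and the
#' reclassification gates (case excess, PM2, PP3, PP4) hold; an
#' already-reclassified decision is returned unchanged.
#'
#' @param decision a one-row decisions data.frame (from [triage_vus()]).
#' @param obs the matching variant observation.
#' @param constraints a constraint table data.frame.
#' @param meioses observed segregating meioses for PP1.
#' @param thresholds a [cm_thresholds()] object.
#' @return a one-row decisions data.frame.
#' @export
apply_pp1_upgrade <- function(decision, obs, constraints, meioses,
                              thresholds = cm_thresholds()) {
  if (decision$action == "reclassify_LP") return(decision)
  if (decision$route != "ce_ef_gene") return(decision)
  obs$segregating_meioses <- as.integer(meioses)
  entry <- lookup_constraint(obs, constraints)
  if (is.null(entry) || !isTRUE(entry$has_case_excess)) return(decision)
  ev <- assign_evidence(obs, entry, thresholds)
  cls <- combine_acmg(ev)
  gates <- has_criterion(ev, "PM2") && has_criterion(ev, "PP3") &&
    has_criterion(ev, "PP4")
  if (gates && cls %in% c("likely_pathogenic", "pathogenic")) {
    return(.decision_row(obs, "ce_ef_gene", "reclassify_LP",
                         "likely_pathogenic", ev,
      c(strsplit(decision$rationale, " | ", fixed = TRUE)[[1]],
        sprintf("co-segregation: %d meioses", as.integer(meioses)),
        sprintf("combining rules with PP1 -> %s", cls),
        "action upgraded to reclassify_LP")))
  }
  decision
}
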