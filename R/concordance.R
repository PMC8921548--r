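## Concordance of prior likely-pathogenic/pathogenic calls with the
## constraint-metric classification routes.

## per-observation route/concordance annotation shared by the concordance
## validator and the triage engine
.route_obs <- function(obs, constraints, thresholds) {
  entry <- lookup_constraint(obs, constraints)
  if (is.null(entry))
    return(list(route = "unmatched", entry = NULL, concordant = FALSE))
  if (!is.na(entry$has_case_excess))
    return(list(route = "ce_ef_gene", entry = entry,
                concordant = isTRUE(entry$has_case_excess)))
  list(route = "gnomad_gene", entry = entry,
       concordant = isTRUE(gnomad_screen(obs, entry, thresholds)))
}

#' Concordance between prior (L)P calls and the constraint routes
#'
#' Restricts the cohort to variants previously classified likely pathogenic
#' or pathogenic, splits them by route -- (gene, subtype, class)
#' combinations analysed in the case-excess/etiological-fraction burden
#' studies versus those only screenable via gnomAD pLI/mis_z -- and counts
#' how many would also have been called (L)P by that route: on the CE/EF
#' route a variant is concordant when its matched entry has significant
#' case excess; on the gnomAD route when the intolerance screen passes.
#'
#' Variant-level tallies deduplicate by `variant_id` (a variant carried by
#' several patients counts once, and is concordant if any of its
#' observations is); patient-level tallies count patients with at least one
#' route variant resp. at least one concordant one. Founder-flagged
#' discordant variants are reported as a percentage of the route's variant
#' total. Percentages use half-up rounding to integers; an empty
#' denominator reports `NA`.
#'
#' @param cohort a variant table data.frame.
#' @param constraints a constraint table data.frame.
#' @param thresholds a [cm_thresholds()] object.
#' @return an object of class `cm_concordance`: a data.frame with one row
#'   per (route, subtype) plus pooled `TOTAL` rows, with columns
#'   `route`, `subtype`, `n_variants`, `n_concordant_variants`,
#'   `n_patients`, `n_concordant_patients`, `concordance_pct`,
#'   `founder_discordant_pct`.
#' @export
validate_lp_concordance <- function(cohort, constraints,
                                    thresholds = cm_thresholds()) {
  lp <- cohort[cohort$prior_class >= 4L, , drop = FALSE]
  ann <- lapply(seq_len(nrow(lp)), function(i)
    .route_obs(lp[i, ], constraints, thresholds))
  lp$route <- vapply(ann, `[[`, "", "route")
  lp$concordant <- vapply(ann, `[[`, TRUE, "concordant")

  tally <- function(d) {
    if (nrow(d) == 0L)
      return(data.frame(n_variants = 0L, n_concordant_variants = 0L,
                        n_patients = 0L, n_concordant_patients = 0L,
                        concordance_pct = NA_real_,
                        founder_discordant_pct = NA_real_))
    by_var <- tapply(d$concordant, d$variant_id, any)
    founder_disc <- tapply(!d$concordant & d$founder_flag, d$variant_id, all)
    # a variant is founder-discordant when discordant and founder-flagged
    disc_f <- sum(founder_disc[!by_var], na.rm = TRUE)
    nv <- length(by_var)
    data.frame(
      n_variants = nv,
      n_concordant_variants = sum(by_var),
      n_patients = length(unique(d$patient_id)),
      n_concordant_patients = length(unique(d$patient_id[d$concordant])),
      concordance_pct = round_half_up(100 * sum(by_var) / nv),
      founder_discordant_pct = round_half_up(100 * disc_f / nv))
  }

  rows <- list()
  for (rt in c("ce_ef_gene", "gnomad_gene")) {
    dr <- lp[lp$route == rt, , drop = FALSE]
    for (sub in intersect(SUBTYPES, unique(dr$subtype))) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(route = rt, subtype = sub, stringsAsFactors = FALSE),
        tally(dr[dr$subtype == sub, , drop = FALSE]))
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(route = rt, subtype = "TOTAL", stringsAsFactors = FALSE),
      tally(dr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cm_concordance", "data.frame"))
}

#' @export
print.cm_concordance <- function(x, ...) {
  cat("Concordance of prior (L)P calls with constraint-metric routes\n")
  df <- as.data.frame(x)
  for (rt in unique(df$route)) {
    cat(sprintf("\n  %s route:\n", if (rt == "ce_ef_gene") "CE/EF"
                else "gnomAD"))
    d <- df[df$route == rt, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-16s %3d (L)P variants, %3d concordant (%s%%)%s\n",
                  d$subtype[i], d$n_variants[i], d$n_concordant_variants[i],
                  ifelse(is.na(d$concordance_pct[i]), "-",
                         format(d$concordance_pct[i])),
                  if (!is.na(d$founder_discordant_pct[i]) &&
                      d$founder_discordant_pct[i] > 0)
                    sprintf(" [founder discordant %g%%]",
                            d$founder_discordant_pct[i]) else ""))
  }
  invisible(x)
}
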