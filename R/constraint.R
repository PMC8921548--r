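## gnomAD-style gene intolerance screening and constraint-entry lookup.

#' gnomAD constraint screen
#'
#' Decides whether a variant is putatively detrimental from gene-level
#' population constraint: a truncating variant in a loss-of-function
#' intolerant gene (`pli > pli_cut`, default 0.90) or a missense/in-frame
#' variant in a missense-constrained gene (`mis_z > mis_z_cut`, default 3).
#' The class-metric pairing is strict: pLI is never applied to missense
#' variants nor mis_z to truncating variants. When the class-matched metric
#' is missing the screen cannot assert intolerance and returns `FALSE` with
#' a warning, regardless of the other metric.
#'
#' @param obs a variant observation (list or one-row data.frame) with at
#'   least `variant_class`; `gene` is checked against `entry` when both
#'   are present.
#' @param entry a constraint entry (list or one-row data.frame) with `pli`
#'   and `mis_z`.
#' @param thresholds a [cm_thresholds()] object.
#' @return `TRUE` or `FALSE`.
#' @export
gnomad_screen <- function(obs, entry, thresholds = cm_thresholds()) {
  if (!is.null(obs$gene) && !is.null(entry$gene) &&
      !identical(as.character(obs$gene), as.character(entry$gene)))
    validation_error(sprintf("constraint entry gene '%s' does not match '%s'",
                             entry$gene, obs$gene))
  cls <- as.character(obs$variant_class)
  if (cls == "truncating") {
    pli <- entry$pli
    if (is.null(pli) || is.na(pli)) {
      warning(sprintf("gene %s: pLI missing; cannot screen truncating variant",
                      entry$gene %||% "?"), call. = FALSE)
      return(FALSE)
    }
    return(pli > thresholds$pli_cut)
  }
  if (cls == "non_truncating") {
    mz <- entry$mis_z
    if (is.null(mz) || is.na(mz)) {
      warning(sprintf("gene %s: mis_z missing; cannot screen missense variant",
                      entry$gene %||% "?"), call. = FALSE)
      return(FALSE)
    }
    return(mz > thresholds$mis_z_cut)
  }
  FALSE
}

#' Resolve the constraint entry for a variant observation
#'
#' Matches on gene, variant class and subtype compatibility: the entry's
#' subtype equals the patient's, or the entry applies to `ANY` subtype, or
#' the patient has unclassified cardiomyopathy (in which case subtype
#' matching is impossible and any subtype's evidence is usable). When both
#' region-restricted and gene-wide entries match, a region entry is
#' preferred iff the observation's protein position falls inside its
#' (inclusive) residue interval; among several containing regions the one
#' with the highest EF wins. Among gene-wide entries, burden-analysed
#' entries (non-missing `has_case_excess`) are preferred over gnomAD-only
#' entries, significant case excess over non-significant, then higher EF.
#'
#' @param obs a variant observation (list or one-row data.frame).
#' @param constraints a constraint table data.frame.
#' @return a one-row data.frame (the chosen entry) or `NULL` when nothing
#'   matches.
#' @export
lookup_constraint <- function(obs, constraints) {
  cls <- as.character(obs$variant_class)
  if (!cls %in% CONSTRAINT_CLASSES) return(NULL)
  sub <- as.character(obs$subtype)
  hit <- constraints$gene == as.character(obs$gene) &
    constraints$variant_class == cls &
    (constraints$subtype == sub | constraints$subtype == "ANY" |
       sub == "CM_unclassified")
  cand <- constraints[hit, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)

  pos <- obs$protein_position
  has_region <- !is.na(cand$region_start)
  if (!is.null(pos) && !is.na(pos)) {
    inside <- has_region & cand$region_start <= pos & pos <= cand$region_end
    if (any(inside)) {
      reg <- cand[inside, , drop = FALSE]
      ef_key <- ifelse(is.na(reg$ef), -Inf, reg$ef)
      return(reg[which.max(ef_key), , drop = FALSE])
    }
  }
  wide <- cand[!has_region, , drop = FALSE]
  if (nrow(wide) == 0L) return(NULL)
  analysed <- !is.na(wide$has_case_excess)
  signif <- analysed & wide$has_case_excess
  ef_key <- ifelse(is.na(wide$ef), -Inf, wide$ef)
  ord <- order(-as.integer(analysed), -as.integer(signif), -ef_key)
  wide[ord[1L], , drop = FALSE]
}
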