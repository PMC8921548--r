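## ACMG/AMP evidence assignment and combining, with the EF-banded PM1
## adaptation used for constraint-metric-driven cardiomyopathy variant
## interpretation.

ACMG_NATIVE_STRENGTH <- c(
  PVS1 = "very_strong",
  PS1 = "strong", PS2 = "strong", PS3 = "strong", PS4 = "strong",
  PM1 = "moderate", PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
  PM5 = "moderate", PM6 = "moderate",
  PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
  PP4 = "supporting", PP5 = "supporting",
  BA1 = "standalone",
  BS1 = "strong", BS2 = "strong", BS3 = "strong", BS4 = "strong",
  BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
  BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
  BP7 = "supporting")

STRENGTH_LEVELS <- c("standalone", "very_strong", "strong", "moderate",
                     "supporting")

#' A single piece of ACMG evidence
#'
#' @param criterion one of the 28 ACMG criterion codes (`PVS1`, `PS1`..`PS4`,
#'   `PM1`..`PM6`, `PP1`..`PP5`, `BA1`, `BS1`..`BS4`, `BP1`..`BP7`).
#' @param strength effective strength; defaults to the criterion's native
#'   level. Overriding (e.g. `PM1` applied at `strong` for EF >= 0.95)
#'   records both the override and the native level.
#' @return a one-row data.frame with `criterion`, `strength`,
#'   `native_strength`.
#' @export
evidence <- function(criterion, strength = NULL) {
  if (!criterion %in% names(ACMG_NATIVE_STRENGTH))
    validation_error(paste0("unknown ACMG criterion: ", criterion))
  native <- ACMG_NATIVE_STRENGTH[[criterion]]
  strength <- strength %||% native
  if (!strength %in% STRENGTH_LEVELS)
    validation_error(paste0("unknown evidence strength: ", strength))
  data.frame(criterion = criterion, strength = strength,
             native_strength = native, stringsAsFactors = FALSE)
}

#' An evidence set with provenance
#'
#' @param items a data.frame of [evidence()] rows (criteria must be unique).
#' @param provenance character vector of human-readable rationale strings.
#' @return an object of class `evidence_set`.
#' @export
evidence_set <- function(items = NULL, provenance = character(0)) {
  if (is.null(items))
    items <- data.frame(criterion = character(0), strength = character(0),
                        native_strength = character(0),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(items$criterion))
    validation_error("a criterion may appear at most once per evidence set")
  structure(list(items = items, provenance = provenance),
            class = "evidence_set")
}

add_evidence <- function(ev, item, why = NULL) {
  if (is.null(item)) return(ev)
  ev$items <- rbind(ev$items, item)
  if (anyDuplicated(ev$items$criterion))
    validation_error("a criterion may appear at most once per evidence set")
  if (!is.null(why)) ev$provenance <- c(ev$provenance, why)
  ev
}

has_criterion <- function(ev, criterion) criterion %in% ev$items$criterion

#' Serialize an evidence set to its token form
#'
#' Criteria are comma-joined; a strength suffix is attached only when the
#' effective strength differs from the native one, e.g.
#' `"PM1:strong,PM2,PP3"`.
#'
#' @param ev an [evidence_set()].
#' @return a single string (empty for an empty set).
#' @export
format_evidence_set <- function(ev) {
  it <- ev$items
  if (nrow(it) == 0L) return("")
  tok <- ifelse(it$strength == it$native_strength, it$criterion,
                paste0(it$criterion, ":", it$strength))
  paste(tok, collapse = ",")
}

#' Parse the token form back into an evidence set
#' @param x a string such as `"PM1:strong,PM2,PP3"`.
#' @return an [evidence_set()].
#' @export
parse_evidence_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(evidence_set())
  toks <- strsplit(x, ",", fixed = TRUE)[[1]]
  items <- do.call(rbind, lapply(toks, function(tk) {
    parts <- strsplit(tk, ":", fixed = TRUE)[[1]]
    evidence(parts[1], if (length(parts) > 1L) parts[2] else NULL)
  }))
  evidence_set(items)
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("ACMG evidence:", if (nrow(x$items)) format_evidence_set(x) else
    "(none)", "\n")
  for (p in x$provenance) cat("  -", p, "\n")
  invisible(x)
}

#' Map an etiological fraction to the EF-banded PM1 criterion
#'
#' The hotspot/functional-domain criterion PM1 is applied at a strength set
#' by the etiological fraction of the matching gene (or protein region) and
#' variant class, with left-closed bands:
#' `EF >= 0.95` -> PM1 at strong; `0.90 <= EF < 0.95` -> PM1 at moderate;
#' `0.80 <= EF < 0.90` -> PM1 at supporting; below 0.80 no criterion.
#'
#' @param ef etiological fraction in `[0, 1]` (must be present).
#' @param thresholds a [cm_thresholds()] object supplying the band edges.
#' @return an [evidence()] row, or `NULL` for `ef` below the lowest band.
#' @export
ef_to_pm1 <- function(ef, thresholds = cm_thresholds()) {
  if (is.null(ef) || is.na(ef))
    validation_error("ef must be present for PM1 banding")
  if (ef >= thresholds$ef_strong_low) return(evidence("PM1", "strong"))
  if (ef >= thresholds$ef_moderate_low) return(evidence("PM1", "moderate"))
  if (ef >= thresholds$ef_supporting_low) return(evidence("PM1", "supporting"))
  NULL
}

#' Assign ACMG evidence for one variant observation
#'
#' Emits the criteria this pipeline can assert from its inputs:
#'
#' * `PM1` (EF-banded via [ef_to_pm1()]) when the resolved constraint entry
#'   carries an EF;
#' * `PM2` when the popmax allele frequency is missing (absent from large
#'   population studies) or below the PM2 cutoff (0.004%);
#' * `PP3` / `PP4` from the in-silico and phenotype-specificity input flags;
#' * `PS4` when the variant was identified in at least `ps4_probands`
#'   (default 15) probands with consistent phenotypes;
#' * `PP1` at the highest applicable co-segregation tier only
#'   (supporting/moderate/strong for >= 3/5/7 segregating meioses).
#'
#' Absent inputs simply yield no criterion; benign-side criteria are never
#' emitted by this pipeline (no variant class showed significant depletion
#' in cases).
#'
#' @param obs a variant observation (list or one-row data.frame).
#' @param entry the constraint entry resolved by [lookup_constraint()], or
#'   `NULL`.
#' @param thresholds a [cm_thresholds()] object.
#' @return an [evidence_set()] whose provenance records each trigger.
#' @export
assign_evidence <- function(obs, entry, thresholds = cm_thresholds()) {
  t <- thresholds
  ev <- evidence_set()

  if (!is.null(entry) && !is.na(entry$ef)) {
    pm1 <- ef_to_pm1(entry$ef, t)
    if (!is.null(pm1)) {
      where <- if (!is.na(entry$region_start))
        sprintf("region %d-%d", entry$region_start, entry$region_end)
      else "gene-wide"
      ev <- add_evidence(ev, pm1,
        sprintf("PM1@%s: EF=%g (%s, %s %s)", pm1$strength, entry$ef, where,
                entry$gene, entry$variant_class))
    }
  }

  af <- obs$popmax_af
  if (is.null(af) || is.na(af)) {
    ev <- add_evidence(ev, evidence("PM2"),
      "PM2: absent from large population studies")
  } else if (af < t$pm2_maf) {
    ev <- add_evidence(ev, evidence("PM2"),
      sprintf("PM2: popmax AF %g < %g", af, t$pm2_maf))
  }

  if (isTRUE(obs$insilico_support))
    ev <- add_evidence(ev, evidence("PP3"),
      "PP3: computational evidence supports a deleterious effect")
  if (isTRUE(obs$phenotype_specific))
    ev <- add_evidence(ev, evidence("PP4"),
      "PP4: phenotype highly specific for a single genetic etiology")

  pc <- obs$proband_count
  if (!is.null(pc) && !is.na(pc) && pc >= t$ps4_probands)
    ev <- add_evidence(ev, evidence("PS4"),
      sprintf("PS4: identified in %d probands (>= %d)", pc, t$ps4_probands))

  sm <- obs$segregating_meioses
  if (!is.null(sm) && !is.na(sm) && sm >= t$pp1_supporting) {
    tier <- if (sm >= t$pp1_strong) "strong"
            else if (sm >= t$pp1_moderate) "moderate"
            else "supporting"
    ev <- add_evidence(ev, evidence("PP1", tier),
      sprintf("PP1@%s: segregates with %d meioses", tier, sm))
  }

  ev
}

#' Combine an evidence set into a five-tier classification
#'
#' Evaluates the full published combining table over effective strengths
#' (a strength override counts at its override level in every rule).
#' Pathogenic rules take precedence over likely-pathogenic; conflicting
#' pathogenic- and benign-side evidence yields `vus`, as does an evidence
#' set firing no rule.
#'
#' @param ev an [evidence_set()], or a data.frame of [evidence()] rows.
#' @return one of `"pathogenic"`, `"likely_pathogenic"`, `"vus"`,
#'   `"likely_benign"`, `"benign"`.
#' @export
combine_acmg <- function(ev) {
  items <- if (inherits(ev, "evidence_set")) ev$items else ev
  if (anyDuplicated(items$criterion))
    validation_error("a criterion may appear at most once per evidence set")
  benign <- grepl("^B", items$criterion)
  ps <- items$strength[!benign]
  bs <- items$strength[benign]
  nvs <- sum(ps == "very_strong")
  nst <- sum(ps == "strong")
  nmo <- sum(ps == "moderate")
  nsu <- sum(ps == "supporting")
  nba <- sum(bs == "standalone")
  nbs <- sum(bs == "strong")
  nbp <- sum(bs == "supporting")

  pathogenic <-
    nvs >= 2 ||
    (nvs >= 1 && (nst >= 1 || nmo >= 2 || (nmo >= 1 && nsu >= 1) ||
                    nsu >= 2)) ||
    nst >= 2 ||
    (nst >= 1 && (nmo >= 3 || (nmo >= 2 && nsu >= 2) ||
                    (nmo >= 1 && nsu >= 4)))
  likely_pathogenic <- pathogenic ||
    (nvs >= 1 && nmo >= 1) ||
    (nst >= 1 && nmo >= 1) ||
    (nst >= 1 && nsu >= 2) ||
    nmo >= 3 ||
    (nmo >= 2 && nsu >= 2) ||
    (nmo >= 1 && nsu >= 4)
  benign_cls <- nba >= 1 || nbs >= 2
  likely_benign <- benign_cls || (nbs >= 1 && nbp >= 1) || nbp >= 2

  if (likely_pathogenic && likely_benign) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign_cls) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}
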