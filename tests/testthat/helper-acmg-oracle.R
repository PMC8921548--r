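# Independent oracle for the five-tier evidence combining table.
#
# This is a literal, rule-by-rule transcription of the published combining
# guideline, deliberately structured as an explicit list of requirement
# vectors (counts of very-strong / strong / moderate / supporting evidence
# per side) rather than the arithmetic short-circuits the engine uses, so
# that the two implementations can only agree by computing the same table.

oracle_combine <- function(strengths_path, strengths_benign = character(0)) {
  n <- function(v, s) sum(v == s)
  vs <- n(strengths_path, "very_strong")
  st <- n(strengths_path, "strong")
  mo <- n(strengths_path, "moderate")
  su <- n(strengths_path, "supporting")
  ba <- n(strengths_benign, "standalone")
  bs <- n(strengths_benign, "strong")
  bp <- n(strengths_benign, "supporting")

  path_rules <- list(
    c(vs = 2, st = 0, mo = 0, su = 0),  # >=2 very strong
    c(vs = 1, st = 1, mo = 0, su = 0),  # Ia: PVS + >=1 strong
    c(vs = 1, st = 0, mo = 2, su = 0),  # Ib: PVS + >=2 moderate
    c(vs = 1, st = 0, mo = 1, su = 1),  # Ic: PVS + 1 moderate + 1 supporting
    c(vs = 1, st = 0, mo = 0, su = 2),  # Id: PVS + >=2 supporting
    c(vs = 0, st = 2, mo = 0, su = 0),  # II: >=2 strong
    c(vs = 0, st = 1, mo = 3, su = 0),  # IIIa
    c(vs = 0, st = 1, mo = 2, su = 2),  # IIIb
    c(vs = 0, st = 1, mo = 1, su = 4)   # IIIc
  )
  lp_rules <- list(
    c(vs = 1, st = 0, mo = 1, su = 0),  # i
    c(vs = 0, st = 1, mo = 1, su = 0),  # ii: 1 strong + 1-2 moderate
    c(vs = 0, st = 1, mo = 0, su = 2),  # iii: 1 strong + >=2 supporting
    c(vs = 0, st = 0, mo = 3, su = 0),  # iv
    c(vs = 0, st = 0, mo = 2, su = 2),  # v
    c(vs = 0, st = 0, mo = 1, su = 4)   # vi
  )
  meets <- function(rule) vs >= rule["vs"] && st >= rule["st"] &&
    mo >= rule["mo"] && su >= rule["su"]
  is_path <- any(vapply(path_rules, meets, TRUE))
  is_lp <- is_path || any(vapply(lp_rules, meets, TRUE))
  is_ben <- ba >= 1 || bs >= 2
  is_lb <- is_ben || (bs >= 1 && bp >= 1) || bp >= 2

  if (is_lp && is_lb) return("vus")  # conflicting evidence
  if (is_path) return("pathogenic")
  if (is_lp) return("likely_pathogenic")
  if (is_ben) return("benign")
  if (is_lb) return("likely_benign")
  "vus"
}

# native strengths used by the oracle when enumerating criterion subsets
oracle_native <- c(PVS1 = "very_strong",
                   PS1 = "strong", PS2 = "strong", PS3 = "strong",
                   PS4 = "strong",
                   PM1 = "moderate", PM2 = "moderate", PM3 = "moderate",
                   PM4 = "moderate", PM5 = "moderate", PM6 = "moderate",
                   PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
                   PP4 = "supporting", PP5 = "supporting",
                   BA1 = "standalone",
                   BS1 = "strong", BS2 = "strong", BS3 = "strong",
                   BS4 = "strong",
                   BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
                   BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
                   BP7 = "supporting")

oracle_combine_criteria <- function(criteria,
                                    overrides = character(0)) {
  str <- oracle_native[criteria]
  str[names(overrides)[names(overrides) %in% criteria]] <-
    overrides[names(overrides) %in% criteria]
  benign <- grepl("^B", criteria)
  oracle_combine(unname(str[!benign]), unname(str[benign]))
}
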