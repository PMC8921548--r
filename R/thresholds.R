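#' Interpretation thresholds
#'
#' Bundles every tunable cutoff used by the triage pipeline. Defaults follow
#' the published cardiomyopathy interpretation framework:
#'
#' * `rare_maf` (1e-4): population MAF below which a variant counts as "rare"
#'   for burden comparisons against reference samples.
#' * `pm2_maf` (4e-5, i.e. 0.004%): ACMG PM2 "absent/extremely rare" cutoff;
#'   a missing population frequency also satisfies PM2.
#' * `ef_reclass` (0.90): minimum etiological fraction for immediate
#'   VUS -> LP reclassification.
#' * `ef_supporting_low` / `ef_moderate_low` / `ef_strong_low`
#'   (0.80 / 0.90 / 0.95): left-closed EF band edges mapping to
#'   PM1 at supporting / moderate / strong.
#' * `pli_cut` (0.90), `mis_z_cut` (3.0): gnomAD gene-intolerance screen for
#'   truncating resp. missense variants (strict class-metric pairing).
#' * `ps4_probands` (15): minimum independent probands for PS4.
#' * `pp1_supporting` / `pp1_moderate` / `pp1_strong` (3/5/7): minimum
#'   segregating meioses for the tiered co-segregation criterion PP1.
#' * `alpha` (0.05): two-sided significance level for the case-excess test.
#'
#' @param rare_maf,pm2_maf,ef_reclass,ef_supporting_low,ef_moderate_low,ef_strong_low,pli_cut,mis_z_cut,ps4_probands,pp1_supporting,pp1_moderate,pp1_strong,alpha
#'   see above.
#' @return an object of class `cm_thresholds` (a validated named list).
#' @examples
#' t <- cm_thresholds()
#' t$ef_reclass
#' @export
cm_thresholds <- function(rare_maf = 1e-4,
                          pm2_maf = 4e-5,
                          ef_reclass = 0.90,
                          ef_supporting_low = 0.80,
                          ef_moderate_low = 0.90,
                          ef_strong_low = 0.95,
                          pli_cut = 0.90,
                          mis_z_cut = 3.0,
                          ps4_probands = 15L,
                          pp1_supporting = 3L,
                          pp1_moderate = 5L,
                          pp1_strong = 7L,
                          alpha = 0.05) {
  t <- list(rare_maf = rare_maf, pm2_maf = pm2_maf, ef_reclass = ef_reclass,
            ef_supporting_low = ef_supporting_low,
            ef_moderate_low = ef_moderate_low,
            ef_strong_low = ef_strong_low,
            pli_cut = pli_cut, mis_z_cut = mis_z_cut,
            ps4_probands = as.integer(ps4_probands),
            pp1_supporting = as.integer(pp1_supporting),
            pp1_moderate = as.integer(pp1_moderate),
            pp1_strong = as.integer(pp1_strong),
            alpha = alpha)
  fracs <- c("rare_maf", "pm2_maf", "ef_reclass", "ef_supporting_low",
             "ef_moderate_low", "ef_strong_low", "pli_cut", "alpha")
  for (f in fracs) {
    v <- t[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      validation_error("must be a fraction in [0, 1]", field = f)
  }
  if (!(t$ef_supporting_low < t$ef_moderate_low &&
        t$ef_moderate_low < t$ef_strong_low && t$ef_strong_low <= 1))
    validation_error(
      "EF band edges must satisfy supporting < moderate < strong <= 1")
  if (!(t$pp1_supporting <= t$pp1_moderate && t$pp1_moderate <= t$pp1_strong))
    validation_error("PP1 meiosis tiers must be non-decreasing")
  structure(t, class = "cm_thresholds")
}

#' Read thresholds from a JSON config file
#'
#' Any subset of the [cm_thresholds()] fields may be present; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path path to a JSON object of threshold overrides.
#' @param base thresholds to override, default [cm_thresholds()].
#' @return a `cm_thresholds` object.
#' @export
thresholds_from_json <- function(path, base = cm_thresholds()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    validation_error(paste0("unknown threshold key(s): ",
                            paste(unknown, collapse = ", ")))
  args <- utils::modifyList(unclass(base), as.list(cfg))
  do.call(cm_thresholds, args)
}

#' @export
print.cm_thresholds <- function(x, ...) {
  cat("Cardiomyopathy triage thresholds\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
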