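## Seeded synthetic diagnostic cohorts with the statistical structure the
## triage analysis assumes: subtype mix, per-gene etiological fractions,
## planted prior (L)P calls, Poisson VUS multiplicity with Bernoulli
## evidence flags, and founder contamination.

#' Simulation configuration
#'
#' @param n_patients cohort size (default 2002, a consecutive diagnostic
#'   referral series).
#' @param subtype_mix named fractions over the five subtypes, summing to 1.
#' @param n_genes_ce number of genes with published case-excess analyses
#'   (default 33, split over HCM/DCM/ACM).
#' @param n_genes_gnomad number of additional gnomAD-only genes.
#' @param ef_distribution list `(shape1, shape2, lo, hi)`: per-gene EF is
#'   drawn as `lo + (hi-lo) * Beta(shape1, shape2)`.
#' @param p_ce_significant probability that a burden-analysed gene has
#'   significant case excess.
#' @param lp_rate probability a patient carries a prior (L)P (matches a
#'   ~21.5% diagnostic yield by default).
#' @param p_lp_in_ce fraction of prior (L)Ps planted in burden-analysed
#'   genes (the remainder go to gnomAD-only genes).
#' @param vus_per_patient Poisson rate of VUS observations per patient.
#' @param p_pm2_pass,p_pp3,p_pp4 Bernoulli rates for the PM2 frequency
#'   condition and the PP3/PP4 input flags.
#' @param founder_rate founder-variant contamination rate among prior
#'   (L)Ps (default 4%).
#' @param seed mandatory integer seed; per-component substreams are derived
#'   from it deterministically.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2002L,
                       subtype_mix = c(HCM = 0.34, DCM = 0.38, ACM = 0.04,
                                       LVNC = 0.08, CM_unclassified = 0.16),
                       n_genes_ce = 33L,
                       n_genes_gnomad = 10L,
                       ef_distribution = list(shape1 = 8, shape2 = 2,
                                              lo = 0, hi = 1),
                       p_ce_significant = 0.8,
                       lp_rate = 0.215,
                       p_lp_in_ce = 0.9,
                       vus_per_patient = 0.5,
                       p_pm2_pass = 0.9,
                       p_pp3 = 0.8,
                       p_pp4 = 0.7,
                       founder_rate = 0.04,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    validation_error("seed is mandatory", field = "seed")
  if (!setequal(names(subtype_mix), SUBTYPES))
    validation_error("subtype_mix must name all five subtypes",
                     field = "subtype_mix")
  if (abs(sum(subtype_mix) - 1) > 1e-9)
    validation_error("subtype_mix must sum to 1", field = "subtype_mix")
  for (p in c("p_ce_significant", "lp_rate", "p_lp_in_ce", "p_pm2_pass",
              "p_pp3", "p_pp4", "founder_rate")) {
    v <- get(p)
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      validation_error("must be a fraction in [0, 1]", field = p)
  }
  structure(list(n_patients = as.integer(n_patients),
                 subtype_mix = subtype_mix[SUBTYPES],
                 n_genes_ce = as.integer(n_genes_ce),
                 n_genes_gnomad = as.integer(n_genes_gnomad),
                 ef_distribution = ef_distribution,
                 p_ce_significant = p_ce_significant,
                 lp_rate = lp_rate, p_lp_in_ce = p_lp_in_ce,
                 vus_per_patient = vus_per_patient,
                 p_pm2_pass = p_pm2_pass, p_pp3 = p_pp3, p_pp4 = p_pp4,
                 founder_rate = founder_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.substream <- function(seed, k) set.seed((seed %% 2000000000L) + k)

#' Generate a synthetic cohort and constraint table
#'
#' Draws per-gene EFs from the configured distribution, plants prior (L)P
#' observations at `lp_rate` (a configurable fraction in burden-analysed
#' genes, with founder contamination), and gives each patient a
#' Poisson-distributed number of VUS observations with Bernoulli
#' PM2/PP3/PP4 characteristics. Reproducible given the seed; the output
#' always passes [validate_variant_table()] and
#' [validate_constraint_table()].
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `variants` and `constraints`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ed <- cfg$ef_distribution

  ## -- constraint table (substream 1) --
  .substream(cfg$seed, 1L)
  ce_sub <- rep(c("HCM", "DCM", "ACM"), length.out = cfg$n_genes_ce)
  ce_cls <- rep(c("truncating", "non_truncating"),
                length.out = cfg$n_genes_ce)
  ef <- ed$lo + (ed$hi - ed$lo) *
    stats::rbeta(cfg$n_genes_ce, ed$shape1, ed$shape2)
  ce <- data.frame(
    gene = sprintf("CEG%03d", seq_len(cfg$n_genes_ce)),
    subtype = ce_sub, variant_class = ce_cls,
    has_case_excess = stats::runif(cfg$n_genes_ce) < cfg$p_ce_significant,
    ef = round(ef, 6), ef_ci_low = NA_real_, ef_ci_high = NA_real_,
    region_start = NA_integer_, region_end = NA_integer_,
    pli = NA_real_, mis_z = NA_real_, stringsAsFactors = FALSE)
  gn_cls <- rep(c("truncating", "non_truncating"),
                length.out = cfg$n_genes_gnomad)
  gn <- data.frame(
    gene = sprintf("GNG%03d", seq_len(cfg$n_genes_gnomad)),
    subtype = "ANY", variant_class = gn_cls,
    has_case_excess = NA, ef = NA_real_,
    ef_ci_low = NA_real_, ef_ci_high = NA_real_,
    region_start = NA_integer_, region_end = NA_integer_,
    pli = ifelse(gn_cls == "truncating",
                 round(stats::runif(cfg$n_genes_gnomad, 0.85, 1), 4),
                 NA_real_),
    mis_z = ifelse(gn_cls == "non_truncating",
                   round(stats::runif(cfg$n_genes_gnomad, 2.5, 4.5), 3),
                   NA_real_),
    stringsAsFactors = FALSE)
  constraints <- rbind(ce, gn)

  ## -- patients (substream 2) --
  .substream(cfg$seed, 2L)
  n <- cfg$n_patients
  subtype <- sample(SUBTYPES, n, replace = TRUE, prob = cfg$subtype_mix)
  vc <- 0L
  rows <- vector("list", 4L * n)
  nr <- 0L
  push <- function(row) {
    nr <<- nr + 1L
    rows[[nr]] <<- row
  }
  obs <- function(i, gene, cls, prior, af, pos = NA_integer_,
                  insil = FALSE, pheno = FALSE, founder = FALSE) {
    vc <<- vc + 1L
    data.frame(patient_id = sprintf("SP%05d", i),
               family_id = sprintf("SF%05d", i),
               subtype = subtype[i], gene = gene,
               variant_id = sprintf("SV%06d", vc),
               variant_class = cls, popmax_af = af,
               protein_position = pos,
               insilico_support = insil, phenotype_specific = pheno,
               proband_count = 0L, segregating_meioses = 0L,
               prior_class = prior, founder_flag = founder,
               stringsAsFactors = FALSE)
  }
  compatible_ce <- function(sub) {
    if (sub == "CM_unclassified") ce
    else ce[ce$subtype == sub, , drop = FALSE]
  }
  for (i in seq_len(n)) {
    pool <- compatible_ce(subtype[i])
    if (stats::runif(1) < cfg$lp_rate) {
      in_ce <- nrow(pool) > 0L && stats::runif(1) < cfg$p_lp_in_ce
      src <- if (in_ce) pool else gn
      g <- src[sample.int(nrow(src), 1L), ]
      push(obs(i, g$gene, g$variant_class,
               prior = sample(4:5, 1L), af = NA_real_,
               founder = stats::runif(1) < cfg$founder_rate))
    }
    nv <- stats::rpois(1L, cfg$vus_per_patient)
    for (k in seq_len(nv)) {
      u <- stats::runif(1)
      src <- if (u < 0.7 && nrow(pool) > 0L) pool
             else if (u < 0.9) gn
             else data.frame(gene = sprintf("BGG%02d", sample.int(20L, 1L)),
                             variant_class = sample(
                               c("truncating", "non_truncating"), 1L),
                             stringsAsFactors = FALSE)
      g <- src[sample.int(nrow(src), 1L), ]
      pm2 <- stats::runif(1) < cfg$p_pm2_pass
      push(obs(i, g$gene, g$variant_class, prior = 3L,
               af = if (pm2) NA_real_ else stats::runif(1, 5e-5, 1e-3),
               insil = stats::runif(1) < cfg$p_pp3,
               pheno = stats::runif(1) < cfg$p_pp4))
    }
  }
  ## ensure every patient appears (pipeline denominators count patients)
  seen <- vapply(rows[seq_len(nr)], function(r) r$patient_id[1L], "")
  for (i in which(!sprintf("SP%05d", seq_len(n)) %in% seen))
    push(obs(i, sprintf("BGG%02d", 1L + i %% 20L), "non_truncating",
             prior = 2L, af = 1e-3))
  variants <- do.call(rbind, rows[seq_len(nr)])
  variants <- variants[order(variants$patient_id, variants$variant_id), ]
  rownames(variants) <- NULL
  validate_variant_table(variants)
  validate_constraint_table(constraints)
  list(variants = variants, constraints = constraints)
}

#' EF estimator recovery experiment
#'
#' Simulates carrier burden counts under a known true etiological fraction
#' and summarises how well [compute_burden()] recovers it: mean estimate,
#' bias (with the first-order delta-method bias of the frequency-ratio
#' estimator for reference), Monte-Carlo standard error, coverage of the
#' nominal CI among all-positive-cell replicates, and the fraction of
#' replicates whose estimate falls outside the true EF's PM1 band
#' (0.8/0.9/0.95 boundaries).
#'
#' @param true_ef true etiological fraction.
#' @param f_ctrl control carrier frequency; the case frequency is
#'   `f_ctrl / (1 - true_ef)`. Default 0.004, an aggregate rare-variant
#'   carrier frequency typical of a large cardiomyopathy gene.
#' @param case_n,control_n cohort sizes (defaults 1000 cases vs the 60706
#'   reference samples of the exome aggregation era).
#' @param n_reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @param thresholds a [cm_thresholds()] (band edges and alpha).
#' @return a list of summary statistics (see Description).
#' @export
parameter_recovery_experiment <- function(true_ef = 0.9, f_ctrl = 0.004,
                                          case_n = 1000L, control_n = 60706L,
                                          n_reps = 500L, seed = 1L,
                                          thresholds = cm_thresholds()) {
  stopifnot(true_ef < 1)
  f_case <- f_ctrl / (1 - true_ef)
  stopifnot(f_case <= 1)
  .substream(as.integer(seed), 3L)
  band <- function(e) {
    findInterval(e, c(thresholds$ef_supporting_low,
                      thresholds$ef_moderate_low, thresholds$ef_strong_low))
  }
  ef_hat <- rep(NA_real_, n_reps)
  covered <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    a <- stats::rbinom(1L, case_n, f_case)
    c0 <- stats::rbinom(1L, control_n, f_ctrl)
    br <- compute_burden(list(case_carriers = a, case_n = case_n,
                              control_carriers = c0, control_n = control_n),
                         alpha = thresholds$alpha)
    if (br$ef_defined) ef_hat[r] <- br$ef
    if (!is.na(br$ef_ci_low))
      covered[r] <- br$ef_ci_low <= true_ef && true_ef <= br$ef_ci_high
  }
  ok <- !is.na(ef_hat)
  mean_ef <- mean(ef_hat[ok])
  sd_ef <- stats::sd(ef_hat[ok])
  list(true_ef = true_ef, f_case = f_case, f_ctrl = f_ctrl,
       case_n = case_n, control_n = control_n,
       n_reps = n_reps, n_defined = sum(ok),
       mean_ef = mean_ef, bias = mean_ef - true_ef,
       sd_ef = sd_ef, mc_se = sd_ef / sqrt(sum(ok)),
       first_order_bias = -(1 - true_ef) * (1 - f_case) / (case_n * f_case),
       ci_coverage = mean(covered, na.rm = TRUE),
       n_ci = sum(!is.na(covered)),
       misbin_rate = mean(band(ef_hat[ok]) != band(true_ef)))
}
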