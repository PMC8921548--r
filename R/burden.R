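## Case excess and etiological fraction from carrier burden counts.
##
## Definitions follow the rare-variant burden convention of the ExAC-era
## cardiomyopathy case-control studies (the Walsh convention): with
## f_case = case_carriers/case_n and f_ctrl = control_carriers/control_n,
##   CE = f_case - f_ctrl
##   EF = (f_case - f_ctrl)/f_case = 1 - f_ctrl/f_case
## EF is the attributable fraction: the probability that a rare variant of
## that class, observed in an affected carrier, is disease-causing.

#' Case excess and etiological fraction for one carrier table
#'
#' Computes the case-excess score (difference of carrier frequencies), the
#' etiological fraction, a two-sided exact test on the 2x2 carrier table,
#' and an EF confidence interval obtained by mapping the exact
#' (conditional maximum-likelihood) odds-ratio interval through
#' `1 - 1/OR`, clamped to EF's attainable range. The CI is reported missing
#' whenever any cell of the 2x2 table is zero. With no case carriers the EF
#' is undefined (an attributable fraction has no meaning without exposed
#' cases) and is reported missing, never zero.
#'
#' @param counts a list or one-row data.frame with `case_carriers`,
#'   `case_n`, `control_carriers`, `control_n`.
#' @param alpha two-sided significance level for the case-excess call
#'   (default 0.05). Significance additionally requires a positive CE.
#' @return an object of class `burden_result`: a list with elements `ce`,
#'   `ef`, `ef_defined`, `p_value`, `significant`, `ef_ci_low`,
#'   `ef_ci_high`, `odds_ratio` (conditional MLE), `f_case`, `f_ctrl` and
#'   the input counts.
#' @examples
#' compute_burden(list(case_carriers = 20, case_n = 100,
#'                     control_carriers = 2, control_n = 1000))
#' @export
compute_burden <- function(counts, alpha = 0.05) {
  a <- as.integer(counts$case_carriers)
  cn <- as.integer(counts$case_n)
  c0 <- as.integer(counts$control_carriers)
  kn <- as.integer(counts$control_n)
  if (anyNA(c(a, cn, c0, kn)))
    validation_error("burden counts must all be present")
  validate_burden_table(data.frame(
    gene = counts$gene %||% "g", subtype = counts$subtype %||% "ANY",
    variant_class = counts$variant_class %||% "truncating",
    case_carriers = a, case_n = cn, control_carriers = c0, control_n = kn,
    stringsAsFactors = FALSE))

  f_case <- a / cn
  f_ctrl <- c0 / kn
  ce <- f_case - f_ctrl
  ef_defined <- a > 0L
  ef <- if (ef_defined) 1 - f_ctrl / f_case else NA_real_

  tab <- matrix(c(a, cn - a, c0, kn - c0), nrow = 2L)
  ft <- stats::fisher.test(tab, conf.level = 1 - alpha)
  p <- ft$p.value
  significant <- (p < alpha) && (ce > 0)

  ef_ci_low <- ef_ci_high <- NA_real_
  if (all(tab > 0L)) {
    or_ci <- ft$conf.int
    ef_ci_low <- 1 - 1 / or_ci[1]
    ef_ci_high <- min(1 - 1 / or_ci[2], 1)
  }

  structure(list(
    ce = ce, ef = ef, ef_defined = ef_defined,
    p_value = p, significant = significant,
    ef_ci_low = ef_ci_low, ef_ci_high = ef_ci_high,
    odds_ratio = unname(ft$estimate),
    f_case = f_case, f_ctrl = f_ctrl,
    case_carriers = a, case_n = cn,
    control_carriers = c0, control_n = kn,
    alpha = alpha
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Carrier burden: %d/%d cases vs %d/%d controls\n",
              x$case_carriers, x$case_n, x$control_carriers, x$control_n))
  cat(sprintf("  case excess (CE)      : %+0.4g\n", x$ce))
  if (x$ef_defined) {
    ci <- if (!is.na(x$ef_ci_low))
      sprintf("  [%0.3f, %0.3f]", x$ef_ci_low, x$ef_ci_high) else ""
    cat(sprintf("  etiological fraction  : %0.4g%s\n", x$ef, ci))
  } else {
    cat("  etiological fraction  : undefined (no case carriers)\n")
  }
  cat(sprintf("  exact test p-value    : %0.4g (%ssignificant at alpha=%g)\n",
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Burden results for a whole counts table
#'
#' Applies [compute_burden()] to every row of a burden-counts table.
#'
#' @param counts a burden-counts data.frame (see [read_burden_table()]).
#' @param alpha passed to [compute_burden()].
#' @return a data.frame with one row per input row: the grouping columns
#'   plus `ce`, `ef`, `p_value`, `significant`, `ef_ci_low`, `ef_ci_high`.
#' @export
burden_table <- function(counts, alpha = 0.05) {
  validate_burden_table(counts)
  res <- lapply(seq_len(nrow(counts)),
                function(i) compute_burden(counts[i, ], alpha))
  data.frame(
    gene = counts$gene, subtype = counts$subtype,
    variant_class = counts$variant_class,
    ce = vapply(res, `[[`, 0, "ce"),
    ef = vapply(res, `[[`, 0, "ef"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    significant = vapply(res, `[[`, TRUE, "significant"),
    ef_ci_low = vapply(res, `[[`, 0, "ef_ci_low"),
    ef_ci_high = vapply(res, `[[`, 0, "ef_ci_high"),
    stringsAsFactors = FALSE)
}
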