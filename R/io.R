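## Readers, writers and invariant validation for the three tab-delimited
## tables the pipeline consumes (variant observations, gene constraint
## entries, carrier burden counts) and the decisions table it emits.
##
## Conventions shared by all tables: UTF-8 TSV with a mandatory header row;
## missing values are an empty cell or the literal token "NA" ("." is NOT
## accepted and is rejected as an invalid token); row order is preserved.

## ---- column specifications ------------------------------------------------

.col <- function(name, type, values = NULL, required = FALSE,
                 min = NULL, max = NULL) {
  list(name = name, type = type, values = values, required = required,
       min = min, max = max)
}

variant_cols <- function() list(
  .col("patient_id", "chr", required = TRUE),
  .col("family_id", "chr", required = TRUE),
  .col("subtype", "enum", values = SUBTYPES, required = TRUE),
  .col("gene", "chr", required = TRUE),
  .col("variant_id", "chr", required = TRUE),
  .col("variant_class", "enum", values = VARIANT_CLASSES, required = TRUE),
  .col("popmax_af", "num", min = 0, max = 1),
  .col("protein_position", "int", min = 1),
  .col("insilico_support", "lgl", required = TRUE),
  .col("phenotype_specific", "lgl", required = TRUE),
  .col("proband_count", "int", required = TRUE, min = 0),
  .col("segregating_meioses", "int", required = TRUE, min = 0),
  .col("prior_class", "prior", required = TRUE),
  .col("founder_flag", "lgl", required = TRUE)
)

constraint_cols <- function() list(
  .col("gene", "chr", required = TRUE),
  .col("subtype", "enum", values = c(SUBTYPES, "ANY"), required = TRUE),
  .col("variant_class", "enum", values = CONSTRAINT_CLASSES, required = TRUE),
  .col("has_case_excess", "lgl"),
  .col("ef", "num", min = 0, max = 1),
  .col("ef_ci_low", "num", min = 0, max = 1),
  .col("ef_ci_high", "num", min = 0, max = 1),
  .col("region_start", "int", min = 1),
  .col("region_end", "int", min = 1),
  .col("pli", "num", min = 0, max = 1),
  .col("mis_z", "num")
)

burden_cols <- function() list(
  .col("gene", "chr", required = TRUE),
  .col("subtype", "enum", values = c(SUBTYPES, "ANY"), required = TRUE),
  .col("variant_class", "enum", values = CONSTRAINT_CLASSES, required = TRUE),
  .col("case_carriers", "int", required = TRUE, min = 0),
  .col("case_n", "int", required = TRUE, min = 1),
  .col("control_carriers", "int", required = TRUE, min = 0),
  .col("control_n", "int", required = TRUE, min = 1)
)

decision_cols <- function() list(
  .col("patient_id", "chr", required = TRUE),
  .col("variant_id", "chr", required = TRUE),
  .col("route", "enum", values = c("ce_ef_gene", "gnomad_gene", "unmatched"),
       required = TRUE),
  .col("action", "enum", values = c("reclassify_LP", "prioritize", "none"),
       required = TRUE),
  .col("new_class", "enum", values = ACMG_CLASSES),
  .col("evidence", "chr"),
  .col("rationale", "chr")
)

## ---- cell parsing ---------------------------------------------------------

.is_missing_tok <- function(x) is.na(x) | x == "" | x == "NA"

.parse_cell <- function(tok, col, row) {
  if (.is_missing_tok(tok)) {
    if (isTRUE(col$required))
      validation_error("value is required but missing", row, col$name)
    return(switch(col$type, chr = NA_character_, num = NA_real_,
                  int = NA_integer_, lgl = NA, enum = NA_character_,
                  prior = NA_integer_))
  }
  switch(col$type,
    chr = tok,
    enum = {
      if (!tok %in% col$values)
        validation_error(sprintf("unknown token '%s' (expected one of: %s)",
                                 tok, paste(col$values, collapse = ", ")),
                         row, col$name)
      tok
    },
    lgl = {
      v <- switch(tok, "TRUE" = TRUE, "true" = TRUE, "T" = TRUE, "1" = TRUE,
                  "FALSE" = FALSE, "false" = FALSE, "F" = FALSE, "0" = FALSE,
                  NULL)
      if (is.null(v))
        validation_error(sprintf("not a logical value: '%s'", tok),
                         row, col$name)
      v
    },
    num = {
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v))
        validation_error(sprintf("not a number: '%s'", tok), row, col$name)
      v
    },
    int = {
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v) || v != trunc(v))
        validation_error(sprintf("not an integer: '%s'", tok), row, col$name)
      as.integer(v)
    },
    prior = {
      if (tok %in% names(PRIOR_CLASS_TOKENS)) return(PRIOR_CLASS_TOKENS[[tok]])
      v <- suppressWarnings(as.integer(tok))
      if (is.na(v) || !v %in% 1:5)
        validation_error(
          sprintf("prior class must be 1..5 or B/LB/VUS/LP/P, got '%s'", tok),
          row, col$name)
      v
    })
}

.check_range <- function(df, col) {
  v <- df[[col$name]]
  bad <- rep(FALSE, length(v))
  if (!is.null(col$min)) bad <- bad | (!is.na(v) & v < col$min)
  if (!is.null(col$max)) bad <- bad | (!is.na(v) & v > col$max)
  if (any(bad)) {
    row <- which(bad)[1L]
    validation_error(
      sprintf("value %s out of range [%s, %s]", format(v[row]),
              format(col$min %||% -Inf), format(col$max %||% Inf)),
      row, col$name)
  }
}

.read_tsv <- function(path, cols, table_name) {
  if (!file.exists(path))
    stop(sprintf("cannot read %s table: file not found: %s", table_name, path))
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = character(0), check.names = FALSE,
                           quote = "", comment.char = "", fileEncoding = "UTF-8")
  want <- vapply(cols, `[[`, "", "name")
  missing_cols <- setdiff(want, names(raw))
  if (length(missing_cols))
    validation_error(sprintf("%s table is missing column(s): %s", table_name,
                             paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(raw), want)
  if (length(extra))
    validation_error(sprintf("%s table has unexpected column(s): %s",
                             table_name, paste(extra, collapse = ", ")))
  raw <- raw[, want, drop = FALSE]
  out <- vector("list", length(cols))
  names(out) <- want
  n <- nrow(raw)
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    toks <- raw[[j]]
    out[[j]] <- if (n == 0L) {
      .parse_cell("NA", utils::modifyList(col, list(required = FALSE)), 0L)[0]
    } else {
      vapply(seq_len(n), function(i) .parse_cell(toks[i], col, i),
             .parse_cell(if (col$type == "enum") col$values[1] else
                         switch(col$type, chr = "x", lgl = "TRUE",
                                num = "0", int = "0", prior = "3"),
                         col, 0L))
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  for (col in cols) .check_range(df, col)
  df
}

## ---- table-level invariants -----------------------------------------------

#' Validate a variant observation table
#'
#' Checks every row of an in-memory variant table against the domain
#' invariants: population frequency in `[0, 1]` when present, a defined
#' variant class and prior class for every row, and uniqueness of
#' `(patient_id, variant_id)` pairs. Signals a condition of class
#' `vustriage_validation_error` naming the offending row and field.
#'
#' @param df data.frame with the variant-table columns (see
#'   [read_variant_table()]).
#' @return `df`, invisibly, when valid.
#' @export
validate_variant_table <- function(df) {
  for (col in variant_cols()) {
    if (!col$name %in% names(df))
      validation_error(paste0("missing column ", col$name))
    v <- df[[col$name]]
    if (isTRUE(col$required) && anyNA(v))
      validation_error("value is required but missing",
                       which(is.na(v))[1L], col$name)
    .check_range(df, col)
  }
  if (!all(df$prior_class %in% 1:5))
    validation_error("prior class outside 1..5",
                     which(!df$prior_class %in% 1:5)[1L], "prior_class")
  key <- paste(df$patient_id, df$variant_id, sep = "\r")
  if (anyDuplicated(key))
    validation_error("duplicate (patient_id, variant_id) pair",
                     anyDuplicated(key), "variant_id")
  invisible(df)
}

#' Validate a gene constraint table
#'
#' Checks EF confidence-interval ordering (`ef_ci_low <= ef <= ef_ci_high`
#' when all present), protein-region interval sanity (both ends present
#' together, `region_start <= region_end`) and uniqueness of
#' `(gene, subtype, variant_class, region)` keys.
#'
#' @param df data.frame with the constraint-table columns (see
#'   [read_constraint_table()]).
#' @return `df`, invisibly, when valid.
#' @export
validate_constraint_table <- function(df) {
  for (col in constraint_cols()) {
    if (!col$name %in% names(df))
      validation_error(paste0("missing column ", col$name))
    v <- df[[col$name]]
    if (isTRUE(col$required) && anyNA(v))
      validation_error("value is required but missing",
                       which(is.na(v))[1L], col$name)
    .check_range(df, col)
  }
  half <- xor(is.na(df$region_start), is.na(df$region_end))
  if (any(half))
    validation_error("region_start and region_end must be present together",
                     which(half)[1L], "region_start")
  bad <- !is.na(df$region_start) & df$region_start > df$region_end
  if (any(bad))
    validation_error("region_start > region_end", which(bad)[1L],
                     "region_start")
  bad <- !is.na(df$ef) & !is.na(df$ef_ci_low) & df$ef_ci_low > df$ef
  if (any(bad))
    validation_error("ef_ci_low > ef", which(bad)[1L], "ef_ci_low")
  bad <- !is.na(df$ef) & !is.na(df$ef_ci_high) & df$ef > df$ef_ci_high
  if (any(bad))
    validation_error("ef > ef_ci_high", which(bad)[1L], "ef_ci_high")
  key <- paste(df$gene, df$subtype, df$variant_class,
               df$region_start, df$region_end, sep = "\r")
  if (anyDuplicated(key))
    validation_error("duplicate (gene, subtype, variant_class, region) key",
                     anyDuplicated(key), "gene")
  invisible(df)
}

#' Validate a burden-counts table
#'
#' Checks carrier counts against sample sizes (`case_carriers <= case_n`,
#' `control_carriers <= control_n`) and positivity of the sample sizes.
#'
#' @param df data.frame with the burden-table columns (see
#'   [read_burden_table()]).
#' @return `df`, invisibly, when valid.
#' @export
validate_burden_table <- function(df) {
  for (col in burden_cols()) {
    if (!col$name %in% names(df))
      validation_error(paste0("missing column ", col$name))
    if (isTRUE(col$required) && anyNA(df[[col$name]]))
      validation_error("value is required but missing",
                       which(is.na(df[[col$name]]))[1L], col$name)
    .check_range(df, col)
  }
  bad <- df$case_carriers > df$case_n
  if (any(bad))
    validation_error("case_carriers > case_n", which(bad)[1L], "case_carriers")
  bad <- df$control_carriers > df$control_n
  if (any(bad))
    validation_error("control_carriers > control_n", which(bad)[1L],
                     "control_carriers")
  invisible(df)
}

## ---- readers --------------------------------------------------------------

#' Read a variant observation table
#'
#' One row per patient-variant observation from a diagnostic gene panel,
#' post annotation: phenotype subtype, gene, variant class
#' (truncating = frameshift/nonsense/canonical splice,
#' non_truncating = missense/in-frame indel), popmax population allele
#' frequency (missing = absent from population data), optional protein
#' position for region-restricted EF lookup, in-silico (PP3) and phenotype
#' specificity (PP4) input flags, proband and segregating-meioses counts,
#' the lab's prior five-tier class, and a founder-variant flag.
#'
#' @param path path to a tab-delimited file whose header names all variant
#'   fields. Missing values are empty cells or `NA` (never `.`).
#' @param thresholds optional [cm_thresholds()]; accepted for interface
#'   symmetry (parsing itself is threshold-free).
#' @return a validated `data.frame`, rows in file order.
#' @export
read_variant_table <- function(path, thresholds = cm_thresholds()) {
  validate_variant_table(.read_tsv(path, variant_cols(), "variant"))
}

#' Read a gene constraint table
#'
#' One row per (gene, cardiomyopathy subtype, variant class) with the
#' published burden/constraint evidence for that combination:
#' `has_case_excess` (TRUE/FALSE = analysed in the case-control burden
#' studies with/without significant case excess; NA = never analysed there,
#' i.e. a gnomAD-only gene), the etiological fraction `ef` with optional CI,
#' an optional protein-residue interval (`region_start`..`region_end`,
#' inclusive both ends) restricting the EF to a cluster, and the gnomAD
#' gene-level metrics `pli` and `mis_z`. `subtype` may be `ANY`.
#'
#' @param path path to a tab-delimited constraint table.
#' @return a validated `data.frame`, rows in file order.
#' @export
read_constraint_table <- function(path) {
  validate_constraint_table(.read_tsv(path, constraint_cols(), "constraint"))
}

#' Read a burden-counts table
#'
#' Raw carrier counts per (gene, subtype, variant class): rare-variant
#' carriers and totals in the case cohort and in the population reference
#' sample, from which case excess and etiological fraction are computed by
#' [compute_burden()].
#'
#' @param path path to a tab-delimited counts table.
#' @return a validated `data.frame`, rows in file order.
#' @export
read_burden_table <- function(path) {
  validate_burden_table(.read_tsv(path, burden_cols(), "burden"))
}

#' Read a triage decisions table
#'
#' Round-trips the output of [write_decisions()].
#'
#' @param path path to a decisions TSV.
#' @return a `data.frame` with one row per decision.
#' @export
read_decisions <- function(path) {
  .read_tsv(path, decision_cols(), "decisions")
}

## ---- writers --------------------------------------------------------------

.write_tsv <- function(df, path, cols) {
  if (nrow(df) == 0L) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(vapply(cols, `[[`, "", "name"), collapse = "\t"),
               con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }
  mat <- vapply(cols, function(col) {
    v <- df[[col$name]]
    out <- switch(col$type,
      chr = , enum = ifelse(is.na(v), "NA", as.character(v)),
      lgl = ifelse(is.na(v), "NA", ifelse(v, "TRUE", "FALSE")),
      num = num2str(v),
      int = , prior = ifelse(is.na(v), "NA", format(v, scientific = FALSE)))
    if (any(grepl("[\t\n\r]", out)))
      validation_error("field contains tab/newline; cannot serialize",
                       grep("[\t\n\r]", out)[1L], col$name)
    out
  }, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  header <- paste(vapply(cols, `[[`, "", "name"), collapse = "\t")
  body <- apply(mat, 1L, paste, collapse = "\t")
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a variant observation table
#' @param df a valid variant table (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  validate_variant_table(df)
  .write_tsv(df, path, variant_cols())
}

#' Write a gene constraint table
#' @param df a valid constraint table (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_constraint_table <- function(df, path) {
  validate_constraint_table(df)
  .write_tsv(df, path, constraint_cols())
}

#' Write a burden-counts table
#' @param df a valid burden table (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(df, path) {
  validate_burden_table(df)
  .write_tsv(df, path, burden_cols())
}

#' Write a triage decisions table
#'
#' One row per decision with the route taken, the action, any new class and
#' the full rationale trail (individual rationale steps joined by `" | "`).
#' The output round-trips through [read_decisions()] and is byte-identical
#' for identical inputs.
#'
#' @param decisions a decisions data.frame as produced by [triage_vus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  .write_tsv(decisions, path, decision_cols())
}
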