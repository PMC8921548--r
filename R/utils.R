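#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (commercial rounding), the convention used by all printed percentages in
#' this package (e.g. 354/378 -> 94%, 25/2002 -> 1.2%, 19/2002 -> 1%).
#' Base [round()] rounds half to even and would print 0.5 -> 0.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(100 * 354/378)      # 94
#' round_half_up(100 * 25/2002, 1)   # 1.2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small eps guards values sitting a float-ulp below an exact .5 boundary
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## condition helper: all table/row validation failures signal this class so
## callers (and the CLI, which maps it to exit status 2) can distinguish bad
## input from programming errors.
validation_error <- function(msg, row = NULL, field = NULL) {
  loc <- character(0)
  if (!is.null(row)) loc <- c(loc, paste0("row ", row))
  if (!is.null(field)) loc <- c(loc, paste0("field ", field))
  if (length(loc)) msg <- paste0(paste(loc, collapse = ", "), ": ", msg)
  stop(structure(
    class = c("vustriage_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## serialize doubles so that read(write(x)) is bit-identical; 17 significant
## digits are sufficient for any IEEE double
num2str <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (!is.na(v) && v == trunc(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    s <- formatC(v, digits = 15, format = "g")
    if (as.numeric(s) == v) s else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

SUBTYPES <- c("HCM", "DCM", "ACM", "LVNC", "CM_unclassified")
VARIANT_CLASSES <- c("truncating", "non_truncating", "other")
CONSTRAINT_CLASSES <- c("truncating", "non_truncating")
PRIOR_CLASS_TOKENS <- c(B = 1L, LB = 2L, VUS = 3L, LP = 4L, P = 5L)
ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "vus",
                  "likely_benign", "benign")
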