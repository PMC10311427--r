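# Cohort domain types, validation and CSV I/O.
#
# A cohort is a plain data.frame of one row per ROP-screened infant with the
# canonical columns below; every other module takes its coding conventions
# from here.
#
#   infant_id               opaque string
#   ga_weeks                gestational age at birth, decimal weeks
#   sex                     factor, levels c("girl","boy"); girl is the
#                           indicator reference
#   bw_g                    birth weight, grams
#   bwsds                   standardized birth-weight score (optional, NA ok)
#   pnd_days                days of parenteral protein+lipid supplementation;
#                           NA encodes UNKNOWN (a first-class category, never
#                           imputed)
#   first_rop_dx_pna_weeks  postnatal age at first any-ROP diagnosis (NA if
#                           never diagnosed)
#   max_rop_stage           ordered factor none < 1 < 2 < 3 < 5
#   treated                 logical, ROP treatment given
#   treatment_pna_weeks     postnatal age at first treatment (NA if untreated)
#   last_exam_pna_weeks     censoring time, decimal weeks (defaults to the
#                           20-week integration horizon when absent)
#   weights_g_by_day        list column: named numeric vector of grams indexed
#                           by postnatal day (day 0 = birth day), or NULL
#   hydrocephalus           logical (optional, comparator use)

ROP_STAGES <- c("none", "1", "2", "3", "5")

COHORT_COLUMNS <- c(
  "infant_id", "ga_weeks", "sex", "bw_g", "bwsds", "pnd_days",
  "first_rop_dx_pna_weeks", "max_rop_stage", "treated",
  "treatment_pna_weeks", "last_exam_pna_weeks", "weights_g_by_day",
  "hydrocephalus"
)

GA_RANGE <- c(21, 40)
BW_RANGE <- c(250, 4000)

#' Categorize parenteral nutrition duration
#'
#' Maps days of parenteral nutrition to the three-level exposure category
#' used throughout the models: fewer than `cutoff_days` days, at least
#' `cutoff_days` days, or unknown. Unknown (coded `NA`) is a first-class
#' level and is never imputed.
#'
#' @param pnd_days integer vector of days on parenteral nutrition; `NA`
#'   means unknown.
#' @param cutoff_days dichotomization cutoff in days (default 14).
#' @return factor with levels `c("lt14", "ge14", "unknown")` (level names
#'   follow the default cutoff; a different cutoff keeps the same labels,
#'   which name the category roles rather than the numeric value).
#' @export
#' @examples
#' pnd_category(c(13, 14, NA))
pnd_category <- function(pnd_days, cutoff_days = 14) {
  stopifnot(cutoff_days >= 1)
  out <- ifelse(is.na(pnd_days), "unknown",
                ifelse(pnd_days >= cutoff_days, "ge14", "lt14"))
  factor(out, levels = c("lt14", "ge14", "unknown"))
}

#' Gestational-age stratum for cutoff calibration
#'
#' Bins completed gestational weeks into the strata used for GA-specific
#' cutoffs: `<=24, 25, 26, ..., 30, >=31`.
#'
#' @param ga_weeks numeric vector of gestational ages in decimal weeks.
#' @return factor of strata, ordered from most to least premature.
#' @export
ga_stratum <- function(ga_weeks) {
  wk <- floor(ga_weeks)
  lab <- ifelse(wk <= 24, "<=24", ifelse(wk >= 31, ">=31", as.character(wk)))
  factor(lab, levels = c("<=24", as.character(25:30), ">=31"))
}

#' Assemble and validate a cohort
#'
#' Coerces a data.frame with the canonical columns into a validated
#' `rop_cohort`. Rows violating domain invariants are rejected with
#' row-level diagnostics; rows with missing birth weight are dropped and
#' counted separately (mirroring registry exclusion accounting). Missing
#' `last_exam_pna_weeks` defaults to the 20-week screening horizon.
#'
#' @param data data.frame with at least `ga_weeks`, `sex`, `bw_g`,
#'   `pnd_days`, `treated`. Missing optional columns are filled with `NA`.
#' @return an `rop_cohort` data.frame; attributes `exclusions` (data.frame
#'   of row, infant_id, reason) and `exclusion_counts` (named integer
#'   vector) record dropped rows.
#' @export
rop_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("ga_weeks", "sex", "bw_g", "pnd_days", "treated")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stopf("mandatory columns missing: %s", paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  df <- data.frame(row.names = NULL)
  df <- data
  if (!("infant_id" %in% names(df)) || all(is.na(df$infant_id)))
    df$infant_id <- sprintf("infant%05d", seq_len(max(n, 1))[seq_len(n)])
  df$infant_id <- as.character(df$infant_id)
  for (col in setdiff(COHORT_COLUMNS, names(df)))
    df[[col]] <- if (col == "weights_g_by_day") vector("list", n)
                 else rep(NA, n)
  df <- df[, COHORT_COLUMNS, drop = FALSE]

  df$ga_weeks <- as.numeric(df$ga_weeks)
  df$bw_g <- as.numeric(df$bw_g)
  df$bwsds <- as.numeric(df$bwsds)
  df$pnd_days <- suppressWarnings(as.integer(df$pnd_days))
  df$first_rop_dx_pna_weeks <- as.numeric(df$first_rop_dx_pna_weeks)
  df$treatment_pna_weeks <- as.numeric(df$treatment_pna_weeks)
  df$last_exam_pna_weeks <- as.numeric(df$last_exam_pna_weeks)
  df$last_exam_pna_weeks[is.na(df$last_exam_pna_weeks)] <- DIGIROP_HORIZON
  df$treated <- as.logical(df$treated)
  df$hydrocephalus <- as.logical(df$hydrocephalus)
  stage <- as.character(df$max_rop_stage)
  stage[is.na(stage)] <- "none"
  df$max_rop_stage <- stage

  sex_chr <- tolower(as.character(df$sex))
  sex_chr[sex_chr %in% c("f", "female")] <- "girl"
  sex_chr[sex_chr %in% c("m", "male")] <- "boy"

  reasons <- vector("list", n)
  flag <- function(i, why) reasons[[i]] <<- c(reasons[[i]], why)
  for (i in seq_len(n)) {
    if (is.na(df$bw_g[i])) { flag(i, "missing birth weight"); next }
    if (is.na(sex_chr[i]) || !(sex_chr[i] %in% c("girl", "boy")))
      flag(i, sprintf("unknown sex code '%s'", as.character(df$sex[i])))
    if (!is.na(df$pnd_days[i]) && df$pnd_days[i] < 0)
      flag(i, "negative parenteral nutrition duration")
    if (is.na(df$ga_weeks[i]) || df$ga_weeks[i] < GA_RANGE[1] ||
        df$ga_weeks[i] > GA_RANGE[2])
      flag(i, sprintf("gestational age %s outside [%g, %g] weeks",
                      format(df$ga_weeks[i]), GA_RANGE[1], GA_RANGE[2]))
    if (df$bw_g[i] < BW_RANGE[1] || df$bw_g[i] > BW_RANGE[2])
      flag(i, sprintf("birth weight %g g outside [%g, %g]",
                      df$bw_g[i], BW_RANGE[1], BW_RANGE[2]))
    if (!(stage[i] %in% ROP_STAGES))
      flag(i, sprintf("unknown ROP stage '%s'", stage[i]))
    if (is.na(df$treated[i]))
      flag(i, "missing treatment indicator")
    if (isTRUE(df$treated[i])) {
      if (is.na(df$treatment_pna_weeks[i]))
        flag(i, "treated without treatment time")
      else if (!is.na(df$first_rop_dx_pna_weeks[i]) &&
               df$treatment_pna_weeks[i] < df$first_rop_dx_pna_weeks[i])
        flag(i, "treatment precedes first ROP diagnosis")
    }
    # diagnosis time present <=> some ROP stage recorded
    has_dx <- !is.na(df$first_rop_dx_pna_weeks[i])
    has_stage <- stage[i] %in% ROP_STAGES && stage[i] != "none"
    if (has_dx != has_stage)
      flag(i, "first ROP diagnosis time and maximum stage are inconsistent")
  }

  bad <- which(!vapply(reasons, is.null, logical(1)))
  exclusions <- data.frame(
    row = bad,
    infant_id = df$infant_id[bad],
    reason = vapply(reasons[bad], function(r) paste(r, collapse = "; "), ""),
    stringsAsFactors = FALSE
  )
  keep <- setdiff(seq_len(n), bad)
  out <- df[keep, , drop = FALSE]
  out$sex <- factor(sex_chr[keep], levels = c("girl", "boy"))
  out$max_rop_stage <- factor(stage[keep], levels = ROP_STAGES, ordered = TRUE)
  rownames(out) <- NULL

  counts <- c(
    input_rows = n,
    retained = length(keep),
    missing_birth_weight = sum(grepl("missing birth weight", exclusions$reason)),
    other_invalid = sum(!grepl("missing birth weight", exclusions$reason))
  )
  structure(out, exclusions = exclusions, exclusion_counts = counts,
            class = c("rop_cohort", "data.frame"))
}

#' @export
print.rop_cohort <- function(x, ...) {
  counts <- attr(x, "exclusion_counts")
  cat(sprintf("ROP screening cohort: %d infants\n", nrow(x)))
  cat(sprintf("  treated: %d (%.1f%%); any ROP: %d (%.1f%%)\n",
              sum(x$treated), 100 * mean(x$treated),
              sum(x$max_rop_stage != "none"),
              100 * mean(x$max_rop_stage != "none")))
  pc <- table(pnd_category(x$pnd_days))
  cat(sprintf("  PND <14 d: %d; >=14 d: %d; unknown: %d\n",
              pc[["lt14"]], pc[["ge14"]], pc[["unknown"]]))
  if (!is.null(counts) && counts[["input_rows"]] > counts[["retained"]])
    cat(sprintf("  (%d of %d input rows excluded: %d missing birth weight, %d invalid)\n",
                counts[["input_rows"]] - counts[["retained"]],
                counts[["input_rows"]],
                counts[["missing_birth_weight"]], counts[["other_invalid"]]))
  invisible(x)
}

# serialize a weights-by-day map to "day:g;day:g" and back
weights_to_string <- function(w) {
  if (is.null(w) || length(w) == 0) return("")
  paste(sprintf("%s:%s", names(w), format(unname(w), trim = TRUE)),
        collapse = ";")
}

weights_from_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  w <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(w) <- vapply(kv, `[[`, "", 1)
  w[order(as.integer(names(w)))]
}

#' Read a screening cohort from CSV
#'
#' Reads a comma-separated UTF-8 file with a header row into a validated
#' [rop_cohort()]. Column names can be remapped through a schema
#' configuration (a named list or a JSON file mapping canonical names to
#' the file's column names). Missing values are empty cells; unknown
#' parenteral nutrition duration is an empty `pnd_days` cell. Daily
#' weights, if present, are encoded in a single column as
#' `"day:grams;day:grams"`.
#'
#' @param path CSV file path.
#' @param schema optional named list (or path to a JSON file) mapping
#'   canonical column names to the names used in the file, e.g.
#'   `list(ga_weeks = "GA", bw_g = "weight")`.
#' @return an `rop_cohort`; see [rop_cohort()] for the exclusion
#'   accounting attributes.
#' @export
#' @examples
#' # a small simulator-generated (synthetic) cohort ships with the package
#' path <- system.file("extdata", "example_cohort_synthetic.csv",
#'                     package = "digirop")
#' head(read_rop_cohort(path))
read_rop_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  if (is.character(schema) && length(schema) == 1)
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  raw[raw == ""] <- NA
  if ("weights_g_by_day" %in% names(raw)) {
    wcol <- lapply(raw$weights_g_by_day,
                   function(s) weights_from_string(if (is.na(s)) "" else s))
    raw$weights_g_by_day <- NULL
    raw$weights_g_by_day <- wcol
  }
  rop_cohort(raw)
}

#' Write a screening cohort to CSV
#'
#' Inverse of [read_rop_cohort()]: the round trip
#' `read_rop_cohort(write_rop_cohort(x, f))` reproduces `x` field by field.
#' Unknown parenteral nutrition duration is written as an empty cell.
#'
#' @param cohort an `rop_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rop_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$weights_g_by_day <- vapply(cohort$weights_g_by_day %||%
                                  vector("list", nrow(cohort)),
                                weights_to_string, "")
  df$sex <- as.character(df$sex)
  df$max_rop_stage <- as.character(df$max_rop_stage)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write cohort to %s: %s", path,
                         conditionMessage(ok))
  invisible(path)
}
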