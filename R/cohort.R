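# Cohort data model: canonical columns, validation, delimited-text IO.

.conditions <- c("cad", "t2d", "htn")

.numeric_cols <- c(
  "age", "sbp", "dbp", "total_chol", "ldl", "hdl", "triglycerides",
  "hscrp", "fasting_glucose", "hba1c_pct", "bmi", "waist", "egfr", "acr",
  paste0("fh_", .conditions), paste0("time_", .conditions),
  paste0("pc", 1:4)
)
.logical_cols <- c("bp_treatment", paste0("dx_", .conditions),
                   paste0("event_", .conditions))
.concentration_cols <- c("total_chol", "ldl", "hdl", "triglycerides",
                         "hscrp", "fasting_glucose")

.sex_levels <- c("female", "male")
.smoking_levels <- c("never_or_quit_gt1y", "quit_lt1y", "current")

#' Canonical cohort column names
#'
#' One participant per row. Units are fixed: mmol/L for lipids and glucose,
#' mg/L for hs-CRP, mmHg for blood pressure, NGSP percent for HbA1c,
#' kg/m2 for BMI, cm for waist, mL/min/1.73m2 for eGFR, mg/mmol for the
#' albumin-creatinine ratio, years for age and follow-up time. `fh_*` columns
#' count affected parents (0, 1 or 2); `dx_*` flag a physician diagnosis at
#' baseline; `event_*`/`time_*` give incident-event status and time to event
#' or censoring. `array` and `pc1`..`pc4` (genotyping array, genetic
#' principal components) are optional covariates for PRS adjustment.
#'
#' @param optional include the optional covariate columns (default `TRUE`).
#' @return character vector of column names.
#' @export
cohort_columns <- function(optional = TRUE) {
  base <- c("id", "age", "sex", "sbp", "dbp",
            "total_chol", "ldl", "hdl", "triglycerides", "hscrp",
            "fasting_glucose", "hba1c_pct", "bmi", "waist", "smoking",
            "bp_treatment", "egfr", "acr",
            paste0("fh_", .conditions), paste0("dx_", .conditions),
            paste0("event_", .conditions), paste0("time_", .conditions))
  if (optional) c(base, "array", paste0("pc", 1:4)) else base
}

#' Convert HbA1c from IFCC (mmol/mol) to NGSP (%)
#'
#' Rule thresholds are stated on the NGSP percent scale while UK laboratory
#' values are commonly reported in IFCC mmol/mol; the two scales interconvert
#' linearly.
#'
#' @param ifcc HbA1c in mmol/mol.
#' @return HbA1c in NGSP percent.
#' @export
hba1c_ngsp_from_ifcc <- function(ifcc) 0.09148 * ifcc + 2.152

# Per-row invariant check. Returns character vector of reasons ("" = valid).
# Missing values do not violate invariants (missingness is handled by the
# eligibility module); only present, out-of-contract values reject a row.
.row_violations <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  add <- function(bad, msg) {
    bad <- !is.na(bad) & bad
    reason[bad & reason == ""] <<- msg
  }
  add(df$age <= 0, "age <= 0")
  for (col in .concentration_cols)
    add(df[[col]] < 0, paste0(col, " < 0 violated"))
  add(df$sbp <= df$dbp, "sbp>dbp violated")
  add(df$hba1c_pct < 3 | df$hba1c_pct > 20, "hba1c_pct outside [3, 20]")
  for (col in paste0("fh_", .conditions))
    add(!(df[[col]] %in% c(0, 1, 2)), paste0(col, " not in {0,1,2}"))
  add(!is.na(df$sex) & !(df$sex %in% .sex_levels), "unknown sex level")
  add(!is.na(df$smoking) & !(df$smoking %in% .smoking_levels),
      "unknown smoking level")
  for (col in paste0("time_", .conditions))
    add(df[[col]] <= 0, paste0(col, " <= 0"))
  reason
}

.as_cohort <- function(df, source = NA_character_,
                       rejections = data.frame(row = integer(),
                                               id = character(),
                                               reason = character())) {
  rownames(df) <- NULL
  structure(df, class = c("cohort", "data.frame"),
            source = source, rejections = rejections)
}

#' Construct a validated cohort from a data frame
#'
#' Rows violating the data-model invariants (non-positive age, negative
#' concentrations, `sbp <= dbp`, HbA1c outside 3--20%, family-history counts
#' outside \{0,1,2\}, unknown factor levels, non-positive follow-up times,
#' duplicated ids) are removed and logged; every input row ends up either in
#' the cohort or in the rejection log, never both.
#'
#' @param df data frame with canonical columns (see [cohort_columns()]).
#' @param source provenance note.
#' @return a `cohort` (data frame subclass) with a `rejections` attribute.
#' @export
as_cohort <- function(df, source = NA_character_) {
  mandatory <- cohort_columns(optional = FALSE)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  reason <- .row_violations(df)
  dup <- duplicated(df$id)
  reason[dup & reason == ""] <- "duplicate id"
  bad <- reason != ""
  rej <- data.frame(row = which(bad), id = df$id[bad], reason = reason[bad],
                    stringsAsFactors = FALSE)
  if (nrow(rej) > 0)
    message(nrow(rej), " row(s) rejected by cohort validation")
  .as_cohort(df[!bad, , drop = FALSE], source = source, rejections = rej)
}

#' Rows rejected when a cohort was validated or read
#' @param cohort a `cohort`.
#' @return data frame with columns `row`, `id`, `reason`.
#' @export
cohort_rejections <- function(cohort) attr(cohort, "rejections")

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a cohort from delimited text
#'
#' Accepts UTF-8 CSV or TSV with a header row (delimiter inferred from the
#' file extension). `schema` renames file columns to canonical names: a named
#' character vector, `c(canonical = "file_column")`. An `hba1c_ifcc` column
#' (mmol/mol) is accepted and converted to `hba1c_pct` when the latter is
#' absent. Empty cells are missing values (allowed; handled downstream by the
#' eligibility module); non-empty cells that fail numeric parsing reject the
#' row.
#'
#' @param path file path.
#' @param schema optional named character vector mapping canonical field names
#'   to file column names.
#' @return a validated `cohort`; rejected rows are in
#'   [cohort_rejections()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = .delim_for(path), header = TRUE,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema column not in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"hba1c_pct" %in% names(raw) && "hba1c_ifcc" %in% names(raw)) {
    raw$hba1c_pct <- as.character(
      hba1c_ngsp_from_ifcc(as.numeric(raw$hba1c_ifcc)))
    raw$hba1c_ifcc <- NULL
  }
  mandatory <- cohort_columns(optional = FALSE)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  parse_reason <- character(nrow(raw))
  num_here <- intersect(.numeric_cols, names(raw))
  for (col in num_here) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(parsed)
    parse_reason[bad & parse_reason == ""] <-
      paste0("unparseable numeric in ", col)
    raw[[col]] <- parsed
  }
  for (col in intersect(.logical_cols, names(raw))) {
    x <- tolower(raw[[col]])
    parsed <- ifelse(x %in% c("true", "1"), TRUE,
                     ifelse(x %in% c("false", "0"), FALSE, NA))
    bad <- !is.na(raw[[col]]) & is.na(parsed)
    parse_reason[bad & parse_reason == ""] <-
      paste0("unparseable logical in ", col)
    raw[[col]] <- parsed
  }
  pre_bad <- parse_reason != ""
  pre_rej <- data.frame(row = which(pre_bad),
                        id = as.character(raw$id)[pre_bad],
                        reason = parse_reason[pre_bad],
                        stringsAsFactors = FALSE)
  kept <- raw[!pre_bad, , drop = FALSE]
  cohort <- as_cohort(kept, source = path)
  rej <- cohort_rejections(cohort)
  # re-key post-validation rejection rows to the original file row numbers
  if (nrow(rej) > 0) rej$row <- which(!pre_bad)[rej$row]
  all_rej <- rbind(pre_rej, rej)
  all_rej <- all_rej[order(all_rej$row), , drop = FALSE]
  rownames(all_rej) <- NULL
  attr(cohort, "rejections") <- all_rej
  cohort
}

#' Write a cohort to delimited text
#'
#' Canonical column names, one participant per row, missing values as empty
#' cells. [read_cohort()] inverts it exactly: write-read-write is a fixed
#' point (byte-identical files), and numeric values round-trip at full
#' precision (15 significant digits).
#'
#' @param cohort a `cohort`.
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(NULL)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x), "participants,",
    nrow(cohort_rejections(x)), "rejected row(s)\n")
  if (!is.na(attr(x, "source"))) cat("source:", attr(x, "source"), "\n")
  NextMethod()
}
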