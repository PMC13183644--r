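# Reading, validating and filtering front-page inpatient records.

record_fields <- function() {
  c("admission_date", "discharge_date", "primary_dx", "insurance",
    "visit_number", "sex", "age_years", "ethnicity", "marital",
    "admission_route", "length_of_stay_days", "n_other_dx",
    "hypertension", "diabetes", "surgery_level", "discharge_method",
    "total", "out_of_pocket", expense_items())
}

record_levels <- list(
  insurance = c("uninsured", "urban_rural_resident", "urban_employee"),
  sex = c("male", "female"),
  ethnicity = c("han", "zhuang", "other"),
  marital = c("single", "married", "divorced", "widowed", "other"),
  admission_route = c("emergency", "outpatient"),
  surgery_level = c("none", "level1", "level2", "level3", "uncertain"),
  discharge_method = c("transfer", "order_discharge", "non_order_discharge",
                       "death", "other")
)

study_window <- function() as.Date(c("2015-01-01", "2025-07-31"))

#' Parse front-page inpatient records from delimited text
#'
#' Reads one admission per row. Column names in the file are mapped onto the
#' canonical field names through `schema`; malformed rows are collected with
#' their row numbers rather than silently dropped, so the exclusion log is a
#' complete audit trail.
#'
#' Canonical fields: admission/discharge dates (ISO-8601), `primary_dx`,
#' `insurance`, `visit_number`, `sex`, `age_years`, `ethnicity`, `marital`,
#' `admission_route` (may be empty: kept as `NA` and flagged downstream),
#' `length_of_stay_days` (derived from the dates when absent from the file),
#' `n_other_dx`, `hypertension`/`diabetes` (0/1 or TRUE/FALSE),
#' `surgery_level`, `discharge_method`, `total`, `out_of_pocket`, and the
#' seven itemized expenses of [expense_items()], all in yuan.
#'
#' @param path Delimited text file (CSV by default).
#' @param schema Named character vector mapping canonical field names to
#'   column names in the file; `NULL` means columns already use canonical
#'   names. May also be a path to a YAML/JSON file holding such a map.
#' @param sep Field separator (default `,`).
#' @return A list with `records` (data.frame, one row per well-formed row,
#'   carrying its source row in `source_row`) and `errors` (data.frame with
#'   `row`, `field`, `message`).
#' @export
parse_records <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop_drg("file not found: ", path, class = "schema_error")
  schema <- resolve_schema(schema)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  mandatory <- setdiff(record_fields(), "length_of_stay_days")
  # schema may rename only some columns; the rest keep canonical names
  wanted <- vapply(mandatory, function(f) {
    v <- if (is.null(schema)) NA_character_ else unname(schema[f])
    if (is.na(v)) f else v
  }, "")
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stop_drg("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
             class = "schema_error")
  # rename to canonical
  if (!is.null(schema)) {
    hit <- match(names(raw), schema)
    names(raw)[!is.na(hit)] <- names(schema)[hit[!is.na(hit)]]
  }

  n <- nrow(raw)
  errors <- list()
  note <- function(rows, field, msg) {
    if (length(rows))
      errors[[length(errors) + 1L]] <<- data.frame(row = rows, field = field,
                                                   message = msg)
  }

  parse_date <- function(col) {
    out <- as.Date(raw[[col]], format = "%Y-%m-%d")
    bad <- which(!is.na(raw[[col]]) & is.na(out))
    note(bad, col, "unparseable date")
    out
  }
  parse_num <- function(col, required = TRUE) {
    out <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(out))
    note(bad, col, "unparseable amount")
    out
  }
  parse_enum <- function(col) {
    lv <- record_levels[[col]]
    out <- raw[[col]]
    bad <- which(!is.na(out) & !out %in% lv)
    note(bad, col, paste0("not one of: ", paste(lv, collapse = "/")))
    out[!out %in% lv] <- NA
    out
  }
  parse_bool <- function(col) {
    map <- c("0" = FALSE, "1" = TRUE, "TRUE" = TRUE, "FALSE" = FALSE,
             "yes" = TRUE, "no" = FALSE)
    out <- unname(map[raw[[col]]])
    bad <- which(!is.na(raw[[col]]) & is.na(out))
    note(bad, col, "not interpretable as boolean")
    out
  }

  rec <- data.frame(source_row = seq_len(n))
  rec$admission_date <- parse_date("admission_date")
  rec$discharge_date <- parse_date("discharge_date")
  rec$primary_dx <- raw$primary_dx
  for (col in names(record_levels)) rec[[col]] <- parse_enum(col)
  for (col in c("visit_number", "age_years", "n_other_dx", "total",
                "out_of_pocket", expense_items()))
    rec[[col]] <- parse_num(col)
  for (col in c("hypertension", "diabetes")) rec[[col]] <- parse_bool(col)
  rec$length_of_stay_days <-
    if ("length_of_stay_days" %in% names(raw))
      suppressWarnings(as.numeric(raw$length_of_stay_days))
    else as.integer(rec$discharge_date - rec$admission_date)

  errors <- if (length(errors)) do.call(rbind, errors)
            else data.frame(row = integer(), field = character(), message = character())
  bad_rows <- unique(errors$row)
  list(records = rec[!rec$source_row %in% bad_rows, , drop = FALSE],
       errors = errors[order(errors$row), , drop = FALSE])
}

resolve_schema <- function(schema) {
  if (is.null(schema) || is.character(schema) && !is.null(names(schema))) return(schema)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    m <- yaml::read_yaml(schema)
    return(unlist(m))
  }
  if (is.list(schema)) return(unlist(schema))
  stop_drg("schema must be NULL, a named character vector, or a YAML/JSON path",
           class = "schema_error")
}

#' Write records in the CSV dialect `parse_records()` reads
#'
#' @param records Data frame of records (as from [generate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, intersect(record_fields(), names(records)), drop = FALSE]
  out$hypertension <- as.integer(out$hypertension)
  out$diabetes <- as.integer(out$diabetes)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign the DRG payment phase from the admission date
#'
#' Phase 1 ("Non-DRG") runs 2015-01-01 to 2017-08-31, phase 2 ("Liuzhou
#' DRG", the municipal scheme) 2017-09-01 to 2022-06-30, and phase 3
#' ("Guangxi DRG", the provincial scheme) 2022-07-01 to 2025-07-31. The
#' three phases tile the study window exactly.
#'
#' @param date `Date` vector of admission dates.
#' @param strict If `TRUE` (default) a date outside the study window is an
#'   error; otherwise it yields `NA`.
#' @return Integer vector of phase codes 1--3.
#' @examples
#' assign_payment_phase(as.Date(c("2017-08-31", "2017-09-01", "2022-07-01")))
#' @export
assign_payment_phase <- function(date, strict = TRUE) {
  date <- as.Date(date)
  w <- study_window()
  out <- ifelse(date <= as.Date("2017-08-31"), 1L,
         ifelse(date <= as.Date("2022-06-30"), 2L, 3L))
  outside <- !is.na(date) & (date < w[1] | date > w[2])
  if (any(outside)) {
    if (strict)
      stop_drg("admission date(s) outside study window 2015-01-01..2025-07-31",
               class = "window_error")
    out[outside] <- NA_integer_
  }
  out[is.na(date)] <- NA_integer_
  as.integer(out)
}

#' Apply the study inclusion and exclusion criteria
#'
#' Keeps admissions that fall inside the study window, carry the configured
#' primary diagnosis code, have a length of stay of 1--60 days, and are
#' complete on every analysis variable. Each excluded record carries exactly
#' one primary reason code, resolved in the fixed priority order
#' window > diagnosis > length of stay > completeness.
#'
#' @param records Data frame of parsed records.
#' @param dx_code Primary diagnosis code required for inclusion
#'   (default `"I50.9"`).
#' @param los_range Inclusive bounds on length of stay in days
#'   (default `c(1, 60)`).
#' @param require_complete Columns that must be non-missing; defaults to
#'   every analysis field.
#' @return List with `kept` (data.frame) and `excluded` (data.frame with a
#'   `reason` column: `window`, `dx_mismatch`, `los_extreme` or
#'   `incomplete`). Together they partition the input.
#' @export
apply_inclusion_exclusion <- function(records, dx_code = "I50.9",
                                      los_range = c(1, 60),
                                      require_complete = NULL) {
  w <- study_window()
  require_complete <- require_complete %||%
    setdiff(record_fields(), c("primary_dx"))
  require_complete <- intersect(require_complete, names(records))

  # a missing field is a completeness problem, not a window/LOS violation
  out_window <- !is.na(records$admission_date) &
    (records$admission_date < w[1] | records$admission_date > w[2])
  dx_ok <- !is.na(records$primary_dx) & records$primary_dx == dx_code
  los <- records$length_of_stay_days
  los_bad <- !is.na(los) & (los < los_range[1] | los > los_range[2])
  complete <- !Reduce(`|`, lapply(records[require_complete], is.na))

  reason <- rep(NA_character_, nrow(records))
  reason[!complete] <- "incomplete"
  reason[los_bad] <- "los_extreme"
  reason[!dx_ok] <- "dx_mismatch"
  reason[out_window] <- "window"

  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = kept, excluded = excluded)
}
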