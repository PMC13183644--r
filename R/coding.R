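# Categorical coding of included records (X1..X14, Y1, Y2).

code_age <- function(age) {
  if (any(age < 1)) stop_drg("age must be >= 1 year", class = "domain_error")
  findInterval(age, c(1, 61, 66, 71, 76, 81, 86, 91))
}

code_los <- function(los) findInterval(los, c(-Inf, 4, 7, 10))

code_visits <- function(v) {
  if (any(v < 1)) stop_drg("visit_number must be >= 1", class = "domain_error")
  pmin(v, 4L)
}

code_other_dx <- function(k) {
  if (any(k < 1))
    stop_drg("n_other_dx must be >= 1 (coding starts at 1-3)", class = "domain_error")
  pmin(findInterval(k, c(1, 4, 7, 10, 13, 16)), 6L)
}

#' Code included records into analysis variables X1--X14, Y1, Y2
#'
#' Converts a filtered record table into the coded analysis table: payment
#' phase X1 from the admission date; categorical codes X2--X14 (insurance,
#' visit count capped at 4, sex, eight age bands starting 1--60 then
#' five-year bands to >90, ethnicity, marital status, admission route,
#' length-of-stay bands <=3/4--6/7--9/>9 days, other-diagnosis counts banded
#' in threes to >=16, hypertension and diabetes indicators, surgery level
#' 0--4, discharge method 1--5); and CPI-standardized log outcomes
#' Y1 = log(real total) and Y2 = log(real out-of-pocket + `oop_offset`).
#' Itemized expenses are deflated with the same index so share-based and
#' gray-relational analyses run in real (base-year) yuan.
#'
#' @param records Data frame of records that passed
#'   [apply_inclusion_exclusion()].
#' @param cpi Named CPI series covering every discharge year.
#' @param base_year CPI base year (default 2015).
#' @param oop_offset Offset (yuan) added to out-of-pocket amounts before the
#'   log, since fully reimbursed admissions pay exactly zero (default 1).
#' @param nominal If `TRUE`, skip CPI standardization and analyse nominal
#'   yuan (the deflator is forced to 1).
#' @return Data frame with columns `x1_payment_phase` .. `x14_discharge`,
#'   `y1_log_total`, `y2_log_oop`, `discharge_year`, real-yuan amounts
#'   (`total_real`, `oop_real`, and one `<item>_real` per expense item).
#' @export
code_records <- function(records, cpi, base_year = 2015, oop_offset = 1,
                         nominal = FALSE) {
  if (nrow(records) == 0L) stop_drg("no records to code", class = "domain_error")
  year <- as.integer(format(records$discharge_date, "%Y"))
  defl <- if (nominal) function(a, y) a else function(a, y) deflate(a, y, cpi, base_year)
  total_real <- defl(records$total, year)
  oop_real <- defl(records$out_of_pocket, year)

  coded <- data.frame(
    x1_payment_phase = assign_payment_phase(records$admission_date),
    x2_insurance = match(records$insurance, record_levels$insurance),
    x3_visits = code_visits(records$visit_number),
    x4_sex = match(records$sex, record_levels$sex),
    x5_age_group = code_age(records$age_years),
    x6_ethnicity = match(records$ethnicity, record_levels$ethnicity),
    x7_marital = match(records$marital, record_levels$marital),
    x8_route = match(records$admission_route, record_levels$admission_route),
    x9_los_group = code_los(records$length_of_stay_days),
    x10_other_dx_group = code_other_dx(records$n_other_dx),
    x11_hypertension = as.integer(records$hypertension),
    x12_diabetes = as.integer(records$diabetes),
    x13_surgery = match(records$surgery_level, record_levels$surgery_level) - 1L,
    x14_discharge = match(records$discharge_method, record_levels$discharge_method),
    y1_log_total = log_transform(total_real, 0),
    y2_log_oop = log_transform(oop_real, oop_offset),
    discharge_year = year,
    total_real = total_real,
    oop_real = oop_real
  )
  for (it in expense_items()) coded[[paste0(it, "_real")]] <- defl(records[[it]], year)
  attr(coded, "oop_offset") <- oop_offset
  attr(coded, "base_year") <- if (nominal) NA_integer_ else base_year
  coded
}

coded_factor_names <- function() {
  c("x1_payment_phase", "x2_insurance", "x3_visits", "x4_sex", "x5_age_group",
    "x6_ethnicity", "x7_marital", "x8_route", "x9_los_group",
    "x10_other_dx_group", "x11_hypertension", "x12_diabetes", "x13_surgery",
    "x14_discharge")
}
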