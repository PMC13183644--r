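# Builders for single synthetic admissions used across tests.

make_record <- function(admission_date = "2018-03-01", los = 5,
                        primary_dx = "I50.9", insurance = "urban_rural_resident",
                        visit_number = 1, sex = "male", age_years = 70,
                        ethnicity = "zhuang", marital = "married",
                        admission_route = "outpatient", n_other_dx = 5,
                        hypertension = FALSE, diabetes = FALSE,
                        surgery_level = "none", discharge_method = "order_discharge",
                        total = 100, items = c(70, 10, 10, 10, 0, 0, 0),
                        out_of_pocket = 50) {
  adm <- as.Date(admission_date)
  rec <- data.frame(admission_date = adm, discharge_date = adm + los,
                    primary_dx = primary_dx, insurance = insurance,
                    visit_number = visit_number, sex = sex,
                    age_years = age_years, ethnicity = ethnicity,
                    marital = marital, admission_route = admission_route,
                    length_of_stay_days = los, n_other_dx = n_other_dx,
                    hypertension = hypertension, diabetes = diabetes,
                    surgery_level = surgery_level,
                    discharge_method = discharge_method,
                    total = total, out_of_pocket = out_of_pocket)
  it <- as.data.frame(as.list(items))
  names(it) <- expense_items()
  cbind(rec, it)
}

make_records <- function(...) do.call(rbind, list(...))

flat_cpi <- function() generate_cpi(2015, 2015:2025, growth = 0)

write_temp_records <- function(records) {
  path <- tempfile(fileext = ".csv")
  write_records(records, path)
  path
}
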