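test_that("well-formed rows parse one-to-one with no errors", {
  recs <- make_records(make_record(), make_record(los = 10, total = 200),
                       make_record(sex = "female"))
  out <- parse_records(write_temp_records(recs))
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$errors), 0)
  expect_equal(out$records$total, recs$total)
  expect_equal(out$records$admission_date, recs$admission_date)
})

test_that("an empty admission route parses as missing, not as an error", {
  recs <- make_records(make_record(), make_record())
  path <- write_temp_records(recs)
  txt <- readLines(path)
  txt[2] <- sub("outpatient", "", txt[2])
  writeLines(txt, path)
  out <- parse_records(path)
  expect_equal(nrow(out$records), 2)
  expect_true(is.na(out$records$admission_route[1]))
  # and the downstream filter excludes it for incompleteness
  filt <- apply_inclusion_exclusion(out$records)
  expect_equal(filt$excluded$reason, "incomplete")
})

test_that("malformed amounts and dates become row-level error entries", {
  recs <- make_records(make_record(), make_record(), make_record())
  path <- write_temp_records(recs)
  txt <- readLines(path)
  txt[3] <- sub("^2018-03-01", "not-a-date", txt[3])
  txt[4] <- sub(",100,", ",abc,", txt[4])
  writeLines(txt, path)
  out <- parse_records(path)
  expect_equal(nrow(out$records), 1)
  expect_setequal(out$errors$row, c(2, 3))
  expect_true(any(out$errors$row == 3 & out$errors$message == "unparseable amount"))
})

test_that("a missing mandatory column is a schema error", {
  path <- write_temp_records(make_record())
  df <- read.csv(path)
  df$total <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(parse_records(path), class = "schema_error")
})

test_that("a schema map renames file columns onto canonical fields", {
  path <- write_temp_records(make_record(total = 321))
  df <- read.csv(path)
  names(df)[names(df) == "total"] <- "TOTAL_FEE"
  write.csv(df, path, row.names = FALSE)
  out <- parse_records(path, schema = c(total = "TOTAL_FEE"))
  expect_equal(out$records$total, 321)
})

test_that("payment phase honours the reform boundary dates", {
  expect_equal(assign_payment_phase(as.Date(c("2015-01-01", "2017-08-31"))), c(1L, 1L))
  expect_equal(assign_payment_phase(as.Date(c("2017-09-01", "2022-06-30"))), c(2L, 2L))
  expect_equal(assign_payment_phase(as.Date(c("2022-07-01", "2025-07-31"))), c(3L, 3L))
  expect_error(assign_payment_phase(as.Date("2014-12-31")), class = "window_error")
  expect_error(assign_payment_phase(as.Date("2025-08-01")), class = "window_error")
})

test_that("phase assignment tiles the study window monotonically with no gaps", {
  days <- seq(as.Date("2015-01-01"), as.Date("2025-07-31"), by = "day")
  ph <- assign_payment_phase(days)
  expect_false(anyNA(ph))
  expect_true(all(ph %in% 1:3))
  expect_true(all(diff(ph) >= 0))           # monotone in date
  expect_equal(sort(unique(ph)), 1:3)       # all three phases occur
})

test_that("inclusion criteria keep LOS 1-60 and the configured diagnosis", {
  recs <- make_records(
    make_record(los = 0), make_record(los = 61), make_record(los = 60),
    make_record(los = 1), make_record(primary_dx = "I21.0"),
    make_record(admission_date = "2014-06-01"))
  filt <- apply_inclusion_exclusion(recs)
  expect_equal(nrow(filt$kept), 2)
  expect_equal(filt$excluded$reason,
               c("los_extreme", "los_extreme", "dx_mismatch", "window"))
})

test_that("kept and excluded partition the input and reasons follow priority", {
  recs <- make_records(make_record(), make_record(los = 0, primary_dx = "X"),
                       make_record(admission_date = "2013-01-01", primary_dx = "X"))
  filt <- apply_inclusion_exclusion(recs)
  expect_equal(nrow(filt$kept) + nrow(filt$excluded), nrow(recs))
  # dx beats LOS; window beats dx
  expect_equal(filt$excluded$reason, c("dx_mismatch", "window"))
})

test_that("categorical coding reproduces the published variable assignment", {
  cpi <- flat_cpi()
  rec <- make_record(age_years = 72, los = 5, visit_number = 9, n_other_dx = 16)
  coded <- code_records(rec, cpi)
  expect_equal(coded$x5_age_group, 4)
  expect_equal(coded$x9_los_group, 2)
  expect_equal(coded$x3_visits, 4)
  expect_equal(coded$x10_other_dx_group, 6)

  # bin edges
  edges <- code_records(make_records(
    make_record(age_years = 60), make_record(age_years = 61),
    make_record(age_years = 90), make_record(age_years = 91),
    make_record(los = 3), make_record(los = 4),
    make_record(los = 9), make_record(los = 10)), cpi)
  expect_equal(edges$x5_age_group[1:4], c(1, 2, 7, 8))
  expect_equal(edges$x9_los_group[5:8], c(1, 2, 3, 4))
})

test_that("coding rejects ages below 1 and other-diagnosis counts of 0", {
  cpi <- flat_cpi()
  expect_error(code_records(make_record(age_years = 0), cpi), class = "domain_error")
  expect_error(code_records(make_record(n_other_dx = 0), cpi), class = "domain_error")
})

test_that("coding is total and in-range on every kept generated record", {
  cohort <- generate_cohort(cohort_config(n_patients = 400, seed = 11))
  kept <- apply_inclusion_exclusion(cohort)$kept
  coded <- code_records(kept, generate_cpi(2015, 2015:2025, 0.02))
  ranges <- list(x1_payment_phase = 1:3, x2_insurance = 1:3, x3_visits = 1:4,
                 x4_sex = 1:2, x5_age_group = 1:8, x6_ethnicity = 1:3,
                 x7_marital = 1:5, x8_route = 1:2, x9_los_group = 1:4,
                 x10_other_dx_group = 1:6, x11_hypertension = 0:1,
                 x12_diabetes = 0:1, x13_surgery = 0:4, x14_discharge = 1:5)
  for (nm in names(ranges)) expect_true(all(coded[[nm]] %in% ranges[[nm]]), label = nm)
  expect_true(all(is.finite(coded$y1_log_total)))
  expect_true(all(is.finite(coded$y2_log_oop)))
  # idempotent: recoding the same records gives the same table
  expect_identical(coded, code_records(kept, generate_cpi(2015, 2015:2025, 0.02)))
})
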