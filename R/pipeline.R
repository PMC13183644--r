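# End-to-end orchestration and reference-table verification.

#' Pipeline configuration
#'
#' Exactly one of `input` (a records CSV) or `synthetic` (a
#' [cohort_config()]) must be supplied. The CPI series comes from
#' `cpi_path` when given, otherwise it is generated at `cpi_growth`.
#'
#' @param input Path to a records CSV (see [parse_records()]), or `NULL`.
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param schema Optional column map for `input`.
#' @param cpi_path Optional two-column CPI CSV ([read_cpi()]).
#' @param base_year CPI base year (default 2015).
#' @param alpha Univariate screening level (default 0.05).
#' @param log_offset_oop Offset for the out-of-pocket log (default 1 yuan).
#' @param nominal Analyse nominal rather than CPI-standardized yuan.
#' @param share_mode Share basis for [annual_item_shares()].
#' @param gra_normalize Normalization mode for [gray_relational()].
#' @param rho Distinguishing coefficient for the gray analysis.
#' @param out_dir Output directory for report CSVs, or `NULL` to skip writes.
#' @param seed Integer seed covering every random element of the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, schema = NULL,
                            cpi_path = NULL, base_year = 2015, alpha = 0.05,
                            log_offset_oop = 1, nominal = FALSE,
                            share_mode = "aggregate",
                            gra_normalize = "none", rho = 0.5,
                            out_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(synthetic))
    stop_drg("supply exactly one of input / synthetic", class = "config_error")
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input = input, synthetic = synthetic, schema = schema,
                 cpi_path = cpi_path, base_year = base_year, alpha = alpha,
                 log_offset_oop = log_offset_oop, nominal = nominal,
                 share_mode = share_mode, gra_normalize = gra_normalize,
                 rho = rho, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full expense-structure analysis pipeline
#'
#' Stages, in order: load or simulate records; inclusion/exclusion
#' filtering; CPI standardization and coding; univariate screening of both
#' outcomes; dummy-coded OLS on each outcome's screened factors; yearly item
#' shares and structural variation (VSV/DSV/CRSV); gray relational analysis
#' of itemized against total per-admission expenses. When `out_dir` is set,
#' writes the coded cohort, exclusion log, screening tables, regression
#' tables, structural-change tables, gray-relational table, model summaries
#' and run metadata (seed and config echo). Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list bundle with elements `records`, `kept`,
#'   `excluded`, `coded`, `cpi`, `screen_y1`, `screen_y2`, `fit_y1`,
#'   `fit_y2`, `shares`, `structural`, `gra`, `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_drg("stage '", name, "': ", conditionMessage(e), class = "pipeline_error"))
  }

  cpi <- stage("cpi", {
    if (!is.null(config$cpi_path)) read_cpi(config$cpi_path)
    else {
      growth <- if (!is.null(config$synthetic)) config$synthetic$cpi_growth else 0.02
      generate_cpi(config$base_year, 2015:2025, growth)
    }
  })
  records <- stage("records", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic, cpi)
    else parse_records(config$input, config$schema)$records
  })
  filt <- stage("filter", apply_inclusion_exclusion(records))
  if (!nrow(filt$kept)) stop_drg("stage 'filter': no records kept", class = "pipeline_error")
  coded <- stage("coding", code_records(filt$kept, cpi, config$base_year,
                                        config$log_offset_oop, config$nominal))

  run_screen <- function(outcome, display) {
    testable <- Filter(function(f) length(unique(coded[[f]])) > 1L,
                       coded_factor_names())
    skipped <- setdiff(coded_factor_names(), testable)
    if (length(skipped))
      warning("factor(s) with a single observed level skipped: ",
              paste(skipped, collapse = ", "))
    univariate_screen(coded, testable, outcome, config$alpha, display)
  }
  screen_y1 <- stage("univariate_y1", run_screen("y1_log_total", "total_real"))
  screen_y2 <- stage("univariate_y2", run_screen("y2_log_oop", "oop_real"))

  fit_for <- function(screen, outcome) {
    if (!length(screen$selected)) return(NULL)
    fit_expense_model(coded, screen$selected, outcome)
  }
  fit_y1 <- stage("regression_y1", fit_for(screen_y1, "y1_log_total"))
  fit_y2 <- stage("regression_y2", fit_for(screen_y2, "y2_log_oop"))

  shares <- stage("shares", annual_item_shares(coded, mode = config$share_mode))
  structural <- stage("structural_change", structural_change(shares))
  gra <- stage("gray_relational",
               gray_relational(yearly_means(coded), rho = config$rho,
                               normalize = config$gra_normalize))

  meta <- list(seed = config$seed, n_input = nrow(records),
               n_kept = nrow(filt$kept), n_excluded = nrow(filt$excluded),
               base_year = config$base_year, alpha = config$alpha,
               log_offset_oop = config$log_offset_oop, nominal = config$nominal,
               share_mode = config$share_mode, rho = config$rho,
               gra_normalize = config$gra_normalize,
               package_version = as.character(utils::packageVersion("drgcost")))

  bundle <- list(records = records, kept = filt$kept, excluded = filt$excluded,
                 coded = coded, cpi = cpi, screen_y1 = screen_y1,
                 screen_y2 = screen_y2, fit_y1 = fit_y1, fit_y2 = fit_y2,
                 shares = shares, structural = structural, gra = gra,
                 meta = meta)
  if (!is.null(config$out_dir)) stage("write", write_bundle(bundle, config$out_dir))
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(bundle$coded, "coded_records.csv")
  excl <- bundle$excluded
  w(excl[, intersect(c("source_row", "reason"), names(excl)), drop = FALSE],
    "exclusion_log.csv")
  w(screen_table(bundle$screen_y1), "univariate_total.csv")
  w(screen_table(bundle$screen_y2), "univariate_oop.csv")
  if (!is.null(bundle$fit_y1)) w(bundle$fit_y1$table, "regression_total.csv")
  if (!is.null(bundle$fit_y2)) w(bundle$fit_y2$table, "regression_oop.csv")
  rep <- structural_change_report(bundle$structural)
  w(rep$vsv_dsv, "structural_vsv_dsv.csv")
  w(rep$crsv, "structural_crsv.csv")
  w(gra_report(bundle$gra), "gray_relational.csv")
  model_summary <- lapply(Filter(Negate(is.null),
                                 list(total = bundle$fit_y1, oop = bundle$fit_y2)),
                          function(f) list(F = f$F_statistic, adj_r2 = f$adj_r_squared,
                                           n = f$n, df_residual = f$df_residual))
  jsonlite::write_json(model_summary, file.path(out_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load the packaged reference tables
#'
#' The package ships three small reference tables for an 11-year
#' heart-failure cohort under staged DRG reform: the period-by-item VSV
#' table with its printed DSV column, the corresponding printed CRSV table,
#' and the year-by-item gray relational coefficient matrix with printed
#' degrees and ranks. They are the inputs for [verify_reference_tables()].
#'
#' @param which One of `"vsv"`, `"crsv"`, `"gra_xi"`.
#' @return Data frame.
#' @export
reference_table <- function(which = c("vsv", "crsv", "gra_xi")) {
  which <- match.arg(which)
  file <- c(vsv = "reference_vsv_table.csv", crsv = "reference_crsv_table.csv",
            gra_xi = "reference_gra_xi_table.csv")[[which]]
  path <- system.file("extdata", file, package = "drgcost")
  if (path == "") stop_drg("packaged reference table not found", class = "fixture_error")
  utils::read.csv(path, check.names = FALSE)
}

#' Recompute the reference tables' derived statistics and verify them
#'
#' From the shipped VSV table, recomputes DSV and CRSV per period; from the
#' shipped coefficient matrix, recomputes the relational degrees and ranks.
#' Each recomputed value is compared to its printed counterpart at print
#' precision. Because the published inputs are themselves rounded (VSVs and
#' coefficients to 4 decimals), a value recomputed from them can differ from
#' one computed on the unrounded source data; each comparison therefore uses
#' the worst-case propagation of that input rounding (each VSV is off by at
#' most 5e-5, so a period's DSV by at most 3.5e-4, and a CRSV percent by up
#' to `100 * (5e-5 + crsv_i/100 * 3.5e-4) / dsv`), plus half a unit in the
#' last printed digit on both sides. Any difference beyond that bound is a
#' genuine mismatch and is flagged as a failure.
#'
#' @param vsv_table,crsv_table,xi_table Optional replacement tables in the
#'   packaged layout (used by negative-control tests).
#' @return Data frame with one row per check: `check`, `cell`, `expected`,
#'   `recomputed`, `tol`, `pass`. Attribute `all_pass` summarizes.
#' @export
verify_reference_tables <- function(vsv_table = reference_table("vsv"),
                                    crsv_table = reference_table("crsv"),
                                    xi_table = reference_table("gra_xi")) {
  items <- expense_items()
  vsv_step <- 5e-5          # half a unit in the 4th printed decimal
  print_step <- 0.01        # both sides rounded to 2 decimals
  checks <- list()
  add <- function(check, cell, expected, recomputed, tol) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, cell = cell, expected = expected, recomputed = recomputed,
      tol = tol, pass = is.finite(recomputed) & abs(recomputed - expected) <= tol)
  }
  for (i in seq_len(nrow(vsv_table))) {
    v <- as.numeric(vsv_table[i, items])
    d <- dsv(v, as_percent = FALSE)
    add("dsv", vsv_table$period[i], vsv_table$dsv_printed[i],
        round_half_up(dsv(v), 2), 100 * 7 * vsv_step + print_step)
    cr <- round_half_up(crsv(v), 2)
    pr <- as.numeric(crsv_table[match(vsv_table$period[i], crsv_table$period), items])
    for (j in seq_along(items)) {
      tol_j <- 100 * (vsv_step + abs(v[j]) / d * 7 * vsv_step) / d + print_step
      add("crsv", paste0(vsv_table$period[i], ":", items[j]), pr[j], cr[j], tol_j)
    }
  }
  xi <- as.matrix(xi_table[, grep("^y", names(xi_table))])
  rownames(xi) <- xi_table$item
  deg <- relational_degrees(xi)
  for (j in seq_len(nrow(xi_table))) {
    # mean of 11 coefficients each rounded to 4 decimals, plus print rounding
    add("gamma", xi_table$item[j], xi_table$gamma_printed[j],
        round_half_up(deg$gamma[j], 4), 1.5e-4)
    add("rank", xi_table$item[j], xi_table$rank_printed[j],
        deg$ranks[j], 0)
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  out
}
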