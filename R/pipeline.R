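# End-to-end run configuration, orchestration and fixed-precision
# rendering. Rendering is a pure function of the unrounded summaries;
# rounded values never feed back into computation.

#' Run configuration
#'
#' Collects the file paths, thresholds and model settings for a full
#' pipeline run. Inputs may be given as paths or as already-validated
#' objects (a [generate_bundle()] result covers all four).
#'
#' @param factors,ref_stocks,strata,payments paths or objects.
#' @param thresholds positive price thresholds ($ Mg^-1 CO2).
#' @param deflator dollar-year multiplier (applied to `thresholds` only
#'   when `adjust_thresholds = TRUE`).
#' @param adjust_thresholds logical; if `TRUE`, thresholds are supplied
#'   in source-year dollars and carried through `deflator`.
#' @param reserve_fraction reserve-pool fraction in `[0, 1)`.
#' @param horizon years to equilibrium.
#' @param out_dir output directory for the report bundle.
#' @return An object of class `run_config`.
#' @export
run_config <- function(factors, ref_stocks, strata, payments,
                       thresholds = c(36.36, 86.06, 100),
                       deflator = 36.36 / 30, adjust_thresholds = FALSE,
                       reserve_fraction = 0, horizon = 20,
                       out_dir = NULL) {
  if (any(!is.finite(thresholds) | thresholds <= 0)) {
    .soccost_error("soccost_config_error", "thresholds must be positive")
  }
  structure(list(factors = factors, ref_stocks = ref_stocks,
                 strata = strata, payments = payments,
                 thresholds = thresholds, deflator = deflator,
                 adjust_thresholds = adjust_thresholds,
                 reserve_fraction = reserve_fraction, horizon = horizon,
                 out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("soccost_pipeline_error", class(e))))
  })
}

.load_input <- function(x, loader, cls) {
  if (inherits(x, cls)) x else if (is.character(x)) loader(x) else
    switch(cls,
           factor_table = factor_table(x),
           ref_stock_table = ref_stock_table(x),
           soc_strata = read_strata(x),
           payment_schedule = payment_schedule(x))
}

#' Run the full accounting-and-pricing pipeline
#'
#' Executes load -> per-stratum rates -> sequence and region
#' aggregation -> cost curve -> threshold summaries, and (when
#' `config$out_dir` is set) writes `rates.csv`, `curve.csv`,
#' `summary.csv`, `table1.csv`, `table2.csv` (unrounded), their
#' rendered fixed-precision `.txt` companions, and a `run_log.txt`
#' recording input file digests and the configuration. Any stage error
#' aborts with the stage name and the offending records; reruns on the
#' same inputs are byte-identical.
#'
#' @param config a [run_config()]; alternatively pass a
#'   [generate_bundle()] result via `bundle` and the remaining
#'   settings as a config built from it.
#' @param bundle optional `soc_bundle` supplying all four inputs.
#' @return Invisibly, a list with `inventory`, `table1`, `table2`
#'   (or `NULL` without region labels), `curve`, `summary`, `config`.
#' @export
#' @examples
#' b <- generate_bundle(generator_config(n_strata = 60, seed = 5))
#' rep <- run_pipeline(bundle = b)
#' rep$table1
run_pipeline <- function(config = NULL, bundle = NULL) {
  if (!is.null(bundle)) {
    stopifnot(inherits(bundle, "soc_bundle"))
    base <- config %||% run_config(bundle$factors, bundle$ref_stocks,
                                   bundle$strata, bundle$payments)
    base$factors <- bundle$factors
    base$ref_stocks <- bundle$ref_stocks
    base$strata <- bundle$strata
    base$payments <- bundle$payments
    config <- base
  }
  stopifnot(inherits(config, "run_config"))
  factors <- .stage("load factors",
                    .load_input(config$factors, load_factor_table,
                                "factor_table"))
  refs <- .stage("load reference stocks",
                 .load_input(config$ref_stocks, load_ref_stocks,
                             "ref_stock_table"))
  strata <- .stage("load strata",
                   .load_input(config$strata, read_strata, "soc_strata"))
  payments <- .stage("load payments",
                     .load_input(config$payments, load_payments,
                                 "payment_schedule"))
  inv <- .stage("rates", soc_inventory(strata, factors, refs,
                                       config$horizon))
  table1 <- .stage("sequence aggregation", aggregate_by_sequence(inv))
  table2 <- if (any(!is.na(inv$results$region))) {
    .stage("region aggregation", aggregate_by_region(inv))
  } else NULL
  curve <- .stage("cost curve",
                  build_curve(inv, payments,
                              reserve = config$reserve_fraction))
  thr <- if (config$adjust_thresholds) {
    inflation_adjust(config$thresholds, config$deflator)
  } else config$thresholds
  summ <- .stage("threshold summary", threshold_summary(curve, thr))
  if (!is.null(config$out_dir)) {
    .write_report(config, factors, refs, strata, payments,
                  inv, table1, table2, curve, summ)
  }
  invisible(list(inventory = inv, table1 = table1, table2 = table2,
                 curve = curve, summary = summ, config = config))
}

.write_report <- function(config, factors, refs, strata, payments,
                          inv, table1, table2, curve, summ) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  rates <- inv$results[, c("stratum_id", "sequence", "rate_c_mg_ha_yr",
                           "rate_co2_mg_ha_yr", "annual_tg_c",
                           "annual_tg_co2", "flags")]
  write.csv(rates, out("rates.csv"), row.names = FALSE, quote = FALSE)
  cpts <- curve$points
  names(cpts) <- c("stratum_id", "sequence", "unit_cost_usd_per_mg_co2",
                   "annual_tg_co2", "cumulative_tg_co2")
  write.csv(cpts, out("curve.csv"), row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(summ), out("summary.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(as.data.frame(table1), out("table1.csv"), row.names = FALSE,
            quote = FALSE)
  writeLines(render_table(table1), out("table1.txt"))
  if (!is.null(table2)) {
    write.csv(as.data.frame(table2), out("table2.csv"), row.names = FALSE,
              quote = FALSE)
    writeLines(render_table(table2), out("table2.txt"))
  }
  writeLines(render_table(summ), out("summary.txt"))
  digests <- vapply(c(factors = "factors", ref_stocks = "ref_stocks",
                      strata = "strata", payments = "payments"),
                    function(nm) {
      x <- config[[nm]]
      if (is.character(x) && length(x) == 1 && file.exists(x)) {
        sprintf("%s: %s (md5 %s)", nm, x, unname(md5sum(x)))
      } else {
        sprintf("%s: in-memory object", nm)
      }
    }, "")
  log <- c("soccost run log",
           sprintf("package version: %s",
                   as.character(utils::packageVersion("soccost"))),
           digests,
           sprintf("thresholds: %s", paste(config$thresholds, collapse = ", ")),
           sprintf("deflator: %.10g", config$deflator),
           sprintf("reserve_fraction: %g", config$reserve_fraction),
           sprintf("horizon: %g", config$horizon),
           sprintf("n_strata: %d", nrow(strata)),
           sprintf("n_curve_points: %d", nrow(curve$points)))
  writeLines(log, out("run_log.txt"))
  invisible(config$out_dir)
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "N/A",
         formatC(round_half_away(x, digits), format = "f", digits = digits))
}

#' Render a summary at printed precision
#'
#' Formats the pipeline's summary tables with the reporting
#' conventions: one decimal for rates, totals and percentages, two for
#' currency, zero for 20-year totals, half-away-from-zero ties, paired
#' "C (CO2)" columns such as `0.38 (1.4)`, and `N/A` for absent
#' combinations. Rendering never feeds back into computation; the
#' unrounded CSVs are always emitted alongside.
#'
#' @param x a `soc_sequence_summary`, `soc_region_summary` or
#'   `soc_threshold_summary`.
#' @param ... unused.
#' @return A character vector of fixed-width table lines.
#' @export
render_table <- function(x, ...) UseMethod("render_table")

.render_df <- function(df) {
  m <- rbind(names(df), as.matrix(df))
  widths <- apply(nchar(m), 2, max)
  lines <- apply(m, 1, function(r)
    paste(mapply(formatC, r, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  "))
  sub("\\s+$", "", unname(lines))
}

#' @rdname render_table
#' @export
render_table.soc_sequence_summary <- function(x, ...) {
  df <- data.frame(
    `Sequence` = x$sequence,
    `Area (Mha)` = .fmt(x$area_mha, 1),
    `Area (%)` = .fmt(x$area_share_pct, 1),
    `Annual C (CO2) (Tg/yr)` = sprintf("%s (%s)", .fmt(x$annual_tg_c, 1),
                                       .fmt(x$annual_tg_co2, 1)),
    `20-yr C (CO2) (Tg)` = sprintf("%s (%s)", .fmt(x$total_20yr_tg_c, 0),
                                   .fmt(x$total_20yr_tg_co2, 0)),
    `C (%)` = .fmt(x$c_share_pct, 1),
    `Rate C (CO2) (Mg/ha/yr)` = sprintf("%s (%s)", .fmt(x$rate_c_wmean, 2),
                                        .fmt(x$rate_co2_wmean, 1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  .render_df(df)
}

#' @rdname render_table
#' @export
render_table.soc_region_summary <- function(x, ...) {
  df <- as.data.frame(x)
  for (j in seq_along(df)[-1]) df[[j]] <- .fmt(as.numeric(df[[j]]), 2)
  .render_df(df)
}

#' @rdname render_table
#' @export
render_table.soc_threshold_summary <- function(x, ...) {
  df <- data.frame(
    `Threshold ($/Mg CO2)` = sprintf("< $%s", .fmt(x$threshold, 2)),
    `Sequence` = x$sequence,
    `Annual (Tg CO2/yr)` = .fmt(x$annual_tg_co2, 1),
    `Share within (%)` = .fmt(x$share_within_pct, 1),
    `Share of total (%)` = .fmt(x$share_of_total_pct, 1),
    check.names = FALSE, stringsAsFactors = FALSE)
  .render_df(df)
}
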