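# Economics of the conversion payment: per-state payment schedules,
# the per-stratum carbon value (payment divided by the CO2 rate),
# dollar-year adjustment, and the optional reserve-pool discount.

#' Build or load a state payment schedule
#'
#' Annual conservation-program payments for no-till adoption, in dollars
#' per hectare per year. Payments vary across states but not within a
#' state; every stratum inherits its state's payment. Values must be
#' positive and finite, states unique.
#'
#' @param x a data frame with columns `state`, `payment_usd_per_ha_yr`,
#'   or a named numeric vector (names = state codes).
#' @param path CSV path with those columns.
#' @return An object of class `payment_schedule`.
#' @export
#' @examples
#' payment_schedule(c(IA = 25.50, TX = 112.10))
payment_schedule <- function(x) {
  if (inherits(x, "payment_schedule")) return(x)
  df <- if (is.numeric(x) && !is.null(names(x))) {
    data.frame(state = names(x), payment_usd_per_ha_yr = as.numeric(x),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  .require_columns(df, c("state", "payment_usd_per_ha_yr"),
                   "payment schedule")
  df$state <- toupper(trimws(as.character(df$state)))
  df$payment_usd_per_ha_yr <- as.numeric(df$payment_usd_per_ha_yr)
  if (anyDuplicated(df$state)) {
    .soccost_error("soccost_integrity_error",
                   "duplicate state(s) in payment schedule: %s",
                   paste(sQuote(unique(df$state[duplicated(df$state)])),
                         collapse = ", "))
  }
  bad <- !is.finite(df$payment_usd_per_ha_yr) | df$payment_usd_per_ha_yr <= 0
  if (any(bad)) {
    .soccost_error("soccost_domain_error",
                   "payments must be finite and > 0 (state %s)",
                   paste(sQuote(df$state[bad]), collapse = ", "))
  }
  df <- df[order(df$state), c("state", "payment_usd_per_ha_yr")]
  rownames(df) <- NULL
  class(df) <- c("payment_schedule", "data.frame")
  df
}

#' @rdname payment_schedule
#' @export
load_payments <- function(path) {
  if (!file.exists(path)) {
    .soccost_error("soccost_schema_error", "payment file not found: %s", path)
  }
  payment_schedule(read.csv(path, stringsAsFactors = FALSE,
                            strip.white = TRUE))
}

#' @rdname payment_schedule
#' @param schedule a `payment_schedule`.
#' @param state state code vector.
#' @export
lookup_payment <- function(schedule, state) {
  stopifnot(inherits(schedule, "payment_schedule"))
  idx <- match(toupper(trimws(state)), schedule$state)
  if (anyNA(idx)) {
    .soccost_error("soccost_config_error",
                   "no payment rate for state(s): %s",
                   paste(sQuote(unique(state[is.na(idx)])), collapse = ", "))
  }
  schedule$payment_usd_per_ha_yr[idx]
}

#' Carbon value of a priced stratum
#'
#' The unit cost of sequestration: the annual payment required for
#' no-till adoption divided by the annual CO2 sequestration rate,
#' `usd_per_mg_co2 = payment / rate_co2`, with the C-basis companion
#' `usd_per_mg_c = usd_per_mg_co2 * 44/12` (a tonne of carbon embodies
#' 44/12 tonnes of CO2, so it is worth proportionally more).
#'
#' Strata with zero or negative rates have no defined cost and must be
#' excluded from curves, not silently priced: such inputs raise an
#' error of class `soccost_undefined_cost`.
#'
#' @param payment payment in $ ha^-1 yr^-1 (> 0).
#' @param rate_co2 sequestration rate in Mg CO2 ha^-1 yr^-1 (> 0).
#' @return A data frame with columns `usd_per_mg_co2`, `usd_per_mg_c`
#'   (one row per input element).
#' @export
#' @examples
#' carbon_value(18.29, 2.86)
carbon_value <- function(payment, rate_co2) {
  n <- max(length(payment), length(rate_co2))
  payment <- rep_len(as.numeric(payment), n)
  rate_co2 <- rep_len(as.numeric(rate_co2), n)
  if (any(!is.finite(payment) | payment <= 0)) {
    .soccost_error("soccost_domain_error", "payment must be finite and > 0")
  }
  if (any(!is.finite(rate_co2) | rate_co2 <= 0)) {
    .soccost_error("soccost_undefined_cost",
                   "carbon value undefined for zero or negative rates; exclude such strata from the curve")
  }
  usd_co2 <- payment / rate_co2
  data.frame(usd_per_mg_co2 = usd_co2, usd_per_mg_c = c_to_co2(usd_co2))
}

#' Dollar-year adjustment
#'
#' Multiplies a dollar value by a deflator factor carrying it from the
#' source to the target dollar year. The default factor is the exact
#' ratio 36.36/30 used to carry the geologic-storage cost range from
#' 2005 to 2014 dollars ($30 -> $36.36, $71 -> $86.05).
#'
#' @param value dollar value(s).
#' @param deflator positive multiplier (default `36.36/30`).
#' @return Adjusted dollar value(s).
#' @export
#' @examples
#' inflation_adjust(c(30, 71))
inflation_adjust <- function(value, deflator = 36.36 / 30) {
  if (!is.numeric(deflator) || length(deflator) != 1 ||
      !is.finite(deflator) || deflator <= 0) {
    .soccost_error("soccost_domain_error", "deflator must be a positive number")
  }
  value * deflator
}

#' Reserve-pool discount
#'
#' Retains a fraction of the sequestration in a reserve pool insuring
#' against reversal (e.g. the 20 percent used by the Chicago Climate
#' Exchange), crediting only `rate * (1 - fraction)`. Every downstream
#' carbon value is thereby multiplied by exactly `1 / (1 - fraction)`.
#'
#' @param rate_co2 non-negative sequestration rate(s).
#' @param fraction reserve fraction in `[0, 1)` (default 0 = no reserve).
#' @return Discounted rate(s).
#' @export
#' @examples
#' apply_reserve(1.0, 0.20)
apply_reserve <- function(rate_co2, fraction = 0) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction < 0 || fraction >= 1) {
    .soccost_error("soccost_domain_error",
                   "reserve fraction must lie in [0, 1)")
  }
  if (any(rate_co2 < 0, na.rm = TRUE)) {
    .soccost_error("soccost_domain_error",
                   "reserve discount applies to non-negative rates only")
  }
  rate_co2 * (1 - fraction)
}
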