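# S3 methods for the fitted objects.

#' @export
print.soc_inventory <- function(x, ...) {
  r <- x$results
  el <- r$flags != "ineligible"
  cat("Tier-1 no-till conversion inventory\n")
  cat(sprintf("  strata: %d (%d eligible, %d already no-till, %d ineligible)\n",
              nrow(r), sum(el), sum(r$flags == "already-nt"),
              sum(r$flags == "ineligible")))
  cat(sprintf("  convertible area: %.1f Mha of %.1f Mha\n",
              sum(r$area_ha[r$flags == "ok"]) / 1e6,
              sum(r$area_ha[el]) / 1e6))
  cat(sprintf("  annual potential: %.1f Tg C/yr (%.1f Tg CO2/yr)\n",
              sum(r$annual_tg_c[el]), sum(r$annual_tg_co2[el])))
  cat(sprintf("  %g-year total:   %.0f Tg CO2\n", x$horizon,
              sum(r$total_20yr_tg_co2[el])))
  invisible(x)
}

#' @export
summary.soc_inventory <- function(object, ...) {
  aggregate_by_sequence(object)
}

#' @export
print.soc_sequence_summary <- function(x, ...) {
  writeLines(render_table(x))
  invisible(x)
}

#' @export
print.soc_region_summary <- function(x, ...) {
  writeLines(render_table(x))
  invisible(x)
}

#' @export
print.soc_threshold_summary <- function(x, ...) {
  writeLines(render_table(x))
  invisible(x)
}

#' @export
print.soc_cost_curve <- function(x, ...) {
  p <- x$points
  cat("Marginal cost curve for SOC sequestration via no-till adoption\n")
  cat(sprintf("  points: %d strata, %d excluded\n", nrow(p),
              nrow(x$excluded)))
  cat(sprintf("  unit cost range: $%.2f to $%.2f per Mg CO2\n",
              min(p$unit_cost), max(p$unit_cost)))
  cat(sprintf("  annual quantity on curve: %.1f Tg CO2/yr (potential %.1f)\n",
              sum(p$annual_qty), x$total_potential))
  if (!is.null(x$reserve) && !is.na(x$reserve) && x$reserve > 0) {
    cat(sprintf("  reserve fraction applied: %.0f%%\n", 100 * x$reserve))
  }
  invisible(x)
}

#' @export
summary.soc_cost_curve <- function(object, thresholds = c(36.36, 86.06),
                                   total_potential = NULL, ...) {
  threshold_summary(object, thresholds, total_potential)
}

#' Quantity available below a price
#'
#' `predict()` on a cost curve evaluates the supply step function: the
#' annual quantity (Tg CO2 yr^-1) available at unit costs strictly
#' below each price.
#'
#' @param object a `soc_cost_curve`.
#' @param price price(s) in $ Mg^-1 CO2.
#' @param ... unused.
#' @return Numeric vector, one value per price.
#' @export
predict.soc_cost_curve <- function(object, price, ...) {
  quantity_below(object, price)
}

#' Plot a marginal cost curve
#'
#' Step plot of unit cost against cumulative annual quantity, with
#' optional vertical price thresholds.
#'
#' @param x a `soc_cost_curve`.
#' @param thresholds prices to mark with horizontal reference lines
#'   (`NULL` for none).
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.soc_cost_curve <- function(x, thresholds = c(36.36, 86.06), ...) {
  p <- x$points
  qx <- c(0, p$cumulative_qty)
  cy <- c(p$unit_cost[1], p$unit_cost)
  plot.default(qx, cy, type = "s",
               xlab = expression(paste("Cumulative quantity (Tg ", CO[2],
                                       " ", yr^-1, ")")),
               ylab = expression(paste("Unit cost ($ ", Mg^-1, " ", CO[2],
                                       ")")), ...)
  if (!is.null(thresholds)) abline(h = thresholds, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
print.soc_bundle <- function(x, ...) {
  cat("Synthetic input bundle\n")
  cat(sprintf("  strata: %d (total area %.1f Mha)\n", nrow(x$strata),
              sum(x$strata$area_ha) / 1e6))
  cat(sprintf("  states: %d, climate zones: %d, soils: %d\n",
              nrow(x$payments), length(unique(x$strata$climate_zone)),
              length(unique(x$strata$soil_class))))
  cat(sprintf("  seed: %d\n", x$provenance$seed))
  invisible(x)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic generator configuration\n")
  cat(sprintf("  n_strata: %d, total area: %.1f Mha, seed: %d\n",
              x$n_strata, x$total_area_mha, x$seed))
  cat(sprintf("  rate range: %.2f-%.2f Mg C/ha/yr; payments: $%.2f-$%.2f/ha\n",
              x$rate_range_c[1], x$rate_range_c[2],
              x$payment_range[1], x$payment_range[2]))
  invisible(x)
}

#' @export
print.soc_sensitivity <- function(x, ...) {
  cat("Factor-uncertainty sensitivity envelope\n")
  cat(sprintf("  draws: %d (seed %d); price grid: %d points\n",
              x$n_draws, x$seed, length(x$prices)))
  cat(sprintf("  factor uncertainty (%%): %s\n",
              paste(sprintf("%s=%g", names(x$factor_uncertainty),
                            x$factor_uncertainty), collapse = ", ")))
  invisible(x)
}

#' Plot a sensitivity envelope
#'
#' Baseline supply curve with the Monte Carlo quantile band from
#' [sensitivity_sweep()].
#'
#' @param x a `soc_sensitivity`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.soc_sensitivity <- function(x, ...) {
  lo <- x$quantiles[, 1]
  hi <- x$quantiles[, ncol(x$quantiles)]
  plot.default(x$prices, x$baseline, type = "l",
               ylim = range(lo, hi, x$baseline),
               xlab = expression(paste("Price ($ ", Mg^-1, " ", CO[2], ")")),
               ylab = expression(paste("Quantity below price (Tg ", CO[2],
                                       " ", yr^-1, ")")), ...)
  polygon(c(x$prices, rev(x$prices)), c(lo, rev(hi)),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(x$prices, x$baseline)
  invisible(x)
}
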