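# Marginal cost curve assembly and queries.
#
# Each positive-rate stratum becomes one point (unit cost, annual
# quantity); sorting by unit cost with lexicographic stratum-id
# tie-breaks gives a deterministic supply curve of sequestration.
# Zero- and negative-rate strata are first-class exclusions, never
# priced at infinity.

#' Construct a cost curve from priced points
#'
#' Low-level constructor used by [build_curve()] and available for
#' assembling curves from already-priced data (e.g. published
#' per-sequence quantities). Points are sorted by non-decreasing unit
#' cost, ties broken by `stratum_id`; the cumulative quantity column is
#' recomputed.
#'
#' @param points data frame with columns `stratum_id`, `sequence`,
#'   `unit_cost` ($ Mg^-1 CO2, positive finite) and `annual_qty`
#'   (Tg CO2 yr^-1, positive).
#' @param excluded optional data frame with columns `stratum_id`,
#'   `sequence`, `annual_qty`, `reason`.
#' @param total_potential scenario-wide annual potential (Tg CO2 yr^-1);
#'   defaults to the sum over points and exclusions.
#' @return An object of class `soc_cost_curve`.
#' @export
cost_curve <- function(points, excluded = NULL, total_potential = NULL) {
  pts <- as.data.frame(points, stringsAsFactors = FALSE)
  .require_columns(pts, c("stratum_id", "sequence", "unit_cost", "annual_qty"),
                   "cost curve points")
  pts$stratum_id <- as.character(pts$stratum_id)
  pts$unit_cost <- as.numeric(pts$unit_cost)
  pts$annual_qty <- as.numeric(pts$annual_qty)
  if (any(!is.finite(pts$unit_cost) | pts$unit_cost <= 0)) {
    .soccost_error("soccost_domain_error",
                   "unit costs must be finite and > 0")
  }
  if (any(!is.finite(pts$annual_qty) | pts$annual_qty <= 0)) {
    .soccost_error("soccost_domain_error",
                   "point quantities must be finite and > 0")
  }
  if (anyDuplicated(pts$stratum_id)) {
    .soccost_error("soccost_integrity_error",
                   "duplicate stratum_id(s) on the curve")
  }
  pts <- pts[order(pts$unit_cost, pts$stratum_id),
             c("stratum_id", "sequence", "unit_cost", "annual_qty")]
  pts$cumulative_qty <- cumsum(pts$annual_qty)
  rownames(pts) <- NULL
  if (is.null(excluded)) {
    excluded <- data.frame(stratum_id = character(), sequence = character(),
                           annual_qty = numeric(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  excluded <- as.data.frame(excluded, stringsAsFactors = FALSE)
  tp <- total_potential %||% (sum(pts$annual_qty) + sum(excluded$annual_qty))
  structure(list(points = pts, excluded = excluded, total_potential = tp),
            class = "soc_cost_curve")
}

#' Build the marginal cost curve from an inventory
#'
#' Prices every convertible positive-rate stratum with its state's
#' payment via [carbon_value()] (after the optional reserve-pool
#' discount of [apply_reserve()]) and assembles the supply curve.
#' Already-no-till, ineligible and negative-rate strata are routed to
#' the `excluded` table with reasons; the scenario's total annual
#' potential (curve plus exclusions) is retained so threshold shares
#' can be expressed against it.
#'
#' @param inventory a [soc_inventory()].
#' @param payments a [payment_schedule()] (or coercible input).
#' @param reserve reserve-pool fraction in `[0, 1)` (default 0).
#' @return An object of class `soc_cost_curve`: list with `points`
#'   (sorted, with `cumulative_qty`), `excluded`, `total_potential`
#'   and `reserve`. Methods: [print()], [summary()] (threshold table),
#'   [predict()] (quantity below a price), [plot()].
#' @export
#' @examples
#' b <- generate_bundle(generator_config(n_strata = 100, seed = 3))
#' inv <- soc_inventory(b$strata, b$factors, b$ref_stocks)
#' mc <- build_curve(inv, b$payments)
#' predict(mc, price = c(36.36, 86.06))
build_curve <- function(inventory, payments, reserve = 0) {
  stopifnot(inherits(inventory, "soc_inventory"))
  sched <- payment_schedule(payments)
  res <- inventory$results
  disc <- apply_reserve(pmax(res$rate_co2_mg_ha_yr, 0), reserve)
  qty <- disc * res$area_ha / 1e6
  on_curve <- res$flags == "ok" & res$rate_co2_mg_ha_yr > 0
  reason <- c("ineligible" = "ineligible: non-crop or set-aside in 1997",
              "already-nt" = "zero rate: already under no-till in 1997",
              "negative-rate" = "negative rate: tillage intensification",
              "ok" = "zero rate")
  excluded <- data.frame(
    stratum_id = res$stratum_id[!on_curve],
    sequence = res$sequence[!on_curve],
    annual_qty = qty[!on_curve],
    reason = unname(reason[res$flags[!on_curve]]),
    stringsAsFactors = FALSE)
  if (!any(on_curve)) {
    .soccost_error("soccost_empty_error",
                   "no positive-rate strata: the cost curve would be empty")
  }
  pay <- lookup_payment(sched, res$state[on_curve])
  cv <- carbon_value(pay, disc[on_curve])
  pts <- data.frame(stratum_id = res$stratum_id[on_curve],
                    sequence = res$sequence[on_curve],
                    unit_cost = cv$usd_per_mg_co2,
                    annual_qty = qty[on_curve],
                    stringsAsFactors = FALSE)
  out <- cost_curve(pts, excluded,
                    total_potential = sum(qty[on_curve]) +
                      sum(excluded$annual_qty))
  out$reserve <- reserve
  out
}

#' Annual quantity available below a price
#'
#' Sums the annual quantity over curve points whose unit cost is
#' strictly less than `price` (matching the strict "less than"
#' convention of threshold reporting). A non-decreasing step function
#' of price: zero below the cheapest point, the curve total above the
#' dearest.
#'
#' @param curve a `soc_cost_curve`.
#' @param price price(s) in $ Mg^-1 CO2.
#' @return Tg CO2 yr^-1, one value per price.
#' @export
quantity_below <- function(curve, price) {
  stopifnot(inherits(curve, "soc_cost_curve"))
  vapply(as.numeric(price), function(p)
    sum(curve$points$annual_qty[curve$points$unit_cost < p]), numeric(1))
}

#' Threshold summary by tillage sequence
#'
#' For each price threshold, the annual quantity available strictly
#' below it broken down by tillage sequence, the share of that
#' within-threshold quantity (%), and the share of the scenario-wide
#' annual potential (%). A `Total` row closes each threshold block.
#'
#' @param curve a `soc_cost_curve`.
#' @param thresholds positive prices in $ Mg^-1 CO2; the defaults are
#'   the low and high geologic-storage cost estimates in 2014 dollars.
#' @param total_potential denominator for the share-of-total column
#'   (Tg CO2 yr^-1); defaults to the curve's stored scenario total.
#' @return A data frame of class `soc_threshold_summary` with columns
#'   `threshold`, `sequence`, `annual_tg_co2`, `share_within_pct`,
#'   `share_of_total_pct`.
#' @export
threshold_summary <- function(curve, thresholds = c(36.36, 86.06),
                              total_potential = NULL) {
  stopifnot(inherits(curve, "soc_cost_curve"))
  if (any(!is.finite(thresholds) | thresholds <= 0)) {
    .soccost_error("soccost_domain_error", "thresholds must be positive")
  }
  tp <- total_potential %||% curve$total_potential
  if (!is.finite(tp) || tp <= 0) {
    .soccost_error("soccost_domain_error",
                   "total_potential must be positive")
  }
  seqs <- intersect(tillage_sequences(), unique(curve$points$sequence))
  blocks <- lapply(thresholds, function(thr) {
    below <- curve$points[curve$points$unit_cost < thr, ]
    q <- vapply(seqs, function(sq)
      sum(below$annual_qty[below$sequence == sq]), numeric(1))
    tot <- sum(q)
    data.frame(
      threshold = thr,
      sequence = c(seqs, "Total"),
      annual_tg_co2 = c(q, tot),
      share_within_pct = if (tot > 0) c(100 * q / tot, 100) else 0,
      share_of_total_pct = 100 * c(q, tot) / tp,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("soc_threshold_summary", "data.frame")
  out
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Factor-uncertainty sensitivity sweep
#'
#' Propagates the reported relative uncertainty of the stock-change
#' factors to the cost curve: each draw perturbs every factor
#' multiplier with an independent multiplicative normal error whose 95%
#' half-width equals the per-kind percentage, rebuilds the inventory
#' and curve through the full pipeline, and evaluates
#' [quantity_below()] on a common price grid. The result is a
#' per-price quantile envelope, seeded and reproducible.
#'
#' @param inventory a [soc_inventory()].
#' @param payments a [payment_schedule()].
#' @param factor_uncertainty named vector of per-kind relative
#'   uncertainties in percent (names among `LU`, `MG`, `I`); defaults
#'   to the reported 12 / 10 / 15.
#' @param n_draws number of Monte Carlo draws (>= 1).
#' @param seed integer seed; the caller's RNG state is restored.
#' @param prices price grid; defaults to 201 points spanning the
#'   baseline curve.
#' @param probs envelope quantile levels.
#' @param reserve reserve fraction passed to [build_curve()].
#' @return An object of class `soc_sensitivity`: list with `prices`,
#'   `quantiles` (matrix, one row per price), `draws` (draw x price
#'   matrix), `baseline` quantities, the settings used.
#' @export
sensitivity_sweep <- function(inventory, payments,
                              factor_uncertainty = c(LU = 12, MG = 10, I = 15),
                              n_draws = 100, seed = 1L, prices = NULL,
                              probs = c(0.025, 0.5, 0.975), reserve = 0) {
  stopifnot(inherits(inventory, "soc_inventory"))
  if (!is.numeric(n_draws) || n_draws < 1) {
    .soccost_error("soccost_domain_error", "n_draws must be >= 1")
  }
  fu <- factor_uncertainty
  if (is.null(names(fu)) || !all(names(fu) %in% .FACTOR_KINDS) ||
      any(!is.finite(fu) | fu < 0)) {
    .soccost_error("soccost_domain_error",
                   "factor_uncertainty must be a named non-negative vector with names among LU, MG, I")
  }
  base <- build_curve(inventory, payments, reserve = reserve)
  if (is.null(prices)) {
    prices <- seq(0, max(base$points$unit_cost) * 1.05, length.out = 201)
  }
  ft <- as.data.frame(inventory$factors)
  sdv <- setNames(rep(0, nrow(ft)), NULL)
  for (k in names(fu)) sdv[ft$factor_kind == k] <- fu[[k]] / 100 / 1.96
  draws <- .with_seed(seed, {
    m <- vapply(seq_len(n_draws), function(d) {
      pf <- ft
      pf$value <- pmax(pf$value * (1 + sdv * rnorm(nrow(pf))), 1e-9)
      pf <- suppressWarnings(factor_table(pf))
      inv_d <- soc_inventory(inventory$strata, pf, inventory$ref_stocks,
                             inventory$horizon)
      cv_d <- build_curve(inv_d, payments, reserve = reserve)
      quantity_below(cv_d, prices)
    }, numeric(length(prices)))
    matrix(m, nrow = n_draws, ncol = length(prices), byrow = TRUE)
  })
  qs <- t(apply(draws, 2, quantile, probs = probs, names = FALSE))
  colnames(qs) <- sprintf("q%g", probs * 100)
  structure(list(prices = prices, quantiles = qs, draws = draws,
                 baseline = quantity_below(base, prices),
                 factor_uncertainty = fu, n_draws = n_draws, seed = seed),
            class = "soc_sensitivity")
}
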