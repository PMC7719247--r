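make_inventory <- function() {
  ft <- tiny_factors(); rt <- tiny_refs()
  strata <- rbind(
    tiny_stratum("A", state = "AA", area_ha = 1e6),                    # CT->NT
    tiny_stratum("B", state = "AB", area_ha = 5e5, tillage_1997 = "RT"),
    tiny_stratum("C", state = "AC", area_ha = 2e5, tillage_1997 = "NT"),
    tiny_stratum("D", state = "AA", area_ha = 3e5, input_level = "low"),
    tiny_stratum("E", state = "AB", area_ha = 1e5,
                 landuse_1997 = "set-aside", tillage_1997 = "none"))
  soc_inventory(strata, ft, rt)
}

tiny_payments <- function() payment_schedule(c(AA = 30, AB = 60, AC = 90))

test_that("curve points sort by unit cost with deterministic id tie-breaks", {
  pts <- data.frame(stratum_id = c("x", "y", "z"),
                    sequence = "CTCTNT",
                    unit_cost = c(10, 5, 20), annual_qty = c(1, 1, 1))
  cv <- cost_curve(pts)
  expect_equal(cv$points$unit_cost, c(5, 10, 20))
  expect_equal(cv$points$cumulative_qty, c(1, 2, 3))
  # equal costs: lexicographic stratum order, identical across runs
  tie <- data.frame(stratum_id = c("b", "a", "c"), sequence = "CTCTNT",
                    unit_cost = 7, annual_qty = c(1, 2, 3))
  expect_equal(cost_curve(tie)$points$stratum_id, c("a", "b", "c"))
  expect_identical(cost_curve(tie), cost_curve(tie[c(3, 1, 2), ]))
})

test_that("zero- and negative-rate strata are excluded with reasons, never priced", {
  inv <- make_inventory()
  mc <- build_curve(inv, tiny_payments())
  expect_setequal(mc$points$stratum_id, c("A", "B", "D"))
  expect_setequal(mc$excluded$stratum_id, c("C", "E"))
  expect_match(mc$excluded$reason[mc$excluded$stratum_id == "C"], "no-till")
  expect_match(mc$excluded$reason[mc$excluded$stratum_id == "E"], "ineligible")
  # conservation: curve + exclusions recover the scenario total
  res <- inv$results
  total <- sum(res$annual_tg_co2[res$flags != "ineligible"])
  expect_equal(sum(mc$points$annual_qty) + sum(mc$excluded$annual_qty[
    mc$excluded$stratum_id != "E"]), total, tolerance = 1e-12)
  expect_equal(quantity_below(mc, Inf), sum(mc$points$annual_qty))
})

test_that("a missing state payment aborts naming the offending strata", {
  inv <- make_inventory()
  expect_error(build_curve(inv, payment_schedule(c(AA = 30))),
               class = "soccost_config_error")
})

test_that("quantity_below equals a brute-force filter-and-sum oracle", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:100, 1)
    pts <- data.frame(stratum_id = sprintf("s%03d", 1:n),
                      sequence = sample(tillage_sequences(), n, TRUE),
                      unit_cost = round(runif(n, 1, 200), 1),
                      annual_qty = runif(n, 0.01, 5))
    cv <- cost_curve(pts)
    prices <- runif(20, 0, 220)
    oracle <- vapply(prices, function(p)
      sum(pts$annual_qty[pts$unit_cost < p]), numeric(1))
    expect_equal(quantity_below(cv, prices), oracle)
  }
  # step-function edges
  pts <- data.frame(stratum_id = c("a", "b"), sequence = "CTCTNT",
                    unit_cost = c(10, 20), annual_qty = c(1, 2))
  cv <- cost_curve(pts)
  expect_equal(quantity_below(cv, 5), 0)
  expect_equal(quantity_below(cv, 10), 0)   # strict "<"
  expect_equal(quantity_below(cv, 10.01), 1)
  expect_equal(quantity_below(cv, 1e6), 3)
})

test_that("quantity_below is a non-decreasing step function of price", {
  inv <- make_inventory()
  mc <- build_curve(inv, tiny_payments())
  prices <- seq(0, 300, by = 0.5)
  q <- quantity_below(mc, prices)
  expect_true(all(diff(q) >= 0))
  # steps occur exactly at the distinct unit costs
  eps <- 1e-9
  for (uc in unique(mc$points$unit_cost)) {
    expect_gt(quantity_below(mc, uc + eps), quantity_below(mc, uc - eps))
  }
})

test_that("doubling payments doubles unit costs and leaves quantities unchanged", {
  inv <- make_inventory()
  p1 <- tiny_payments()
  p2 <- payment_schedule(setNames(p1$payment_usd_per_ha_yr * 2, p1$state))
  mc1 <- build_curve(inv, p1)
  mc2 <- build_curve(inv, p2)
  expect_equal(mc2$points$unit_cost, mc1$points$unit_cost * 2)
  expect_equal(mc2$points$annual_qty, mc1$points$annual_qty)
  expect_equal(mc2$points$stratum_id, mc1$points$stratum_id)
})

test_that("reserve fraction scales unit costs by 1/(1-f) and quantities by (1-f)", {
  inv <- make_inventory()
  mc0 <- build_curve(inv, tiny_payments())
  mcf <- build_curve(inv, tiny_payments(), reserve = 0.2)
  expect_equal(mcf$points$unit_cost, mc0$points$unit_cost / 0.8)
  expect_equal(mcf$points$annual_qty, mc0$points$annual_qty * 0.8)
})

test_that("threshold summaries report per-sequence quantities and shares", {
  inv <- make_inventory()
  mc <- build_curve(inv, tiny_payments())
  ts <- threshold_summary(mc, thresholds = c(50, 1000))
  # above the dearest point the summary reproduces the sequence totals
  tab <- aggregate_by_sequence(inv)
  for (sq in unique(mc$points$sequence)) {
    expect_equal(ts$annual_tg_co2[ts$threshold == 1000 & ts$sequence == sq],
                 tab$annual_tg_co2[tab$sequence == sq])
  }
  tot <- ts[ts$sequence == "Total", ]
  expect_equal(tot$annual_tg_co2,
               quantity_below(mc, c(50, 1000)))
  # within-threshold shares sum to 100 where anything qualifies
  within50 <- ts[ts$threshold == 50 & ts$sequence != "Total", ]
  expect_equal(sum(within50$share_within_pct), 100)
  expect_error(threshold_summary(mc, total_potential = 0),
               class = "soccost_domain_error")
  expect_error(threshold_summary(mc, thresholds = -5),
               class = "soccost_domain_error")
})

test_that("a single-sequence curve takes the full within-threshold share", {
  pts <- data.frame(stratum_id = c("a", "b"), sequence = "CTRTNT",
                    unit_cost = c(12, 30), annual_qty = c(1, 4))
  ts <- threshold_summary(cost_curve(pts), thresholds = 40)
  expect_equal(ts$share_within_pct[ts$sequence == "CTRTNT"], 100)
})

test_that("sensitivity sweep is seeded, collapses at zero uncertainty, and brackets its median", {
  inv <- make_inventory()
  pay <- tiny_payments()
  sw0 <- sensitivity_sweep(inv, pay, factor_uncertainty = c(LU = 0, MG = 0, I = 0),
                           n_draws = 5, seed = 3)
  expect_true(all(abs(sweep(sw0$draws, 2, sw0$baseline)) < 1e-12))
  sw1 <- sensitivity_sweep(inv, pay, n_draws = 8, seed = 42)
  sw2 <- sensitivity_sweep(inv, pay, n_draws = 8, seed = 42)
  expect_identical(sw1$quantiles, sw2$quantiles)
  # order statistics: the median column lies within per-price min/max
  med <- sw1$quantiles[, "q50"]
  expect_true(all(med >= apply(sw1$draws, 2, min) - 1e-12))
  expect_true(all(med <= apply(sw1$draws, 2, max) + 1e-12))
  expect_error(sensitivity_sweep(inv, pay, factor_uncertainty = c(LU = -5)),
               class = "soccost_domain_error")
})
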