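# Seeded synthetic strata, factor tables and payment schedules.
#
# The generator emulates the statistical structure of the survey-based
# inputs: nine tillage-transition sequences with configurable area
# shares, long-tailed stratum areas rescaled to an exact national total,
# per-state payments drawn uniformly over the observed payment range,
# and factor/reference tables constructed so that every convertible
# stratum's implied rate falls inside the configured range while
# already-no-till sequences imply exactly zero. Rates are never written
# into strata directly - they always arise through the real Tier-1
# pipeline.

.default_shares <- function() {
  # Table-1-style area shares (%); the lower-to-higher-intensity
  # sequence RTCTNT is kept at a small 0.1 so all nine codes occur.
  c(CTCTNT = 57.9, CTRTNT = 23.2, CTNTNT = 2.2,
    RTCTNT = 0.1,  RTRTNT = 0.9,  RTNTNT = 4.8,
    NCCTNT = 6.9,  NCRTNT = 3.1,  NCNTNT = 0.9)
}

.default_rotation_map <- function() {
  c("continuous-row-crop" = "medium",
    "row-crop-small-grain" = "high",
    "continuous-small-grain" = "medium",
    "wheat-fallow" = "low",
    "hay-rotation" = "high")
}

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions: nine-sequence area shares in
#' the proportions of the national inventory, a 124.7 Mha cropland
#' total, convertible-stratum rates spanning 0.12-0.47 Mg C ha^-1
#' yr^-1, state payments spanning $18.29-$125.73 ha^-1 across 48
#' states, and a 20-year equilibrium horizon.
#'
#' @param n_strata number of strata to generate.
#' @param sequence_shares named vector of area shares (%) over
#'   [tillage_sequences()]; must be non-negative and sum to 100.
#' @param total_area_mha national cropland total (million hectares).
#' @param rate_range_c bounds (Mg C ha^-1 yr^-1) that every convertible
#'   stratum's implied rate must respect.
#' @param payment_range bounds ($ ha^-1 yr^-1) for state payments.
#' @param n_states number of synthetic states.
#' @param climate_catalog,soil_catalog climate zones and soil classes
#'   sampled uniformly per stratum.
#' @param rotation_input_map named map rotation -> input level; the
#'   rotation catalog is its names.
#' @param regions Farm Resource Region labels sampled uniformly.
#' @param area_sdlog log-sd of the long-tailed (lognormal) area draw,
#'   mimicking survey expansion-weight heterogeneity.
#' @param horizon years to equilibrium.
#' @param seed master integer seed; one seed drives all draws through a
#'   fixed stream order.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_strata = 5000,
                             sequence_shares = .default_shares(),
                             total_area_mha = 124.7,
                             rate_range_c = c(0.12, 0.47),
                             payment_range = c(18.29, 125.73),
                             n_states = 48,
                             climate_catalog = c("cold-temperate-dry",
                                                 "cold-temperate-moist",
                                                 "warm-temperate-dry",
                                                 "warm-temperate-moist"),
                             soil_catalog = c("high-activity-mineral",
                                              "low-activity-mineral",
                                              "sandy"),
                             rotation_input_map = .default_rotation_map(),
                             regions = farm_resource_regions(),
                             area_sdlog = 1,
                             horizon = 20,
                             seed = 1L) {
  if (!is.numeric(n_strata) || n_strata < 1) {
    .soccost_error("soccost_config_error", "n_strata must be >= 1")
  }
  sh <- sequence_shares
  if (is.null(names(sh)) || !setequal(names(sh), tillage_sequences())) {
    .soccost_error("soccost_config_error",
                   "sequence_shares must be named over the nine tillage sequences")
  }
  sh <- sh[tillage_sequences()]
  if (any(sh < 0) || abs(sum(sh) - 100) > 1e-9) {
    .soccost_error("soccost_config_error",
                   "sequence_shares must be >= 0 and sum to 100 (got %.6f)",
                   sum(sh))
  }
  if (length(rate_range_c) != 2 || diff(rate_range_c) < 0 ||
      rate_range_c[1] <= 0) {
    .soccost_error("soccost_config_error",
                   "rate_range_c must be ordered positive bounds")
  }
  if (length(payment_range) != 2 || diff(payment_range) < 0 ||
      payment_range[1] <= 0) {
    .soccost_error("soccost_config_error",
                   "payment_range must be ordered positive bounds")
  }
  if (n_states < 1) {
    .soccost_error("soccost_config_error", "n_states must be >= 1")
  }
  climate_catalog <- canon_climate(climate_catalog)
  soil_catalog <- canon_soil(soil_catalog)
  if (is.null(names(rotation_input_map))) {
    .soccost_error("soccost_config_error",
                   "rotation_input_map must be a named rotation -> input map")
  }
  rim <- setNames(canon_input(rotation_input_map),
                  .canon_token(names(rotation_input_map)))
  structure(list(n_strata = as.integer(n_strata), sequence_shares = sh,
                 total_area_mha = total_area_mha,
                 rate_range_c = rate_range_c, payment_range = payment_range,
                 n_states = as.integer(n_states),
                 climate_catalog = climate_catalog,
                 soil_catalog = soil_catalog,
                 rotation_input_map = rim, regions = regions,
                 area_sdlog = area_sdlog, horizon = horizon,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.state_codes <- function(n) {
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 26 + 1L], LETTERS[i %% 26 + 1L])
}

# Factor tables are drawn so that for every climate zone the no-till
# conversion deltas (NT-CT and NT-RT tillage multipliers) combined with
# the input-level spread admit a non-empty reference-stock band keeping
# all convertible rates inside rate_range_c.
.draw_factor_tables <- function(config) {
  zones <- config$climate_catalog
  fi_levels <- c(low = 0.92, medium = 1.00, high = 1.08,
                 "high-amendment" = 1.35)
  used_fi <- sort(unique(unname(config$rotation_input_map)))
  rows <- list()
  zone_par <- list()
  for (z in zones) {
    flu <- runif(1, 0.69, 0.80)
    dn <- runif(1, 0.10, 0.15)            # NT tillage delta over CT
    dr_hi <- min(0.08, 0.70 * dn - 0.005) # keep NT-RT delta large enough
    if (dr_hi <= 0.04) {
      .soccost_error("soccost_generation_error",
                     "infeasible tillage-delta configuration for zone %s", z)
    }
    dr <- runif(1, 0.04, dr_hi)
    rows[[z]] <- data.frame(
      factor_kind = c("LU", "LU", "LU", "MG", "MG", "MG", "MG",
                      "I", "I", "I", "I"),
      level = c("long-term-cultivated", "set-aside", "non-crop",
                "CT", "RT", "NT", "none",
                "low", "medium", "high", "high-amendment"),
      climate_zone = z,
      value = c(flu, 0.82, 1.00, 1.00, 1 + dr, 1 + dn, 1.00,
                fi_levels[["low"]], fi_levels[["medium"]],
                fi_levels[["high"]], fi_levels[["high-amendment"]]),
      uncertainty_pct = c(12, 12, 12, 10, 10, 10, 10, 15, 15, 15, 15),
      stringsAsFactors = FALSE)
    zone_par[[z]] <- list(flu = flu, dn = dn, dr = dr,
                          fi_min = min(fi_levels[used_fi]),
                          fi_max = max(fi_levels[used_fi]))
  }
  list(factors = factor_table(do.call(rbind, rows)), zone_par = zone_par)
}

.draw_ref_stocks <- function(config, zone_par) {
  D <- config$horizon
  rmin <- config$rate_range_c[1]
  rmax <- config$rate_range_c[2]
  rows <- list()
  for (z in config$climate_catalog) {
    p <- zone_par[[z]]
    lo <- rmin * D / (p$flu * p$fi_min * (p$dn - p$dr))
    hi <- rmax * D / (p$flu * p$fi_max * p$dn)
    if (lo > hi) {
      .soccost_error("soccost_generation_error",
                     "rate range not representable with positive factors in zone %s", z)
    }
    for (s in config$soil_catalog) {
      rows[[paste(z, s)]] <- data.frame(
        climate_zone = z, soil_class = s,
        soc_ref_mg_c_ha = runif(1, lo, hi), stringsAsFactors = FALSE)
    }
  }
  ref_stock_table(do.call(rbind, rows))
}

.sequence_states <- function(codes) {
  first <- substr(codes, 1, 2)
  mid <- substr(codes, 3, 4)
  data.frame(
    landuse_1982 = ifelse(first == "NC", "non-crop", "long-term-cultivated"),
    tillage_1982 = ifelse(first == "NC", "none", first),
    landuse_1997 = "long-term-cultivated",
    tillage_1997 = mid,
    stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic input bundle
#'
#' Draws a full, internally consistent input set - strata, factor
#' table, reference stocks and payment schedule - fully determined by
#' the config's master seed. The documented stream order is: sequence
#' assignment, raw areas, climate, soil, rotation, state, region,
#' factor tables, reference stocks, payments. Raw areas come from a
#' lognormal and are rescaled so the generated total matches
#' `total_area_mha` exactly.
#'
#' @param config a [generator_config()].
#' @param sequences optional explicit sequence assignment (character
#'   vector of length `n_strata`), overriding the share-driven draw
#'   (useful for exact nine-way coverage).
#' @return An object of class `soc_bundle`: list with `strata`,
#'   `factors`, `ref_stocks`, `payments` and a `provenance` record
#'   (config + seed) from which the bundle regenerates bit-identically.
#' @export
#' @examples
#' b <- generate_bundle(generator_config(n_strata = 20, seed = 42))
#' names(b)
generate_bundle <- function(config = generator_config(), sequences = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_strata
  if (!is.null(sequences)) {
    sequences <- canon_sequence(sequences)
    if (length(sequences) != n) {
      .soccost_error("soccost_config_error",
                     "explicit sequences must have length n_strata = %d", n)
    }
  }
  out <- .with_seed(config$seed, {
    seq_codes <- sequences %||%
      sample(tillage_sequences(), n, replace = TRUE,
             prob = config$sequence_shares / 100)
    raw_area <- rlnorm(n, meanlog = 0, sdlog = config$area_sdlog)
    area_ha <- raw_area / sum(raw_area) * config$total_area_mha * 1e6
    climate <- sample(config$climate_catalog, n, replace = TRUE)
    soil <- sample(config$soil_catalog, n, replace = TRUE)
    rotation <- sample(names(config$rotation_input_map), n, replace = TRUE)
    state <- .state_codes(config$n_states)[sample.int(config$n_states, n,
                                                      replace = TRUE)]
    region <- sample(config$regions, n, replace = TRUE)
    ftab <- .draw_factor_tables(config)
    refs <- .draw_ref_stocks(config, ftab$zone_par)
    payments <- payment_schedule(setNames(
      runif(config$n_states, config$payment_range[1],
            config$payment_range[2]),
      .state_codes(config$n_states)))
    strata <- cbind(
      data.frame(stratum_id = sprintf("STR%05d", seq_len(n)),
                 state = state, region = region, climate_zone = climate,
                 soil_class = soil, rotation = rotation,
                 input_level = unname(
                   config$rotation_input_map[.canon_token(rotation)]),
                 area_ha = area_ha, stringsAsFactors = FALSE),
      .sequence_states(seq_codes))
    list(strata = read_strata(strata), factors = ftab$factors,
         ref_stocks = refs, payments = payments)
  })
  out$provenance <- list(config = unclass(config), seed = config$seed)
  class(out) <- "soc_bundle"
  out
}

#' Analytic recovery targets for a generator configuration
#'
#' Returns the configured sequence area shares and totals as the
#' targets a downstream aggregation should recover, with 3-standard-
#' error sampling tolerances. The share of total area held by one
#' sequence has (for independent long-tailed areas) standard error
#' `sqrt(p (1-p) (1 + cv^2) / n)` where `cv` is the area coefficient
#' of variation, so tolerances scale as `1/sqrt(n_strata)`.
#'
#' @param config a [generator_config()].
#' @return A list with `shares` (data frame: `sequence`,
#'   `expected_share_pct`, `tol_pct`) and `total_area_mha`.
#' @export
expected_aggregates <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$sequence_shares / 100
  cv2 <- exp(config$area_sdlog^2) - 1
  se <- sqrt(p * (1 - p) * (1 + cv2) / config$n_strata)
  list(shares = data.frame(sequence = names(p),
                           expected_share_pct = 100 * unname(p),
                           tol_pct = 300 * unname(se),
                           stringsAsFactors = FALSE),
       total_area_mha = config$total_area_mha)
}

#' Write a synthetic bundle to CSV files
#'
#' Emits `strata.csv`, `factors.csv`, `ref_stocks.csv`, `payments.csv`
#' and a `provenance.json` recording the config and seed. Output is
#' deterministic: regenerating from the recorded provenance and
#' rewriting reproduces the files byte for byte.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "soc_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(bundle$strata), file.path(dir, "strata.csv"),
            row.names = FALSE, quote = FALSE)
  write_table_csv(bundle$factors, file.path(dir, "factors.csv"))
  write_table_csv(bundle$ref_stocks, file.path(dir, "ref_stocks.csv"))
  write.csv(as.data.frame(bundle$payments), file.path(dir, "payments.csv"),
            row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(bundle$provenance, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
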