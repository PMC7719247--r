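# Tier-1 SOC stock model.
#
# Equilibrium stock for a management state is the product form
#   SOC = SOCref(climate, soil) * F_LU * F_MG * F_I
# and a management change moves the stock linearly to the new equilibrium
# over D years (default 20), giving an annual rate
#   (SOC_to - SOC_from) / D   [Mg C ha^-1 yr^-1].
#
# Inventory chaining: each inventory's end state is assumed fully
# equilibrated by the next inventory date, so the rate of the final
# (no-till conversion) period depends only on the 1997 state and the same
# state with tillage replaced by NT. The 1982 state enters only through
# sequence labelling and stratum composition.

#' Carbon to carbon dioxide mass conversion
#'
#' Multiplies a mass or rate on the C basis by the exact molar-mass ratio
#' 44/12 (stored as the rational, never as a rounded 3.67); `co2_to_c()`
#' is the inverse. Both are linear and sign-preserving.
#'
#' @param x numeric vector (any C- or CO2-based mass, rate or price).
#' @return `x` on the other mass basis.
#' @export
#' @examples
#' c_to_co2(38.2)   # Tg C/yr -> Tg CO2/yr
#' co2_to_c(c_to_co2(1.23)) == 1.23
c_to_co2 <- function(x) x * (44 / 12)

#' @rdname c_to_co2
#' @export
co2_to_c <- function(x) x * (12 / 44)

#' Construct a management state
#'
#' A management state is the (land use, tillage, input level) triple that
#' indexes the Tier-1 factors. Non-crop land uses (set-aside, hay or
#' pasture) carry tillage `"none"`; cultivated land must carry one of
#' `CT`, `RT`, `NT`.
#'
#' @param land_use one of [land_uses()] (aliases accepted).
#' @param tillage one of [tillage_levels()].
#' @param input_level one of [input_levels()].
#' @return An object of class `management_state`.
#' @export
#' @examples
#' management_state("long-term-cultivated", "CT", "medium")
management_state <- function(land_use, tillage = "none",
                             input_level = "medium") {
  lu <- canon_land_use(land_use)
  til <- canon_tillage(tillage)
  inp <- canon_input(input_level)
  if (lu != "long-term-cultivated" && til != "none") {
    .soccost_error("soccost_domain_error",
                   "non-crop land use %s must carry tillage 'none', got %s",
                   sQuote(lu), sQuote(til))
  }
  if (lu == "long-term-cultivated" && til == "none") {
    .soccost_error("soccost_domain_error",
                   "cultivated land must carry tillage CT, RT or NT")
  }
  structure(list(land_use = lu, tillage = til, input_level = inp),
            class = "management_state")
}

#' @export
print.management_state <- function(x, ...) {
  cat(sprintf("<management state: %s / %s / %s>\n",
              x$land_use, x$tillage, x$input_level))
  invisible(x)
}

# vectorised core used by both the scalar API and the inventory fit
.equilibrium_stock_vec <- function(land_use, tillage, input_level,
                                   climate, soil, factors, ref_stocks) {
  socref <- lookup_ref_stock(ref_stocks, climate, soil)
  flu <- lookup_factor(factors, "LU", land_use, climate)
  fmg <- lookup_factor(factors, "MG", tillage, climate)
  fi <- lookup_factor(factors, "I", input_level, climate)
  socref * flu * fmg * fi
}

#' Equilibrium SOC stock for a management state
#'
#' The Tier-1 product `SOCref x F_LU x F_MG x F_I` for the 0-30 cm
#' layer, in Mg C per hectare.
#'
#' @param state a [management_state()].
#' @param climate climate zone code.
#' @param soil soil class code.
#' @param factors a [factor_table()].
#' @param ref_stocks a [ref_stock_table()].
#' @return Equilibrium stock in Mg C ha^-1 (finite, positive).
#' @export
equilibrium_stock <- function(state, climate, soil, factors, ref_stocks) {
  stopifnot(inherits(state, "management_state"))
  .equilibrium_stock_vec(state$land_use, state$tillage, state$input_level,
                         climate, soil, factors, ref_stocks)
}

#' Annual SOC stock-change rate between two management states
#'
#' `(equilibrium_stock(to) - equilibrium_stock(from)) / horizon`, the
#' constant annual rate over the D-year approach to the new equilibrium.
#' Identical states give exactly zero; the sign may be negative (tillage
#' intensification loses carbon).
#'
#' @param state_from,state_to [management_state()] objects.
#' @inheritParams equilibrium_stock
#' @param horizon years to equilibrium (D, default 20; must be > 0).
#' @return Rate in Mg C ha^-1 yr^-1.
#' @export
annual_rate <- function(state_from, state_to, climate, soil,
                        factors, ref_stocks, horizon = 20) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    .soccost_error("soccost_domain_error",
                   "horizon D must be a single positive number of years")
  }
  from <- equilibrium_stock(state_from, climate, soil, factors, ref_stocks)
  to <- equilibrium_stock(state_to, climate, soil, factors, ref_stocks)
  (to - from) / horizon
}

#' Classify dated management into a tillage-transition sequence
#'
#' Maps the (1982 land use, 1982 tillage, 1997 tillage) triple onto one
#' of the nine sequence codes of [tillage_sequences()]; the final element
#' is always `NT` because the scenario converts all convertible cropland
#' to no-till at the 1997 inventory. Non-crop 1982 land uses map to the
#' `NC` prefix. State triples outside the nine codes (e.g. no-till
#' already in 1982) raise a classification error.
#'
#' @param landuse_1982,tillage_1982,tillage_1997 character vectors
#'   (recycled to a common length).
#' @return Character vector of sequence codes.
#' @export
classify_sequence <- function(landuse_1982, tillage_1982, tillage_1997) {
  n <- max(length(landuse_1982), length(tillage_1982), length(tillage_1997))
  lu82 <- canon_land_use(rep_len(landuse_1982, n))
  t82 <- canon_tillage(rep_len(tillage_1982, n))
  t97 <- canon_tillage(rep_len(tillage_1997, n))
  first <- ifelse(lu82 == "long-term-cultivated", t82, "NC")
  code <- paste0(first, t97, "NT")
  bad <- !(code %in% tillage_sequences())
  if (any(bad)) {
    .soccost_error("soccost_classification_error",
                   "state triple(s) outside the nine tillage sequences: %s",
                   paste(sQuote(unique(code[bad])), collapse = ", "))
  }
  code
}

#' Read and validate a strata table
#'
#' A stratum is one homogeneous land unit: climate zone x soil class x
#' crop rotation x state x tillage history x area. Required columns:
#' `stratum_id`, `state`, `climate_zone`, `soil_class`, `rotation`,
#' `input_level`, `area_ha`, `landuse_1982`, `tillage_1982`,
#' `landuse_1997`, `tillage_1997`. Optional: `region` (Farm Resource
#' Region label) and `tillage_2017` (must be `NT` where present, by the
#' scenario definition).
#'
#' An `eligible` flag is derived, never trusted from the file: a stratum
#' is eligible exactly when its 1997 land use is cultivated cropland
#' (set-aside/CRP and non-crop land cannot be converted to no-till).
#'
#' @param x a CSV path or a data frame.
#' @return A validated data frame of class `soc_strata`.
#' @export
read_strata <- function(x) {
  if (inherits(x, "soc_strata")) {
    if (nrow(x) == 0) {
      .soccost_error("soccost_empty_error", "strata table is empty")
    }
    return(x)
  }
  df <- if (is.character(x)) {
    if (!file.exists(x)) {
      .soccost_error("soccost_schema_error", "strata file not found: %s", x)
    }
    read.csv(x, stringsAsFactors = FALSE, strip.white = TRUE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    .soccost_error("soccost_empty_error", "strata table is empty")
  }
  .require_columns(df, c("stratum_id", "state", "climate_zone", "soil_class",
                         "rotation", "input_level", "area_ha",
                         "landuse_1982", "tillage_1982",
                         "landuse_1997", "tillage_1997"),
                   "strata table")
  df$stratum_id <- as.character(df$stratum_id)
  if (anyDuplicated(df$stratum_id)) {
    .soccost_error("soccost_integrity_error",
                   "duplicate stratum_id(s): %s",
                   paste(sQuote(unique(df$stratum_id[duplicated(df$stratum_id)])),
                         collapse = ", "))
  }
  df$state <- toupper(trimws(df$state))
  df$climate_zone <- canon_climate(df$climate_zone)
  df$soil_class <- canon_soil(df$soil_class)
  df$input_level <- canon_input(df$input_level)
  df$area_ha <- as.numeric(df$area_ha)
  if (any(!is.finite(df$area_ha) | df$area_ha <= 0)) {
    .soccost_error("soccost_domain_error",
                   "area_ha must be finite and > 0 (stratum %s)",
                   paste(sQuote(df$stratum_id[!is.finite(df$area_ha) |
                                                df$area_ha <= 0]),
                         collapse = ", "))
  }
  df$landuse_1982 <- canon_land_use(df$landuse_1982)
  df$tillage_1982 <- canon_tillage(df$tillage_1982)
  df$landuse_1997 <- canon_land_use(df$landuse_1997)
  df$tillage_1997 <- canon_tillage(df$tillage_1997)
  if (!"region" %in% names(df)) df$region <- NA_character_
  df$region <- ifelse(is.na(df$region) | df$region == "", NA_character_,
                      toupper(trimws(df$region)))
  df$eligible <- df$landuse_1997 == "long-term-cultivated"
  bad97 <- df$eligible & !(df$tillage_1997 %in% c("CT", "RT", "NT"))
  if (any(bad97)) {
    .soccost_error("soccost_domain_error",
                   "cultivated 1997 strata must carry tillage CT/RT/NT: %s",
                   paste(sQuote(df$stratum_id[bad97]), collapse = ", "))
  }
  if ("tillage_2017" %in% names(df)) {
    t17 <- canon_tillage(df$tillage_2017)
    if (any(df$eligible & t17 != "NT")) {
      .soccost_error("soccost_domain_error",
                     "tillage_2017 must be NT under the conversion scenario: %s",
                     paste(sQuote(df$stratum_id[df$eligible & t17 != "NT"]),
                           collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("soc_strata", "data.frame")
  df
}

#' Fit the no-till conversion inventory
#'
#' Runs the Tier-1 model over a strata table under the conversion
#' scenario: every eligible (cultivated-in-1997) stratum switches its
#' tillage to no-till at the 1997 inventory while land use, rotation and
#' inputs stay fixed. Per stratum it classifies the tillage-transition
#' sequence, computes the annual sequestration rate
#' `annual_rate(1997 state, 1997 state with NT)`, and fills CO2
#' companions (exact 44/12), annual totals (Tg yr^-1 = Mg ha^-1 yr^-1
#' x Mha) and `horizon`-year totals. Strata already under no-till in
#' 1997 contribute exactly zero; ineligible strata are flagged and
#' carried with zero rates.
#'
#' @param strata a strata table (path, data frame, or [read_strata()]
#'   output).
#' @param factors a [factor_table()].
#' @param ref_stocks a [ref_stock_table()].
#' @param horizon years to equilibrium (default 20).
#' @return An object of class `soc_inventory`: a list with `results`
#'   (one row per stratum), the validated `strata`, the input tables and
#'   the horizon. Methods: [print()], [summary()] (= sequence table),
#'   [aggregate_by_region()].
#' @seealso [build_curve()] to price the inventory into a cost curve.
#' @export
#' @examples
#' b <- generate_bundle(generator_config(n_strata = 50, seed = 7))
#' inv <- soc_inventory(b$strata, b$factors, b$ref_stocks)
#' summary(inv)
soc_inventory <- function(strata, factors, ref_stocks, horizon = 20) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    .soccost_error("soccost_domain_error",
                   "horizon D must be a single positive number of years")
  }
  s <- read_strata(strata)
  stopifnot(inherits(factors, "factor_table"),
            inherits(ref_stocks, "ref_stock_table"))
  n <- nrow(s)
  sequence <- rep(NA_character_, n)
  rate_c <- numeric(n)
  el <- s$eligible
  if (any(el)) {
    sequence[el] <- classify_sequence(s$landuse_1982[el], s$tillage_1982[el],
                                      s$tillage_1997[el])
  }
  conv <- el & s$tillage_1997 %in% c("CT", "RT")
  if (any(conv)) {
    from <- .equilibrium_stock_vec("long-term-cultivated", s$tillage_1997[conv],
                                   s$input_level[conv], s$climate_zone[conv],
                                   s$soil_class[conv], factors, ref_stocks)
    to <- .equilibrium_stock_vec("long-term-cultivated", "NT",
                                 s$input_level[conv], s$climate_zone[conv],
                                 s$soil_class[conv], factors, ref_stocks)
    rate_c[conv] <- (to - from) / horizon
  }
  flags <- ifelse(!el, "ineligible",
                  ifelse(s$tillage_1997 == "NT", "already-nt",
                         ifelse(rate_c < 0, "negative-rate", "ok")))
  res <- data.frame(
    stratum_id = s$stratum_id,
    state = s$state,
    region = s$region,
    sequence = sequence,
    area_ha = s$area_ha,
    rate_c_mg_ha_yr = rate_c,
    rate_co2_mg_ha_yr = c_to_co2(rate_c),
    annual_tg_c = rate_c * s$area_ha / 1e6,
    annual_tg_co2 = c_to_co2(rate_c) * s$area_ha / 1e6,
    total_20yr_tg_c = rate_c * s$area_ha / 1e6 * horizon,
    total_20yr_tg_co2 = c_to_co2(rate_c) * s$area_ha / 1e6 * horizon,
    flags = flags,
    stringsAsFactors = FALSE)
  structure(list(results = res, strata = s, factors = factors,
                 ref_stocks = ref_stocks, horizon = horizon,
                 call = match.call()),
            class = "soc_inventory")
}

#' Sequestration result for a single stratum
#'
#' Convenience scalar form of [soc_inventory()]: classifies one stratum
#' and returns its one-row result (sequence code, C and CO2 rates,
#' annual and `horizon`-year totals, flag).
#'
#' @param stratum a one-row data frame (or list) with the strata-table
#'   columns.
#' @inheritParams soc_inventory
#' @return A one-row data frame.
#' @export
sequence_rate <- function(stratum, factors, ref_stocks, horizon = 20) {
  df <- as.data.frame(stratum, stringsAsFactors = FALSE)
  if (nrow(df) != 1) {
    .soccost_error("soccost_domain_error",
                   "sequence_rate() expects exactly one stratum")
  }
  soc_inventory(df, factors, ref_stocks, horizon)$results
}

.wmean <- function(x, w) if (sum(w) > 0) sum(x * w) / sum(w) else 0

#' Sequence-level summary of an inventory
#'
#' Aggregates per-stratum results by tillage-transition sequence:
#' total area (Mha), area share (%), annual totals (Tg C yr^-1 and
#' Tg CO2 yr^-1), `horizon`-year totals, share of total carbon (%), and
#' the area-weighted mean sequestration rate, plus a grand-total row.
#' Ineligible strata are excluded (they are not part of the convertible
#' cropland base); already-no-till strata appear with zero totals.
#'
#' @param x a `soc_inventory` or its `results` data frame.
#' @return A data frame of class `soc_sequence_summary`.
#' @export
aggregate_by_sequence <- function(x) {
  res <- if (inherits(x, "soc_inventory")) x$results else as.data.frame(x)
  res <- res[res$flags != "ineligible" & !is.na(res$sequence), ]
  if (nrow(res) == 0) {
    .soccost_error("soccost_empty_error",
                   "no eligible strata to aggregate")
  }
  seqs <- intersect(tillage_sequences(), unique(res$sequence))
  rows <- lapply(seqs, function(sq) {
    r <- res[res$sequence == sq, ]
    data.frame(
      sequence = sq,
      area_mha = sum(r$area_ha) / 1e6,
      annual_tg_c = sum(r$annual_tg_c),
      annual_tg_co2 = sum(r$annual_tg_co2),
      total_20yr_tg_c = sum(r$total_20yr_tg_c),
      total_20yr_tg_co2 = sum(r$total_20yr_tg_co2),
      rate_c_wmean = .wmean(r$rate_c_mg_ha_yr, r$area_ha),
      rate_co2_wmean = .wmean(r$rate_co2_mg_ha_yr, r$area_ha),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot_area <- sum(out$area_mha)
  tot_c <- sum(out$annual_tg_c)
  out$area_share_pct <- 100 * out$area_mha / tot_area
  out$c_share_pct <- if (tot_c > 0) 100 * out$annual_tg_c / tot_c else 0
  total <- data.frame(
    sequence = "Total", area_mha = tot_area,
    annual_tg_c = tot_c, annual_tg_co2 = sum(out$annual_tg_co2),
    total_20yr_tg_c = sum(out$total_20yr_tg_c),
    total_20yr_tg_co2 = sum(out$total_20yr_tg_co2),
    rate_c_wmean = .wmean(res$rate_c_mg_ha_yr, res$area_ha),
    rate_co2_wmean = .wmean(res$rate_co2_mg_ha_yr, res$area_ha),
    area_share_pct = 100, c_share_pct = if (tot_c > 0) 100 else 0,
    stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out <- out[, c("sequence", "area_mha", "area_share_pct", "annual_tg_c",
                 "annual_tg_co2", "total_20yr_tg_c", "total_20yr_tg_co2",
                 "c_share_pct", "rate_c_wmean", "rate_co2_wmean")]
  rownames(out) <- NULL
  class(out) <- c("soc_sequence_summary", "data.frame")
  out
}

#' Region x sequence weighted-average rate table
#'
#' Area-weighted mean annual sequestration rates (Mg C ha^-1 yr^-1, to
#' 30 cm depth) per Farm Resource Region and tillage sequence, with a
#' national `Average` column and an `Overall` row (per-region average
#' weighted across sequences). Combinations with no strata are `NA`
#' (rendered as `N/A`).
#'
#' @param x a `soc_inventory` whose strata carry region labels.
#' @return A data frame of class `soc_region_summary` (first column
#'   `sequence`, one column per region, then `Average`).
#' @export
aggregate_by_region <- function(x) {
  res <- if (inherits(x, "soc_inventory")) x$results else as.data.frame(x)
  res <- res[res$flags != "ineligible" & !is.na(res$sequence), ]
  if (nrow(res) == 0 || all(is.na(res$region))) {
    .soccost_error("soccost_empty_error",
                   "no eligible strata with region labels")
  }
  res <- res[!is.na(res$region), ]
  regions <- sort(unique(res$region))
  seqs <- intersect(tillage_sequences(), unique(res$sequence))
  cell <- function(r) {
    if (nrow(r) == 0) NA_real_ else .wmean(r$rate_c_mg_ha_yr, r$area_ha)
  }
  m <- sapply(regions, function(rg) {
    vapply(seqs, function(sq)
      cell(res[res$region == rg & res$sequence == sq, ]), 0)
  })
  m <- matrix(m, nrow = length(seqs), dimnames = list(seqs, regions))
  avg <- vapply(seqs, function(sq) cell(res[res$sequence == sq, ]), 0)
  overall <- vapply(regions, function(rg) cell(res[res$region == rg, ]), 0)
  out <- data.frame(sequence = seqs, m, Average = avg,
                    check.names = FALSE, stringsAsFactors = FALSE)
  overall_row <- data.frame(sequence = "Overall", t(overall),
                            Average = cell(res),
                            check.names = FALSE, stringsAsFactors = FALSE)
  names(overall_row) <- names(out)
  out <- rbind(out, overall_row)
  rownames(out) <- NULL
  class(out) <- c("soc_region_summary", "data.frame")
  out
}
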