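# Small in-code fixtures shared across the suite. All use the
# cold-temperate-moist zone with round factor values so expected stocks
# and rates are hand-checkable (e.g. 50 * 0.80 * 1.15 = 46).

tiny_factors <- function() {
  factor_table(data.frame(
    factor_kind = c("LU", "LU", "LU",
                    "MG", "MG", "MG", "MG",
                    "I", "I", "I"),
    level = c("long-term-cultivated", "set-aside", "non-crop",
              "CT", "RT", "NT", "none",
              "low", "medium", "high"),
    climate_zone = "cold-temperate-moist",
    value = c(0.80, 0.82, 1.00,
              1.00, 1.08, 1.15, 1.00,
              0.92, 1.00, 1.11),
    stringsAsFactors = FALSE))
}

tiny_refs <- function() {
  ref_stock_table(data.frame(
    climate_zone = "cold-temperate-moist",
    soil_class = c("high-activity-mineral", "sandy"),
    soc_ref_mg_c_ha = c(50, 34),
    stringsAsFactors = FALSE))
}

# one-stratum row builder; defaults give the CT -> NT conversion with
# stocks 40 -> 46 over 20 years, i.e. a rate of 0.30 Mg C/ha/yr
tiny_stratum <- function(stratum_id = "S1", state = "AA", region = "HR",
                         area_ha = 1e6,
                         landuse_1982 = "long-term-cultivated",
                         tillage_1982 = "CT",
                         landuse_1997 = "long-term-cultivated",
                         tillage_1997 = "CT",
                         soil_class = "high-activity-mineral",
                         input_level = "medium") {
  data.frame(stratum_id = stratum_id, state = state, region = region,
             climate_zone = "cold-temperate-moist", soil_class = soil_class,
             rotation = "continuous-row-crop", input_level = input_level,
             area_ha = area_ha, landuse_1982 = landuse_1982,
             tillage_1982 = tillage_1982, landuse_1997 = landuse_1997,
             tillage_1997 = tillage_1997, stringsAsFactors = FALSE)
}

tiny_strata <- function(n = 3, ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    tiny_stratum(stratum_id = sprintf("S%d", i))))
}

cultivated <- function(tillage, input = "medium") {
  management_state("long-term-cultivated", tillage, input)
}
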