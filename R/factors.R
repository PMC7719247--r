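# Tier-1 stock-change factor tables and reference SOC stocks.
#
# Factors are configuration, not code: the package ships editable default
# CSVs under inst/extdata (see soccost_example()) keyed by factor kind
# (LU = land use, MG = management/tillage, I = biomass input), level and
# climate zone. Reference stocks are keyed by climate zone and soil class
# and refer to the 0-30 cm layer in Mg C per hectare.

.FACTOR_KINDS <- c("LU", "MG", "I")

.canon_level <- function(kind, level, strict = TRUE) {
  out <- character(length(level))
  for (k in .FACTOR_KINDS) {
    idx <- kind == k
    if (!any(idx)) next
    f <- switch(k,
                LU = if (strict) canon_land_use else .canon_landuse_lenient,
                MG = if (strict) canon_tillage else .canon_tillage_lenient,
                I  = if (strict) canon_input   else .canon_input_lenient)
    out[idx] <- f(level[idx])
  }
  out
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .soccost_error("soccost_schema_error",
                   "%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", "))
  }
}

#' Build or load a Tier-1 stock-change factor table
#'
#' A factor table maps (factor kind, level, climate zone) to a positive
#' dimensionless multiplier. Kind `LU` holds land-use factors, `MG`
#' tillage (management) factors, `I` biomass-input factors. An optional
#' `uncertainty_pct` column carries the per-row relative uncertainty used
#' by [sensitivity_sweep()].
#'
#' Duplicate keys and non-positive values are rejected. Within each
#' climate zone the temperate convention that the no-till multiplier is
#' at least the conventional-till multiplier is checked with a warning
#' (not an error, so deliberately unusual tables remain loadable).
#'
#' @param entries data frame with columns `factor_kind`, `level`,
#'   `climate_zone`, `value` and optionally `uncertainty_pct`.
#' @param path path to a CSV file with those columns (UTF-8, header row,
#'   "." decimal separator).
#' @return An object of class `factor_table` (a validated, key-sorted
#'   data frame).
#' @seealso [lookup_factor()], [ref_stock_table()], [soccost_example()]
#' @export
#' @examples
#' ft <- factor_table(data.frame(
#'   factor_kind = c("LU", "MG", "MG", "I"),
#'   level = c("long-term-cultivated", "CT", "NT", "medium"),
#'   climate_zone = "cold-temperate-moist",
#'   value = c(0.69, 1.00, 1.15, 1.00)))
#' lookup_factor(ft, "MG", "NT", "cold-temperate-moist")
factor_table <- function(entries) {
  df <- as.data.frame(entries, stringsAsFactors = FALSE)
  .require_columns(df, c("factor_kind", "level", "climate_zone", "value"),
                   "factor table")
  df$factor_kind <- toupper(trimws(as.character(df$factor_kind)))
  bad_kind <- !(df$factor_kind %in% .FACTOR_KINDS)
  if (any(bad_kind)) {
    .soccost_error("soccost_domain_error",
                   "unknown factor_kind value(s): %s (expected LU, MG or I)",
                   paste(sQuote(unique(df$factor_kind[bad_kind])), collapse = ", "))
  }
  df$level <- .canon_level(df$factor_kind, as.character(df$level))
  df$climate_zone <- canon_climate(df$climate_zone)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value) | df$value <= 0)) {
    .soccost_error("soccost_domain_error",
                   "factor multipliers must be finite and > 0; offending key(s): %s",
                   paste(unique(with(df[!is.finite(df$value) | df$value <= 0, ],
                                     paste(factor_kind, level, climate_zone, sep = "/"))),
                         collapse = ", "))
  }
  if (!"uncertainty_pct" %in% names(df)) df$uncertainty_pct <- NA_real_
  df$uncertainty_pct <- as.numeric(df$uncertainty_pct)
  if (any(!is.na(df$uncertainty_pct) & df$uncertainty_pct < 0)) {
    .soccost_error("soccost_domain_error", "uncertainty_pct must be >= 0")
  }
  key <- paste(df$factor_kind, df$level, df$climate_zone, sep = "|")
  if (anyDuplicated(key)) {
    .soccost_error("soccost_integrity_error",
                   "duplicate factor key(s): %s",
                   paste(sQuote(gsub("\\|", "/", unique(key[duplicated(key)]))),
                         collapse = ", "))
  }
  df <- df[order(df$factor_kind, df$level, df$climate_zone),
           c("factor_kind", "level", "climate_zone", "value", "uncertainty_pct")]
  rownames(df) <- NULL
  # temperate convention: reducing disturbance should not lower the multiplier
  for (cz in unique(df$climate_zone)) {
    mg <- df[df$factor_kind == "MG" & df$climate_zone == cz, ]
    ct <- mg$value[mg$level == "CT"]
    nt <- mg$value[mg$level == "NT"]
    if (length(ct) == 1 && length(nt) == 1 && nt < ct) {
      warning(sprintf(
        "tillage factor ordering: NT (%.3f) < CT (%.3f) in climate %s",
        nt, ct, cz), call. = FALSE)
    }
  }
  class(df) <- c("factor_table", "data.frame")
  df
}

#' @rdname factor_table
#' @export
load_factor_table <- function(path) {
  if (!file.exists(path)) {
    .soccost_error("soccost_schema_error", "factor table file not found: %s", path)
  }
  factor_table(read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE))
}

#' Look up a stock-change multiplier
#'
#' Resolves (kind, level, climate) to its unique multiplier. Arguments
#' are recycled to a common length; any unresolved key raises a lookup
#' error naming all three key parts. There are no silent defaults.
#'
#' @param table a [factor_table()].
#' @param kind `"LU"`, `"MG"` or `"I"`.
#' @param level factor level (land use, tillage or input level).
#' @param climate climate zone code.
#' @return Numeric vector of multipliers.
#' @export
lookup_factor <- function(table, kind, level, climate) {
  stopifnot(inherits(table, "factor_table"))
  n <- max(length(kind), length(level), length(climate))
  kind <- toupper(rep_len(as.character(kind), n))
  level <- .canon_level(kind, rep_len(as.character(level), n), strict = FALSE)
  climate <- .canon_climate_lenient(rep_len(climate, n))
  key <- paste(kind, level, climate, sep = "|")
  idx <- match(key, paste(table$factor_kind, table$level, table$climate_zone,
                          sep = "|"))
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    parts <- strsplit(miss, "|", fixed = TRUE)
    .soccost_error("soccost_lookup_error",
                   "unresolved factor key(s): %s",
                   paste(vapply(parts, function(p)
                     sprintf("kind=%s, level=%s, climate=%s", p[1], p[2], p[3]),
                     ""), collapse = "; "))
  }
  table$value[idx]
}

#' Build or load a reference SOC stock table
#'
#' Reference stocks (`soc_ref_mg_c_ha`, Mg C per hectare to 30 cm depth
#' under native vegetation) are keyed by climate zone and soil class.
#' Values must be positive; duplicate keys are rejected.
#'
#' @param entries data frame with columns `climate_zone`, `soil_class`,
#'   `soc_ref_mg_c_ha`.
#' @param path path to a CSV file with those columns.
#' @return An object of class `ref_stock_table`.
#' @export
ref_stock_table <- function(entries) {
  df <- as.data.frame(entries, stringsAsFactors = FALSE)
  .require_columns(df, c("climate_zone", "soil_class", "soc_ref_mg_c_ha"),
                   "reference stock table")
  df$climate_zone <- canon_climate(df$climate_zone)
  df$soil_class <- canon_soil(df$soil_class)
  df$soc_ref_mg_c_ha <- as.numeric(df$soc_ref_mg_c_ha)
  if (any(!is.finite(df$soc_ref_mg_c_ha) | df$soc_ref_mg_c_ha <= 0)) {
    .soccost_error("soccost_domain_error",
                   "reference stocks must be finite and > 0")
  }
  key <- paste(df$climate_zone, df$soil_class, sep = "|")
  if (anyDuplicated(key)) {
    .soccost_error("soccost_integrity_error",
                   "duplicate reference stock key(s): %s",
                   paste(sQuote(gsub("\\|", "/", unique(key[duplicated(key)]))),
                         collapse = ", "))
  }
  df <- df[order(df$climate_zone, df$soil_class),
           c("climate_zone", "soil_class", "soc_ref_mg_c_ha")]
  rownames(df) <- NULL
  class(df) <- c("ref_stock_table", "data.frame")
  df
}

#' @rdname ref_stock_table
#' @export
load_ref_stocks <- function(path) {
  if (!file.exists(path)) {
    .soccost_error("soccost_schema_error",
                   "reference stock file not found: %s", path)
  }
  ref_stock_table(read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE))
}

#' @rdname ref_stock_table
#' @param climate,soil key vectors (recycled to a common length).
#' @param table a `ref_stock_table`.
#' @export
lookup_ref_stock <- function(table, climate, soil) {
  stopifnot(inherits(table, "ref_stock_table"))
  n <- max(length(climate), length(soil))
  climate <- .canon_climate_lenient(rep_len(climate, n))
  soil <- .canon_soil_lenient(rep_len(soil, n))
  idx <- match(paste(climate, soil, sep = "|"),
               paste(table$climate_zone, table$soil_class, sep = "|"))
  if (anyNA(idx)) {
    miss <- unique(paste(climate, soil, sep = "/")[is.na(idx)])
    .soccost_error("soccost_lookup_error",
                   "unresolved reference stock key(s): %s",
                   paste(miss, collapse = "; "))
  }
  table$soc_ref_mg_c_ha[idx]
}

#' Serialise validated tables back to CSV
#'
#' Writes the key-sorted table so that a load/write/load round trip
#' reproduces the table exactly.
#'
#' @param x a `factor_table` or `ref_stock_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a bundled default data file
#'
#' The package ships editable default inputs under `inst/extdata`:
#' `factors.csv` (Tier-1 multipliers), `ref_stocks.csv` (reference SOC
#' stocks), and a small worked-example strata/payment pair
#' (`example_strata.csv`, `example_payments.csv`).
#'
#' @param file file name; with no argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' soccost_example()
#' head(read.csv(soccost_example("factors.csv")))
soccost_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "soccost")))
  }
  path <- system.file("extdata", file, package = "soccost")
  if (!nzchar(path)) {
    .soccost_error("soccost_schema_error", "no bundled file named %s", file)
  }
  path
}
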