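# Controlled vocabularies for the Tier-1 classification dimensions.
# All user-facing strings are canonicalised (lower-case, hyphen-separated)
# through a documented alias map before validation, so prose spellings such
# as "cold temperate, moist" or the short code "ctm" resolve to
# "cold-temperate-moist". Unknown codes are rejected at load time; lookups
# never fall back to silent defaults.

#' Controlled vocabularies
#'
#' The closed enumerations used by the Tier-1 classification: climate
#' zones, soil classes, tillage levels, land uses, biomass input levels,
#' and the nine tillage-transition sequences across the 1982, 1997 and
#' 2017 inventories (e.g. `CTCTNT` = conventional tillage in 1982 and
#' 1997, no-till in 2017; a leading `NC` marks land not under crops in
#' 1982, such as hay or pasture).
#'
#' @return A character vector of canonical codes.
#' @name vocab
NULL

#' @rdname vocab
#' @export
climate_zones <- function() {
  c("boreal-dry", "boreal-moist",
    "cold-temperate-dry", "cold-temperate-moist",
    "warm-temperate-dry", "warm-temperate-moist",
    "tropical-dry", "tropical-moist", "tropical-wet", "tropical-montane")
}

#' @rdname vocab
#' @export
soil_classes <- function() {
  c("high-activity-mineral", "low-activity-mineral", "sandy",
    "volcanic", "spodic", "wetland")
}

#' @rdname vocab
#' @export
tillage_levels <- function() c("CT", "RT", "NT", "none")

#' @rdname vocab
#' @export
land_uses <- function() c("long-term-cultivated", "set-aside", "non-crop")

#' @rdname vocab
#' @export
input_levels <- function() c("low", "medium", "high", "high-amendment")

#' @rdname vocab
#' @export
tillage_sequences <- function() {
  c("CTCTNT", "CTRTNT", "CTNTNT",
    "RTCTNT", "RTRTNT", "RTNTNT",
    "NCCTNT", "NCRTNT", "NCNTNT")
}

#' @rdname vocab
#' @export
farm_resource_regions <- function() {
  # USDA-ERS Farm Resource Region short codes
  c("BRR", "EUR", "FRR", "HR", "MPR", "NCR", "NGPR", "PGR", "SSR")
}

.canon_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ ,_/]+", "-", x)
  gsub("-+", "-", x)
}

.climate_aliases <- c(
  "ctd" = "cold-temperate-dry",  "ctm" = "cold-temperate-moist",
  "wtd" = "warm-temperate-dry",  "wtm" = "warm-temperate-moist",
  "cool-temperate-dry"   = "cold-temperate-dry",
  "cool-temperate-moist" = "cold-temperate-moist",
  "trd" = "tropical-dry", "trm" = "tropical-moist",
  "tropical-moist-wet" = "tropical-moist")

.soil_aliases <- c(
  "hac" = "high-activity-mineral", "lac" = "low-activity-mineral",
  "high-activity-clay" = "high-activity-mineral",
  "low-activity-clay"  = "low-activity-mineral",
  "andosol" = "volcanic", "spodosol" = "spodic", "organic" = "wetland",
  "aquic" = "wetland")

.landuse_aliases <- c(
  "cropland" = "long-term-cultivated", "cultivated" = "long-term-cultivated",
  "crop" = "long-term-cultivated", "crp" = "set-aside",
  "setaside" = "set-aside", "perennial" = "non-crop",
  "hay" = "non-crop", "pasture" = "non-crop", "grass" = "non-crop",
  "noncrop" = "non-crop", "nc" = "non-crop")

.input_aliases <- c(
  "high-with-amendment" = "high-amendment", "high-with-manure" = "high-amendment",
  "high-without-manure" = "high", "med" = "medium")

.apply_alias <- function(x, aliases) {
  hit <- unname(aliases[x])
  ifelse(is.na(hit), x, hit)
}

.canon_or_fail <- function(x, canon, valid, what) {
  bad <- !(canon %in% valid)
  if (any(bad)) {
    .soccost_error("soccost_domain_error", "unknown %s code(s): %s",
                   what, paste(sQuote(unique(as.character(x)[bad])), collapse = ", "))
  }
  canon
}

.canon_climate_lenient <- function(x) .apply_alias(.canon_token(x), .climate_aliases)
canon_climate <- function(x) {
  .canon_or_fail(x, .canon_climate_lenient(x), climate_zones(), "climate zone")
}

.canon_soil_lenient <- function(x) .apply_alias(.canon_token(x), .soil_aliases)
canon_soil <- function(x) {
  .canon_or_fail(x, .canon_soil_lenient(x), soil_classes(), "soil class")
}

.canon_landuse_lenient <- function(x) .apply_alias(.canon_token(x), .landuse_aliases)
canon_land_use <- function(x) {
  .canon_or_fail(x, .canon_landuse_lenient(x), land_uses(), "land use")
}

.canon_tillage_lenient <- function(x) {
  y <- .canon_token(x)
  out <- toupper(y)
  out[y %in% c("none", "na", "n-a", "")] <- "none"
  out[y == "no-till"] <- "NT"
  out[y %in% c("reduced", "reduced-till", "reduced-tillage")] <- "RT"
  out[y %in% c("conventional", "full", "full-till", "full-tillage")] <- "CT"
  out
}
canon_tillage <- function(x) {
  .canon_or_fail(x, .canon_tillage_lenient(x), tillage_levels(), "tillage")
}

.canon_input_lenient <- function(x) .apply_alias(.canon_token(x), .input_aliases)
canon_input <- function(x) {
  .canon_or_fail(x, .canon_input_lenient(x), input_levels(), "input level")
}

canon_sequence <- function(x) {
  .canon_or_fail(x, toupper(trimws(as.character(x))), tillage_sequences(),
                 "tillage sequence")
}
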