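test_that("equilibrium stock is the Tier-1 product of reference stock and factors", {
  ft <- tiny_factors(); rt <- tiny_refs()
  # identity factors on non-crop land: stock equals the reference
  nc <- management_state("non-crop")
  expect_equal(equilibrium_stock(nc, "ctm", "hac", ft, rt), 50)
  # 50 * 0.80 * 1.00 * 1.00 = 40 and 50 * 0.80 * 1.15 * 1.00 = 46
  expect_equal(equilibrium_stock(cultivated("CT"), "ctm", "hac", ft, rt), 40)
  expect_equal(equilibrium_stock(cultivated("NT"), "ctm", "hac", ft, rt), 46)
})

test_that("annual rate is the stock difference over the horizon, antisymmetric, zero for no change", {
  ft <- tiny_factors(); rt <- tiny_refs()
  ct <- cultivated("CT"); nt <- cultivated("NT")
  expect_equal(annual_rate(ct, nt, "ctm", "hac", ft, rt), 0.30)
  expect_equal(annual_rate(nt, ct, "ctm", "hac", ft, rt), -0.30)
  expect_identical(annual_rate(ct, ct, "ctm", "hac", ft, rt), 0)
  expect_error(annual_rate(ct, nt, "ctm", "hac", ft, rt, horizon = 0),
               class = "soccost_domain_error")
  # antisymmetry across all resolvable tillage/input pairs
  states <- c("CT", "RT", "NT")
  for (a in states) for (b in states) for (inp in c("low", "medium")) {
    expect_equal(
      annual_rate(cultivated(a, inp), cultivated(b, inp), "ctm", "hac", ft, rt),
      -annual_rate(cultivated(b, inp), cultivated(a, inp), "ctm", "hac", ft, rt))
  }
})

test_that("management states enforce the tillage/land-use coupling", {
  expect_error(management_state("non-crop", "CT"),
               class = "soccost_domain_error")
  expect_error(management_state("long-term-cultivated", "none"),
               class = "soccost_domain_error")
})

test_that("the nine sequence codes partition eligible state triples", {
  firsts <- list(c("long-term-cultivated", "CT"),
                 c("long-term-cultivated", "RT"),
                 c("non-crop", "none"))
  mids <- c("CT", "RT", "NT")
  got <- character(0)
  for (f in firsts) for (m in mids) {
    got <- c(got, classify_sequence(f[1], f[2], m))
  }
  expect_setequal(got, tillage_sequences())
  expect_length(got, 9)
  # no-till already in 1982 is outside the nine codes
  expect_error(classify_sequence("long-term-cultivated", "NT", "NT"),
               class = "soccost_classification_error")
})

test_that("sequence_rate prices conversions, zeroes already-NT, excludes set-aside", {
  ft <- tiny_factors(); rt <- tiny_refs()
  # (CT, NT, NT): already no-till by 1997 -> zero everything
  r <- sequence_rate(tiny_stratum(tillage_1997 = "NT"), ft, rt)
  expect_equal(r$sequence, "CTNTNT")
  expect_equal(r$rate_c_mg_ha_yr, 0)
  expect_equal(r$annual_tg_co2, 0)
  expect_equal(r$flags, "already-nt")
  # (CT, CT, NT) with stocks 40 -> 46 on 1 Mha: 0.30 Mg/ha/yr, 0.30 Tg/yr
  r <- sequence_rate(tiny_stratum(), ft, rt)
  expect_equal(r$sequence, "CTCTNT")
  expect_equal(r$rate_c_mg_ha_yr, 0.30)
  expect_equal(r$annual_tg_c, 0.30)
  expect_equal(r$total_20yr_tg_c, 6.0)
  expect_equal(r$rate_co2_mg_ha_yr, 0.30 * 44 / 12)
  # CRP in 1997 -> flagged ineligible with all-zero contribution
  r <- sequence_rate(tiny_stratum(landuse_1997 = "set-aside",
                                  tillage_1997 = "none"), ft, rt)
  expect_equal(r$flags, "ineligible")
  expect_equal(r$annual_tg_c, 0)
})

test_that("CO2 companions use the exact 44/12 ratio everywhere", {
  ft <- tiny_factors(); rt <- tiny_refs()
  strata <- rbind(tiny_stratum("A", tillage_1997 = "CT"),
                  tiny_stratum("B", tillage_1997 = "RT"),
                  tiny_stratum("C", tillage_1997 = "NT"))
  res <- soc_inventory(strata, ft, rt)$results
  nz <- res$rate_c_mg_ha_yr != 0
  expect_true(all(abs(res$rate_co2_mg_ha_yr[nz] / res$rate_c_mg_ha_yr[nz] -
                        44 / 12) < 1e-12))
  expect_equal(res$total_20yr_tg_co2, res$annual_tg_co2 * 20)
})

test_that("sequence aggregation matches a brute-force sum over strata", {
  ft <- tiny_factors(); rt <- tiny_refs()
  set.seed(42)
  n <- 100
  mids <- sample(c("CT", "RT", "NT"), n, replace = TRUE)
  firsts <- sample(1:3, n, replace = TRUE)
  strata <- do.call(rbind, lapply(seq_len(n), function(i) {
    tiny_stratum(sprintf("S%03d", i),
                 area_ha = runif(1, 1e4, 1e6),
                 landuse_1982 = c("long-term-cultivated",
                                  "long-term-cultivated", "non-crop")[firsts[i]],
                 tillage_1982 = c("CT", "RT", "none")[firsts[i]],
                 tillage_1997 = mids[i],
                 input_level = sample(c("low", "medium", "high"), 1))
  }))
  inv <- soc_inventory(strata, ft, rt)
  tab <- aggregate_by_sequence(inv)
  # brute-force oracle: straight sums over the raw per-stratum frame
  res <- inv$results
  expect_equal(tab$annual_tg_c[tab$sequence == "Total"],
               sum(res$rate_c_mg_ha_yr * res$area_ha) / 1e6)
  expect_equal(tab$area_mha[tab$sequence == "Total"], sum(res$area_ha) / 1e6)
  for (sq in setdiff(tab$sequence, "Total")) {
    r <- res[res$sequence == sq, ]
    expect_equal(tab$annual_tg_co2[tab$sequence == sq],
                 sum(r$rate_co2_mg_ha_yr * r$area_ha) / 1e6)
    expect_equal(tab$rate_c_wmean[tab$sequence == sq],
                 sum(r$rate_c_mg_ha_yr * r$area_ha) / sum(r$area_ha))
  }
  # shares sum to 100 over sequences
  expect_equal(sum(tab$area_share_pct[tab$sequence != "Total"]), 100)
})

test_that("equal-area strata average symmetrically and NT strata add zero", {
  ft <- tiny_factors(); rt <- tiny_refs()
  # rates 0.30 (medium) and hand-computable low-input CT conversion
  strata <- rbind(tiny_stratum("A", input_level = "medium"),
                  tiny_stratum("B", input_level = "low"),
                  tiny_stratum("C", tillage_1997 = "NT"))
  inv <- soc_inventory(strata, ft, rt)
  tab <- aggregate_by_sequence(inv)
  rate_low <- 50 * 0.80 * 0.92 * (1.15 - 1.00) / 20
  ctctnt <- tab[tab$sequence == "CTCTNT", ]
  expect_equal(ctctnt$rate_c_wmean, (0.30 + rate_low) / 2)
  expect_equal(tab$annual_tg_c[tab$sequence == "CTNTNT"], 0)
})

test_that("region table cells are area-weighted means bounded by member rates", {
  ft <- tiny_factors(); rt <- tiny_refs()
  set.seed(7)
  n <- 60
  strata <- do.call(rbind, lapply(seq_len(n), function(i) {
    tiny_stratum(sprintf("S%03d", i),
                 region = sample(c("HR", "NCR", "PGR"), 1),
                 area_ha = runif(1, 1e4, 1e6),
                 tillage_1997 = sample(c("CT", "RT", "NT"), 1),
                 input_level = sample(c("low", "medium", "high"), 1))
  }))
  inv <- soc_inventory(strata, ft, rt)
  tab <- aggregate_by_region(inv)
  res <- inv$results
  for (rg in c("HR", "NCR", "PGR")) {
    for (sq in setdiff(tab$sequence, "Overall")) {
      members <- res$rate_c_mg_ha_yr[res$region == rg & res$sequence == sq]
      cell <- as.numeric(tab[tab$sequence == sq, rg])
      if (length(members) == 0) {
        expect_true(is.na(cell))
      } else {
        expect_gte(cell, min(members) - 1e-12)
        expect_lte(cell, max(members) + 1e-12)
      }
    }
  }
  # already-NT sequences give exactly-zero rows wherever present
  ntnt <- tab[tab$sequence == "CTNTNT", -1]
  expect_true(all(as.numeric(ntnt[!is.na(ntnt)]) == 0))
})

test_that("single-stratum region cell echoes its rate", {
  ft <- tiny_factors(); rt <- tiny_refs()
  inv <- soc_inventory(tiny_stratum(region = "HR"), ft, rt)
  tab <- aggregate_by_region(inv)
  expect_equal(as.numeric(tab[tab$sequence == "CTCTNT", "HR"]), 0.30)
})

test_that("strata validation rejects duplicates, bad areas and wrong 2017 tillage", {
  s <- tiny_strata(2)
  dup <- s; dup$stratum_id <- "S1"
  expect_error(read_strata(dup), class = "soccost_integrity_error")
  bad <- s; bad$area_ha[1] <- -5
  expect_error(read_strata(bad), class = "soccost_domain_error")
  t17 <- s; t17$tillage_2017 <- c("NT", "CT")
  expect_error(read_strata(t17), class = "soccost_domain_error")
  expect_error(read_strata(s[0, ]), class = "soccost_empty_error")
})
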