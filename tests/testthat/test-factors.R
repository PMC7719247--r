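test_that("factor tables load, resolve lookups and round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("factor_kind,level,climate_zone,value",
               "LU,long-term-cultivated,ctm,0.80",
               "MG,CT,ctm,1.00",
               "I,medium,ctm,1.00"), path)
  ft <- load_factor_table(path)
  expect_s3_class(ft, "factor_table")
  expect_equal(lookup_factor(ft, "MG", "CT", "ctm"), 1.00)
  expect_equal(lookup_factor(ft, "LU", "long-term-cultivated", "ctm"), 0.80)
  # short code and prose spelling resolve to the same zone
  expect_equal(lookup_factor(ft, "LU", "long-term-cultivated",
                             "cold temperate, moist"), 0.80)

  out <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(ft, out)
  expect_identical(as.data.frame(load_factor_table(out)), as.data.frame(ft))
})

test_that("malformed factor tables are rejected with classed errors", {
  base <- data.frame(factor_kind = c("LU", "MG", "I"),
                     level = c("long-term-cultivated", "CT", "medium"),
                     climate_zone = "ctm", value = c(0.8, 1, 1))
  expect_error(factor_table(base[, -4]), class = "soccost_schema_error")
  expect_error(factor_table(rbind(base, base[1, ])),
               class = "soccost_integrity_error")
  expect_error(factor_table(rbind(base, base[1, ])),
               "LU/long-term-cultivated/cold-temperate-moist")
  neg <- base; neg$value[1] <- -0.2
  expect_error(factor_table(neg), class = "soccost_domain_error")
  unknown <- base; unknown$climate_zone <- "mars-equatorial"
  expect_error(factor_table(unknown), class = "soccost_domain_error")
})

test_that("unresolved factor lookups name all three key parts", {
  ft <- tiny_factors()
  err <- expect_error(lookup_factor(ft, "MG", "NT", "tropical-wet"),
                      class = "soccost_lookup_error")
  expect_match(conditionMessage(err), "kind=MG")
  expect_match(conditionMessage(err), "level=NT")
  expect_match(conditionMessage(err), "climate=tropical-wet")
})

test_that("an inverted tillage ordering warns but still loads", {
  df <- data.frame(factor_kind = c("MG", "MG"), level = c("CT", "NT"),
                   climate_zone = "ctm", value = c(1.10, 1.00))
  expect_warning(ft <- factor_table(df), "tillage factor ordering")
  expect_equal(lookup_factor(ft, "MG", "NT", "ctm"), 1.00)
})

test_that("reference stock tables validate and round-trip", {
  rt <- tiny_refs()
  expect_equal(lookup_ref_stock(rt, "ctm", "hac"), 50)
  expect_equal(lookup_ref_stock(rt, "cold-temperate-moist", "sandy"), 34)
  expect_error(lookup_ref_stock(rt, "ctm", "wetland"),
               class = "soccost_lookup_error")
  bad <- data.frame(climate_zone = "ctm", soil_class = "sandy",
                    soc_ref_mg_c_ha = 0)
  expect_error(ref_stock_table(bad), class = "soccost_domain_error")
  dup <- data.frame(climate_zone = c("ctm", "ctm"),
                    soil_class = c("sandy", "sandy"),
                    soc_ref_mg_c_ha = c(34, 35))
  expect_error(ref_stock_table(dup), class = "soccost_integrity_error")

  out <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(rt, out)
  expect_identical(as.data.frame(load_ref_stocks(out)), as.data.frame(rt))
})

test_that("bundled default tables load and cover the pipeline's keys", {
  ft <- load_factor_table(soccost_example("factors.csv"))
  rt <- load_ref_stocks(soccost_example("ref_stocks.csv"))
  # every temperate zone referenced by the strata schema resolves
  for (cz in c("cold-temperate-dry", "cold-temperate-moist",
               "warm-temperate-dry", "warm-temperate-moist")) {
    expect_gt(lookup_factor(ft, "MG", "NT", cz),
              lookup_factor(ft, "MG", "CT", cz))
    expect_gt(lookup_ref_stock(rt, cz, "sandy"), 0)
  }
})
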