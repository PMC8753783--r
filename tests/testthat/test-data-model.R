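test_that("nutrient registry encodes the bound structure", {
  reg <- nutrient_registry()
  expect_equal(nrow(reg), 20)
  expect_equal(sum(reg$macro), 3)
  expect_equal(sum(reg$lower_bound_kind == "AMDR"), 3)
  expect_equal(sum(reg$has_lower_bound), 19)    # all but sodium
  expect_equal(sum(reg$has_upper_bound), 17)    # no UL for B12/ribo/thiamine
  sodium <- reg[reg$nutrient_id == "sodium", ]
  expect_false(sodium$has_lower_bound)
  expect_equal(sodium$upper_bound_kind, "CDRR")
  no_ul <- reg$nutrient_id[!reg$has_upper_bound]
  expect_setequal(no_ul, c("vitamin_b12", "riboflavin", "thiamine"))
  vita <- reg[reg$nutrient_id == "vitamin_a", ]
  expect_equal(vita$lb_column, "vitamin_a_rae")
  expect_equal(vita$ub_column, "retinol")
})

test_that("group enumeration yields the 20 demographic groups", {
  g <- enumerate_groups()
  expect_equal(nrow(g), 20)
  expect_equal(sum(g$reproductive_status == "none"), 14)
  expect_equal(sum(g$sex == "female"), 13)
  expect_equal(sum(g$reproductive_status != "none"), 6)
  expect_false(anyDuplicated(g$group_id) > 0)
  expect_silent(conadiet:::validate_groups(g))
})

test_that("a valid fixture bundle round-trips through CSV files", {
  d <- withr::local_tempdir()
  write.csv(tiny_foods(), file.path(d, "foods.csv"), row.names = FALSE)
  write.csv(tiny_prices(), file.path(d, "prices.csv"), row.names = FALSE)
  write.csv(tiny_countries(), file.path(d, "countries.csv"),
            row.names = FALSE)
  write.csv(synthetic_dri_table(), file.path(d, "dri.csv"),
            row.names = FALSE)
  b <- load_dataset(file.path(d, "foods.csv"), file.path(d, "prices.csv"),
                    file.path(d, "countries.csv"), file.path(d, "dri.csv"),
                    quiet = TRUE)
  expect_s3_class(b, "cona_bundle")
  expect_equal(nrow(b$foods), 4)
  expect_equal(b$foods$edible_fraction, tiny_foods()$edible_fraction,
               tolerance = 1e-10)
  expect_equal(b$prices$price_lcu_per_kg, tiny_prices()$price_lcu_per_kg,
               tolerance = 1e-10)
})

test_that("schema and invariant violations are rejected with named errors", {
  dri <- synthetic_dri_table()
  # duplicated (country, item) price row
  pr <- rbind(tiny_prices(), tiny_prices()[1, ])
  expect_error(load_dataset(tiny_foods(), pr, tiny_countries(), dri,
                            quiet = TRUE),
               "duplicate \\(country_id, item_id\\)")
  # edible fraction out of range
  f <- tiny_foods(); f$edible_fraction[2] <- 1.2
  expect_error(load_dataset(f, tiny_prices(), tiny_countries(), dri,
                            quiet = TRUE),
               "edible_fraction")
  # missing column named in the message
  f <- tiny_foods(); f$calcium <- NULL
  expect_error(load_dataset(f, tiny_prices(), tiny_countries(), dri,
                            quiet = TRUE),
               "calcium")
  # non-positive price
  pr <- tiny_prices(); pr$price_lcu_per_kg[1] <- 0
  expect_error(load_dataset(tiny_foods(), pr, tiny_countries(), dri,
                            quiet = TRUE),
               "positive")
  # prices referencing an unknown item
  pr <- tiny_prices(); pr$item_id[1] <- "ghost"
  expect_error(load_dataset(tiny_foods(), pr, tiny_countries(), dri,
                            quiet = TRUE),
               "ghost")
})

test_that("missing composition values are zero-filled with a warning", {
  f <- tiny_foods(); f$vitamin_c[1] <- NA
  expect_warning(
    b <- load_dataset(f, tiny_prices(), tiny_countries(),
                      synthetic_dri_table(), quiet = TRUE),
    "treated as 0")
  expect_equal(b$foods$vitamin_c[1], 0)
})

test_that("category coverage flags missing categories, fatal on empty", {
  b <- tiny_bundle()
  cov <- validate_category_coverage(b)
  expect_true(all(grepl("oils and fats", cov$missing_categories)))
  expect_false(any(cov$fatal))
  # drop all pulses from one country -> flagged for that category
  b2 <- b
  b2$prices <- b2$prices[!(b2$prices$country_id == "AAA" &
                             b2$prices$item_id == "lentil"), ]
  cov2 <- validate_category_coverage(b2)
  expect_match(cov2$missing_categories[cov2$country_id == "AAA"],
               "pulses, nuts, and seeds")
  # zero priced items -> fatal
  b3 <- b
  b3$prices <- b3$prices[b3$prices$country_id != "AAA", ]
  cov3 <- validate_category_coverage(b3)
  expect_true(cov3$fatal[cov3$country_id == "AAA"])
})

test_that("write_results round-trips and refuses empty input", {
  d <- withr::local_tempdir()
  res <- data.frame(country_id = rep(c("AAA", "BBB"), each = 20),
                    group_id = rep(enumerate_groups()$group_id, 2),
                    cona_usd_day = runif(40))
  p <- file.path(d, "cona_results.csv")
  write_results(res, p)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 40)
  expect_equal(back$cona_usd_day, res$cona_usd_day, tolerance = 1e-10)
  expect_error(write_results(res[0, ], p), "empty")
})
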