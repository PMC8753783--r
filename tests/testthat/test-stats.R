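test_that("median/IQR/notch summary matches hand arithmetic", {
  s <- median_iqr_notch(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$notch_halfwidth, 1.58 * 2 / sqrt(5))
  s1 <- median_iqr_notch(7)
  expect_equal(s1$median, 7)
  expect_equal(s1$iqr, 0)
  expect_equal(s1$notch_halfwidth, 0)
  expect_error(median_iqr_notch(numeric(0)), "non-empty")
})

test_that("summary stats are translation equivariant and match a sort-based oracle", {
  # oracle: linear interpolation between order statistics, written from the
  # definition h = (n-1)p + 1
  oracle_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(c(3, 10, 101, 1000), 1))
    s <- median_iqr_notch(x)
    expect_equal(s$median, oracle_q(x, 0.5), tolerance = 1e-12)
    expect_equal(s$q25, oracle_q(x, 0.25), tolerance = 1e-12)
    expect_equal(s$q75, oracle_q(x, 0.75), tolerance = 1e-12)
    k <- runif(1, -5, 5)
    s2 <- median_iqr_notch(x + k)
    expect_equal(s2$median, s$median + k, tolerance = 1e-10)
    expect_equal(s2$iqr, s$iqr, tolerance = 1e-10)
    expect_equal(s2$notch_halfwidth, s$notch_halfwidth, tolerance = 1e-10)
  }
})

make_panel <- function(country_eff, group_means, noise_sd = 0) {
  panel <- expand.grid(country_id = names(country_eff),
                       group_id = names(group_means),
                       stringsAsFactors = FALSE)
  panel$value <- country_eff[panel$country_id] +
    group_means[panel$group_id] +
    rnorm(nrow(panel), 0, noise_sd)
  panel
}

test_that("fixed-effects group means are exact on a noise-free panel", {
  panel <- make_panel(c(A = 1, B = -1), c(g1 = 2, g2 = 3))
  fe <- suppressWarnings(fe_group_means(panel))  # exact fit
  expect_equal(fe$adjusted_mean[fe$group_id == "g1"], 2, tolerance = 1e-10)
  expect_equal(fe$adjusted_mean[fe$group_id == "g2"], 3, tolerance = 1e-10)
  expect_equal(fe$ci_upper - fe$ci_lower, c(0, 0), tolerance = 1e-8)
  expect_true(all(fe$reliable))
})

test_that("on balanced panels the group contrast equals the raw mean difference", {
  set.seed(21)
  panel <- make_panel(c(A = 0.5, B = -0.2, C = 1), c(g1 = 2, g2 = 3.5),
                      noise_sd = 0.3)
  fe <- fe_group_means(panel)
  raw <- tapply(panel$value, panel$group_id, mean)
  expect_equal(fe$adjusted_mean[fe$group_id == "g2"] -
                 fe$adjusted_mean[fe$group_id == "g1"],
               unname(raw["g2"] - raw["g1"]), tolerance = 1e-10)
})

test_that("group means are invariant to adding per-country constants", {
  set.seed(31)
  panel <- make_panel(c(A = 0, B = 0, C = 0),
                      c(g1 = 1, g2 = 2, g3 = 4), noise_sd = 0.5)
  fe1 <- fe_group_means(panel)
  shift <- c(A = 10, B = -3, C = 0.7)
  panel2 <- panel
  panel2$value <- panel2$value + shift[panel2$country_id]
  fe2 <- fe_group_means(panel2)
  # contrasts unchanged; levels shift by the mean of the added constants
  expect_equal(fe2$adjusted_mean - mean(shift), fe1$adjusted_mean,
               tolerance = 1e-10)
  expect_equal(fe2$ci_upper - fe2$ci_lower, fe1$ci_upper - fe1$ci_lower,
               tolerance = 1e-10)
})

test_that("group ordering is recovered as noise vanishes", {
  set.seed(41)
  truth <- c(g1 = 1, g2 = 1.5, g3 = 2.2, g4 = 3)
  ceff <- rnorm(10); names(ceff) <- paste0("c", 1:10)
  panel <- make_panel(ceff, truth, noise_sd = 0.01)
  fe <- fe_group_means(panel)
  expect_equal(fe$group_id[order(fe$adjusted_mean)], names(truth))
})

test_that("panel preconditions are enforced", {
  panel <- make_panel(c(A = 1), c(g1 = 2, g2 = 3))
  expect_error(fe_group_means(panel), "at least 2 countries")
  panel2 <- make_panel(c(A = 1, B = 2), c(g1 = 2, g2 = 3))
  panel2$group_id[panel2$group_id == "g2" & panel2$country_id == "B"] <- "g1"
  # g2 now present in a single country -> flagged, not an error
  panel2$value <- panel2$value + rnorm(4, 0, 0.1)
  fe <- suppressWarnings(fe_group_means(panel2))
  expect_false(fe$reliable[fe$group_id == "g2"])
})

test_that("income contrast recovers a constructed class effect exactly", {
  groups <- paste0("g", 1:5)
  panel <- expand.grid(country_id = paste0("c", 1:8), group_id = groups,
                       stringsAsFactors = FALSE)
  panel$income_group <- ifelse(panel$country_id %in% paste0("c", 1:4),
                               "low", "high")
  geff <- setNames(seq(100, 300, length.out = 5), groups)
  panel$grams_day <- geff[panel$group_id] +
    ifelse(panel$income_group == "low", -100, 0)
  ct <- suppressWarnings(adjusted_income_contrast(panel))  # exact fit
  expect_equal(ct$contrast, -100, tolerance = 1e-10)
  expect_lte(ct$ci_lower, -100)
  expect_gte(ct$ci_upper, -100)
  # null case: identical distributions across classes
  set.seed(51)
  panel$grams_day <- geff[panel$group_id] + rnorm(nrow(panel), 0, 5)
  ct0 <- adjusted_income_contrast(panel)
  expect_lte(ct0$ci_lower, ct0$contrast)
  expect_gte(abs(ct0$contrast), 0)
  # single class is a domain error
  panel$income_group <- "low"
  expect_error(adjusted_income_contrast(panel), "income classes")
})
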