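# Shared fixtures built in code: a tiny 4-food dataset exercising the full
# CSV schemas, and a random-LP generator for solver property tests.

tiny_foods <- function() {
  comp <- composition_columns()
  f <- data.frame(
    item_id = c("rice", "lentil", "milk", "orange"),
    name = c("rice", "lentil", "milk", "orange"),
    category = c("starchy staples", "pulses, nuts, and seeds",
                 "animal-source foods", "fruits and vegetables"),
    edible_fraction = c(1.0, 1.0, 1.0, 0.7),
    stringsAsFactors = FALSE
  )
  for (cl in comp) f[[cl]] <- c(1, 1, 1, 1)
  f$carbohydrate <- c(78, 60, 5, 12)
  f$protein <- c(7, 25, 3.4, 0.9)
  f$fat <- c(0.7, 1.1, 3.3, 0.1)
  f$calcium <- c(10, 50, 120, 40)
  f$sodium <- c(2, 6, 45, 1)
  f$vitamin_c <- c(0, 4, 1, 53)
  f$vitamin_b12 <- c(0, 0, 0.5, 0)
  f$vitamin_a_rae <- c(0, 2, 46, 11)
  f$retinol <- c(0, 0, 46, 0)
  f$energy_kcal <- 4 * f$carbohydrate + 4 * f$protein + 9 * f$fat
  f
}

tiny_prices <- function() {
  expand_pr <- expand.grid(
    country_id = c("AAA", "BBB"),
    item_id = c("rice", "lentil", "milk", "orange"),
    stringsAsFactors = FALSE
  )
  expand_pr$price_lcu_per_kg <- c(1.2, 2.4, 3, 4, 5, 6, 2, 3)
  expand_pr
}

tiny_countries <- function() {
  data.frame(
    country_id = c("AAA", "BBB"),
    income_group = c("low", "high"),
    ppp_factor = c(2, 1.5),
    food_expenditure_per_capita_day = c(1.5, 6),
    population = c(1e6, 5e6),
    stringsAsFactors = FALSE
  )
}

tiny_bundle <- function() {
  load_dataset(tiny_foods(), tiny_prices(), tiny_countries(),
               synthetic_dri_table(), quiet = TRUE)
}

# Random small LP in diet form: one energy equality + a few >=/<= rows,
# constructed to be feasible more often than not (no guarantee needed: the
# oracle and the solver must simply agree on status and value).
random_small_lp <- function(n_foods = NULL, n_extra = NULL) {
  if (is.null(n_foods)) n_foods <- sample(2:4, 1)
  if (is.null(n_extra)) n_extra <- sample(1:2, 1)
  mat <- matrix(stats::runif(n_foods * (1 + n_extra), 0.5, 10),
                nrow = 1 + n_extra)
  dir <- c("=", sample(c(">=", "<="), n_extra, replace = TRUE))
  x0 <- stats::runif(n_foods, 0, 5)
  lhs0 <- as.numeric(mat %*% x0)
  rhs <- ifelse(dir == ">=", lhs0 * stats::runif(1 + n_extra, 0.5, 1),
                ifelse(dir == "<=", lhs0 * stats::runif(1 + n_extra, 1, 2),
                       lhs0))
  list(obj = stats::runif(n_foods, 0.1, 2), mat = mat, dir = dir, rhs = rhs)
}
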