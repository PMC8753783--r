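#' Load and validate a diet-cost dataset bundle
#'
#' Reads the four CSV inputs of the pipeline and validates them against the
#' schema and invariants documented in the package vignette:
#' \describe{
#'   \item{foods.csv}{`item_id`, `name`, `category`, `edible_fraction`,
#'     `energy_kcal` (per 100 g edible portion) and one column per
#'     composition entry (see [nutrient_registry()]), all per 100 g edible
#'     portion.}
#'   \item{prices.csv}{`country_id`, `item_id`, `price_lcu_per_kg` — local
#'     currency units per kg as purchased.}
#'   \item{countries.csv}{`country_id`, `income_group`, `ppp_factor`,
#'     `food_expenditure_per_capita_day`, `population`.}
#'   \item{dri.csv}{`group_id`, `nutrient_id`, `eer`, `ear`, `har`, `rda`,
#'     `ul`, `cdrr_upper`, `amdr_lower_frac`, `amdr_upper_frac`.}
#' }
#' Missing nutrient values in a food are treated as 0 with a warning (a
#' conservative convention for lower bounds), not as missing data.
#'
#' @param foods,prices,countries,dri Paths to the four CSV files, or data
#'   frames already in the documented schemas.
#' @param quiet Suppress the row-count message.
#' @return A validated bundle: a list with elements `foods`, `prices`,
#'   `countries`, `dri`, `groups` (the 20-group enumeration) and `registry`,
#'   of class `"cona_bundle"`.
#' @export
load_dataset <- function(foods, prices, countries, dri, quiet = FALSE) {
  read_in <- function(x, what) {
    if (is.data.frame(x)) return(x)
    if (!file.exists(x)) stop("file not found for ", what, ": ", x)
    utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  }
  bundle <- list(
    foods = validate_foods(read_in(foods, "foods")),
    prices = validate_prices(read_in(prices, "prices")),
    countries = validate_countries(read_in(countries, "countries")),
    dri = validate_dri(read_in(dri, "dri")),
    groups = enumerate_groups(),
    registry = nutrient_registry()
  )
  unknown <- setdiff(bundle$prices$item_id, bundle$foods$item_id)
  if (length(unknown)) {
    stop("validation error: prices reference unknown item_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!quiet) {
    message(sprintf("loaded %d foods, %d price records, %d countries, %d DRI rows",
                    nrow(bundle$foods), nrow(bundle$prices),
                    nrow(bundle$countries), nrow(bundle$dri)))
  }
  class(bundle) <- "cona_bundle"
  bundle
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

validate_foods <- function(foods) {
  require_columns(foods, c("item_id", "name", "category", "edible_fraction",
                           "energy_kcal"), "foods")
  comp <- composition_columns()
  absent <- setdiff(comp, names(foods))
  if (length(absent)) {
    stop("schema error in foods: missing composition column(s) ",
         paste(absent, collapse = ", "))
  }
  if (anyDuplicated(foods$item_id)) {
    stop("validation error in foods: duplicate item_id ",
         foods$item_id[duplicated(foods$item_id)][1])
  }
  bad_ef <- which(!is.finite(foods$edible_fraction) |
                    foods$edible_fraction <= 0 | foods$edible_fraction > 1)
  if (length(bad_ef)) {
    stop("validation error in foods row ", bad_ef[1],
         ": edible_fraction must lie in (0, 1]")
  }
  bad_cat <- which(!foods$category %in% food_categories())
  if (length(bad_cat)) {
    stop("validation error in foods row ", bad_cat[1],
         ": unknown category '", foods$category[bad_cat[1]], "'")
  }
  num_cols <- c("energy_kcal", comp)
  n_na <- sum(vapply(foods[num_cols], function(x) sum(is.na(x)), 0L))
  if (n_na > 0) {
    warning(n_na, " missing composition value(s) treated as 0")
    foods[num_cols] <- lapply(foods[num_cols], function(x) {
      x[is.na(x)] <- 0
      x
    })
  }
  for (cl in num_cols) {
    bad <- which(foods[[cl]] < 0)
    if (length(bad)) {
      stop("validation error in foods row ", bad[1], ": negative ", cl)
    }
  }
  foods
}

validate_prices <- function(prices) {
  require_columns(prices, c("country_id", "item_id", "price_lcu_per_kg"),
                  "prices")
  key <- paste(prices$country_id, prices$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("validation error in prices row ", dup, ": duplicate (country_id, ",
         "item_id) pair (", prices$country_id[dup], ", ",
         prices$item_id[dup], ")")
  }
  bad <- which(!is.finite(prices$price_lcu_per_kg) |
                 prices$price_lcu_per_kg <= 0)
  if (length(bad)) {
    stop("validation error in prices row ", bad[1],
         ": price_lcu_per_kg must be positive")
  }
  prices
}

validate_countries <- function(countries) {
  require_columns(countries, c("country_id", "income_group", "ppp_factor",
                               "food_expenditure_per_capita_day",
                               "population"), "countries")
  if (anyDuplicated(countries$country_id)) {
    stop("validation error in countries: duplicate country_id")
  }
  if (any(!countries$income_group %in% income_groups())) {
    stop("validation error in countries: income_group must be one of ",
         paste(income_groups(), collapse = ", "))
  }
  if (any(!is.finite(countries$ppp_factor) | countries$ppp_factor <= 0)) {
    stop("validation error in countries: ppp_factor must be positive")
  }
  countries
}

#' @rdname load_dataset
#' @export
income_groups <- function() {
  c("high", "upper-middle", "lower-middle", "low")
}

validate_dri <- function(dri) {
  require_columns(dri, c("group_id", "nutrient_id", "eer", "ear", "har",
                         "rda", "ul", "cdrr_upper", "amdr_lower_frac",
                         "amdr_upper_frac"), "dri")
  both <- !is.na(dri$ear) & !is.na(dri$rda)
  bad <- which(both & dri$ear > dri$rda)
  if (length(bad)) {
    stop("validation error in dri row ", bad[1], ": ear > rda for (",
         dri$group_id[bad[1]], ", ", dri$nutrient_id[bad[1]], ")")
  }
  amdr <- !is.na(dri$amdr_lower_frac) & !is.na(dri$amdr_upper_frac)
  bad <- which(amdr & dri$amdr_lower_frac >= dri$amdr_upper_frac)
  if (length(bad)) {
    stop("validation error in dri row ", bad[1],
         ": amdr_lower_frac must be < amdr_upper_frac")
  }
  if (any(!is.finite(dri$eer) | dri$eer <= 0)) {
    stop("validation error in dri: eer must be positive for every row")
  }
  dri
}

#' Report food-category coverage per country
#'
#' Flags (does not reject) countries whose priced item list lacks one or
#' more of the six reporting categories. A missing category never makes a
#' diet problem unsolvable by itself — constraints are nutrient-based — but
#' sparse lists are a common cause of infeasible or inflated-cost solutions.
#'
#' @param bundle A `cona_bundle` from [load_dataset()].
#' @return Data frame with one row per country: `country_id`, `n_items`,
#'   `missing_categories` (semicolon-separated, "" if none) and `fatal`
#'   (TRUE when a country has zero priced items).
#' @export
validate_category_coverage <- function(bundle) {
  cats <- food_categories()
  item_cat <- stats::setNames(bundle$foods$category, bundle$foods$item_id)
  out <- lapply(bundle$countries$country_id, function(cid) {
    items <- bundle$prices$item_id[bundle$prices$country_id == cid]
    present <- unique(item_cat[as.character(items)])
    missing <- setdiff(cats, present)
    data.frame(country_id = cid, n_items = length(items),
               missing_categories = paste(missing, collapse = ";"),
               fatal = length(items) == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write per-cell solution records to CSV
#'
#' @param results Non-empty data frame of per (country, group, scenario)
#'   records as produced by [run_cona_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop("results are empty; refusing to write an empty file")
  }
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
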