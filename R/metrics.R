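#' Cost normalisations and affordability benchmarks
#'
#' Diet costs are computed in nominal local currency units (LCU) and
#' reported in 2017 international dollars via purchasing power parity (PPP)
#' conversion factors; energy-adjusted cost per 1000 kcal puts groups with
#' very different energy needs on a comparable scale.
#'
#' @param cona_lcu Diet cost, LCU/day.
#' @param ppp_factor PPP conversion factor, LCU per international dollar
#'   (> 0).
#' @return USD/day.
#' @export
to_usd_ppp <- function(cona_lcu, ppp_factor) {
  if (any(ppp_factor <= 0)) stop("ppp_factor must be positive")
  cona_lcu / ppp_factor
}

#' @rdname to_usd_ppp
#' @param cona_usd_day Diet cost, USD/day.
#' @param eer Energy requirement, kcal/day (> 0).
#' @export
cost_per_1000kcal <- function(cona_usd_day, eer) {
  if (any(eer <= 0)) stop("eer must be positive")
  cona_usd_day / (eer / 1000)
}

#' @rdname to_usd_ppp
#' @param food_expenditure_per_capita_day Observed mean food spending,
#'   USD/person/day (> 0). A ratio above 1 means the least-cost adequate
#'   diet costs more than actual mean food spending.
#' @export
affordability_ratio <- function(cona_usd_day, food_expenditure_per_capita_day) {
  if (any(food_expenditure_per_capita_day <= 0)) {
    stop("food expenditure must be positive")
  }
  cona_usd_day / food_expenditure_per_capita_day
}

#' Food budget at a poverty line
#'
#' The benchmark food budget is the share of a poverty-line income that can
#' credibly be reserved for food; the conventional default is 63% of the
#' $2.10/day line, i.e. $1.32/day. Both constants are arguments, not
#' hard-wired.
#'
#' @param poverty_line_usd_day Poverty line, USD/day.
#' @param food_share Fraction of expenditure available for food, in (0, 1].
#' @return USD/day, rounded to 2 decimals (reporting convention).
#' @export
poverty_food_budget <- function(poverty_line_usd_day = 2.10,
                                food_share = 0.63) {
  if (any(poverty_line_usd_day <= 0) || any(food_share <= 0) ||
      any(food_share > 1)) {
    stop("poverty line must be positive and food share in (0, 1]")
  }
  round(poverty_line_usd_day * food_share, 2)
}

#' Percent change between scenario medians
#'
#' @param median_base,median_alt Medians of the baseline (EAR) and
#'   alternative (RDA) scenario; base must be positive.
#' @return Percent change, reported to 1 decimal.
#' @export
scenario_percent_change <- function(median_base, median_alt) {
  if (any(median_base <= 0)) stop("median_base must be positive")
  round(100 * (median_alt - median_base) / median_base, 1)
}

#' Summarise a solved diet by food category
#'
#' Aggregates the optimal quantities into the six reporting categories:
#' grams/day, kcal/day, and shares of total diet weight and energy.
#'
#' @param solution An optimal `cona_solution`.
#' @param foods The food table of the bundle the problem was built from.
#' @return Data frame with one row per category (all six always present):
#'   `category`, `grams_day`, `kcal_day`, `weight_share`, `energy_share`.
#' @export
summarize_composition <- function(solution, foods) {
  stopifnot(inherits(solution, "cona_solution"))
  if (solution$status != "optimal") {
    stop("summarize_composition requires an optimal solution")
  }
  q <- solution$quantities
  idx <- match(names(q), foods$item_id)
  if (anyNA(idx)) {
    stop("item(s) missing from food table: ",
         paste(names(q)[is.na(idx)], collapse = ", "))
  }
  cat_i <- foods$category[idx]
  unknown <- setdiff(unique(cat_i), food_categories())
  if (length(unknown)) {
    stop("item with unknown category: ",
         names(q)[match(unknown[1], cat_i)])
  }
  kcal_i <- q / 100 * foods$energy_kcal[idx]
  grams <- tapply(q, factor(cat_i, levels = food_categories()), sum,
                  default = 0)
  kcal <- tapply(kcal_i, factor(cat_i, levels = food_categories()), sum,
                 default = 0)
  data.frame(
    category = food_categories(),
    grams_day = as.numeric(grams),
    kcal_day = as.numeric(kcal),
    weight_share = as.numeric(grams) / sum(grams),
    energy_share = as.numeric(kcal) / sum(kcal),
    stringsAsFactors = FALSE
  )
}

#' Assemble a normalised cost record for one solved cell
#'
#' @param solution An optimal or failed `cona_solution`.
#' @param country Row of the country table for the solution's country.
#' @return One-row data frame: ids, scenario, status, `cona_lcu_day`,
#'   `cona_usd_day`, `cona_usd_per_1000kcal`, `affordability_ratio`,
#'   `n_foods`, `n_binding`, `binding` (semicolon-separated ids).
#' @export
cost_record <- function(solution, country) {
  if (solution$status != "optimal") {
    return(data.frame(
      country_id = solution$country_id, group_id = solution$group_id,
      scenario = solution$scenario, status = solution$status,
      cona_lcu_day = NA_real_, cona_usd_day = NA_real_,
      cona_usd_per_1000kcal = NA_real_, affordability_ratio = NA_real_,
      n_foods = NA_integer_, n_binding = NA_integer_, binding = "",
      stringsAsFactors = FALSE
    ))
  }
  usd <- to_usd_ppp(solution$cona_lcu, country$ppp_factor)
  data.frame(
    country_id = solution$country_id, group_id = solution$group_id,
    scenario = solution$scenario, status = solution$status,
    cona_lcu_day = solution$cona_lcu, cona_usd_day = usd,
    cona_usd_per_1000kcal = cost_per_1000kcal(usd, solution$problem$eer),
    affordability_ratio =
      affordability_ratio(usd, country$food_expenditure_per_capita_day),
    n_foods = sum(solution$quantities > 1e-6),
    n_binding = length(solution$binding),
    binding = paste(solution$binding, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
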