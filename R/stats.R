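#' Median, quartiles and notch half-width
#'
#' Box-plot summary used for distribution reporting: median, 25% and 75%
#' quantiles (linear interpolation between order statistics, R's default
#' type 7 — the common convention), interquartile range, and the notch
#' half-width `1.58 * IQR / sqrt(N)` giving the approximate range of the
#' median.
#'
#' @param values Non-empty numeric vector; NAs are dropped.
#' @return A list: `median`, `q25`, `q75`, `iqr`, `notch_halfwidth`, `n`.
#' @export
median_iqr_notch <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("values must be non-empty")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(median = q[2], q25 = q[1], q75 = q[3], iqr = iqr,
       notch_halfwidth = 1.58 * iqr / sqrt(length(values)),
       n = length(values))
}

#' Country-fixed-effects adjusted group means
#'
#' Regresses the outcome on demographic-group indicators with a fixed
#' effect for every country, absorbing national price-level differences
#' (including artefacts such as inflated costs in countries with short food
#' lists). The saturated group-indicator parameterisation spans the same
#' space as sex, age and their interactions. The adjusted mean for a group
#' is its model prediction averaged over the country effects (intercept +
#' group effect + mean country effect), with classical homoskedastic 95%
#' CIs; within-country demeaning would give identical group contrasts.
#'
#' @param panel Data frame with columns `country_id`, `group_id` and the
#'   outcome column.
#' @param outcome Name of the outcome column (default "value").
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame, one row per group: `group_id`, `adjusted_mean`,
#'   `ci_lower`, `ci_upper`, `n_countries`, `reliable` (FALSE when the
#'   group appears in fewer than 2 countries).
#' @export
fe_group_means <- function(panel, outcome = "value", conf_level = 0.95) {
  stopifnot(all(c("country_id", "group_id", outcome) %in% names(panel)))
  panel <- panel[!is.na(panel[[outcome]]), , drop = FALSE]
  if (length(unique(panel$country_id)) < 2 ||
      length(unique(panel$group_id)) < 2) {
    stop("panel needs at least 2 countries and 2 groups")
  }
  panel$group_id <- factor(panel$group_id)
  panel$country_id <- factor(panel$country_id)
  fit <- stats::lm(stats::reformulate(c("group_id", "country_id"),
                                      response = outcome), data = panel)
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("collinear design: some effects are not estimable")
  V <- stats::vcov(fit)
  groups <- levels(panel$group_id)
  countries <- levels(panel$country_id)
  n_c <- length(countries)
  df <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)

  rows <- lapply(groups, function(g) {
    L <- stats::setNames(numeric(length(beta)), names(beta))
    L["(Intercept)"] <- 1
    gn <- paste0("group_id", g)
    if (gn %in% names(L)) L[gn] <- 1
    cn <- paste0("country_id", countries)
    L[intersect(cn, names(L))] <- 1 / n_c
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    ncg <- length(unique(panel$country_id[panel$group_id == g]))
    data.frame(group_id = g, adjusted_mean = est,
               ci_lower = est - tcrit * se, ci_upper = est + tcrit * se,
               n_countries = ncg, reliable = ncg >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Adjusted low- vs high-income contrast for one food category
#'
#' Linear model of grams/day on income-class indicators with
#' demographic-group fixed effects; returns the adjusted low-minus-high
#' difference with its 95% CI. This is the design behind statements like
#' "low-income countries' least-cost diets included X g/day less
#' animal-source foods than high-income countries'".
#'
#' @param panel Data frame with columns `country_id`, `group_id`,
#'   `income_group` and the outcome column (grams/day of one category).
#' @param outcome Name of the outcome column (default "grams_day").
#' @param low,high Income-class labels to contrast.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `contrast` (adjusted low - high), `ci_lower`,
#'   `ci_upper`, `n_low`, `n_high`.
#' @export
adjusted_income_contrast <- function(panel, outcome = "grams_day",
                                     low = "low", high = "high",
                                     conf_level = 0.95) {
  stopifnot(all(c("income_group", "group_id", outcome) %in% names(panel)))
  panel <- panel[!is.na(panel[[outcome]]), , drop = FALSE]
  present <- unique(panel$income_group)
  if (length(present) < 2 || !all(c(low, high) %in% present)) {
    stop("panel must contain both income classes '", low, "' and '",
         high, "'")
  }
  panel$income_group <- stats::relevel(factor(panel$income_group),
                                       ref = high)
  panel$group_id <- factor(panel$group_id)
  fit <- stats::lm(stats::reformulate(c("income_group", "group_id"),
                                      response = outcome), data = panel)
  cn <- paste0("income_group", low)
  est <- stats::coef(fit)[[cn]]
  ci <- stats::confint(fit, cn, level = conf_level)
  list(contrast = est, ci_lower = ci[1], ci_upper = ci[2],
       n_low = sum(panel$income_group == low),
       n_high = sum(panel$income_group == high))
}
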