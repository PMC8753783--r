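#' Specification for a synthetic world of food prices
#'
#' Defines the conditions a generated dataset emulates: a master list of
#' items classified into six categories with category-structured nutrient
#' densities (cheap calories concentrated in starchy staples, calcium in
#' animal-source foods, vitamin C in fruits and vegetables, ...),
#' log-normal price dispersion around category base prices, country price
#' levels and PPP factors, and partial availability — each country prices a
#' random subset of the master list. Defaults emulate the reported shape of
#' national price collections: around 200 candidate items of which a
#' country prices roughly 125 (availability 0.625), with income-graded
#' relative prices for animal-source foods.
#'
#' @param n_countries Number of countries.
#' @param n_master_items Size of the master item list.
#' @param availability_prob Probability an item is priced in a country.
#' @param seed Integer seed; mandatory, fully determines the world.
#' @param animal_price_mult Extra multiplier on animal-source prices,
#'   applied on top of the income-class gradient (used for paired-world
#'   substitution experiments).
#' @return A list of class `"cona_world_spec"`, including
#'   `price_lognormal_params` and `nutrient_density_params` tables.
#' @export
world_spec <- function(n_countries = 20, n_master_items = 200,
                       availability_prob = 0.625, seed,
                       animal_price_mult = 1) {
  if (missing(seed)) stop("seed is a mandatory argument")
  if (availability_prob <= 0 || availability_prob > 1) {
    stop("availability_prob must lie in (0, 1]")
  }
  structure(
    list(n_countries = n_countries, n_master_items = n_master_items,
         availability_prob = availability_prob, seed = as.integer(seed),
         animal_price_mult = animal_price_mult,
         price_lognormal_params = category_price_params(),
         nutrient_density_params = category_nutrient_profiles()),
    class = "cona_world_spec"
  )
}

# Category base prices (USD/kg as purchased), log-normal dispersion of
# item-level and country-level price draws, and mean edible fractions.
category_price_params <- function() {
  data.frame(
    category = food_categories(),
    base_usd_per_kg = c(0.65, 1.90, 4.20, 1.30, 1.60, 1.40),
    sdlog_item = 0.35, sdlog_country = 0.25,
    edible_fraction_mean = c(0.85, 0.95, 0.80, 0.75, 1.00, 0.95),
    share_of_master = c(0.18, 0.14, 0.25, 0.25, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
}

# Mean nutrient densities per 100 g edible portion by category. Magnitudes
# are plausible for the category archetypes (grain, legume/nut, dairy/meat
# mix, produce, oil, sugar/beverage) but the table is synthetic: it encodes
# the economic structure of food composition, not any real database.
category_nutrient_profiles <- function() {
  cols <- c("carbohydrate", "protein", "fat", "calcium", "iron", "zinc",
            "magnesium", "phosphorus", "copper", "selenium", "sodium",
            "vitamin_c", "thiamine", "riboflavin", "niacin", "vitamin_b6",
            "folate", "vitamin_b12", "vitamin_a_rae", "retinol", "vitamin_e")
  m <- rbind(
    c(72, 9, 2, 25, 2.5, 1.6, 90, 220, 0.35, 18, 5, 0, 0.35, 0.12,
      4.5, 0.25, 120, 0, 0, 0, 0.6),                      # starchy staples
    c(28, 21, 22, 120, 5.0, 3.2, 180, 400, 1.0, 10, 8, 1.5, 0.5, 0.2,
      2.5, 0.4, 280, 0, 1, 0, 6),                         # pulses/nuts/seeds
    c(5, 17, 10, 250, 1.5, 3.0, 25, 250, 0.1, 20, 90, 1, 0.1, 0.3,
      3.5, 0.3, 15, 2.2, 90, 85, 0.5),                    # animal-source
    c(11, 1.6, 0.4, 45, 1.1, 0.4, 22, 40, 0.12, 1, 15, 45, 0.06, 0.07,
      0.7, 0.16, 65, 0, 180, 0, 1.2),                     # fruits/vegetables
    c(0, 0, 98, 2, 0.1, 0.05, 1, 2, 0.01, 0.5, 2, 0, 0, 0,
      0, 0, 0, 0, 30, 25, 14),                            # oils/fats
    c(70, 2.5, 4, 25, 0.8, 0.4, 15, 40, 0.1, 2, 40, 4, 0.05, 0.08,
      0.5, 0.05, 10, 0, 5, 2, 0.5)                        # sweets/beverages
  )
  dimnames(m) <- list(food_categories(), cols)
  as.data.frame(m)
}

#' Generate a synthetic dataset bundle
#'
#' Draws a complete foods/prices/countries/DRI bundle from a
#' [world_spec()]. Deterministic given the spec's seed (the global RNG
#' state is saved and restored). Nutrient densities are drawn per item from
#' mean-preserving log-normal noise around the category profile; energy is
#' set to the Atwater sum `4*carbohydrate + 4*protein + 9*fat` so that
#' macronutrient energy shares are internally consistent with the energy
#' balance constraint. Every country is guaranteed at least one item per
#' category: the availability draw is retried a bounded number of times and
#' then one item of any still-missing category is force-added with a
#' warning.
#'
#' @param spec A `cona_world_spec`.
#' @return A validated `cona_bundle` (see [load_dataset()]).
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "cona_world_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  pp <- spec$price_lognormal_params
  prof <- spec$nutrient_density_params

  # master food list
  n_items <- spec$n_master_items
  n_per_cat <- pmax(2L, round(n_items * pp$share_of_master))
  cats <- rep(pp$category, n_per_cat)[seq_len(max(n_items, sum(n_per_cat)))]
  cats <- cats[!is.na(cats)]
  n_items <- length(cats)
  item_id <- sprintf("F%03d", seq_len(n_items))

  lnoise <- function(n, sdlog) {
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  foods <- data.frame(item_id = item_id,
                      name = paste0(gsub("[ ,]+", "_", cats), "_",
                                    seq_len(n_items)),
                      category = cats, stringsAsFactors = FALSE)
  ci <- match(cats, pp$category)
  ef <- stats::rnorm(n_items, pp$edible_fraction_mean[ci], 0.05)
  foods$edible_fraction <- pmin(1, pmax(0.4, ef))
  for (col in names(prof)) {
    mu <- prof[[col]][ci]
    foods[[col]] <- mu * lnoise(n_items, 0.35)
  }
  foods$energy_kcal <- 4 * foods$carbohydrate + 4 * foods$protein +
    9 * foods$fat
  # item-level price heterogeneity (USD/kg scale, shared across countries)
  item_price_usd <- pp$base_usd_per_kg[ci] * lnoise(n_items, pp$sdlog_item[ci])

  # countries: income classes in fixed rotation, PPP and price levels drawn
  n_c <- spec$n_countries
  country_id <- sprintf("C%03d", seq_len(n_c))
  income <- rep(income_groups(), length.out = n_c)
  ppp <- stats::rlnorm(n_c, meanlog = log(3), sdlog = 0.8)
  rel_price <- lnoise(n_c, 0.15)
  fexp_base <- c(high = 8, `upper-middle` = 4, `lower-middle` = 2.2,
                 low = 1.4)
  fexp <- fexp_base[income] * lnoise(n_c, 0.25)
  countries <- data.frame(
    country_id = country_id, income_group = income, ppp_factor = ppp,
    food_expenditure_per_capita_day = as.numeric(fexp),
    population = round(stats::rlnorm(n_c, log(2e7), 1)),
    stringsAsFactors = FALSE
  )
  # animal-source foods are relatively dearer where incomes are lower
  animal_mult <- c(high = 1.0, `upper-middle` = 1.1, `lower-middle` = 1.3,
                   low = 1.6)[income] * spec$animal_price_mult

  prices <- vector("list", n_c)
  for (k in seq_len(n_c)) {
    avail <- draw_availability(cats, spec$availability_prob, pp$category)
    mult <- ifelse(cats == "animal-source foods", animal_mult[k], 1)
    p_usd <- item_price_usd * mult * rel_price[k] *
      lnoise(n_items, pp$sdlog_country[ci])
    prices[[k]] <- data.frame(
      country_id = country_id[k], item_id = item_id[avail],
      price_lcu_per_kg = p_usd[avail] * ppp[k],
      stringsAsFactors = FALSE
    )
  }
  prices <- do.call(rbind, prices)

  dri <- synthetic_dri_table()
  load_dataset(foods, prices, countries, dri, quiet = TRUE)
}

# Availability draw guaranteeing >= 1 item per category (bounded retries,
# then force-add).
draw_availability <- function(cats, prob, categories, max_retry = 10L) {
  for (r in seq_len(max_retry)) {
    avail <- stats::runif(length(cats)) < prob
    if (all(categories %in% cats[avail]) && any(avail)) return(which(avail))
  }
  avail <- stats::runif(length(cats)) < prob
  for (cat in setdiff(categories, cats[avail])) {
    pick <- sample(which(cats == cat), 1)
    avail[pick] <- TRUE
    warning("force-added one '", cat, "' item to keep category coverage")
  }
  which(avail)
}

#' Synthetic dietary-reference-intake table for the 20 groups
#'
#' Builds a complete DRI table (EER, EAR, HAR, RDA, UL, sodium CDRR, AMDR
#' fractions) for every demographic group and registry nutrient. Values are
#' synthetic: adult reference magnitudes in plausible ranges with age-, sex-
#' and reproductive-status multipliers (higher calcium in adolescence and
#' old age, higher iron for women of reproductive age and in pregnancy,
#' higher folate in pregnancy, higher vitamins A/C in lactation), chosen so
#' that EAR <= RDA <= UL everywhere. No claim is made of reproducing any
#' published reference table.
#'
#' @return A data frame in the dri.csv schema (see [load_dataset()]).
#' @export
synthetic_dri_table <- function() {
  groups <- enumerate_groups()
  reg <- nutrient_registry()

  # adult male 19-30 reference EAR and (food-basis) UL per nutrient
  ref <- list(
    carbohydrate = list(ear = 100, ul = NA),
    protein      = list(ear = 47, ul = NA),
    fat          = list(ear = NA, ul = NA),
    calcium      = list(ear = 800, ul = 2500),
    iron         = list(ear = 6, ul = 45),
    zinc         = list(ear = 9.4, ul = 40),
    magnesium    = list(ear = 330, ul = 900),
    phosphorus   = list(ear = 580, ul = 4000),
    copper       = list(ear = 0.7, ul = 10),
    selenium     = list(ear = 45, ul = 400),
    sodium       = list(ear = NA, ul = NA),
    vitamin_c    = list(ear = 75, ul = 2000),
    thiamine     = list(ear = 1.0, ul = NA),
    riboflavin   = list(ear = 1.1, ul = NA),
    niacin       = list(ear = 12, ul = 60),
    vitamin_b6   = list(ear = 1.1, ul = 100),
    folate       = list(ear = 320, ul = 2000),
    vitamin_b12  = list(ear = 2.0, ul = NA),
    vitamin_a    = list(ear = 625, ul = 3000),
    vitamin_e    = list(ear = 12, ul = 1000)
  )
  age_mult <- c(`4-8` = 0.55, `9-13` = 0.85, `14-18` = 1.05, `19-30` = 1,
                `31-50` = 1, `51-70` = 1, `71+` = 1)
  ul_age_mult <- c(`4-8` = 0.6, `9-13` = 0.8, `14-18` = 1, `19-30` = 1,
                   `31-50` = 1, `51-70` = 1, `71+` = 1)
  eer_tab <- list(
    male = c(`4-8` = 1800, `9-13` = 2300, `14-18` = 3200, `19-30` = 3000,
             `31-50` = 2900, `51-70` = 2600, `71+` = 2400),
    female = c(`4-8` = 1700, `9-13` = 2100, `14-18` = 2400, `19-30` = 2400,
               `31-50` = 2200, `51-70` = 2100, `71+` = 2000)
  )
  cdrr <- c(`4-8` = 1500, `9-13` = 1800, `14-18` = 2300, `19-30` = 2300,
            `31-50` = 2300, `51-70` = 2300, `71+` = 2300)

  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    eer <- eer_tab[[g$sex]][[g$age_band]] +
      switch(g$reproductive_status, none = 0, pregnant = 300,
             lactating = 400)
    for (ni in seq_len(nrow(reg))) {
      nid <- reg$nutrient_id[ni]
      r <- ref[[nid]]
      mult <- age_mult[[g$age_band]]
      if (g$sex == "female") mult <- mult * 0.88
      # targeted physiology: iron for menstruating women, calcium in
      # adolescence/old age, folate in pregnancy, vitamins A/C in lactation
      if (nid == "iron" && g$sex == "female" &&
          g$age_band %in% c("14-18", "19-30", "31-50")) mult <- mult * 1.5
      if (nid == "calcium" && g$age_band %in% c("9-13", "14-18")) {
        mult <- mult * 1.35
      }
      if (nid == "calcium" && g$age_band %in% c("51-70", "71+")) {
        mult <- mult * 1.15
      }
      mult <- mult * switch(
        g$reproductive_status,
        none = 1,
        pregnant = if (nid == "folate") 1.6 else if (nid == "iron") 1.8
                   else 1.25,
        lactating = if (nid %in% c("vitamin_a", "vitamin_c")) 1.45 else 1.35
      )
      ear <- if (is.na(r$ear)) NA_real_ else r$ear * mult
      rda <- if (is.na(ear)) NA_real_ else ear * 1.25
      har <- if (nid == "iron") ear * 1.6
             else if (nid == "zinc") ear * 1.5 else NA_real_
      ul <- if (is.na(r$ul)) NA_real_ else r$ul * ul_age_mult[[g$age_band]]
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g$group_id, nutrient_id = nid, eer = eer,
        ear = ear, har = har, rda = rda, ul = ul,
        cdrr_upper = if (nid == "sodium") cdrr[[g$age_band]] else NA_real_,
        amdr_lower_frac = if (reg$macro[ni]) {
          c(carbohydrate = 0.45, protein = 0.10, fat = 0.20)[[nid]]
        } else NA_real_,
        amdr_upper_frac = if (reg$macro[ni]) {
          c(carbohydrate = 0.65, protein = 0.35, fat = 0.35)[[nid]]
        } else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  dri <- do.call(rbind, rows)
  with_ul <- !is.na(dri$ul)
  stopifnot(all(dri$rda[with_ul & !is.na(dri$rda)] <=
                  dri$ul[with_ul & !is.na(dri$rda)]))
  dri
}

#' Analytic fixtures with documented optima
#'
#' Small diet problems whose solutions are known in closed form or by
#' exhaustive vertex enumeration, used as exact oracles for the solver and
#' the sensitivity machinery.
#'
#' `fixtureA` is a two-food problem — food X: 100 kcal and 10 mg of a
#' limiting nutrient per 100 g at 0.10 LCU/unit; food Y: 200 kcal and 2 mg
#' per 100 g at 0.05 LCU/unit — with an energy equality of 2000 kcal and a
#' nutrient lower bound of 100 mg. Solving the two binding rows gives
#' quantities 800/0.9 g of X and 500/0.9 g of Y, optimum 7/6 LCU/day, duals
#' 1/6000 LCU/kcal (energy) and 1/120 LCU/mg (nutrient), hence elasticities
#' 2/7 and 5/7.
#'
#' `fixtureB` is a four-food problem with two nutrient lower bounds and a
#' binding sodium-like upper bound; its optimum is computed on construction
#' by [lp_enumerate()] and stored in the `expected` element.
#'
#' @param name "fixtureA" or "fixtureB".
#' @return A list: `problem` (a `cona_lp`), and `expected` (named list of
#'   documented values).
#' @export
analytic_fixture <- function(name = c("fixtureA", "fixtureB")) {
  name <- match.arg(name)
  if (name == "fixtureA") {
    mat <- rbind(energy = c(100, 200), `lb:nutrient` = c(10, 2))
    colnames(mat) <- c("X", "Y")
    problem <- structure(
      list(country_id = "FIX", group_id = "fixtureA", scenario = "EAR",
           item_ids = c("X", "Y"), cost = c(0.10, 0.05), mat = mat,
           dir = c("=", ">="), rhs = c(2000, 100),
           constraint_ids = c("energy", "lb:nutrient"), eer = 2000),
      class = "cona_lp"
    )
    expected <- list(
      cona = 7 / 6,
      quantities = c(X = 100 * 80 / 9, Y = 100 * 50 / 9),
      duals = c(energy = 1 / 6000, `lb:nutrient` = 1 / 120),
      elasticities = c(energy = 2 / 7, `lb:nutrient` = 5 / 7),
      binding = c("energy", "lb:nutrient")
    )
    return(list(problem = problem, expected = expected))
  }
  # fixtureB: staple / legume / dairy / salty-snack archetypes; calcium and
  # protein lower bounds plus a sodium cap that the cheap salty item makes
  # bind at the optimum
  mat <- rbind(
    energy = c(350, 400, 150, 450),
    `lb:protein` = c(8, 22, 16, 6),
    `lb:calcium` = c(20, 120, 280, 30),
    `ub:sodium` = c(5, 10, 100, 800)
  )
  colnames(mat) <- c("staple", "legume", "dairy", "snack")
  problem <- structure(
    list(country_id = "FIX", group_id = "fixtureB", scenario = "EAR",
         item_ids = colnames(mat), cost = c(0.30, 0.60, 0.90, 0.10),
         mat = mat, dir = c("=", ">=", ">=", "<="),
         rhs = c(2000, 50, 1000, 1500),
         constraint_ids = rownames(mat), eer = 2000),
    class = "cona_lp"
  )
  oracle <- lp_enumerate(problem$cost, problem$mat, problem$dir,
                         problem$rhs)
  stopifnot(oracle$status == "optimal")
  list(problem = problem,
       expected = list(cona = oracle$objective,
                       quantities = stats::setNames(100 * oracle$x,
                                                    colnames(mat))))
}
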