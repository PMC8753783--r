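#' Nutrient registry
#'
#' The diet model constrains energy plus 20 nutrients: three macronutrients
#' (carbohydrate, protein, fat) bounded on both sides by the acceptable
#' macronutrient distribution range (AMDR), and 17 micronutrients. Lower
#' bounds are average requirements (EAR, or the harmonised average
#' requirement HAR for iron and zinc); upper bounds are tolerable upper
#' intake levels (UL) for 13 micronutrients and the chronic disease risk
#' reduction (CDRR) level for sodium. Sodium has no lower bound; vitamin
#' B12, riboflavin and thiamine have no upper bound. Vitamin A is a single
#' nutrient concept with two composition columns: retinol activity
#' equivalents (RAE) feed the lower bound, preformed retinol feeds the UL.
#'
#' @return A data frame with one row per nutrient (energy excluded) and
#'   columns `nutrient_id`, `name`, `unit`, `macro`, `has_lower_bound`,
#'   `has_upper_bound`, `lower_bound_kind` (EAR, HAR, AMDR or none),
#'   `upper_bound_kind` (UL, CDRR, AMDR or none), `lb_column` and
#'   `ub_column` naming the food-composition columns each bound reads.
#' @export
nutrient_registry <- function() {
  def <- function(id, name, unit, macro = FALSE,
                  lb_kind = "EAR", ub_kind = "UL",
                  lb_col = id, ub_col = id) {
    data.frame(
      nutrient_id = id, name = name, unit = unit, macro = macro,
      has_lower_bound = lb_kind != "none",
      has_upper_bound = ub_kind != "none",
      lower_bound_kind = lb_kind, upper_bound_kind = ub_kind,
      lb_column = if (lb_kind != "none") lb_col else NA_character_,
      ub_column = if (ub_kind != "none") ub_col else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    def("carbohydrate", "Total carbohydrate", "g", macro = TRUE,
        lb_kind = "AMDR", ub_kind = "AMDR"),
    def("protein", "Protein", "g", macro = TRUE,
        lb_kind = "AMDR", ub_kind = "AMDR"),
    def("fat", "Total fat (lipids)", "g", macro = TRUE,
        lb_kind = "AMDR", ub_kind = "AMDR"),
    def("calcium", "Calcium", "mg"),
    def("iron", "Iron", "mg", lb_kind = "HAR"),
    def("zinc", "Zinc", "mg", lb_kind = "HAR"),
    def("magnesium", "Magnesium", "mg"),
    def("phosphorus", "Phosphorus", "mg"),
    def("copper", "Copper", "mg"),
    def("selenium", "Selenium", "ug"),
    def("sodium", "Sodium", "mg", lb_kind = "none", ub_kind = "CDRR"),
    def("vitamin_c", "Vitamin C", "mg"),
    def("thiamine", "Thiamine", "mg", ub_kind = "none"),
    def("riboflavin", "Riboflavin", "mg", ub_kind = "none"),
    def("niacin", "Niacin", "mg"),
    def("vitamin_b6", "Vitamin B6", "mg"),
    def("folate", "Folate", "ug"),
    def("vitamin_b12", "Vitamin B12", "ug", ub_kind = "none"),
    def("vitamin_a", "Vitamin A", "ug",
        lb_col = "vitamin_a_rae", ub_col = "retinol"),
    def("vitamin_e", "Vitamin E", "mg")
  )
}

#' Food categories used for composition reporting
#'
#' The six reporting categories foods are classified into. Category
#' membership never enters the optimisation (constraints are nutrient-based
#' only); it is used for diet-composition summaries and coverage checks.
#'
#' @return Character vector of the six category names.
#' @export
food_categories <- function() {
  c("starchy staples", "pulses, nuts, and seeds", "animal-source foods",
    "fruits and vegetables", "oils and fats", "sweets and beverages")
}

# Composition columns expected in a food table, in registry order.
# Vitamin A contributes two columns: RAE (adequacy) and preformed retinol (UL).
composition_columns <- function() {
  reg <- nutrient_registry()
  unique(c(reg$nutrient_id[reg$nutrient_id != "vitamin_a"],
           "vitamin_a_rae", "retinol"))
}
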