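#' Convert an AMDR energy fraction to grams per day
#'
#' The acceptable macronutrient distribution range (AMDR) expresses
#' macronutrient bounds as fractions of total energy; the diet LP needs them
#' in grams/day. Uses the Atwater conversion factors: 4 kcal/g for
#' carbohydrate and protein, 9 kcal/g for fat.
#'
#' @param energy_fraction Fraction of total energy in [0, 1].
#' @param eer Estimated energy requirement, kcal/day (> 0).
#' @param kcal_per_gram Energy density of the macronutrient, kcal/g.
#' @return grams/day.
#' @examples
#' amdr_to_grams(0.50, 2000, 4) # 250 g carbohydrate
#' @export
amdr_to_grams <- function(energy_fraction, eer, kcal_per_gram) {
  if (any(kcal_per_gram <= 0)) stop("kcal_per_gram must be positive")
  if (any(energy_fraction < 0 | energy_fraction > 1)) {
    stop("energy_fraction must lie in [0, 1]")
  }
  if (any(eer <= 0)) stop("eer must be positive")
  energy_fraction * eer / kcal_per_gram
}

macro_kcal_per_gram <- c(carbohydrate = 4, protein = 4, fat = 9)

#' Build the per-group constraint bounds from a DRI table
#'
#' Applies the full set of dietary-reference-intake rules for one
#' demographic group under a chosen scenario:
#' \itemize{
#'   \item lower bounds are the EAR (scenario "EAR") or RDA (scenario
#'     "RDA") for every nutrient carrying a lower bound;
#'   \item iron and zinc use `max(HAR, scenario value)` — the harmonised
#'     average requirement reflects low bioavailability from plant-dominated
#'     least-cost diets;
#'   \item macronutrient bounds come from the AMDR fractions via
#'     [amdr_to_grams()]; protein and carbohydrate lower bounds are
#'     `max(scenario grams, AMDR-lower grams)` since both constraints apply;
#'   \item upper bounds are the UL for 13 micronutrients, the CDRR for
#'     sodium (which has no lower bound), and the AMDR-upper for the
#'     macronutrients; the vitamin A lower bound reads the RAE composition
#'     column while its UL reads preformed retinol.
#' }
#'
#' @param group_id A group identifier from [enumerate_groups()].
#' @param dri DRI table (see [load_dataset()]).
#' @param scenario "EAR" (default) or "RDA".
#' @return A list of class `"cona_requirements"` with elements `group_id`,
#'   `scenario`, `eer` (kcal/day), `lower_bounds` and `upper_bounds` (named
#'   numeric vectors, amount/day) and `bound_columns` mapping each bounded
#'   nutrient to the composition column its constraint row reads.
#' @export
build_requirement_set <- function(group_id, dri, scenario = c("EAR", "RDA")) {
  scenario <- match.arg(scenario)
  reg <- nutrient_registry()
  rows <- dri[dri$group_id == group_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("no DRI rows for group ", group_id)
  eer <- unique(rows$eer)
  if (length(eer) != 1 || !is.finite(eer) || eer <= 0) {
    stop("group ", group_id, " must have one positive eer")
  }

  cell <- function(nid, col) {
    r <- rows[rows$nutrient_id == nid, col]
    if (length(r) == 0) stop("missing DRI row for (", group_id, ", ", nid, ")")
    r[1]
  }

  lb <- c(); ub <- c()
  lb_col <- c(); ub_col <- c()
  for (k in seq_len(nrow(reg))) {
    nid <- reg$nutrient_id[k]
    if (reg$macro[k]) {
      kpg <- macro_kcal_per_gram[[nid]]
      lo_frac <- cell(nid, "amdr_lower_frac")
      hi_frac <- cell(nid, "amdr_upper_frac")
      if (is.na(lo_frac) || is.na(hi_frac)) {
        stop("missing AMDR fractions for (", group_id, ", ", nid, ")")
      }
      lo <- amdr_to_grams(lo_frac, eer, kpg)
      hi <- amdr_to_grams(hi_frac, eer, kpg)
      if (nid %in% c("carbohydrate", "protein")) {
        base <- cell(nid, if (scenario == "EAR") "ear" else "rda")
        if (!is.na(base)) lo <- max(lo, base)
      }
      lb[nid] <- lo; ub[nid] <- hi
      lb_col[nid] <- nid; ub_col[nid] <- nid
      next
    }
    if (reg$has_lower_bound[k]) {
      base <- cell(nid, if (scenario == "EAR") "ear" else "rda")
      if (is.na(base)) stop("missing DRI value for (", group_id, ", ", nid, ")")
      if (reg$lower_bound_kind[k] == "HAR") {
        har <- cell(nid, "har")
        if (!is.na(har)) base <- max(base, har)
      }
      lb[nid] <- base
      lb_col[nid] <- reg$lb_column[k]
    }
    if (reg$has_upper_bound[k]) {
      u <- if (reg$upper_bound_kind[k] == "CDRR") {
        cell(nid, "cdrr_upper")
      } else {
        cell(nid, "ul")
      }
      if (is.na(u)) stop("missing upper bound for (", group_id, ", ", nid, ")")
      ub[nid] <- u
      ub_col[nid] <- reg$ub_column[k]
    }
  }

  shared <- intersect(names(lb), names(ub))
  # vitamin A bounds apply to different composition columns, so the usual
  # LB <= UB sanity check only holds where both read the same column
  same_col <- shared[lb_col[shared] == ub_col[shared]]
  bad <- same_col[lb[same_col] > ub[same_col]]
  if (length(bad)) {
    stop("infeasible bounds for group ", group_id, ": lower bound exceeds ",
         "upper bound for ", paste(bad, collapse = ", "))
  }
  structure(
    list(group_id = group_id, scenario = scenario, eer = eer,
         lower_bounds = lb, upper_bounds = ub,
         lb_columns = lb_col, ub_columns = ub_col),
    class = "cona_requirements"
  )
}
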