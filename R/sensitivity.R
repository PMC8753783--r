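#' Shadow prices of the diet-problem constraints
#'
#' The shadow price of a constraint is its dual value at the optimum: the
#' marginal change in minimised diet cost per unit change in that
#' constraint's bound, in the currency of the objective. Non-binding
#' constraints have a shadow price of zero; the solver's duals already
#' satisfy complementary slackness, and this accessor additionally snaps
#' sub-tolerance values on non-binding rows to exact zero.
#'
#' @param solution An optimal `cona_solution` from [solve_cona()].
#' @return Named numeric vector, one entry per constraint (LCU per
#'   constraint unit).
#' @export
shadow_prices <- function(solution) {
  stopifnot(inherits(solution, "cona_solution"))
  if (solution$status != "optimal") {
    stop("shadow_prices requires an optimal solution")
  }
  sp <- solution$duals
  nonbind <- setdiff(names(sp), solution$binding)
  sp[nonbind][abs(sp[nonbind]) <= 1e-8 * max(1, abs(solution$cona_lcu))] <- 0
  sp
}

#' Shadow-price elasticity of diet cost with respect to one requirement
#'
#' The percentage change in minimised cost for a 1% change in the
#' requirement: `e = shadow_price * rhs / CoNA`. For upper-bound
#' constraints a higher bound relaxes the problem, so the raw elasticity is
#' non-positive; the conventional headline value is its magnitude, returned
#' alongside the signed value. The energy elasticity can take either sign:
#' a larger energy requirement needs more food but also admits cheap
#' energy-dense items.
#'
#' @param solution An optimal `cona_solution`.
#' @param constraint_id A constraint id such as "energy", "lb:calcium" or
#'   "ub:sodium".
#' @return A list: `constraint_id`, `shadow_price`, `elasticity` (signed),
#'   `magnitude` (absolute value), `rhs`, `binding` flag, and `defined`
#'   (FALSE when rhs is zero, where a percentage change is undefined).
#' @export
shadow_price_elasticity <- function(solution, constraint_id) {
  sp_all <- shadow_prices(solution)
  if (!constraint_id %in% names(sp_all)) {
    stop("unknown constraint id: ", constraint_id)
  }
  rhs <- solution$problem$rhs[match(constraint_id,
                                    solution$problem$constraint_ids)]
  sp <- sp_all[[constraint_id]]
  if (rhs == 0) {
    return(list(constraint_id = constraint_id, shadow_price = sp,
                elasticity = NA_real_, magnitude = NA_real_, rhs = rhs,
                binding = constraint_id %in% solution$binding,
                defined = FALSE))
  }
  e <- sp * rhs / solution$cona_lcu
  list(constraint_id = constraint_id, shadow_price = sp, elasticity = e,
       magnitude = abs(e), rhs = rhs,
       binding = constraint_id %in% solution$binding, defined = TRUE)
}

#' All shadow-price elasticities of a solution as a table
#'
#' @param solution An optimal `cona_solution`.
#' @return Data frame with one row per constraint: `country_id`,
#'   `group_id`, `scenario`, `constraint`, `shadow_price`, `elasticity`,
#'   `magnitude`, `binding`.
#' @export
sensitivity_table <- function(solution) {
  sp <- shadow_prices(solution)
  rows <- lapply(names(sp), function(cid) {
    e <- shadow_price_elasticity(solution, cid)
    data.frame(country_id = solution$country_id,
               group_id = solution$group_id, scenario = solution$scenario,
               constraint = cid, shadow_price = e$shadow_price,
               elasticity = e$elasticity, magnitude = e$magnitude,
               binding = e$binding, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Finite-difference elasticity (verification oracle)
#'
#' Re-solves the diet LP with the chosen constraint's bound perturbed to
#' `rhs * (1 +/- delta_frac)` and returns the central-difference
#' `%d(cost) / %d(rhs)`. Because the optimal cost is piecewise linear in any
#' single bound, this equals the dual-based elasticity exactly whenever no
#' basis change occurs inside the interval; it is the package's independent
#' check on [shadow_price_elasticity()], not the reported value.
#'
#' @param problem A `cona_lp`.
#' @param constraint_id Constraint to perturb.
#' @param delta_frac Relative perturbation (> 0); default 0.01, i.e. the
#'   literal 1% change in the requirement.
#' @return A list: `elasticity`, `method` ("central" or "one_sided") and
#'   `cona` (the unperturbed optimum).
#' @export
finite_difference_elasticity <- function(problem, constraint_id,
                                         delta_frac = 0.01) {
  if (delta_frac <= 0) stop("delta_frac must be positive")
  j <- match(constraint_id, problem$constraint_ids)
  if (is.na(j)) stop("unknown constraint id: ", constraint_id)
  if (problem$rhs[j] == 0) stop("elasticity undefined at rhs = 0")

  solve_at <- function(mult) {
    p <- problem
    p$rhs[j] <- problem$rhs[j] * mult
    lp_solve(p$cost, p$mat, p$dir, p$rhs)
  }
  base <- solve_at(1)
  if (base$status != "optimal") stop("base problem is not optimal")
  up <- solve_at(1 + delta_frac)
  dn <- solve_at(1 - delta_frac)
  if (up$status == "optimal" && dn$status == "optimal") {
    e <- (up$objective - dn$objective) / (2 * delta_frac * base$objective)
    method <- "central"
  } else if (up$status == "optimal") {
    warning("downward perturbation infeasible; using one-sided difference")
    e <- (up$objective - base$objective) / (delta_frac * base$objective)
    method <- "one_sided"
  } else if (dn$status == "optimal") {
    warning("upward perturbation infeasible; using one-sided difference")
    e <- (base$objective - dn$objective) / (delta_frac * base$objective)
    method <- "one_sided"
  } else {
    stop("both perturbed problems infeasible for ", constraint_id)
  }
  list(elasticity = e, method = method, cona = base$objective)
}
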