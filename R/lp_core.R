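#' Assemble the least-cost diet linear program for one country and group
#'
#' Decision variables are the priced items of the country, measured in
#' 100 g-edible-portion units (composition tables are per 100 g edible
#' portion, so constraint coefficients are used as-is). The cost coefficient
#' converts the price per kg as purchased to the price of 100 g edible:
#' `price_lcu_per_kg / (10 * edible_fraction)`. Rows are one energy
#' equality (rhs = EER), one `>=` row per lower bound and one `<=` row per
#' upper bound; the vitamin A lower row reads the RAE column and its upper
#' row the preformed-retinol column.
#'
#' @param bundle A `cona_bundle` from [load_dataset()].
#' @param country_id Country to price the diet in.
#' @param reqs A `cona_requirements` from [build_requirement_set()].
#' @return A list of class `"cona_lp"`: `country_id`, `group_id`,
#'   `scenario`, `item_ids`, `cost` (LCU per 100 g-edible unit), `mat`,
#'   `dir`, `rhs`, `constraint_ids` and `eer`.
#' @export
assemble_lp <- function(bundle, country_id, reqs) {
  pr <- bundle$prices[bundle$prices$country_id == country_id, , drop = FALSE]
  if (nrow(pr) == 0) stop("no priced items for country ", country_id)
  foods <- bundle$foods[match(pr$item_id, bundle$foods$item_id), , drop = FALSE]
  cost <- pr$price_lcu_per_kg / (10 * foods$edible_fraction)

  lb <- reqs$lower_bounds; ub <- reqs$upper_bounds
  comp <- function(col) as.numeric(foods[[col]])

  rows <- list(energy = comp("energy_kcal"))
  dir <- "="
  rhs <- reqs$eer
  ids <- "energy"
  for (nid in names(lb)) {
    rows[[paste0("lb:", nid)]] <- comp(reqs$lb_columns[[nid]])
    dir <- c(dir, ">=")
    rhs <- c(rhs, lb[[nid]])
    ids <- c(ids, paste0("lb:", nid))
  }
  for (nid in names(ub)) {
    rows[[paste0("ub:", nid)]] <- comp(reqs$ub_columns[[nid]])
    dir <- c(dir, "<=")
    rhs <- c(rhs, ub[[nid]])
    ids <- c(ids, paste0("ub:", nid))
  }
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(ids, pr$item_id)
  structure(
    list(country_id = country_id, group_id = reqs$group_id,
         scenario = reqs$scenario, item_ids = as.character(pr$item_id),
         cost = cost, mat = mat, dir = dir, rhs = rhs,
         constraint_ids = ids, eer = reqs$eer),
    class = "cona_lp"
  )
}

#' Solve a diet LP for its cost of nutrient adequacy
#'
#' @param problem A `cona_lp` from [assemble_lp()].
#' @param tol Solver feasibility tolerance.
#' @return A list of class `"cona_solution"`: `status` ("optimal",
#'   "infeasible" or "unbounded"); and when optimal, `quantities` (named,
#'   grams/day per item), `cona_lcu` (objective, LCU/day), `duals` (named by
#'   constraint, LCU per constraint unit), `binding` (constraint ids at
#'   their bound, see [binding_constraints()]), plus the problem metadata.
#' @export
solve_cona <- function(problem, tol = 1e-9) {
  stopifnot(inherits(problem, "cona_lp"))
  res <- lp_solve(problem$cost, problem$mat, problem$dir, problem$rhs,
                  tol = tol)
  sol <- list(country_id = problem$country_id, group_id = problem$group_id,
              scenario = problem$scenario, status = res$status,
              problem = problem)
  if (res$status != "optimal") {
    sol$quantities <- NULL
    sol$cona_lcu <- NA_real_
    sol$duals <- NULL
    sol$binding <- character(0)
    class(sol) <- "cona_solution"
    return(sol)
  }
  q_units <- res$x
  sol$quantities <- stats::setNames(100 * q_units, problem$item_ids)
  sol$cona_lcu <- res$objective
  sol$duals <- stats::setNames(res$duals, problem$constraint_ids)
  sol$achieved <- stats::setNames(as.numeric(problem$mat %*% q_units),
                                  problem$constraint_ids)
  class(sol) <- "cona_solution"
  sol$binding <- binding_constraints(sol)
  sol
}

#' Constraints active at the optimum
#'
#' A constraint is binding when its achieved value lies within a relative
#' tolerance of its bound; equality rows are always binding. At a
#' non-degenerate vertex optimum the number of foods used equals the number
#' of binding constraints.
#'
#' @param solution An optimal `cona_solution`.
#' @param rel_tol Relative tolerance on `|achieved - rhs|`, scaled by
#'   `max(1, |rhs|)`.
#' @return Character vector of binding constraint ids.
#' @export
binding_constraints <- function(solution, rel_tol = 1e-6) {
  stopifnot(inherits(solution, "cona_solution"))
  if (solution$status != "optimal") {
    stop("binding_constraints requires an optimal solution")
  }
  pb <- solution$problem
  gap <- abs(solution$achieved - pb$rhs) <= rel_tol * pmax(1, abs(pb$rhs))
  ids <- pb$constraint_ids[gap | pb$dir == "="]
  ids
}

#' @export
print.cona_solution <- function(x, ...) {
  cat(sprintf("<cona_solution> %s / %s / %s: %s\n", x$country_id,
              x$group_id, x$scenario, x$status))
  if (x$status == "optimal") {
    used <- x$quantities[x$quantities > 1e-6]
    cat(sprintf("  CoNA = %.4f LCU/day; %d foods; %d binding constraints\n",
                x$cona_lcu, length(used), length(x$binding)))
  }
  invisible(x)
}
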