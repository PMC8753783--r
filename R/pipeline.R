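#' Enumerate the pipeline's work list
#'
#' One least-cost diet problem is solved per country x demographic group x
#' scenario; with 172 countries and 20 groups that is 3440 problems per
#' scenario.
#'
#' @param country_ids Character vector of countries.
#' @param scenarios Scenarios to run ("EAR", "RDA" or both).
#' @param groups Group table (defaults to the full 20-group enumeration).
#' @return Data frame with columns `country_id`, `group_id`, `scenario`.
#' @export
build_work_list <- function(country_ids, scenarios = "EAR",
                            groups = enumerate_groups()) {
  out <- expand.grid(group_id = groups$group_id, country_id = country_ids,
                     scenario = scenarios, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("country_id", "group_id", "scenario")]
}

#' Run the full cost-of-nutrient-adequacy pipeline
#'
#' For every country x group x scenario cell: builds the requirement set,
#' assembles and solves the least-cost diet LP, derives normalised cost
#' records, shadow-price sensitivity rows and food-category composition
#' rows, then fits the country-fixed-effects group comparison on the
#' baseline-scenario costs. Per-cell infeasibility is recorded in the
#' status column, never fatal: short food lists can genuinely fail the
#' constraint system, and dropping them silently would bias summaries.
#'
#' @param bundle A `cona_bundle` from [load_dataset()] or
#'   [generate_world()].
#' @param scenario "EAR", "RDA" or "both".
#' @param out_dir Optional directory; when given, writes cona_results.csv,
#'   sensitivity.csv, composition.csv, group_effects.csv and run_log.txt.
#' @param verbose Emit a message per country.
#' @return A list of class `"cona_run"`: `results`, `sensitivity`,
#'   `composition`, `group_effects` (per outcome), and `log` (solver status
#'   counts).
#' @export
run_cona_pipeline <- function(bundle, scenario = c("EAR", "RDA", "both"),
                              out_dir = NULL, verbose = FALSE) {
  scenario <- match.arg(scenario)
  scenarios <- if (scenario == "both") c("EAR", "RDA") else scenario
  stopifnot(inherits(bundle, "cona_bundle"))

  reqs <- list()
  for (sc in scenarios) {
    for (g in bundle$groups$group_id) {
      reqs[[paste(g, sc)]] <- build_requirement_set(g, bundle$dri, sc)
    }
  }

  res_rows <- list(); sens_rows <- list(); comp_rows <- list()
  for (cid in bundle$countries$country_id) {
    if (verbose) message("solving country ", cid)
    country <- bundle$countries[bundle$countries$country_id == cid, ]
    for (sc in scenarios) {
      for (g in bundle$groups$group_id) {
        rq <- reqs[[paste(g, sc)]]
        sol <- solve_cona(assemble_lp(bundle, cid, rq))
        res_rows[[length(res_rows) + 1L]] <- cost_record(sol, country)
        if (sol$status == "optimal") {
          sens_rows[[length(sens_rows) + 1L]] <- sensitivity_table(sol)
          cmp <- summarize_composition(sol, bundle$foods)
          cmp <- cbind(country_id = cid, group_id = g, scenario = sc, cmp,
                       stringsAsFactors = FALSE)
          comp_rows[[length(comp_rows) + 1L]] <- cmp
        }
      }
    }
  }
  results <- do.call(rbind, res_rows)
  sensitivity <- do.call(rbind, sens_rows)
  composition <- do.call(rbind, comp_rows)

  base_sc <- scenarios[1]
  ge <- NULL
  ok <- results$status == "optimal" & results$scenario == base_sc
  if (sum(ok) > 0 && length(unique(results$country_id[ok])) >= 2) {
    panel_day <- data.frame(country_id = results$country_id[ok],
                            group_id = results$group_id[ok],
                            value = results$cona_usd_day[ok])
    panel_kcal <- data.frame(country_id = results$country_id[ok],
                             group_id = results$group_id[ok],
                             value = results$cona_usd_per_1000kcal[ok])
    ge <- rbind(
      cbind(outcome = "cona_usd_day", fe_group_means(panel_day),
            stringsAsFactors = FALSE),
      cbind(outcome = "cona_usd_per_1000kcal", fe_group_means(panel_kcal),
            stringsAsFactors = FALSE)
    )
  }

  log <- as.list(table(results$status))
  log$n_cells <- nrow(results)
  log$n_countries <- nrow(bundle$countries)
  log$scenarios <- paste(scenarios, collapse = ",")

  run <- structure(list(results = results, sensitivity = sensitivity,
                        composition = composition, group_effects = ge,
                        log = log),
                   class = "cona_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(results, file.path(out_dir, "cona_results.csv"))
    write_results(sensitivity, file.path(out_dir, "sensitivity.csv"))
    write_results(composition, file.path(out_dir, "composition.csv"))
    if (!is.null(ge)) {
      write_results(ge, file.path(out_dir, "group_effects.csv"))
    }
    writeLines(paste(names(log), unlist(log), sep = " = "),
               file.path(out_dir, "run_log.txt"))
  }
  run
}

#' @export
print.cona_run <- function(x, ...) {
  cat("<cona_run>\n")
  cat(paste0("  ", names(x$log), " = ", unlist(x$log), collapse = "\n"),
      "\n")
  invisible(x)
}
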