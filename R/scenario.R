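#' Scenario configuration
#'
#' Bundles every model the pipeline needs: the serum response, the
#' relative-risk-reduction anchors, the cost model, and the burden inputs.
#' Burden can be supplied either as calibrated totals (`total_deaths`,
#' `total_yll`) or as mortality + life tables; when `total_yll` is `NULL`
#' it is computed from the tables, and when no tables are given the
#' calibrated synthetic defaults are generated (deterministically, from
#' `seed`).
#'
#' @param doses dose grid, IU/day.
#' @param variants cost variants, subset of `base`, `low20`, `high20`.
#' @param serum a [serum_model()].
#' @param anchors an [rrr_anchors()] set.
#' @param cost a [cost_model()].
#' @param total_deaths total annual cancer deaths; default the Germany-2016
#'   calibration of 229827 (back-solved, see [calibrate_total_deaths()]).
#' @param total_yll total years of life lost; `NULL` (default) computes it
#'   from `deaths_table`/`life` (falling back to the synthetic defaults).
#' @param deaths_table optional [mortality_table()] overriding the
#'   synthetic generator (its death total also overrides `total_deaths`).
#' @param life optional [life_table()].
#' @param seed forwarded to the synthetic generators only.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(doses = c(400, 600, 800, 1000),
                            variants = c("base", "low20", "high20"),
                            serum = serum_model(),
                            anchors = rrr_anchors(),
                            cost = cost_model(),
                            total_deaths = 229827,
                            total_yll = NULL,
                            deaths_table = NULL,
                            life = NULL,
                            seed = 1L) {
  if (!all(variants %in% c("base", "low20", "high20")))
    vd_stop("config", "variants must be among base, low20, high20")
  doses <- as.numeric(doses)
  if (!is.null(deaths_table)) {
    stopifnot(inherits(deaths_table, "mortality_table"))
    total_deaths <- sum(deaths_table$deaths)
  }
  if (is.null(total_yll)) {
    dt <- deaths_table %||%
      gen_mortality_table(mortality_gen_spec(total_deaths = total_deaths,
                                             seed = seed))
    lt <- life %||% gen_life_table()
    total_yll <- total_yll(dt, lt)$total_yll
  }
  structure(list(doses = doses, variants = variants, serum = serum,
                 anchors = anchors, cost = cost,
                 total_deaths = total_deaths, total_yll = total_yll,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from a JSON file
#'
#' Accepts a nested JSON document with optional keys `doses`, `variants`,
#' `serum` (`slope`), `anchors` (`dose`, `rrr`), `cost`
#' (`unit_ingredient_cost`, `loss_fraction`, `component_shares`,
#' `population`, `cost_overrides`, `cost_per_death`, `loss_convention`),
#' `burden` (`total_deaths`, `total_yll`, `seed`). Missing keys fall back
#' to the packaged defaults; `vdfort` ships the full default document at
#' `system.file("extdata", "default_config.json", package = "vdfort")`.
#'
#' @param path path to a JSON config file.
#' @return a [scenario_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  serum <- if (!is.null(raw$serum$slope)) serum_model(raw$serum$slope)
           else serum_model()
  anchors <- if (!is.null(raw$anchors)) rrr_anchors(raw$anchors$dose, raw$anchors$rrr)
             else rrr_anchors()
  cost_args <- raw$cost %||% list()
  if (!is.null(cost_args$component_shares))
    cost_args$component_shares <- unlist(cost_args$component_shares)
  if (!is.null(cost_args$cost_overrides))
    cost_args$cost_overrides <- unlist(cost_args$cost_overrides)
  cost <- do.call(cost_model, cost_args)
  burden <- raw$burden %||% list()
  scenario_config(doses = raw$doses %||% c(400, 600, 800, 1000),
                  variants = raw$variants %||% c("base", "low20", "high20"),
                  serum = serum, anchors = anchors, cost = cost,
                  total_deaths = burden$total_deaths %||% 229827,
                  total_yll = burden$total_yll,
                  seed = burden$seed %||% 1L)
}

#' Run one fortification scenario
#'
#' Chains the pipeline for a single (dose, cost-variant) pair: serum
#' increase, interpolated relative risk reduction, prevented deaths,
#' savings, program cost, net savings and cost per life-year. Monetary
#' values are in thousand euro; savings chain from the unrounded
#' prevented-death value while the displayed count is rounded half-up.
#'
#' @param dose daily dose, IU.
#' @param variant `"base"`, `"low20"` or `"high20"`.
#' @param config a [scenario_config()].
#' @return one-row `data.frame` with the frozen grid columns
#'   `dose_iu, cost_variant, serum_increase_nmol_l, rrr, deaths_prevented,
#'   savings_keur, cost_keur, net_savings_keur, eur_per_life_year`.
#' @examples
#' run_scenario(400, "base")
#' @export
run_scenario <- function(dose, variant = "base", config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  res <- withCallingHandlers(
    {
      serum <- serum_increase(dose, config$serum)
      rrr <- rrr_at_dose(dose, config$anchors)
      prevented <- deaths_prevented(config$total_deaths, rrr)
      sav <- savings(config$total_deaths, rrr, config$cost$cost_per_death)
      cost <- fortification_cost(dose, config$cost, variant)
      pyll <- preventable_yll(config$total_yll, rrr)
      vd_debug("dose=%g variant=%s rrr=%.6f prevented=%.4f pyll=%.2f",
               dose, variant, rrr, prevented, pyll)
      data.frame(dose_iu = dose,
                 cost_variant = variant,
                 serum_increase_nmol_l = serum,
                 rrr = rrr,
                 deaths_prevented = round_half_up(prevented),
                 savings_keur = sav,
                 cost_keur = cost,
                 net_savings_keur = net_savings(sav, cost),
                 eur_per_life_year = if (pyll > 0)
                   cost_per_life_year(cost, pyll) else NA_real_,
                 stringsAsFactors = FALSE)
    },
    error = function(e) {
      e$message <- sprintf("scenario (dose %s IU, %s): %s", dose, variant,
                           conditionMessage(e))
      stop(e)
    }
  )
  res
}

#' Run the full scenario grid
#'
#' One row per (dose, cost-variant) combination, ordered by dose then
#' variant. With the packaged defaults this reproduces the Germany-2016
#' scenario table (4 doses x 3 cost variants). Deterministic: regenerating
#' the grid under the same configuration is bit-identical.
#'
#' @param config a [scenario_config()].
#' @param doses,variants optional overrides of the config's grid.
#' @return `data.frame` with the frozen grid columns, one row per
#'   combination.
#' @export
run_grid <- function(config = scenario_config(), doses = config$doses,
                     variants = config$variants) {
  if (length(doses) == 0 || length(variants) == 0)
    vd_stop("config", "doses and variants must be non-empty")
  rows <- lapply(doses, function(d)
    do.call(rbind, lapply(variants, function(v) run_scenario(d, v, config))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a scenario grid to CSV
#'
#' @param grid output of [run_grid()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
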