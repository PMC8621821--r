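#' Fortification cost model
#'
#' Cost structure of a national food-fortification program. The annual
#' ingredient (cholecalciferol) cost is `unit_ingredient_cost` euro per
#' person-year for a delivered dose of 800 IU/day and scales linearly in
#' dose. Processing destroys `loss_fraction` of the added vitamin, so
#' production must exceed delivery. Ingredient cost is only
#' `component_shares["ingredient"]` of the total program cost; the
#' remainder covers marketing/education, food control and monitoring, and
#' other recurrent program costs.
#'
#' Published per-dose total program costs are usually derived from a more
#' detailed costing appendix than the headline parameters; `cost_overrides`
#' (named by dose in IU/day, values in thousand euro) therefore takes
#' precedence over the parametric formula when present. The packaged
#' defaults carry the four published dose scenarios.
#'
#' @param unit_ingredient_cost euro per person-year at 800 IU/day delivered
#'   (default 0.11).
#' @param loss_fraction fraction of added vitamin D lost during processing,
#'   in `[0, 1)` (default 0.41).
#' @param component_shares named shares of total cost; must sum to 1.
#' @param population persons covered; needed only when no override exists
#'   for a requested dose.
#' @param cost_overrides named numeric, total program cost in thousand euro
#'   by dose (IU/day); `NULL` disables overrides.
#' @param cost_per_death end-of-life cancer care cost saved per prevented
#'   death, euro (default 40000).
#' @param loss_convention `"divide"` (default): production =
#'   delivered / (1 - loss); `"multiply"`: production = delivered *
#'   (1 + loss). The published phrase "processing losses of 41%" admits
#'   both readings.
#' @return object of class `cost_model`.
#' @export
cost_model <- function(unit_ingredient_cost = 0.11,
                       loss_fraction = 0.41,
                       component_shares = c(ingredient = 0.80, marketing = 0.08,
                                            monitoring = 0.07, other = 0.05),
                       population = NULL,
                       cost_overrides = c("400" = 15166, "600" = 17493,
                                          "800" = 19819, "1000" = 22146),
                       cost_per_death = 40000,
                       loss_convention = c("divide", "multiply")) {
  loss_convention <- match.arg(loss_convention)
  if (abs(sum(component_shares) - 1) > 1e-9)
    vd_stop("config", "component_shares must sum to 1")
  if (loss_fraction < 0 || loss_fraction >= 1)
    vd_stop("config", "loss_fraction must be in [0, 1)")
  if (!"ingredient" %in% names(component_shares))
    vd_stop("config", "component_shares must include an 'ingredient' share")
  if (!is.null(population) && population <= 0)
    vd_stop("config", "population must be positive")
  out <- list(unit_ingredient_cost = unit_ingredient_cost,
              loss_fraction = loss_fraction,
              component_shares = component_shares,
              population = population,
              cost_overrides = cost_overrides,
              cost_per_death = cost_per_death,
              loss_convention = loss_convention)
  class(out) <- "cost_model"
  out
}

#' Annual fortification program cost
#'
#' Total program cost for a dose scenario, in thousand euro. If the model
#' carries an override for the dose it is used as the base cost; otherwise
#' the parametric formula applies:
#' `unit_ingredient_cost * (dose/800) * loss_adjust / ingredient_share *
#' population / 1000`. Sensitivity variants scale the base cost by 0.8
#' (`low20`) or 1.2 (`high20`) before rounding half-up to the nearest
#' thousand euro.
#'
#' @param dose daily dose, IU (> 0).
#' @param model a [cost_model()].
#' @param variant `"base"`, `"low20"` or `"high20"`.
#' @return cost in thousand euro, rounded half-up to integer.
#' @examples
#' fortification_cost(400, variant = "low20")   # 12133
#' fortification_cost(1000, variant = "high20") # 26575
#' @export
fortification_cost <- function(dose, model = cost_model(),
                               variant = c("base", "low20", "high20")) {
  stopifnot(inherits(model, "cost_model"))
  variant <- match.arg(variant)
  if (!is.numeric(dose) || length(dose) != 1 || dose <= 0)
    vd_stop("domain", "dose must be a single positive number (IU/day)")
  key <- as.character(dose)
  if (!is.null(model$cost_overrides) && key %in% names(model$cost_overrides)) {
    base <- model$cost_overrides[[key]]
  } else {
    if (is.null(model$population))
      vd_stop("config",
              paste0("no cost override for dose ", dose,
                     " IU and no population set for the parametric formula"))
    loss_adjust <- if (model$loss_convention == "divide")
      1 / (1 - model$loss_fraction) else 1 + model$loss_fraction
    base <- model$unit_ingredient_cost * (dose / 800) * loss_adjust /
      model$component_shares[["ingredient"]] * model$population / 1000
  }
  scale <- c(base = 1, low20 = 0.8, high20 = 1.2)[[variant]]
  round_half_up(base * scale)
}

#' Savings from prevented cancer deaths
#'
#' End-of-life cancer care costs avoided, in thousand euro, computed on the
#' unrounded prevented-death count and then rounded half-up to the nearest
#' thousand euro.
#'
#' @param total_deaths total annual cancer deaths.
#' @param rrr relative risk reduction, fraction.
#' @param cost_per_death euro saved per prevented death.
#' @return savings in thousand euro (integer-valued).
#' @examples
#' savings(229827, 0.11)  # 1011239
#' @export
savings <- function(total_deaths, rrr, cost_per_death = 40000) {
  if (any(c(total_deaths, rrr, cost_per_death) < 0))
    vd_stop("domain", "savings inputs must be non-negative")
  round_half_up(deaths_prevented(total_deaths, rrr) * cost_per_death / 1000)
}

#' Net savings
#'
#' `savings - cost`, on the rounded thousand-euro values, so a published
#' table remains internally consistent row by row.
#'
#' @param savings,cost thousand euro.
#' @return net savings in thousand euro.
#' @export
net_savings <- function(savings, cost) savings - cost

#' Cost per life-year saved, disregarding savings
#'
#' @param cost program cost in thousand euro.
#' @param preventable_yll preventable years of life lost (> 0).
#' @return euro per life-year, rounded half-up to the whole euro.
#' @export
cost_per_life_year <- function(cost, preventable_yll) {
  if (cost == 0) return(0)
  if (!is.numeric(preventable_yll) || preventable_yll <= 0)
    vd_stop("domain", "preventable_yll must be positive")
  round_half_up(cost * 1000 / preventable_yll)
}

#' Savings-to-cost ratio
#'
#' @param savings,cost thousand euro; `cost` must be positive.
#' @return `savings / cost`, full precision.
#' @export
savings_cost_ratio <- function(savings, cost) {
  if (!is.numeric(cost) || any(cost <= 0))
    vd_stop("domain", "cost must be positive")
  savings / cost
}
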