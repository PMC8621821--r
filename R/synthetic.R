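# Synthetic inputs with the statistical structure the pipeline assumes:
# age/sex-stratified mortality tables, remaining-life-expectancy tables,
# and simulated study-effect sets for pooling recovery tests.

# standard 5-year age groups 0-4 ... 80-84, 85+
vd_age_groups <- function() {
  lo <- seq(0, 85, 5)
  hi <- c(seq(4, 84, 5), NA)
  data.frame(age_low = lo, age_high = hi)
}

#' Largest-remainder integer allocation
#'
#' Allocates an integer `total` across categories proportionally to
#' `weights`, conserving the total exactly: each category first receives
#' the floor of its exact share, then the remaining units go to the
#' categories with the largest fractional remainders (ties broken by
#' category order).
#'
#' @param total non-negative integer to allocate.
#' @param weights non-negative weights (normalized internally).
#' @return integer vector summing exactly to `total`.
#' @export
largest_remainder <- function(total, weights) {
  if (total < 0 || total != round(total))
    vd_stop("domain", "total must be a non-negative integer")
  if (any(weights < 0) || sum(weights) <= 0)
    vd_stop("domain", "weights must be non-negative with positive sum")
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Specification of a synthetic mortality table
#'
#' Age-at-death weights follow a discretized normal over the 18 five-year
#' group midpoints; the defaults place the mode in the 75-79 group, which
#' is where cancer mortality peaks in an aged Western population.
#'
#' @param total_deaths total annual cancer deaths to allocate (default
#'   229827, the Germany-2016 calibration back-solved from published
#'   scenario figures - not itself a registry-printed number).
#' @param age_location centre of the age-at-death distribution, years.
#' @param age_shape spread (standard deviation) of the distribution, years.
#' @param sex_split fraction of deaths among males (default 0.54).
#' @param seed integer seed (reserved for optional stochastic extensions;
#'   the default allocation is deterministic).
#' @return list of class `mortality_gen_spec`.
#' @export
mortality_gen_spec <- function(total_deaths = 229827, age_location = 77,
                               age_shape = 14, sex_split = 0.54, seed = 1L) {
  if (total_deaths <= 0)
    vd_stop("domain", "total_deaths must be positive")
  if (age_shape <= 0)
    vd_stop("domain", "age_shape must be positive")
  if (sex_split < 0 || sex_split > 1)
    vd_stop("domain", "sex_split must be a fraction in [0, 1]")
  structure(list(total_deaths = total_deaths, age_location = age_location,
                 age_shape = age_shape, sex_split = sex_split,
                 seed = as.integer(seed)),
            class = "mortality_gen_spec")
}

#' Generate an age/sex-stratified mortality table
#'
#' Deterministic for a fixed spec: the male/female split and the
#' discretized-normal age weights are turned into integer death counts by
#' largest-remainder allocation, so the generated table sums to
#' `total_deaths` exactly.
#'
#' @param spec a [mortality_gen_spec()].
#' @return a [mortality_table()] covering 0-4 ... 85+ for both sexes.
#' @export
gen_mortality_table <- function(spec = mortality_gen_spec()) {
  stopifnot(inherits(spec, "mortality_gen_spec"))
  grp <- vd_age_groups()
  mids <- age_midpoint(grp$age_low, grp$age_high)
  w <- stats::dnorm(mids, spec$age_location, spec$age_shape)
  w <- w / sum(w)
  by_sex <- largest_remainder(spec$total_deaths,
                              c(spec$sex_split, 1 - spec$sex_split))
  male <- largest_remainder(by_sex[1], w)
  female <- largest_remainder(by_sex[2], w)
  mortality_table(sex = rep(c("male", "female"), each = nrow(grp)),
                  age_low = rep(grp$age_low, 2),
                  age_high = rep(grp$age_high, 2),
                  deaths = c(male, female))
}

#' Generate a remaining-life-expectancy table
#'
#' Linear decline of remaining life expectancy with age,
#' `ex(age) = max(e0 - decline_rate * age, floor)`, tabulated at 5-year
#' ages 0 to `age_max` for both sexes. A stand-in for a period life table:
#' it preserves the structural features the burden computation relies on
#' (positivity, monotone decline, female >= male), not actuarial detail.
#' Defaults approximate Germany-2016 period life expectancy at birth.
#'
#' @param e0_male,e0_female life expectancy at birth, years.
#' @param decline_rate loss of remaining life expectancy per year of age
#'   (default 0.95).
#' @param floor minimum remaining life expectancy, years (default 1.5).
#' @param age_max oldest tabulated age (default 95, so every 5-year group
#'   midpoint up to 85+ is covered).
#' @return a [life_table()].
#' @export
gen_life_table <- function(e0_male = 78.2, e0_female = 83.1,
                           decline_rate = 0.95, floor = 1.5, age_max = 95) {
  if (e0_male <= 0 || e0_female <= 0)
    vd_stop("domain", "life expectancy at birth must be positive")
  if (decline_rate < 0)
    vd_stop("domain", "decline_rate must be non-negative")
  if (floor <= 0)
    vd_stop("domain", "life expectancy floor must be positive")
  ages <- seq(0, age_max, 5)
  life_table(sex = rep(c("male", "female"), each = length(ages)),
             age = rep(ages, 2),
             ex = c(pmax(e0_male - decline_rate * ages, floor),
                    pmax(e0_female - decline_rate * ages, floor)))
}

#' Simulate a set of study effects for pooling
#'
#' Draws `k` log relative risks from `Normal(true_log_rr, tau2)`, standard
#' errors uniform in `se_range`, and reports each study as RR with a 95%
#' CI (`exp(theta +/- 1.96 se)`) - the same shape as a published trial
#' table, so CI inversion and pooling can be exercised end to end with
#' known truth.
#'
#' @param k number of studies (>= 2).
#' @param true_log_rr true common log relative risk.
#' @param tau2 between-study variance of the log relative risk (>= 0).
#' @param se_range length-2 positive range of per-study standard errors.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a [study_effects()] table with labels `sim_01`, `sim_02`, ...
#' @export
gen_study_set <- function(k, true_log_rr = -0.14, tau2 = 0,
                          se_range = c(0.08, 0.3), seed = 1L) {
  if (k < 2) vd_stop("domain", "k must be at least 2")
  if (tau2 < 0) vd_stop("domain", "tau2 must be non-negative")
  if (length(se_range) != 2 || any(se_range <= 0) || se_range[1] > se_range[2])
    vd_stop("domain", "se_range must be a positive (lo, hi) pair")
  # draw under a private seed, restoring the caller's RNG state
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rng <- list(theta = stats::rnorm(k, true_log_rr, sqrt(tau2)),
              se = stats::runif(k, se_range[1], se_range[2]))
  study_effects(label = sprintf("sim_%02d", seq_len(k)),
                rr = exp(rng$theta),
                ci_low = exp(rng$theta - 1.96 * rng$se),
                ci_high = exp(rng$theta + 1.96 * rng$se))
}
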