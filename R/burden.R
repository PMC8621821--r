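#' Age/sex-stratified cancer mortality table
#'
#' One row per sex and 5-year age group with the number of cancer deaths.
#' The last group per sex may be open-ended (`age_high = NA`). Groups must
#' not overlap within a sex.
#'
#' @param sex character, `"male"`/`"female"`.
#' @param age_low,age_high integer bounds of the age group in years
#'   (inclusive, e.g. 70 and 74); `age_high = NA` marks the open-ended top
#'   group.
#' @param deaths non-negative death counts.
#' @return a `data.frame` of class `mortality_table`.
#' @export
mortality_table <- function(sex, age_low, age_high, deaths) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    vd_stop("domain", "sex must be 'male' or 'female'")
  age_low <- as.numeric(age_low); age_high <- as.numeric(age_high)
  deaths <- as.numeric(deaths)
  if (any(!is.finite(deaths)) || any(deaths < 0))
    vd_stop("domain", "deaths must be non-negative")
  if (any(!is.na(age_high) & age_high < age_low))
    vd_stop("domain", "age_high must be >= age_low")
  out <- data.frame(sex = sex, age_low = age_low, age_high = age_high,
                    deaths = deaths, stringsAsFactors = FALSE)
  out <- out[order(out$sex, out$age_low), ]
  for (s in unique(out$sex)) {
    g <- out[out$sex == s, ]
    hi <- ifelse(is.na(g$age_high), Inf, g$age_high)
    if (sum(is.infinite(hi)) > 1)
      vd_stop("domain", paste0("more than one open-ended group for sex ", s))
    if (nrow(g) > 1 && any(g$age_low[-1] <= hi[-nrow(g)]))
      vd_stop("domain", paste0("overlapping age groups for sex ", s))
  }
  rownames(out) <- NULL
  class(out) <- c("mortality_table", "data.frame")
  out
}

#' Remaining-life-expectancy table
#'
#' @param sex character, `"male"`/`"female"`.
#' @param age exact ages in years.
#' @param ex remaining life expectancy at `age`, in years; must be positive
#'   and non-increasing with age within each sex.
#' @return a `data.frame` of class `life_table`.
#' @export
life_table <- function(sex, age, ex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    vd_stop("domain", "sex must be 'male' or 'female'")
  age <- as.numeric(age); ex <- as.numeric(ex)
  if (any(!is.finite(ex)) || any(ex <= 0))
    vd_stop("domain", "remaining life expectancy must be positive")
  out <- data.frame(sex = sex, age = age, ex = ex, stringsAsFactors = FALSE)
  out <- out[order(out$sex, out$age), ]
  for (s in unique(out$sex)) {
    e <- out$ex[out$sex == s]
    if (any(diff(e) > 1e-9))
      vd_stop("domain",
              paste0("remaining life expectancy must be non-increasing in age (sex ", s, ")"))
  }
  rownames(out) <- NULL
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read mortality / life tables from CSV
#'
#' `read_mortality_csv()` expects a header `sex,age_low,age_high,deaths`
#' (empty `age_high` = open-ended group); `read_life_csv()` expects
#' `sex,age,ex`.
#'
#' @param path path to a CSV file.
#' @return a [mortality_table()] or [life_table()].
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mortality_table(df$sex, df$age_low, df$age_high, df$deaths)
}

#' @rdname read_mortality_csv
#' @export
read_life_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  life_table(df$sex, df$age, df$ex)
}

#' Midpoint of an age group
#'
#' Closed groups spanning integer ages `[lo, hi]` cover `hi - lo + 1` years
#' of age, so the midpoint is `(lo + hi + 1) / 2` (72.5 for 70-74). The
#' open-ended top group has no upper bound; an effective midpoint of
#' `lo + open_offset` is used (default offset 2.5 years).
#'
#' @param age_low,age_high group bounds; `NA` `age_high` = open-ended.
#' @param open_offset years added to `age_low` for the open-ended group.
#' @return midpoint ages in years.
#' @export
age_midpoint <- function(age_low, age_high, open_offset = 2.5) {
  ifelse(is.na(age_high), age_low + open_offset, (age_low + age_high + 1) / 2)
}

# remaining LE at exact ages, linearly interpolated within sex
le_lookup <- function(life, sex, ages) {
  stopifnot(inherits(life, "life_table"))
  out <- numeric(length(ages))
  for (s in unique(sex)) {
    i <- sex == s
    tab <- life[life$sex == s, ]
    if (nrow(tab) == 0 || any(ages[i] < min(tab$age)) || any(ages[i] > max(tab$age))) {
      miss <- if (nrow(tab) == 0) ages[i] else
        ages[i][ages[i] < min(tab$age) | ages[i] > max(tab$age)]
      vd_stop("coverage",
              paste0("life table does not cover: ",
                     paste(sprintf("(%s, %.1f)", s, miss), collapse = ", ")))
    }
    out[i] <- stats::approx(tab$age, tab$ex, xout = ages[i],
                            method = "linear", ties = "ordered")$y
  }
  out
}

#' Total years of life lost
#'
#' Deaths in each (sex, 5-year age group) cell are multiplied by the
#' remaining life expectancy at the group midpoint and summed over all
#' cells. Midpoints not tabulated in the life table are linearly
#' interpolated; midpoints outside its age range raise a coverage error
#' listing the missing strata.
#'
#' @param deaths a [mortality_table()].
#' @param life a [life_table()].
#' @param open_offset midpoint convention for the open-ended top group,
#'   see [age_midpoint()].
#' @return list of class `burden_summary` with `total_deaths` and
#'   `total_yll` (person-years).
#' @export
total_yll <- function(deaths, life, open_offset = 2.5) {
  stopifnot(inherits(deaths, "mortality_table"))
  if (nrow(deaths) == 0) {
    out <- list(total_deaths = 0, total_yll = 0)
  } else {
    mids <- age_midpoint(deaths$age_low, deaths$age_high, open_offset)
    le <- le_lookup(life, deaths$sex, mids)
    out <- list(total_deaths = sum(deaths$deaths),
                total_yll = sum(deaths$deaths * le))
  }
  class(out) <- "burden_summary"
  out
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("Total deaths: %s; total YLL: %s person-years\n",
              format(x$total_deaths, big.mark = ","),
              format(round(x$total_yll), big.mark = ",")))
  invisible(x)
}

#' Back-solve the total death count from an anchor scenario
#'
#' Given the prevented-death count published for one scenario and its
#' relative risk reduction, recovers the implied total annual cancer death
#' count `T = round(prevented / rrr)`.
#'
#' @param prevented_at_anchor prevented deaths in the anchor scenario.
#' @param rrr_anchor the anchor's relative risk reduction, in (0, 1).
#' @return implied total deaths (integer-valued).
#' @examples
#' calibrate_total_deaths(25281, 0.11)  # 229827
#' @export
calibrate_total_deaths <- function(prevented_at_anchor, rrr_anchor) {
  if (!is.numeric(prevented_at_anchor) || prevented_at_anchor <= 0)
    vd_stop("domain", "prevented_at_anchor must be positive")
  if (!is.numeric(rrr_anchor) || rrr_anchor <= 0 || rrr_anchor >= 1)
    vd_stop("domain", "rrr_anchor must be in (0, 1)")
  round_half_up(prevented_at_anchor / rrr_anchor)
}

#' Cancer deaths prevented at a given relative risk reduction
#'
#' Returns the unrounded product `total_deaths * rrr`; downstream savings
#' chain from the unrounded value, display tables round half-up.
#'
#' @param total_deaths total annual cancer deaths (>= 0).
#' @param rrr relative risk reduction, fraction in `[0, 1]`.
#' @return prevented deaths (unrounded).
#' @export
deaths_prevented <- function(total_deaths, rrr) {
  if (!is.numeric(total_deaths) || any(total_deaths < 0))
    vd_stop("domain", "total_deaths must be non-negative")
  if (!is.numeric(rrr) || any(rrr < 0 | rrr > 1))
    vd_stop("domain", "rrr must be a fraction in [0, 1]")
  total_deaths * rrr
}

#' Preventable years of life lost
#'
#' @param total_yll total YLL, person-years (>= 0).
#' @param rrr relative risk reduction, fraction in `[0, 1]`.
#' @return preventable YLL (unrounded person-years).
#' @export
preventable_yll <- function(total_yll, rrr) {
  if (!is.numeric(total_yll) || any(total_yll < 0))
    vd_stop("domain", "total_yll must be non-negative")
  if (!is.numeric(rrr) || any(rrr < 0 | rrr > 1))
    vd_stop("domain", "rrr must be a fraction in [0, 1]")
  total_yll * rrr
}
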