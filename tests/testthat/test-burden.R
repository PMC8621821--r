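# deaths, years of life lost, and back-calibration of totals

test_that("total YLL matches the hand-computed toy case", {
  b <- total_yll(toy_deaths(), toy_life())
  expect_equal(b$total_deaths, 150)
  expect_equal(b$total_yll, 100 * 14.5 + 50 * 8.9)  # 1895
})

test_that("empty mortality table gives zero burden", {
  empty <- mortality_table(character(), numeric(), numeric(), numeric())
  b <- total_yll(empty, toy_life())
  expect_equal(b$total_deaths, 0)
  expect_equal(b$total_yll, 0)
})

test_that("total YLL agrees with the double-loop oracle on random tables", {
  for (seed in 1:5) {
    tabs <- random_tables(seed)
    expect_equal(total_yll(tabs$deaths, tabs$life)$total_yll,
                 oracle_yll(tabs$deaths, tabs$life), tolerance = 1e-9)
  }
})

test_that("YLL is additive over death-count splits", {
  tabs <- random_tables(7)
  d <- tabs$deaths
  half <- d; half$deaths <- d$deaths * 0.4
  rest <- d; rest$deaths <- d$deaths * 0.6
  expect_equal(total_yll(half, tabs$life)$total_yll +
                 total_yll(rest, tabs$life)$total_yll,
               total_yll(d, tabs$life)$total_yll, tolerance = 1e-9)
})

test_that("age midpoints follow the (lo + hi + 1)/2 and open-group conventions", {
  expect_equal(age_midpoint(70, 74), 72.5)
  expect_equal(age_midpoint(0, 4), 2.5)
  expect_equal(age_midpoint(85, NA), 87.5)
  expect_equal(age_midpoint(85, NA, open_offset = 5), 90)
})

test_that("life-table lookup interpolates and reports missing strata", {
  life <- life_table(rep("male", 3), c(70, 75, 80), c(15, 12, 9))
  d <- mortality_table("male", 70, 74, 10)  # midpoint 72.5 not tabulated
  expect_equal(total_yll(d, life)$total_yll, 10 * 13.5)

  d2 <- mortality_table("male", 85, NA, 10)  # midpoint 87.5 beyond table
  expect_error(total_yll(d2, life), regexp = "87.5", class = "vdfort_coverage")
  d3 <- mortality_table("female", 70, 74, 10)  # sex absent from table
  expect_error(total_yll(d3, life), class = "vdfort_coverage")
})

test_that("table constructors validate their invariants", {
  expect_error(mortality_table("male", c(70, 72), c(74, 76), c(1, 1)),
               class = "vdfort_domain")
  expect_error(mortality_table("male", 70, 74, -1), class = "vdfort_domain")
  expect_error(mortality_table("other", 70, 74, 1), class = "vdfort_domain")
  expect_error(life_table(c("male", "male"), c(70, 75), c(10, 11)),
               class = "vdfort_domain")
  expect_error(life_table("male", 70, 0), class = "vdfort_domain")
})

test_that("total deaths back-calibrate from an anchor scenario", {
  expect_equal(calibrate_total_deaths(25281, 0.11), 229827)
  expect_equal(calibrate_total_deaths(100, 0.5), 200)
  # recovery: for any true total T, rounding T*r and back-solving stays
  # within 1/r of the truth
  set.seed(3)
  for (i in 1:25) {
    T <- sample.int(5e5, 1)
    r <- runif(1, 0.05, 0.5)
    expect_lte(abs(calibrate_total_deaths(round_half_up(T * r), r) - T), 1 / r)
  }
  expect_error(calibrate_total_deaths(0, 0.1), class = "vdfort_domain")
  expect_error(calibrate_total_deaths(100, 1.2), class = "vdfort_domain")
})

test_that("prevented deaths and preventable YLL scale as expected", {
  expect_equal(round_half_up(deaths_prevented(229827, 0.11)), 25281)
  expect_equal(round_half_up(deaths_prevented(229827, 0.15)), 34474)
  expect_equal(deaths_prevented(12345, 0), 0)
  expect_equal(preventable_yll(2.8e6, 0.11), 308000)
  expect_equal(preventable_yll(777, 1), 777)
  expect_equal(preventable_yll(1895, 0.13), 246.35)

  # monotone in rrr, homogeneous of degree 1 in the burden input
  rr <- seq(0, 1, 0.1)
  expect_true(all(diff(deaths_prevented(1000, rr)) >= 0))
  expect_true(all(diff(preventable_yll(1000, rr)) >= 0))
  expect_equal(deaths_prevented(3 * 1000, 0.2), 3 * deaths_prevented(1000, 0.2))
  expect_equal(preventable_yll(3 * 1000, 0.2), 3 * preventable_yll(1000, 0.2))

  expect_error(deaths_prevented(100, 1.5), class = "vdfort_domain")
  expect_error(preventable_yll(-1, 0.5), class = "vdfort_domain")
})

test_that("calibrated synthetic burden lands near the back-solved total YLL", {
  b <- total_yll(gen_mortality_table(), gen_life_table())
  expect_equal(b$total_deaths, 229827)
  expect_lt(abs(b$total_yll - 2.8e6) / 2.8e6, 0.05)
})

test_that("mortality and life-table CSV round-trips preserve the tables", {
  d <- toy_deaths(); l <- toy_life()
  fd <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  write.csv(d, fd, row.names = FALSE)
  write.csv(l, fl, row.names = FALSE)
  expect_equal(as.data.frame(read_mortality_csv(fd)), as.data.frame(d))
  expect_equal(as.data.frame(read_life_csv(fl)), as.data.frame(l))
})
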