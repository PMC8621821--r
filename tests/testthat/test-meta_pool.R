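# random-effects pooling of study-level relative risks

test_that("CI inversion recovers log effect and standard error", {
  s <- study_effects("a", 0.89, 0.77, 1.03)
  le <- log_effect_from_ci(s)
  expect_equal(le$theta, log(0.89), tolerance = 1e-12)
  expect_equal(le$theta, -0.1165, tolerance = 1e-3)
  expect_equal(le$se, (log(1.03) - log(0.77)) / 3.92, tolerance = 1e-12)
  expect_equal(le$se, 0.0742, tolerance = 1e-3)

  # Scragg row, the widest CI in the evidence base
  le2 <- log_effect_from_ci(study_effects("s", 0.99, 0.60, 1.64))
  expect_equal(le2$se, 0.2565, tolerance = 1e-3)

  # symmetric CI around the null: theta 0, se = ln(k)/z for any width k
  for (k in c(1.2, 2, 5)) {
    le3 <- log_effect_from_ci(study_effects("n", 1, 1 / k, k))
    expect_equal(le3$theta, 0, tolerance = 1e-12)
    expect_equal(le3$se, log(k) / 1.96, tolerance = 1e-12)
  }
})

test_that("invalid studies are rejected with the offending label", {
  expect_error(study_effects("bad", 0.9, 1.1, 1.3), class = "vdfort_invalid_study")
  expect_error(study_effects("neg", -0.5, 0.3, 0.7), class = "vdfort_invalid_study")
  expect_error(study_effects(c("a", "flat"), c(0.9, 0.8), c(0.8, 0.8), c(1.0, 0.8)),
               regexp = "flat", class = "vdfort_invalid_study")
  expect_error(study_effects(c("a", "a"), c(0.9, 0.9), c(0.8, 0.8), c(1, 1)),
               class = "vdfort_invalid_study")
})

test_that("DL heterogeneity matches hand-computed cases", {
  # five-trial evidence base: frozen oracle values from a direct expansion
  le <- log_effect_from_ci(keum2019_studies())
  het <- dl_tau2(le$theta, le$se)
  expect_equal(het$q, 0.5868, tolerance = 1e-3)
  expect_identical(het$tau2, 0)

  # identical effects: no heterogeneity at all
  het0 <- dl_tau2(rep(-0.1, 4), rep(0.2, 4))
  expect_equal(het0$q, 0, tolerance = 1e-12)
  expect_identical(het0$tau2, 0)

  # two-study case solvable by hand: Q = 50, tau2 = 49/100
  het2 <- dl_tau2(c(0, 1), c(0.1, 0.1))
  expect_equal(het2$q, 50, tolerance = 1e-9)
  expect_equal(het2$tau2, 0.49, tolerance = 1e-9)

  expect_error(dl_tau2(0.1, 0.1), class = "vdfort_insufficient_studies")
})

test_that("pooling the five-trial evidence base gives 0.87 (0.79-0.96)", {
  p <- pool_random_effects(keum2019_studies())
  expect_equal(round_half_up(p$rr, 2), 0.87)
  expect_equal(round_half_up(p$ci_low, 2), 0.79)
  expect_equal(round_half_up(p$ci_high, 2), 0.96)
  # full-precision values frozen from the hand-expanded oracle
  expect_equal(p$rr, 0.8695471, tolerance = 1e-6)
  expect_equal(p$ci_low, 0.7879150, tolerance = 1e-6)
  expect_equal(p$ci_high, 0.9596369, tolerance = 1e-6)
  expect_equal(format(p), "0.87 (0.79-0.96)")
})

test_that("pooling invariants hold", {
  studies <- keum2019_studies()
  p <- pool_random_effects(studies)
  expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  expect_gte(p$rr, min(studies$rr))
  expect_lte(p$rr, max(studies$rr))
  expect_true(p$ci_low < p$rr && p$rr < p$ci_high)

  # duplicating a study set halves the pooled variance, not the estimate
  dup <- study_effects(c(studies$label, paste0(studies$label, " copy")),
                       rep(studies$rr, 2), rep(studies$ci_low, 2),
                       rep(studies$ci_high, 2))
  pd <- pool_random_effects(dup)
  expect_equal(pd$rr, p$rr, tolerance = 1e-12)
  expect_equal(pd$se, p$se / sqrt(2), tolerance = 1e-12)

  # with tau2 = 0 the random-effects result equals fixed effect exactly
  le <- log_effect_from_ci(studies)
  w <- 1 / le$se^2
  expect_identical(p$tau2, 0)
  expect_equal(p$theta, sum(w * le$theta) / sum(w), tolerance = 1e-15)
})

test_that("pooled estimate matches the hand-expanded oracle for small k", {
  cases <- list(
    list(rr = c(0.8, 1.1), lo = c(0.6, 0.9), hi = c(1.07, 1.35)),
    list(rr = c(0.7, 0.95, 1.2), lo = c(0.5, 0.8, 0.9), hi = c(0.98, 1.13, 1.6))
  )
  for (cs in cases) {
    s <- study_effects(paste0("s", seq_along(cs$rr)), cs$rr, cs$lo, cs$hi)
    le <- log_effect_from_ci(s)
    expect_equal(pool_random_effects(s)$theta,
                 oracle_pooled_theta(le$theta, le$se), tolerance = 1e-12)
  }
})

test_that("simulated pooling recovers the true effect", {
  s <- gen_study_set(k = 50, true_log_rr = -0.14, tau2 = 0.01, seed = 11)
  p <- pool_random_effects(s)
  expect_lt(abs(p$theta - (-0.14)), 2 * p$se)
})

test_that("leave-one-out pooling behaves", {
  studies <- keum2019_studies()
  # dropping the bolus-dosing trial leaves the point estimate at 0.87
  p <- leave_one_out(studies, "Scragg 2018")
  expect_equal(round_half_up(p$rr, 2), 0.87)
  expect_equal(p$k, 4)

  # excluding a study sitting exactly at the pooled mean leaves rr unchanged
  p0 <- pool_random_effects(studies)
  at_mean <- study_effects("at mean", p0$rr, p0$rr * exp(-1.96 * 0.1),
                           p0$rr * exp(1.96 * 0.1))
  aug <- study_effects(c(studies$label, "at mean"),
                       c(studies$rr, at_mean$rr),
                       c(studies$ci_low, at_mean$ci_low),
                       c(studies$ci_high, at_mean$ci_high))
  expect_equal(round_half_up(leave_one_out(aug, "at mean")$rr, 2),
               round_half_up(p0$rr, 2))

  # every leave-one-out result is a valid pooled effect
  for (lab in studies$label) {
    pl <- leave_one_out(studies, lab)
    expect_gte(pl$tau2, 0)
    expect_equal(sum(pl$weights), 1, tolerance = 1e-12)
  }

  expect_error(leave_one_out(studies, "nope"), class = "vdfort_lookup")
  two <- study_effects(c("a", "b"), c(0.9, 0.8), c(0.7, 0.6), c(1.1, 1.0))
  expect_error(leave_one_out(two, "a"), class = "vdfort_insufficient_studies")
})

test_that("flat RRR cross-check from the pooled effect is 0.13", {
  expect_equal(rrr_from_pooled(pool_random_effects(keum2019_studies())), 0.13)
})
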