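test_that("nonresponder death/progression split follows the 12-month anchors", {
  s <- nonresponder_split(0.4, 0.7)
  expect_equal(unname(s), c(0.5, 0.5))
  expect_equal(sum(s), 1)
  expect_equal(unname(nonresponder_split(0.3, 0.3)), c(1, 0))
  expect_equal(unname(nonresponder_split(0.3, 1)), c(0, 1))
  expect_error(nonresponder_split(1, 1), "no nonresponders")
  expect_error(nonresponder_split(0.5, 0.4), "ordering")
})

test_that("a single anchor converts to a constant monthly event probability", {
  expect_equal(monthly_rate_from_anchor(12, 1), 0)
  expect_equal(monthly_rate_from_anchor(12, exp(-1.2)), 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(monthly_rate_from_anchor(1, 0.5), 0.5)
  expect_error(monthly_rate_from_anchor(12, 0), "infinite hazard")
})

test_that("exponential fit recovers rates from anchors", {
  # noiseless recovery through multiple anchors
  a <- tibble::tibble(month = c(6, 12, 18), survival = exp(-0.08 * c(6, 12, 18)))
  expect_equal(fit_exponential(a), 0.08, tolerance = 1e-9)
  # single anchor: closed form
  expect_equal(fit_exponential(data.frame(month = 12, survival = 0.375)),
               -log(0.375) / 12, tolerance = 1e-12)
  expect_error(fit_exponential(data.frame(month = 12, survival = 0)), "degenerate")
})

test_that("exponential fit is unbiased under small log-scale noise", {
  lambda0 <- 0.1
  est <- sapply(1:100, function(s) {
    fit_exponential(generate_survival_anchors(lambda0, c(6, 12, 18),
                                              noise_sd = 0.01, seed = s))
  })
  expect_lt(abs(mean(est) - lambda0) / lambda0, 0.02)
})

test_that("post-progression survival is a mean-matched geometric process", {
  expect_equal(post_progression_death_prob(5.4), 1 / 5.4)
  expect_equal(post_progression_death_prob(1), 1)
  expect_equal(post_progression_death_prob(0.5), 1) # capped
  expect_error(post_progression_death_prob(0), "invalid mean")
  # Monte-Carlo sojourn check: mean months in progression = mean_pps
  withr::with_seed(7, {
    sojourn <- stats::rgeom(1e5, post_progression_death_prob(10)) + 1
    expect_lt(abs(mean(sojourn) - 10), 0.1)
  })
})

test_that("responder schedules carry the fitted progression hazard from cycle 1", {
  p <- toy_params("LT1", r_combo = 0.5, r_mono = 0.25, anchor_survival = 0.375)
  sched <- build_schedule(p, "IMMUNOCHEMO", responder = TRUE)
  expect_equal(sched$p_prog, rep(1 - 0.375^(1 / 12), 60), tolerance = 1e-12)
  expect_equal(sched$p_prog[1], 0.07848, tolerance = 1e-4)
  # alternative mode: progression-free during the 12-month response window
  p2 <- as_parameter_set(modifyList(unclass(p),
                                    list(options = list(responder_pfs_mode = "after_12m"))))
  sched2 <- build_schedule(p2, "IMMUNOCHEMO", responder = TRUE)
  expect_equal(sched2$p_prog[1:12], rep(0, 12))
  expect_equal(sched2$p_prog[13:60], sched$p_prog[13:60])
})

test_that("the dying nonresponder stream is fully dead by the 12-month boundary", {
  p <- toy_params("LT1", r_combo = 0.4, r_mono = 0.2, pfs12 = 0.4, os12 = 0.7)
  sched <- build_schedule(p, "IMMUNOCHEMO", responder = FALSE)
  expect_equal(unname(sched$split), unname(nonresponder_split(0.4, 0.7)))
  expect_equal(sched$h_die[12], 1)
  expect_true(all(sched$h_die[13:60] == 0))
  surv <- cumprod(1 - sched$h_die[1:12])
  expect_equal(surv[12], 0, tolerance = 1e-12)
  # hazards follow the OS-anchor exponential shape before the boundary
  expect_true(all(diff(sched$h_die[1:11]) > 0)) # rescaling makes them increase
})

test_that("the progressing stream jumps deterministically after the mean progression time", {
  p <- toy_params("LT1", r_combo = 1e-9, r_mono = 0, pfs12 = 1e-9, os12 = 1,
                  t_prog = 9, q_x = 0)
  d <- initial_distribution(p, "CURRENT_PRACTICE")
  tr <- run_cohort(d, build_schedules(p, d))
  agg <- tidy(tr)
  expect_equal(agg$progression[agg$cycle == 9], 0, tolerance = 1e-6)
  expect_equal(agg$progression[agg$cycle == 10], 1, tolerance = 1e-6)
})

test_that("no background mortality means no other-cause deaths anywhere", {
  p <- toy_params("LT1", r_combo = 0.4, r_mono = 0.2, pfs12 = 0.4, os12 = 0.7,
                  anchor_survival = 0.4, q_x = 0, mean_pps = 5.4)
  d <- initial_distribution(p, "CURRENT_PRACTICE")
  tr <- run_cohort(d, build_schedules(p, d))
  expect_true(all(tr$death_other == 0))
})

test_that("schedule probabilities conserve mass at every cycle", {
  sched <- build_schedule(toy_params("GE50", r_combo = 0.6, r_mono = 0.375,
                                     pfs12 = 0.375, os12 = 0.6, q_x = 0.002,
                                     anchor_survival = 0.375, mean_pps = 5.4),
                          "IMMUNO", responder = FALSE)
  s <- tidy(sched)
  expect_true(all(s$p_death_disease >= 0 & s$p_death_disease <= 1))
  expect_true(all(s$p_death_other == 0.002))
})
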