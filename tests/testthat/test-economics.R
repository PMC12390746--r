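test_that("side-effect aggregates are prevalence-weighted sums", {
  expect_equal(aggregate_disutility(NULL), 0)
  expect_equal(aggregate_side_effect_cost(NULL), 0)
  one <- data.frame(name = "a", prevalence = 0.5, disutility = 0.1, cost = 0)
  expect_equal(aggregate_disutility(one), 0.05)
  two <- data.frame(name = c("a", "b"), prevalence = c(0.2, 0.3),
                    disutility = c(0.1, 0.2), cost = c(1000, 500))
  expect_equal(aggregate_disutility(two), 0.08)
  expect_equal(aggregate_side_effect_cost(two), 350)
  expect_equal(aggregate_side_effect_cost(
    data.frame(name = "a", prevalence = 0.1, disutility = 0, cost = 1000)), 100)
})

test_that("monthly discount factors follow annual compounding", {
  expect_equal(discount_factor(0, 0.04), 1)
  expect_equal(discount_factor(0, 0), 1)
  expect_equal(discount_factor(12, 0.04), 1 / 1.04, tolerance = 1e-12)
  expect_equal(discount_factor(24, 0.015), 1.015^-2, tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.04), "cycle")
  expect_error(discount_factor(12, 1), "annual_rate")
})

test_that("an immortal full-utility cohort accrues the horizon bound in QALYs", {
  p <- toy_params("LT1", r_combo = 1, u_response = 1, horizon = 60)
  out <- run_strategy(p, "CURRENT_PRACTICE")
  expect_equal(out$qalys, 5, tolerance = 1e-12)
  expect_equal(out$costs, 0)

  # with health discounting: closed-form geometric sum
  p2 <- toy_params("LT1", r_combo = 1, u_response = 1, horizon = 60,
                   discount_health = 0.015)
  out2 <- run_strategy(p2, "CURRENT_PRACTICE")
  expect_equal(out2$qalys, sum(1.015^(-(1:60) / 12)) / 12, tolerance = 1e-12)
  expect_equal(out2$qalys_undiscounted, 5, tolerance = 1e-12)
})

test_that("medication is paid per on-treatment cycle until progression", {
  p <- toy_params("LT1", r_combo = 1e-9, r_mono = 0, pfs12 = 1e-9, os12 = 1,
                  t_prog = 10, q_x = 0, med_cost = 1000)
  out <- run_strategy(p, "CURRENT_PRACTICE")
  # deterministic progression after 10 on-treatment months
  expect_equal(out$costs, 10000, tolerance = 1e-6)
})

test_that("discontinuation and terminal-care one-time costs attach to their transitions", {
  # whole cohort progresses at month 4 and dies of disease at month 5
  sched <- transition_schedule("IMMUNOCHEMO", FALSE, 24,
                               split = c(p_death = 0, p_progress = 1),
                               h_die = rep(0, 24), jump_cycle = 4,
                               p_pps = 1, q_x = rep(0, 24))
  d <- manual_distribution(one_time_cost = 950)
  tr <- run_cohort(d, list(IMMUNOCHEMO.nonresponder = sched))
  p <- toy_params("LT1", r_combo = 0.5, r_mono = 0.25, med_cost = 1000,
                  disc_cost = 300, terminal = 7000,
                  state_cost_progression = 200, horizon = 24)
  out <- accumulate_outcomes(tr, p)
  expect_equal(out$costs, 950 + 3 * 1000 + 300 + 200 + 7000)
  # utilities: three on-treatment months, one progressed month
  p_u <- toy_params("LT1", r_combo = 0.5, r_mono = 0.25,
                    u_response = 0.8, u_progression = 0.6, horizon = 24)
  out_u <- accumulate_outcomes(tr, p_u)
  expect_equal(out_u$qalys, (3 * 0.8 + 1 * 0.6) / 12, tolerance = 1e-12)
})

test_that("under a fixed duration rule medication and its stop cost end at the fixed month", {
  sched <- transition_schedule("IMMUNOCHEMO", FALSE, 24,
                               split = c(p_death = 0, p_progress = 1),
                               h_die = rep(0, 24), jump_cycle = 10,
                               p_pps = 0, q_x = rep(0, 24))
  tr <- run_cohort(manual_distribution(), list(IMMUNOCHEMO.nonresponder = sched))
  p <- toy_params("LT1", r_combo = 0.5, r_mono = 0.25, med_cost = 1000,
                  disc_cost = 300, duration_rule = "FIXED_MONTHS",
                  fixed_months = 4, horizon = 24)
  out <- accumulate_outcomes(tr, p)
  expect_equal(out$costs, 4 * 1000 + 300)
})

test_that("side-effect burden applies only while on medication", {
  se <- data.frame(name = "ae", prevalence = 0.5, disutility = 0.2, cost = 100)
  sched <- transition_schedule("IMMUNOCHEMO", FALSE, 24,
                               split = c(p_death = 0, p_progress = 1),
                               h_die = rep(0, 24), jump_cycle = 4,
                               p_pps = 0, q_x = rep(0, 24))
  tr <- run_cohort(manual_distribution(), list(IMMUNOCHEMO.nonresponder = sched))
  p <- toy_params("LT1", r_combo = 0.5, r_mono = 0.25, u_response = 0.8,
                  u_progression = 0.6, side_effects = se, horizon = 24)
  out <- accumulate_outcomes(tr, p)
  # 3 months on medication at utility 0.8 - 0.1, then progressed at 0.6
  expect_equal(out$qalys, (3 * 0.7 + 21 * 0.6) / 12, tolerance = 1e-12)
  expect_equal(out$costs, 3 * 50)
})

test_that("disabling discounting equates discounted and undiscounted outcomes", {
  p <- generate_parameter_set("LT1", seed = 6)
  p <- set_parameter(p, "economics.discount_rate_health", 0)
  p <- set_parameter(p, "economics.discount_rate_cost", 0)
  out <- run_strategy(p, "BIOMARKER")
  expect_equal(out$qalys, out$qalys_undiscounted, tolerance = 1e-12)
  expect_equal(out$costs, out$costs_undiscounted, tolerance = 1e-12)
})

test_that("QALYs rise with state utilities and fall with disutilities", {
  p <- generate_parameter_set("PD1_49", seed = 8)
  base <- run_strategy(p, "CURRENT_PRACTICE")$qalys
  up <- run_strategy(set_parameter(p, "economics.u_response",
                                   min(1, p$economics$u_response + 0.05)),
                     "CURRENT_PRACTICE")$qalys
  expect_gt(up, base)
  se <- p$regimens$IMMUNOCHEMO$side_effects
  se$disutility <- se$disutility + 0.05
  worse <- run_strategy(set_parameter(p, "regimens.IMMUNOCHEMO.side_effects", se),
                        "CURRENT_PRACTICE")$qalys
  expect_lt(worse, base)
})

test_that("incremental comparisons reproduce the published headroom deltas", {
  # PD-L1 <1%: current practice vs perfect-test biomarker strategy
  lt1 <- compare_outcomes(strategy_outcome(0.825, 155968),
                          strategy_outcome(0.780, 125654), threshold = 80000)
  expect_equal(lt1$delta_cost, -30314)
  expect_equal(lt1$quadrant, "lost")
  expect_true(lt1$cost_effective)
  expect_gt(lt1$icer, 80000)

  pd149 <- compare_outcomes(strategy_outcome(0.903, 175837),
                            strategy_outcome(0.884, 151734), threshold = 80000)
  expect_equal(pd149$delta_cost, -24103)
  expect_true(pd149$cost_effective)

  ge50 <- compare_outcomes(strategy_outcome(0.842, 106922),
                           strategy_outcome(1.369, 247347), threshold = 80000)
  expect_equal(ge50$delta_qaly, 0.527)
  expect_equal(ge50$quadrant, "gained")
  expect_false(ge50$cost_effective)
  expect_gt(ge50$icer, 80000)
})

test_that("comparison quadrants and verdicts cover dominance and cost minimisation", {
  dom <- compare_outcomes(strategy_outcome(1, 100), strategy_outcome(1.2, 50))
  expect_equal(dom$quadrant, "dominant")
  expect_true(dom$cost_effective)
  expect_true(is.na(dom$icer))
  dtd <- compare_outcomes(strategy_outcome(1.2, 50), strategy_outcome(1, 100))
  expect_equal(dtd$quadrant, "dominated")
  expect_false(dtd$cost_effective)
  cm <- compare_outcomes(strategy_outcome(1, 100), strategy_outcome(1, 80))
  expect_equal(cm$quadrant, "cost_minimisation")
  expect_true(cm$cost_effective)
})

test_that("swapping reference and comparator negates deltas and flips the quadrant", {
  withr::with_seed(11, {
    flip <- c(gained = "lost", lost = "gained", dominant = "dominated",
              dominated = "dominant", cost_minimisation = "cost_minimisation")
    for (i in 1:25) {
      a <- strategy_outcome(runif(1, 0.1, 2), runif(1, 1e4, 3e5))
      b <- strategy_outcome(runif(1, 0.1, 2), runif(1, 1e4, 3e5))
      ab <- compare_outcomes(a, b)
      ba <- compare_outcomes(b, a)
      expect_equal(ba$delta_qaly, -ab$delta_qaly)
      expect_equal(ba$delta_cost, -ab$delta_cost)
      expect_equal(ba$quadrant, unname(flip[ab$quadrant]))
    }
  })
})
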