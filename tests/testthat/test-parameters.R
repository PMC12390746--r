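test_that("conditional response to the comparator matches the published ratios", {
  # pooled trial rates: combination vs chemotherapy alone
  expect_equal(response_given_comparator(0.328, 0.193), 0.193 / 0.328, tolerance = 1e-12)
  expect_lt(abs(response_given_comparator(0.328, 0.193) - 0.587), 0.005)
  expect_equal(response_given_comparator(0.429, 0.177), 0.4126, tolerance = 1e-3)
  for (r in c(0.05, 0.3, 1)) expect_equal(response_given_comparator(r, r), 1)
  expect_error(response_given_comparator(0, 0), "undefined rate")
  expect_error(response_given_comparator(0.3, 0.4), "nesting violation")
})

test_that("hazard-ratio conversion reproduces the published response rate", {
  expect_equal(hr_to_response_rate(0.375, 1.81), 1 - 0.625 / 1.81, tolerance = 1e-12)
  expect_lt(abs(hr_to_response_rate(0.375, 1.81) - 0.655), 0.0005)
  expect_equal(hr_to_response_rate(0.42, 1), 0.42)
  expect_equal(hr_to_response_rate(0.5, 2), 0.75)
  expect_error(hr_to_response_rate(0.5, 0), "hazard ratio")
  expect_error(hr_to_response_rate(0.5, -1), "hazard ratio")
})

test_that("hazard-ratio conversion is monotone in hr and clips to [0, 1]", {
  hrs <- c(0.5, 0.8, 1, 1.5, 2, 5)
  vals <- hr_to_response_rate(0.375, hrs)
  expect_true(all(diff(vals) > 0))
  expect_equal(hr_to_response_rate(0.1, 0.5), 0) # clipped at zero
  expect_equal(hr_to_response_rate(0.375, 1.81, mode = "hazard_power"),
               0.375^(1 / 1.81))
})

test_that("crossover rate recovers the published rescue fraction", {
  expect_equal(crossover_response_rate(0.655, 0.375), 0.448, tolerance = 1e-12)
  for (r in c(0.1, 0.5, 0.9)) expect_equal(crossover_response_rate(r, r), 0)
  expect_equal(crossover_response_rate(1, 0.5), 1)
  expect_error(crossover_response_rate(1, 1), "no nonresponders")
})

test_that("conditional and crossover rates jointly reconstruct the 2x2 responder table", {
  grid <- expand.grid(r_combo = c(0.2, 0.45, 0.7, 1), frac = c(0, 0.3, 0.6, 1))
  for (i in seq_len(nrow(grid))) {
    rc <- grid$r_combo[i]
    rm <- rc * grid$frac[i]
    rho <- response_given_comparator(rc, rm)
    # joint cells implied by the two conditional rates
    p_both <- rc * rho
    p_combo_only <- rc * (1 - rho)
    p_neither <- (1 - rc)
    expect_equal(p_both, rm, tolerance = 1e-12)
    expect_equal(p_both + p_combo_only + p_neither, 1, tolerance = 1e-12)
    if (rm < 1) {
      cx <- crossover_response_rate(rc, rm)
      # among mono nonresponders, the crossover fraction responds to combo
      expect_equal((1 - rm) * cx, p_combo_only, tolerance = 1e-12)
      expect_equal((1 - rm) * (1 - cx), p_neither, tolerance = 1e-12)
    }
  }
})

test_that("parameter sets round-trip through YAML and JSON unchanged", {
  p <- generate_parameter_set("PD1_49", seed = 5)
  for (ext in c("yaml", "json")) {
    f1 <- withr::local_tempfile(fileext = paste0(".", ext))
    f2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, f1)
    p2 <- load_parameters(f1)
    # YAML serialises doubles at finite precision; JSON is exact
    expect_equal(p2, p, ignore_attr = TRUE,
                 tolerance = if (ext == "yaml") 1e-6 else 1e-12)
    write_parameters(p2, f2)
    p3 <- load_parameters(f2)
    expect_equal(p3, p2, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the GE50 combination-arm rate is derived from the hazard ratio on load", {
  p <- generate_parameter_set("GE50", seed = 2)
  expect_equal(p$derived$r_combo, hr_to_response_rate(0.375, 1.81), tolerance = 1e-12)
  expect_equal(p$derived$p_crossover,
               crossover_response_rate(p$derived$r_combo, 0.375), tolerance = 1e-12)
})

test_that("validation reports offending fields with their paths", {
  expect_error(toy_params(u_response = 0.6, u_progression = 0.8),
               "u_progression <= u_response")
  raw <- unclass(toy_params())
  raw$derived <- NULL
  raw$survival$arms$CHEMO$pfs12 <- NULL
  expect_error(as_parameter_set(raw), "pfs12")
  raw2 <- unclass(toy_params())
  raw2$survival <- NULL
  expect_error(as_parameter_set(raw2), "survival")
  expect_error(toy_params(se = 1.2), "sensitivity")
})

test_that("set_parameter edits by dot path and re-validates", {
  p <- toy_params(u_response = 0.8, u_progression = 0.6)
  p2 <- set_parameter(p, "economics.u_response", 0.9)
  expect_equal(get_parameter(p2, "economics.u_response"), 0.9)
  expect_error(set_parameter(p, "economics.nope", 1), "cannot resolve")
  # lowering u_response below u_progression fails unless repaired
  expect_error(set_parameter(p, "economics.u_response", 0.5))
  p3 <- set_parameter(p, "economics.u_response", 0.5, repair = TRUE)
  expect_equal(p3$economics$u_progression, 0.5)
})
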