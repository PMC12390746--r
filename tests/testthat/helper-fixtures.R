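# minimal controllable parameter set: all costs zero, flat survival
# (lambda = 0), no background mortality, no discounting unless overridden
toy_params <- function(group = "LT1", r_combo = 1, r_mono = r_combo,
                       pfs12 = min(r_combo, 1 - 1e-12), os12 = 1,
                       anchor_survival = 1,
                       u_response = 1, u_progression = u_response,
                       q_x = 0, horizon = 60,
                       mean_pps = 1e9, t_prog = 9,
                       discount_health = 0, discount_cost = 0,
                       med_cost = 0, duration_rule = "UNTIL_PROGRESSION",
                       fixed_months = NULL,
                       state_cost_response = 0, state_cost_progression = 0,
                       biopsy = 0, pdl1 = 0, disc_cost = 0, terminal = 0,
                       test_cost = 0, se = 1, sp = 1,
                       side_effects = NULL) {
  arm <- function() list(
    pfs12 = pfs12, os12 = os12,
    pfs_anchors = data.frame(month = 12, survival = anchor_survival)
  )
  regimen <- function() {
    rg <- list(med_cost_per_cycle = med_cost, duration_rule = duration_rule,
               side_effects = side_effects)
    if (!is.null(fixed_months)) rg$fixed_months <- fixed_months
    rg
  }
  as_parameter_set(list(
    group = group,
    response = list(derivation_mode = "RATIO", r_combo = r_combo, r_mono = r_mono),
    test = list(sensitivity = se, specificity = sp, test_cost = test_cost),
    regimens = list(CHEMO = regimen(), IMMUNO = regimen(), IMMUNOCHEMO = regimen()),
    survival = list(
      arms = list(CHEMO = arm(), IMMUNO = arm(), IMMUNOCHEMO = arm()),
      mean_time_to_progression_nonresp = t_prog,
      mean_post_progression_survival = mean_pps
    ),
    economics = list(
      u_response = u_response, u_progression = u_progression,
      state_cost_response = state_cost_response,
      state_cost_progression = state_cost_progression,
      biopsy_cost = biopsy, pdl1_test_cost = pdl1,
      discontinuation_cost = disc_cost, terminal_care_cost = terminal,
      discount_rate_health = discount_health, discount_rate_cost = discount_cost,
      wtp_wta_threshold = 80000, horizon_cycles = horizon,
      terminal_care_other_cause = TRUE
    ),
    mortality = list(monthly_other_cause_death = q_x),
    options = list(responder_pfs_mode = "from_cycle_1")
  ))
}

# independent decision-tree oracle: exhaustive enumeration over the joint
# responder table (nested: mono responders are a subset of combo responders)
# x test result x routing
enumerate_cells <- function(group, r_combo, r_mono, se, sp,
                            strategy = "BIOMARKER") {
  joint <- data.frame(
    combo = c(TRUE, TRUE, FALSE),
    mono = c(TRUE, FALSE, FALSE),
    prob = c(r_mono, r_combo - r_mono, 1 - r_combo)
  )
  mono_arm <- if (group == "GE50") "IMMUNO" else "CHEMO"
  if (strategy == "BIOMARKER") {
    pos <- if (group == "GE50") "IMMUNO" else "IMMUNOCHEMO"
    neg <- if (group == "GE50") "IMMUNOCHEMO" else "CHEMO"
  } else {
    pos <- neg <- if (group == "GE50") "IMMUNO" else "IMMUNOCHEMO"
  }
  rows <- list()
  for (i in seq_len(nrow(joint))) {
    status <- if (group == "GE50") joint$mono[i] else joint$combo[i]
    for (test_pos in c(TRUE, FALSE)) {
      p_test <- if (strategy == "CURRENT_PRACTICE") {
        if (test_pos) 1 else 0 # test ignored; put all mass on one branch
      } else if (status) {
        if (test_pos) se else 1 - se
      } else {
        if (test_pos) 1 - sp else sp
      }
      reg <- if (test_pos) pos else neg
      responds <- if (reg == mono_arm) joint$mono[i] else joint$combo[i]
      rows[[length(rows) + 1]] <- data.frame(
        regimen = reg, responder = responds, mass = joint$prob[i] * p_test
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- stats::aggregate(mass ~ regimen + responder, data = out, FUN = sum)
  out <- out[out$mass > 0, ]
  out[order(out$regimen, -out$responder), c("regimen", "responder", "mass")]
}

# hand-built single-stream distribution for engine-level tests
manual_distribution <- function(regimen = "IMMUNOCHEMO", responder = FALSE,
                                mass = 1, one_time_cost = 0) {
  structure(
    tibble::tibble(regimen = regimen, responder = responder, mass = mass),
    class = c("initial_distribution", "tbl_df", "tbl", "data.frame"),
    one_time_cost = one_time_cost, strategy = "CURRENT_PRACTICE", group = "LT1"
  )
}
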