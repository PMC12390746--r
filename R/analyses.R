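#' Run one strategy end to end
#'
#' Convenience pipeline: decision tree, transition schedules, Markov cohort
#' run and outcome accumulation for a single strategy.
#'
#' @param params A `parameter_set`.
#' @param strategy `"CURRENT_PRACTICE"` or `"BIOMARKER"` (or a
#'   `strategy_definition`).
#' @return A `strategy_outcome`; the cohort trace is attached as attribute
#'   `"trace"`.
#' @export
#' @examples
#' p <- generate_parameter_set("LT1", seed = 1)
#' run_strategy(p, "CURRENT_PRACTICE")
run_strategy <- function(params, strategy) {
  dist <- initial_distribution(params, strategy)
  scheds <- build_schedules(params, dist)
  trace <- run_cohort(dist, scheds)
  out <- accumulate_outcomes(trace, params)
  attr(out, "trace") <- trace
  out
}

#' Compare the biomarker strategy with current practice
#'
#' Runs both strategies under the same parameter set (optionally overriding
#' the test's sensitivity and specificity) and returns their incremental
#' comparison at the configured WTP/WTA threshold.
#'
#' @param params A `parameter_set`.
#' @param se,sp Optional overrides for test sensitivity and specificity.
#' @return A `strategy_comparison` (reference = current practice,
#'   comparator = biomarker strategy).
#' @export
compare_strategies <- function(params, se = NULL, sp = NULL) {
  if (!is.null(se)) params$test$sensitivity <- se
  if (!is.null(sp)) params$test$specificity <- sp
  validate_parameters(params)
  cur <- run_strategy(params, "CURRENT_PRACTICE")
  bio <- run_strategy(params, "BIOMARKER")
  compare_outcomes(cur, bio, params$economics$wtp_wta_threshold)
}

#' Headroom analysis: the value of a perfect test
#'
#' Upper bound on the biomarker's value, obtained by running the comparison
#' with sensitivity and specificity both set to 100%.
#'
#' @param params A `parameter_set`.
#' @return A `strategy_comparison`.
#' @export
headroom <- function(params) {
  compare_strategies(params, se = 1, sp = 1)
}

#' Default sensitivity/specificity scenario grid
#'
#' The three finite-accuracy scenarios (75/75, 90/60, 60/90) plus the
#' zero-accuracy corner (0/0), which anchors the claim that omitting
#' immunotherapy in the PD-L1 <50% strata stays cost-effective even for a
#' completely uninformative test. [scenario_table()] prepends the headroom
#' (100/100) row.
#'
#' @return A tibble with columns `label`, `se`, `sp`.
#' @export
default_scenarios <- function() {
  tibble::tribble(
    ~label,        ~se,  ~sp,
    "se75_sp75",   0.75, 0.75,
    "se90_sp60",   0.90, 0.60,
    "se60_sp90",   0.60, 0.90,
    "se0_sp0",     0.00, 0.00
  )
}

#' Scenario table over test accuracies
#'
#' One comparison per (sensitivity, specificity) scenario, preceded by the
#' headroom row, with per-strategy QALYs and costs, incremental deltas, the
#' ICER and the cost-effectiveness verdict.
#'
#' @param params A `parameter_set`.
#' @param scenarios A tibble with columns `label`, `se`, `sp` (default
#'   [default_scenarios()]).
#' @return A `scenario_table` tibble (one row per scenario plus headroom).
#' @export
#' @examples
#' p <- generate_parameter_set("LT1", seed = 1)
#' scenario_table(p)
scenario_table <- function(params, scenarios = default_scenarios()) {
  grid <- bind_rows(
    tibble(label = "headroom", se = 1, sp = 1),
    as_tibble(scenarios)
  )
  rows <- purrr::pmap(grid, function(label, se, sp) {
    cmp <- compare_strategies(params, se = se, sp = sp)
    bind_cols(tibble(label = label, se = se, sp = sp), glance(cmp))
  })
  out <- purrr::list_rbind(rows)
  names(out) <- sub("_reference$", "_current", names(out))
  names(out) <- sub("_comparator$", "_biomarker", names(out))
  structure(out,
            class = c("scenario_table", class(out)),
            group = params$group,
            threshold = params$economics$wtp_wta_threshold)
}

#' Cost-effectiveness plane for a scenario table
#'
#' Plots each scenario's incremental QALYs and costs on the
#' cost-effectiveness plane with the WTP/WTA threshold line.
#'
#' @param object A `scenario_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_table <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 80000
  ggplot(object, aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    geom_abline(slope = thr, intercept = 0, linetype = "dashed") +
    geom_point(aes(colour = .data$label), size = 3) +
    labs(x = "incremental QALYs", y = "incremental cost (EUR)",
         colour = "scenario",
         title = sprintf("Cost-effectiveness plane (PD-L1 %s)",
                         attr(object, "group") %||% "")) +
    theme_minimal()
}

#' Default one-way sensitivity-analysis ranges
#'
#' Mean post-progression survival varied over 50--150% of its value and the
#' two state utilities varied between 50% of their values and their upper
#' bound (1.0 for the response-state utility, the response-state utility for
#' the progression-state utility).
#'
#' @param params A `parameter_set`.
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
default_dsa_ranges <- function(params) {
  ec <- params$economics
  mpps <- params$survival$mean_post_progression_survival
  tibble::tribble(
    ~parameter,                                  ~low,                   ~high,
    "survival.mean_post_progression_survival",   0.5 * mpps,             1.5 * mpps,
    "economics.u_response",                      0.5 * ec$u_response,    1.0,
    "economics.u_progression",                   0.5 * ec$u_progression, ec$u_response
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the biomarker-versus-current-practice comparison at the low and
#' high end of each parameter range (all other inputs at their base values)
#' in the given test-accuracy scenario, and reports the ICER at both ends,
#' the ICER swing, and whether the cost-effectiveness verdict flips.
#' Setting the response-state utility below the progression-state utility
#' would break the utility ordering, so the progression utility is clamped
#' down to the response utility where needed.
#'
#' @param params A `parameter_set`.
#' @param ranges A tibble with columns `parameter` (dot path), `low`,
#'   `high` (default [default_dsa_ranges()]).
#' @param se,sp Test accuracy of the scenario analysed (default 0.75/0.75).
#' @return A `dsa_table` tibble sorted by decreasing ICER swing.
#' @export
one_way_dsa <- function(params, ranges = default_dsa_ranges(params),
                        se = 0.75, sp = 0.75) {
  base <- compare_strategies(params, se = se, sp = sp)
  ranges <- as_tibble(ranges)
  if (nrow(ranges) == 0) {
    out <- tibble(parameter = character(), low = double(), high = double(),
                  icer_low = double(), icer_high = double(),
                  cost_effective_low = logical(), cost_effective_high = logical(),
                  swing = double(), verdict_flip = logical())
  } else {
    rows <- purrr::pmap(ranges, function(parameter, low, high) {
      run_at <- function(value) {
        compare_strategies(set_parameter(params, parameter, value, repair = TRUE),
                           se = se, sp = sp)
      }
      cl <- run_at(low)
      ch <- run_at(high)
      tibble(parameter = parameter, low = low, high = high,
             icer_low = cl$icer, icer_high = ch$icer,
             cost_effective_low = cl$cost_effective,
             cost_effective_high = ch$cost_effective,
             swing = abs(ch$icer - cl$icer),
             verdict_flip = !identical(cl$cost_effective, ch$cost_effective))
    })
    out <- purrr::list_rbind(rows) |> arrange(desc(.data$swing))
  }
  structure(out,
            class = c("dsa_table", class(out)),
            baseline_icer = base$icer,
            baseline_cost_effective = base$cost_effective,
            se = se, sp = sp, group = params$group)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param dsa A `dsa_table` from [one_way_dsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa) {
  base <- attr(dsa, "baseline_icer")
  d <- dsa |>
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot(d) +
    geom_segment(aes(x = .data$icer_low, xend = .data$icer_high,
                     y = .data$parameter, yend = .data$parameter),
                 linewidth = 5, colour = "steelblue") +
    geom_vline(xintercept = base, linetype = "dashed") +
    labs(x = "ICER (EUR per QALY)", y = NULL,
         title = "One-way sensitivity analysis") +
    theme_minimal()
}

#' Equal-medication-duration scenario for the PD-L1 >=50% stratum
#'
#' In the base case medication runs until progression, so the survival gain
#' of rescued nonresponders on immunochemotherapy inflates medication costs.
#' This scenario gives both arms the same fixed total therapy duration
#' (default: the expected months on treatment of the immunotherapy arm
#' under current practice, rounded to whole cycles) and reruns the
#' comparison; passing `duration_rule = "UNTIL_PROGRESSION"` reproduces the
#' baseline comparison unchanged.
#'
#' @param params A `parameter_set` for group `"GE50"`.
#' @param se,sp Test accuracy of the scenario (default 0.75/0.75).
#' @param fixed_months Fixed therapy duration in months for both arms;
#'   derived from the immunotherapy arm when `NULL`.
#' @param duration_rule `"FIXED_MONTHS"` (default) or
#'   `"UNTIL_PROGRESSION"` (no-op).
#' @return A `strategy_comparison`; the duration used is attached as
#'   attribute `"fixed_months"`.
#' @export
medication_duration_scenario <- function(params, se = 0.75, sp = 0.75,
                                         fixed_months = NULL,
                                         duration_rule = c("FIXED_MONTHS",
                                                           "UNTIL_PROGRESSION")) {
  duration_rule <- match.arg(duration_rule)
  if (!identical(params$group, "GE50")) {
    abort("scope error: the equal-duration scenario is defined for the GE50 group only.")
  }
  if (duration_rule == "UNTIL_PROGRESSION") {
    return(compare_strategies(params, se = se, sp = sp))
  }
  if (is.null(fixed_months)) {
    cur <- run_strategy(params, "CURRENT_PRACTICE")
    trace <- attr(cur, "trace")
    fixed_months <- trace |>
      filter(.data$cycle >= 1) |>
      summarise(m = sum(.data$response + .data$stable)) |>
      pull(.data$m) |>
      round()
  }
  raw <- unclass(params)
  raw$derived <- NULL
  for (nm in names(raw$regimens)) {
    raw$regimens[[nm]]$duration_rule <- "FIXED_MONTHS"
    raw$regimens[[nm]]$fixed_months <- fixed_months
  }
  cmp <- compare_strategies(as_parameter_set(raw), se = se, sp = sp)
  attr(cmp, "fixed_months") <- fixed_months
  cmp
}
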