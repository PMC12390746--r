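#' Prevalence-weighted side-effect aggregates
#'
#' Side-effect disutilities (and, analogously, management costs) are
#' multiplied by the prevalence of each side effect and summed into a single
#' decrement attached to the on-medication health states:
#' `sum(prevalence * disutility)` and `sum(prevalence * cost)`. Costs are in
#' EUR per monthly cycle while on medication.
#'
#' @param side_effects A data frame (or list of lists) with columns
#'   `prevalence`, `disutility` and `cost`.
#' @return A single utility decrement (or EUR/month amount).
#' @export
#' @examples
#' aggregate_disutility(tibble::tibble(name = c("a", "b"),
#'   prevalence = c(0.2, 0.3), disutility = c(0.1, 0.2), cost = c(0, 0)))
aggregate_disutility <- function(side_effects) {
  se <- as_side_effects(side_effects)
  sum(se$prevalence * se$disutility)
}

#' @rdname aggregate_disutility
#' @export
aggregate_side_effect_cost <- function(side_effects) {
  se <- as_side_effects(side_effects)
  sum(se$prevalence * se$cost)
}

#' Discount factor for a monthly cycle
#'
#' Annual discounting applied at monthly resolution:
#' `(1 + rate)^(-cycle / 12)`.
#'
#' @param cycle Month index (>= 0).
#' @param annual_rate Annual discount rate in \[0, 1).
#' @return The discount multiplier.
#' @export
#' @examples
#' discount_factor(12, 0.04) # 1 / 1.04
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) abort("`cycle` must be >= 0.")
  if (any(annual_rate < 0) || any(annual_rate >= 1)) {
    abort("`annual_rate` must lie in [0, 1).")
  }
  (1 + annual_rate)^(-cycle / 12)
}

#' Attach utilities and costs to a cohort trace
#'
#' Computes the per-strategy outcome from a trace:
#'
#' * QALYs accrue per cycle as occupancy times the state utility
#'   (`u_response` for the on-treatment states, `u_progression` after
#'   progression) minus the aggregated side-effect disutility while on
#'   medication, divided by 12 and discounted at the health rate.
#' * Costs accrue as medication cost (per the regimen's duration rule) plus
#'   side-effect cost while on medication, state costs per cycle, one-time
#'   discontinuation costs at the medication-stop event (the progression
#'   transition under `UNTIL_PROGRESSION`, the fixed stop under
#'   `FIXED_MONTHS`), terminal-care costs at death transitions
#'   (other-cause deaths included unless
#'   `economics.terminal_care_other_cause` is `FALSE`), and the one-time
#'   tree-stage costs at cycle 0, discounted at the cost rate.
#'
#' Rewards accrue in continuous monthly increments from cycle 1 through the
#' horizon with no half-cycle correction.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The `parameter_set` the trace was produced from.
#' @return A `strategy_outcome` object with discounted and undiscounted
#'   QALYs and costs, life-years, and a per-cycle breakdown.
#' @export
accumulate_outcomes <- function(trace, params) {
  ec <- params$economics
  terminal_other <- !isFALSE(ec$terminal_care_other_cause)
  reg_tbl <- purrr::imap(params$regimens, function(rg, nm) {
    tibble(regimen = nm,
           med_cost = rg$med_cost_per_cycle,
           duration_rule = rg$duration_rule,
           fixed_months = rg$fixed_months %||% NA_real_,
           disutility = aggregate_disutility(rg$side_effects),
           se_cost = aggregate_side_effect_cost(rg$side_effects))
  }) |> purrr::list_rbind()

  x <- trace |>
    as_tibble() |>
    filter(.data$cycle >= 1) |>
    left_join(reg_tbl, by = "regimen") |>
    mutate(
      on_trt = .data$response + .data$stable,
      fixed = .data$duration_rule == "FIXED_MONTHS",
      on_med = ifelse(.data$fixed,
                      .data$on_trt * (.data$cycle <= .data$fixed_months),
                      .data$on_trt),
      stop_flow = ifelse(.data$fixed,
                         ifelse(.data$cycle == .data$fixed_months, .data$on_trt, 0),
                         .data$new_progression),
      death_flow = .data$new_death_disease +
        (if (terminal_other) .data$new_death_other else 0),
      qaly_cycle = (.data$on_trt * ec$u_response +
                      .data$progression * ec$u_progression -
                      .data$on_med * .data$disutility) / 12,
      cost_cycle = .data$on_med * (.data$med_cost + .data$se_cost) +
        .data$on_trt * ec$state_cost_response +
        .data$progression * ec$state_cost_progression +
        .data$death_flow * ec$terminal_care_cost +
        .data$stop_flow * ec$discontinuation_cost,
      dfq = discount_factor(.data$cycle, ec$discount_rate_health),
      dfc = discount_factor(.data$cycle, ec$discount_rate_cost)
    )

  per_cycle <- x |>
    group_by(.data$cycle) |>
    summarise(
      qaly = sum(.data$qaly_cycle * .data$dfq),
      cost = sum(.data$cost_cycle * .data$dfc),
      qaly_undiscounted = sum(.data$qaly_cycle),
      cost_undiscounted = sum(.data$cost_cycle),
      .groups = "drop"
    )
  one_time <- attr(trace, "one_time_cost") %||% 0

  strategy_outcome(
    qalys = sum(per_cycle$qaly),
    costs = one_time + sum(per_cycle$cost),
    qalys_undiscounted = sum(per_cycle$qaly_undiscounted),
    costs_undiscounted = one_time + sum(per_cycle$cost_undiscounted),
    life_years = life_years(trace),
    per_cycle = per_cycle,
    one_time_cost = one_time,
    strategy = attr(trace, "strategy"),
    group = attr(trace, "group")
  )
}

#' Per-strategy outcome container
#'
#' Holds discounted QALYs and costs per patient for one strategy, plus
#' undiscounted variants and an optional per-cycle breakdown. Exposed so
#' published per-strategy aggregates can be entered directly and compared
#' with [compare_outcomes()].
#'
#' @param qalys Discounted QALYs per patient.
#' @param costs Discounted costs per patient (EUR).
#' @param qalys_undiscounted,costs_undiscounted Undiscounted variants
#'   (default to the discounted values).
#' @param life_years Undiscounted life-years (optional).
#' @param per_cycle Per-cycle breakdown tibble (optional).
#' @param one_time_cost One-time tree-stage cost included in `costs`.
#' @param strategy,group Labels.
#' @return A `strategy_outcome` object.
#' @export
strategy_outcome <- function(qalys, costs,
                             qalys_undiscounted = qalys,
                             costs_undiscounted = costs,
                             life_years = NA_real_, per_cycle = NULL,
                             one_time_cost = 0,
                             strategy = NULL, group = NULL) {
  if (qalys < 0 || costs < 0) {
    abort("`qalys` and `costs` must be >= 0.")
  }
  structure(
    list(qalys = qalys, costs = costs,
         qalys_undiscounted = qalys_undiscounted,
         costs_undiscounted = costs_undiscounted,
         life_years = life_years, per_cycle = per_cycle,
         one_time_cost = one_time_cost,
         strategy = strategy, group = group),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome>%s%s\n",
              if (!is.null(x$strategy)) paste0(" ", x$strategy) else "",
              if (!is.null(x$group)) paste0(" (PD-L1 ", x$group, ")") else ""))
  cat(sprintf("  QALYs: %.3f (undiscounted %.3f)\n", x$qalys, x$qalys_undiscounted))
  cat(sprintf("  costs: EUR %s (undiscounted %s)\n",
              format(round(x$costs), big.mark = ","),
              format(round(x$costs_undiscounted), big.mark = ",")))
  if (is.finite(x$life_years)) {
    cat(sprintf("  life-years: %.3f\n", x$life_years))
  }
  invisible(x)
}

#' @export
glance.strategy_outcome <- function(x, ...) {
  tibble(strategy = x$strategy %||% NA_character_,
         group = x$group %||% NA_character_,
         qalys = x$qalys, costs = x$costs,
         qalys_undiscounted = x$qalys_undiscounted,
         costs_undiscounted = x$costs_undiscounted,
         life_years = x$life_years)
}

#' @export
tidy.strategy_outcome <- function(x, ...) {
  if (is.null(x$per_cycle)) {
    abort("this outcome has no per-cycle breakdown.")
  }
  x$per_cycle
}

#' Incremental comparison of two strategy outcomes
#'
#' Computes `comparator - reference` differences in QALYs and costs and the
#' incremental cost-effectiveness ratio with quadrant semantics:
#'
#' * `gained` (more QALYs at extra cost): ICER = dCost/dQALY in EUR per QALY
#'   gained; cost-effective iff ICER <= threshold (willingness to pay).
#' * `lost` (fewer QALYs at lower cost): the positive ratio is EUR saved per
#'   QALY lost; cost-effective iff the savings per QALY lost are at least
#'   the threshold (willingness to accept).
#' * `dominant` / `dominated`: no division; always / never cost-effective.
#' * `cost_minimisation` (equal QALYs): cost-effective iff not costlier.
#'
#' @param reference The reference `strategy_outcome` (current practice).
#' @param comparator The comparator `strategy_outcome` (biomarker strategy).
#' @param threshold WTP/WTA threshold in EUR per QALY (default 80000).
#' @return A `strategy_comparison` object.
#' @export
#' @examples
#' compare_outcomes(strategy_outcome(0.825, 155968),
#'                  strategy_outcome(0.780, 125654))
compare_outcomes <- function(reference, comparator, threshold = 80000) {
  dq <- comparator$qalys - reference$qalys
  dc <- comparator$costs - reference$costs
  if (dq == 0) {
    quadrant <- "cost_minimisation"
    icer <- NA_real_
    ce <- dc <= 0
  } else if (dq > 0 && dc > 0) {
    quadrant <- "gained"
    icer <- dc / dq
    ce <- icer <= threshold
  } else if (dq < 0 && dc < 0) {
    quadrant <- "lost"
    icer <- dc / dq # positive: EUR saved per QALY lost
    ce <- icer >= threshold
  } else if (dq > 0) {
    quadrant <- "dominant"
    icer <- NA_real_
    ce <- TRUE
  } else {
    quadrant <- "dominated"
    icer <- NA_real_
    ce <- FALSE
  }
  structure(
    list(delta_qaly = dq, delta_cost = dc, icer = icer,
         quadrant = quadrant, cost_effective = ce, threshold = threshold,
         reference = reference, comparator = comparator),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  cat(sprintf("  dQALY: %+.4f   dCost: EUR %s\n", x$delta_qaly,
              format(round(x$delta_cost), big.mark = ",")))
  icer_txt <- switch(x$quadrant,
    gained = sprintf("EUR %s per QALY gained", format(round(x$icer), big.mark = ",")),
    lost = sprintf("EUR %s saved per QALY lost", format(round(x$icer), big.mark = ",")),
    x$quadrant)
  cat(sprintf("  ICER: %s\n", icer_txt))
  cat(sprintf("  %scost-effective at EUR %s per QALY\n",
              if (x$cost_effective) "" else "NOT ",
              format(x$threshold, big.mark = ",")))
  invisible(x)
}

#' @export
tidy.strategy_comparison <- function(x, ...) {
  tibble(delta_qaly = x$delta_qaly, delta_cost = x$delta_cost,
         icer = x$icer, quadrant = x$quadrant,
         cost_effective = x$cost_effective, threshold = x$threshold)
}

#' @export
glance.strategy_comparison <- function(x, ...) {
  tibble(qalys_reference = x$reference$qalys, costs_reference = x$reference$costs,
         qalys_comparator = x$comparator$qalys, costs_comparator = x$comparator$costs,
         delta_qaly = x$delta_qaly, delta_cost = x$delta_cost,
         icer = x$icer, quadrant = x$quadrant,
         cost_effective = x$cost_effective)
}
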