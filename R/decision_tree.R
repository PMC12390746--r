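#' Define a treatment strategy for a PD-L1 stratum
#'
#' Two strategies exist per stratum. Under `"CURRENT_PRACTICE"` every
#' patient receives the guideline regimen unconditionally: immunochemotherapy
#' for PD-L1 <1% and 1--49%, immunotherapy alone for PD-L1 >=50%. Under
#' `"BIOMARKER"` a predictive test routes patients: in the <1% and 1--49%
#' strata a positive test keeps immunochemotherapy and a negative test omits
#' immunotherapy (chemotherapy alone); in the >=50% stratum a positive test
#' keeps immunotherapy alone and a negative test adds chemotherapy
#' (immunochemotherapy).
#'
#' @param name `"CURRENT_PRACTICE"` or `"BIOMARKER"`.
#' @param group PD-L1 stratum label (see [pdl1_groups()]).
#' @return A `strategy_definition` object holding the branch map.
#' @export
#' @examples
#' strategy_definition("BIOMARKER", "GE50")
strategy_definition <- function(name = c("CURRENT_PRACTICE", "BIOMARKER"), group) {
  name <- match.arg(name)
  if (!group %in% pdl1_groups()) {
    abort(sprintf("unknown PD-L1 group `%s`.", group))
  }
  arms <- group_arms(group)
  branch_map <- if (name == "CURRENT_PRACTICE") {
    list(all = arms$current)
  } else if (group == "GE50") {
    list(positive = "IMMUNO", negative = "IMMUNOCHEMO")
  } else {
    list(positive = "IMMUNOCHEMO", negative = "CHEMO")
  }
  structure(list(name = name, group = group, branch_map = branch_map),
            class = "strategy_definition")
}

#' @export
print.strategy_definition <- function(x, ...) {
  cat(sprintf("<strategy_definition> %s (PD-L1 group %s)\n", x$name, x$group))
  for (k in names(x$branch_map)) {
    cat(sprintf("  %s -> %s\n", k, x$branch_map[[k]]))
  }
  invisible(x)
}

#' Initial cohort distribution from the decision tree
#'
#' Pushes a unit cohort through the stratum's decision tree and returns the
#' starting distribution over (assigned regimen, responder status) cells for
#' the Markov model. The reference responder status is response to the
#' stratum's combination arm for PD-L1 <1% and 1--49% (prevalence
#' `r_combo`) and response to immunotherapy alone for PD-L1 >=50%
#' (prevalence `r_mono`). The biomarker test is positive with probability
#' `sensitivity` among reference responders and negative with probability
#' `specificity` among reference nonresponders. Patients rerouted by the
#' test carry their conditional response probability on the new regimen:
#' a combination responder moved to chemotherapy responds with probability
#' [response_given_comparator()], an immunotherapy nonresponder moved to
#' immunochemotherapy responds with probability
#' [crossover_response_rate()], and nesting makes an immunotherapy responder
#' certain to respond to immunochemotherapy. One-time tree-stage costs
#' (biopsy, PD-L1 determination, plus the biomarker test cost under the
#' biomarker strategy) are recorded as an attribute.
#'
#' @param params A `parameter_set`.
#' @param strategy A `strategy_definition`, or a strategy name which is
#'   resolved against `params$group`.
#' @return An `initial_distribution` tibble with columns `regimen`,
#'   `responder` and `mass` (masses sum to one), and attributes
#'   `one_time_cost`, `strategy` and `group`.
#' @export
#' @examples
#' p <- generate_parameter_set("LT1", seed = 1)
#' initial_distribution(p, "CURRENT_PRACTICE")
initial_distribution <- function(params, strategy) {
  if (is.character(strategy)) {
    strategy <- strategy_definition(strategy, params$group)
  }
  if (!identical(strategy$group, params$group)) {
    abort(sprintf("strategy is for group `%s` but parameters are for `%s`.",
                  strategy$group, params$group))
  }
  se <- params$test$sensitivity
  sp <- params$test$specificity
  d <- params$derived
  bm <- strategy$branch_map

  cells <- if (strategy$name == "CURRENT_PRACTICE") {
    reg <- bm$all
    prev <- if (params$group == "GE50") d$r_mono else d$r_combo
    tibble(regimen = reg,
           responder = c(TRUE, FALSE),
           mass = c(prev, 1 - prev))
  } else if (params$group == "GE50") {
    q <- d$r_mono            # responds to immunotherapy alone
    cx <- d$p_crossover      # IO-nonresponder rescued by added chemotherapy
    tibble(
      regimen = c(bm$positive, bm$negative, bm$negative, bm$negative, bm$positive),
      responder = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      mass = c(
        q * se,                    # true positive, stays on immunotherapy
        q * (1 - se),              # false negative, nesting: responds to combo
        (1 - q) * sp * cx,         # true negative, rescued by combination
        (1 - q) * sp * (1 - cx),   # true negative, not rescued
        (1 - q) * (1 - sp)         # false positive, stays on immunotherapy
      )
    )
  } else {
    p <- d$r_combo                 # responds to immunochemotherapy
    rho <- d$p_respond_comparator  # combo responder also responds to chemo
    tibble(
      regimen = c(bm$positive, bm$negative, bm$negative, bm$negative, bm$positive),
      responder = c(TRUE, TRUE, FALSE, FALSE, FALSE),
      mass = c(
        p * se,                      # true positive, stays on combination
        p * (1 - se) * rho,          # false negative, still responds to chemo
        p * (1 - se) * (1 - rho),    # false negative, loses response on chemo
        (1 - p) * sp,                # true negative (never responds, nesting)
        (1 - p) * (1 - sp)           # false positive, stays on combination
      )
    )
  }

  cells <- cells |>
    group_by(.data$regimen, .data$responder) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    filter(.data$mass > 0) |>
    arrange(.data$regimen, desc(.data$responder))

  missing <- setdiff(unique(cells$regimen), names(params$regimens))
  if (length(missing)) {
    abort(sprintf("configuration error: missing field `regimens.%s`.", missing[[1]]))
  }
  stopifnot(abs(sum(cells$mass) - 1) < 1e-12)

  ec <- params$economics
  one_time <- ec$biopsy_cost + ec$pdl1_test_cost +
    if (strategy$name == "BIOMARKER") (params$test$test_cost %||% 0) else 0

  structure(cells,
            class = c("initial_distribution", class(cells)),
            one_time_cost = one_time,
            strategy = strategy$name,
            group = params$group)
}

#' Overall response rate implied by an initial distribution
#'
#' The total probability mass landing in responder cells, i.e. the fraction
#' of the cohort that starts the Markov model in the response-on-treatment
#' state.
#'
#' @param dist An `initial_distribution`.
#' @return A single probability.
#' @export
overall_response_rate <- function(dist) {
  sum(dist$mass[dist$responder])
}
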