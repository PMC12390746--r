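#' PD-L1 strata and regimen vocabulary
#'
#' The model stratifies advanced NSCLC patients by tumour PD-L1 expression
#' into three groups: `"LT1"` (<1%), `"PD1_49"` (1--49%) and `"GE50"`
#' (>=50%). Treatment arms are `"CHEMO"` (platinum doublet chemotherapy),
#' `"IMMUNO"` (pembrolizumab monotherapy) and `"IMMUNOCHEMO"` (the
#' combination).
#'
#' @return A character vector of valid labels.
#' @export
pdl1_groups <- function() c("LT1", "PD1_49", "GE50")

#' @rdname pdl1_groups
#' @export
regimen_names <- function() c("CHEMO", "IMMUNO", "IMMUNOCHEMO")

#' Published 12-month response rates per PD-L1 stratum
#'
#' Pooled KEYNOTE trial response rates (response defined as progression-free
#' survival at 12 months). For the <1% and 1--49% strata both arms were
#' observed directly; for the >=50% stratum only immunotherapy monotherapy
#' was observed (37.5%) and the immunochemotherapy rate is derived from an
#' indirect-comparison PFS hazard ratio of 1.81 via [hr_to_response_rate()].
#'
#' @return A tibble with columns `group`, `derivation_mode`, `r_combo`,
#'   `r_mono` and `hr`.
#' @export
#' @examples
#' printed_response_rates()
printed_response_rates <- function() {
  tibble::tribble(
    ~group,    ~derivation_mode,   ~r_combo, ~r_mono, ~hr,
    "LT1",     "RATIO",            0.328,    0.193,   NA_real_,
    "PD1_49",  "RATIO",            0.429,    0.177,   NA_real_,
    "GE50",    "HR_RISK_SCALING",  NA_real_, 0.375,   1.81
  )
}

#' Probability that a combination-arm responder also responds to the comparator
#'
#' Under the nested-responder assumption (every responder to the weaker arm
#' is also a responder to the stronger arm), the conditional probability that
#' a responder to the combination arm would also have responded to the
#' comparator arm is the ratio of the marginal response rates,
#' `r_mono / r_combo`.
#'
#' @param r_combo Marginal response probability on the combination arm, in
#'   (0, 1].
#' @param r_mono Marginal response probability on the comparator arm; must
#'   not exceed `r_combo`.
#' @return The conditional response probability, in \[0, 1\].
#' @export
#' @examples
#' response_given_comparator(0.328, 0.193) # ~0.588
response_given_comparator <- function(r_combo, r_mono) {
  if (!is.numeric(r_combo) || !is.numeric(r_mono)) {
    abort("`r_combo` and `r_mono` must be numeric.")
  }
  if (any(r_combo <= 0)) {
    abort("undefined rate: `r_combo` must be > 0.")
  }
  if (any(r_mono < 0) || any(r_combo > 1)) {
    abort("response probabilities must lie in [0, 1].")
  }
  if (any(r_mono > r_combo + 1e-12)) {
    abort("nesting violation: `r_mono` must not exceed `r_combo`.")
  }
  r_mono / r_combo
}

#' Convert a response rate across arms with a PFS hazard ratio
#'
#' Converts a 12-month response (progression-free) probability on a baseline
#' arm into the corresponding probability on an arm whose progression hazard
#' is lower by the factor `hr`. The default `"risk_scaling"` convention
#' divides the nonresponse risk by the hazard ratio,
#' `1 - (1 - r_base) / hr`, clipped to \[0, 1\]. The proportional-hazards
#' alternative `"hazard_power"` raises the progression-free fraction to the
#' power `1 / hr` and is offered for exploration; the two differ for
#' `hr != 1`.
#'
#' @param r_base Baseline response probability in \[0, 1\].
#' @param hr Hazard ratio (> 0) of the baseline arm relative to the target
#'   arm.
#' @param mode Conversion convention; `"risk_scaling"` (default) or
#'   `"hazard_power"`.
#' @return The converted response probability.
#' @export
#' @examples
#' hr_to_response_rate(0.375, 1.81) # ~0.655
hr_to_response_rate <- function(r_base, hr,
                                mode = c("risk_scaling", "hazard_power")) {
  mode <- match.arg(mode)
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    abort("invalid hazard ratio: `hr` must be > 0.")
  }
  if (any(r_base < 0) || any(r_base > 1)) {
    abort("`r_base` must lie in [0, 1].")
  }
  out <- switch(mode,
    risk_scaling = 1 - (1 - r_base) / hr,
    hazard_power = r_base^(1 / hr)
  )
  pmin(pmax(out, 0), 1)
}

#' Crossover response among comparator-arm nonresponders
#'
#' Among patients who do not respond to the weaker (comparator) arm, the
#' fraction who would nevertheless respond to the combination arm,
#' `1 - (1 - r_combo) / (1 - r_mono)`, again under the nested-responder
#' assumption. This is the "rescue" probability used when a negative test
#' adds chemotherapy to immunotherapy in the PD-L1 >=50% stratum.
#'
#' @inheritParams response_given_comparator
#' @return The crossover response probability, in \[0, 1\].
#' @export
#' @examples
#' crossover_response_rate(0.655, 0.375) # 0.448
crossover_response_rate <- function(r_combo, r_mono) {
  if (any(r_mono >= 1)) {
    abort("undefined: `r_mono` = 1 leaves no nonresponders.")
  }
  if (any(r_mono < 0) || any(r_combo > 1)) {
    abort("response probabilities must lie in [0, 1].")
  }
  if (any(r_combo < r_mono - 1e-12)) {
    abort("nesting violation: `r_combo` must be at least `r_mono`.")
  }
  1 - (1 - r_combo) / (1 - r_mono)
}

# arm roles within a stratum: which regimen is the "combination" (stronger)
# and which the comparator, plus the current standard of care
group_arms <- function(group) {
  switch(group,
    LT1    = list(combo = "IMMUNOCHEMO", mono = "CHEMO",  current = "IMMUNOCHEMO"),
    PD1_49 = list(combo = "IMMUNOCHEMO", mono = "CHEMO",  current = "IMMUNOCHEMO"),
    GE50   = list(combo = "IMMUNOCHEMO", mono = "IMMUNO", current = "IMMUNO"),
    abort(sprintf("unknown PD-L1 group `%s`.", group))
  )
}

# ---- parameter-set construction and validation -------------------------------

as_side_effects <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
    return(tibble(name = character(), prevalence = double(),
                  disutility = double(), cost = double()))
  }
  if (!is.data.frame(x)) x <- dplyr::bind_rows(lapply(x, as_tibble))
  x <- as_tibble(x)
  x$name <- as.character(x$name)
  for (col in c("prevalence", "disutility", "cost")) {
    if (is.null(x[[col]])) abort(sprintf("side effect is missing `%s`.", col))
    x[[col]] <- as.numeric(x[[col]])
  }
  x[c("name", "prevalence", "disutility", "cost")]
}

as_anchors <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.data.frame(x)) {
    if (is.list(x)) {
      x <- dplyr::bind_rows(lapply(x, function(a) {
        a <- unlist(a)
        if (is.null(names(a)) || !all(c("month", "survival") %in% names(a))) {
          names(a) <- c("month", "survival")[seq_along(a)]
        }
        as_tibble(as.list(a))
      }))
    } else if (is.numeric(x) && length(x) == 2) {
      x <- tibble(month = x[[1]], survival = x[[2]])
    }
  }
  x <- as_tibble(x)
  x$month <- as.numeric(x$month)
  x$survival <- as.numeric(x$survival)
  x[c("month", "survival")]
}

get_path <- function(x, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    if (!is.list(x) || is.null(x[[p]])) return(NULL)
    x <- x[[p]]
  }
  x
}

#' Assemble and validate a model parameter set
#'
#' Canonicalises a nested list of model inputs into a `parameter_set`
#' object: side-effect tables and survival anchors become tibbles, the
#' response model is resolved (deriving the combination-arm rate from the
#' hazard ratio where applicable), the secondary response probabilities used
#' by the decision trees are computed and cached under `$derived`, and every
#' invariant is checked.
#'
#' @param x A nested list following the configuration schema (see
#'   [load_parameters()] for the field reference).
#' @param validate Check invariants (default `TRUE`).
#' @return A `parameter_set` object (a classed nested list).
#' @seealso [load_parameters()], [generate_parameter_set()]
#' @export
as_parameter_set <- function(x, validate = TRUE) {
  if (inherits(x, "parameter_set")) x <- unclass(x)
  if (!is.list(x)) abort("parameter set must be a list.")
  x$derived <- NULL

  required <- c("group", "response", "test", "regimens", "survival",
                "economics", "mortality")
  for (f in required) {
    if (is.null(x[[f]])) {
      abort(sprintf("configuration error: missing field `%s`.", f))
    }
  }
  req_leaf <- c(
    "response.derivation_mode",
    "test.sensitivity", "test.specificity",
    "survival.arms",
    "survival.mean_time_to_progression_nonresp",
    "survival.mean_post_progression_survival",
    "economics.u_response", "economics.u_progression",
    "economics.state_cost_response", "economics.state_cost_progression",
    "economics.biopsy_cost", "economics.pdl1_test_cost",
    "economics.discontinuation_cost", "economics.terminal_care_cost",
    "economics.discount_rate_health", "economics.discount_rate_cost",
    "economics.wtp_wta_threshold", "economics.horizon_cycles",
    "mortality.monthly_other_cause_death"
  )
  for (f in req_leaf) {
    if (is.null(get_path(x, f))) {
      abort(sprintf("configuration error: missing field `%s`.", f))
    }
  }

  x$regimens <- lapply(x$regimens, function(rg) {
    rg$med_cost_per_cycle <- as.numeric(rg$med_cost_per_cycle)
    rg$duration_rule <- rg$duration_rule %||% "UNTIL_PROGRESSION"
    rg$fixed_months <- if (is.null(rg$fixed_months)) NULL else as.numeric(rg$fixed_months)
    rg$side_effects <- as_side_effects(rg$side_effects)
    rg
  })
  x$survival$arms <- lapply(x$survival$arms, function(arm) {
    arm$pfs12 <- as.numeric(arm$pfs12)
    arm$os12 <- as.numeric(arm$os12)
    arm$pfs_anchors <- as_anchors(arm$pfs_anchors)
    arm
  })
  x$economics <- lapply(x$economics, function(v) {
    if (is.logical(v)) v else as.numeric(v)
  })
  x$mortality$monthly_other_cause_death <-
    as.numeric(x$mortality$monthly_other_cause_death)
  x$options <- x$options %||% list()
  x$options$responder_pfs_mode <- x$options$responder_pfs_mode %||% "from_cycle_1"

  resp <- x$response
  mode <- resp$derivation_mode
  r_mono <- as.numeric(resp$r_mono)
  r_combo <- switch(mode,
    RATIO = as.numeric(resp$r_combo),
    HR_RISK_SCALING = hr_to_response_rate(r_mono, as.numeric(resp$hr), "risk_scaling"),
    HR_HAZARD_POWER = hr_to_response_rate(r_mono, as.numeric(resp$hr), "hazard_power"),
    abort(sprintf(
      "configuration error: `response.derivation_mode` must be RATIO, HR_RISK_SCALING or HR_HAZARD_POWER, not `%s`.",
      mode))
  )
  x$derived <- list(
    r_combo = r_combo,
    r_mono = r_mono,
    p_respond_comparator = response_given_comparator(r_combo, r_mono),
    p_crossover = if (r_mono < 1) crossover_response_rate(r_combo, r_mono) else NA_real_
  )

  out <- structure(x, class = c("parameter_set", "list"))
  if (validate) validate_parameters(out)
  out
}

#' Validate a parameter set against the model invariants
#'
#' Checks probability ranges, the utility and survival orderings
#' (`u_progression <= u_response <= 1`, `pfs12 <= os12` per arm, anchors
#' monotone), nonnegativity of all costs, discount rates in \[0, 1) and the
#' presence of both treatment arms for the stratum. All violations are
#' collected and reported together with their field paths.
#'
#' @param params A `parameter_set` (or coercible list).
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   offending field.
#' @export
validate_parameters <- function(params) {
  problems <- character()
  chk <- function(ok, msg) {
    if (!isTRUE(all(ok))) problems <<- c(problems, msg)
  }
  p <- params

  chk(p$group %in% pdl1_groups(),
      sprintf("`group` must be one of %s.", paste(pdl1_groups(), collapse = ", ")))
  d <- p$derived
  chk(is.finite(d$r_combo) && d$r_combo > 0 && d$r_combo <= 1,
      "`response.r_combo` (derived) must lie in (0, 1].")
  chk(is.finite(d$r_mono) && d$r_mono >= 0 && d$r_mono <= 1,
      "`response.r_mono` must lie in [0, 1].")
  chk(d$r_mono <= d$r_combo + 1e-12,
      "`response.r_mono` must not exceed the combination-arm rate (nested responders).")

  chk(p$test$sensitivity >= 0 && p$test$sensitivity <= 1,
      "`test.sensitivity` must lie in [0, 1].")
  chk(p$test$specificity >= 0 && p$test$specificity <= 1,
      "`test.specificity` must lie in [0, 1].")
  chk((p$test$test_cost %||% 0) >= 0, "`test.test_cost` must be >= 0.")

  arms <- group_arms(p$group)
  for (nm in unique(c(arms$combo, arms$mono))) {
    chk(!is.null(p$regimens[[nm]]),
        sprintf("configuration error: missing field `regimens.%s`.", nm))
    chk(!is.null(p$survival$arms[[nm]]),
        sprintf("configuration error: missing field `survival.arms.%s`.", nm))
  }
  for (nm in names(p$regimens)) {
    rg <- p$regimens[[nm]]
    pre <- paste0("regimens.", nm)
    chk(rg$med_cost_per_cycle >= 0, sprintf("`%s.med_cost_per_cycle` must be >= 0.", pre))
    chk(rg$duration_rule %in% c("UNTIL_PROGRESSION", "FIXED_MONTHS"),
        sprintf("`%s.duration_rule` must be UNTIL_PROGRESSION or FIXED_MONTHS.", pre))
    if (identical(rg$duration_rule, "FIXED_MONTHS")) {
      chk(!is.null(rg$fixed_months) && rg$fixed_months >= 0,
          sprintf("`%s.fixed_months` must be >= 0 under FIXED_MONTHS.", pre))
    }
    se <- rg$side_effects
    chk(all(se$prevalence >= 0 & se$prevalence <= 1),
        sprintf("`%s.side_effects.prevalence` must lie in [0, 1].", pre))
    chk(all(se$disutility >= 0), sprintf("`%s.side_effects.disutility` must be >= 0.", pre))
    chk(all(se$cost >= 0), sprintf("`%s.side_effects.cost` must be >= 0.", pre))
  }
  for (nm in names(p$survival$arms)) {
    arm <- p$survival$arms[[nm]]
    pre <- paste0("survival.arms.", nm)
    if (length(arm$pfs12) != 1 || !is.finite(arm$pfs12)) {
      chk(FALSE, sprintf("configuration error: missing field `%s.pfs12`.", pre))
      next
    }
    chk(arm$pfs12 >= 0 && arm$pfs12 <= 1, sprintf("`%s.pfs12` must lie in [0, 1].", pre))
    chk(arm$os12 >= arm$pfs12 - 1e-12 && arm$os12 <= 1,
        sprintf("`%s.os12` must satisfy pfs12 <= os12 <= 1.", pre))
    a <- arm$pfs_anchors
    if (is.null(a) || nrow(a) == 0) {
      chk(FALSE, sprintf("configuration error: missing field `%s.pfs_anchors`.", pre))
    } else {
      chk(all(a$month > 0) && all(diff(a$month) > 0),
          sprintf("`%s.pfs_anchors` months must be positive and strictly increasing.", pre))
      chk(all(a$survival > 0 & a$survival <= 1),
          sprintf("`%s.pfs_anchors` survival must lie in (0, 1].", pre))
      chk(all(diff(a$survival) <= 1e-12),
          sprintf("`%s.pfs_anchors` survival must be nonincreasing.", pre))
    }
  }
  sv <- p$survival
  chk(sv$mean_time_to_progression_nonresp > 0 && sv$mean_time_to_progression_nonresp < 12,
      "`survival.mean_time_to_progression_nonresp` must lie in (0, 12) months.")
  chk(sv$mean_post_progression_survival > 0,
      "`survival.mean_post_progression_survival` must be > 0 months.")

  ec <- p$economics
  chk(ec$u_progression >= 0 && ec$u_progression <= ec$u_response + 1e-12 && ec$u_response <= 1,
      "`economics` utilities must satisfy 0 <= u_progression <= u_response <= 1.")
  for (f in c("state_cost_response", "state_cost_progression", "biopsy_cost",
              "pdl1_test_cost", "discontinuation_cost", "terminal_care_cost")) {
    chk(ec[[f]] >= 0, sprintf("`economics.%s` must be >= 0.", f))
  }
  for (f in c("discount_rate_health", "discount_rate_cost")) {
    chk(ec[[f]] >= 0 && ec[[f]] < 1, sprintf("`economics.%s` must lie in [0, 1).", f))
  }
  chk(ec$wtp_wta_threshold > 0, "`economics.wtp_wta_threshold` must be > 0.")
  chk(ec$horizon_cycles >= 1, "`economics.horizon_cycles` must be >= 1.")

  qx <- p$mortality$monthly_other_cause_death
  chk(all(qx >= 0 & qx <= 1), "`mortality.monthly_other_cause_death` must lie in [0, 1].")
  chk(p$options$responder_pfs_mode %in% c("from_cycle_1", "after_12m"),
      "`options.responder_pfs_mode` must be `from_cycle_1` or `after_12m`.")

  if (length(problems)) {
    abort(c("validation error:", setNames(problems, rep("x", length(problems)))))
  }
  invisible(params)
}

#' Read or write a parameter set as YAML or JSON
#'
#' The configuration schema mirrors the structure of a `parameter_set`:
#' top-level fields `group`, `response` (`derivation_mode`, `r_combo`,
#' `r_mono`, `hr`), `test` (`sensitivity`, `specificity`, `test_cost`),
#' `regimens` (per regimen: `med_cost_per_cycle` in EUR/month,
#' `duration_rule`, `fixed_months`, `side_effects` with `name`,
#' `prevalence`, `disutility`, `cost` in EUR/month), `survival` (`arms` with
#' `pfs12`, `os12`, `pfs_anchors`; `mean_time_to_progression_nonresp`,
#' `mean_post_progression_survival`, months), `economics` (utilities, EUR
#' state costs, one-time costs, annual discount rates, threshold in
#' EUR/QALY, `horizon_cycles`) and `mortality`
#' (`monthly_other_cause_death`, scalar or per-cycle vector). The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#' Loading, writing and reloading yields an equivalent parameter set.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param validate Check invariants after loading (default `TRUE`).
#' @return `load_parameters()` returns a validated `parameter_set`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
load_parameters <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("configuration error: file `%s` does not exist.", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE),
    abort("configuration error: unsupported extension (use .yaml, .yml or .json).")
  )
  as_parameter_set(raw, validate = validate)
}

#' @rdname load_parameters
#' @param params A `parameter_set`.
#' @export
write_parameters <- function(params, path) {
  raw <- unclass(params)
  raw$derived <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    # data frames -> row lists so the YAML reads back as the same schema
    raw$regimens <- lapply(raw$regimens, function(rg) {
      rg$side_effects <- unname(apply(rg$side_effects, 1, as.list, simplify = FALSE))
      rg$side_effects <- lapply(rg$side_effects, function(r) {
        r$prevalence <- as.numeric(r$prevalence)
        r$disutility <- as.numeric(r$disutility)
        r$cost <- as.numeric(r$cost)
        r
      })
      rg
    })
    raw$survival$arms <- lapply(raw$survival$arms, function(arm) {
      arm$pfs_anchors <- unname(apply(arm$pfs_anchors, 1, as.list, simplify = FALSE))
      arm
    })
    yaml::write_yaml(raw, path, precision = 12)
  } else if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  } else {
    abort("configuration error: unsupported extension (use .yaml, .yml or .json).")
  }
  invisible(path)
}

#' Get or set a single parameter by path
#'
#' Paths are dot-separated field references into the parameter set, e.g.
#' `"survival.mean_post_progression_survival"` or
#' `"regimens.IMMUNOCHEMO.med_cost_per_cycle"`. After setting, derived
#' response probabilities are recomputed and the full set is re-validated.
#'
#' @param params A `parameter_set`.
#' @param path Dot-separated field path.
#' @param value Replacement value.
#' @param repair If `TRUE`, clamp `economics.u_progression` down to
#'   `economics.u_response` when the edit would break the utility ordering
#'   (used by [one_way_dsa()]).
#' @return `set_parameter()` returns the modified, re-validated
#'   `parameter_set`; `get_parameter()` returns the current value.
#' @export
set_parameter <- function(params, path, value, repair = FALSE) {
  raw <- unclass(params)
  raw$derived <- NULL
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (is.null(get_path(raw, path))) {
    abort(sprintf("configuration error: cannot resolve parameter path `%s`.", path))
  }
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts, quote(raw))
  eval(call("<-", expr, value))
  if (repair && raw$economics$u_progression > raw$economics$u_response) {
    raw$economics$u_progression <- raw$economics$u_response
  }
  as_parameter_set(raw)
}

#' @rdname set_parameter
#' @export
get_parameter <- function(params, path) {
  out <- get_path(unclass(params), path)
  if (is.null(out)) {
    abort(sprintf("configuration error: cannot resolve parameter path `%s`.", path))
  }
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  d <- x$derived
  cat(sprintf("<parameter_set> PD-L1 group %s\n", x$group))
  cat(sprintf("  response: r_combo = %.4f, r_mono = %.4f (%s)\n",
              d$r_combo, d$r_mono, x$response$derivation_mode))
  cat(sprintf("  test: Se = %.2f, Sp = %.2f\n",
              x$test$sensitivity, x$test$specificity))
  cat(sprintf("  horizon: %d monthly cycles; discounting %.1f%% (QALYs) / %.1f%% (costs)\n",
              as.integer(x$economics$horizon_cycles),
              100 * x$economics$discount_rate_health,
              100 * x$economics$discount_rate_cost))
  cat(sprintf("  regimens: %s\n", paste(names(x$regimens), collapse = ", ")))
  invisible(x)
}
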