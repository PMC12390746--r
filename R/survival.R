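#' Split 12-month nonresponders into dying and progressing streams
#'
#' Patients without a response (progression-free survival) at 12 months
#' either died or progressed within the first year. The split is identified
#' from the arm's 12-month survival anchors: among the nonresponder mass
#' `1 - pfs12`, the fraction that died is `(1 - os12) / (1 - pfs12)` and the
#' fraction that progressed but survived is `(os12 - pfs12) / (1 - pfs12)`.
#'
#' @param pfs12 Probability of being progression-free at 12 months (< 1).
#' @param os12 Probability of being alive at 12 months; `os12 >= pfs12`.
#' @return A named numeric vector `c(p_death, p_progress)` summing to one.
#' @export
#' @examples
#' nonresponder_split(0.4, 0.7) # 0.5 / 0.5
nonresponder_split <- function(pfs12, os12) {
  if (pfs12 >= 1) abort("no nonresponders: `pfs12` must be < 1.")
  if (pfs12 < 0 || os12 > 1) abort("survival anchors must lie in [0, 1].")
  if (os12 < pfs12 - 1e-12) abort("ordering error: `os12` must be >= `pfs12`.")
  p_death <- (1 - os12) / (1 - pfs12)
  c(p_death = p_death, p_progress = 1 - p_death)
}

#' Per-cycle event probability from a single survival anchor
#'
#' Assumes a constant exponential hazard through the anchor:
#' `lambda = -log(s_t) / t`, returned as the per-month event probability
#' `1 - exp(-lambda)`.
#'
#' @param t Anchor time in months (> 0).
#' @param s_t Survival fraction at `t`, in (0, 1].
#' @return Per-cycle event probability.
#' @export
monthly_rate_from_anchor <- function(t, s_t) {
  if (any(t <= 0)) abort("anchor month must be > 0.")
  if (any(s_t <= 0)) abort("infinite hazard: survival anchor must be > 0.")
  if (any(s_t > 1)) abort("survival anchor must be <= 1.")
  1 - exp(log(s_t) / t)
}

#' Fit a constant exponential rate through survival anchors
#'
#' Least-squares fit of the cumulative hazard `-log(S)` against time through
#' the origin: `lambda = sum(t * (-log(S))) / sum(t^2)` per month. With a
#' single anchor this reduces to the closed form `-log(s) / t`. This is the
#' extrapolation model for progression-free survival beyond the observed
#' window.
#'
#' @param anchors A data frame (or coercible) with columns `month` and
#'   `survival`, survivals in (0, 1\].
#' @return The fitted rate `lambda` (per month).
#' @export
#' @examples
#' fit_exponential(tibble::tibble(month = c(6, 12, 18),
#'                                survival = exp(-0.08 * c(6, 12, 18))))
fit_exponential <- function(anchors) {
  a <- as_anchors(anchors)
  if (is.null(a) || nrow(a) == 0) abort("at least one anchor is required.")
  if (any(a$month <= 0)) abort("anchor months must be > 0.")
  if (any(a$survival <= 0)) abort("degenerate anchor: survival must be > 0.")
  if (any(a$survival > 1)) abort("anchor survival must be <= 1.")
  sum(a$month * (-log(a$survival))) / sum(a$month^2)
}

#' Per-cycle death probability after progression
#'
#' Post-progression survival is modelled as a memoryless (geometric) process
#' whose mean sojourn matches the supplied mean: the constant per-cycle
#' death probability is `1 / mean_pps`, capped at one.
#'
#' @param mean_pps Mean post-progression survival in months (> 0).
#' @return Per-cycle death probability.
#' @export
#' @examples
#' post_progression_death_prob(5.4) # ~0.185
post_progression_death_prob <- function(mean_pps) {
  if (any(!is.finite(mean_pps)) || any(mean_pps <= 0)) {
    abort("invalid mean: `mean_pps` must be > 0.")
  }
  pmin(1, 1 / mean_pps)
}

#' Construct a per-cycle transition schedule
#'
#' Low-level constructor for the per-cycle hazards a sub-cohort stream
#' follows; normally produced by [build_schedule()] but exposed so schedules
#' can be built or edited directly for audit.
#'
#' @param regimen Regimen name.
#' @param responder Logical responder status of the stream's decision-tree
#'   cell.
#' @param horizon Number of monthly cycles covered.
#' @param p_prog Responder per-cycle progression probability (length
#'   `horizon`); `NULL` for nonresponder schedules.
#' @param split Named vector `c(p_death, p_progress)` splitting nonresponder
#'   mass into the dying and progressing streams; `NULL` for responders.
#' @param h_die Per-cycle conditional death probability of the dying stream
#'   (length `horizon`, one at the 12-month boundary).
#' @param jump_cycle Cycle at which the progressing stream moves to the
#'   progression state.
#' @param p_pps Per-cycle death probability in the progression state.
#' @param q_x Per-cycle other-cause mortality (length `horizon`).
#' @return A `transition_schedule` object.
#' @export
transition_schedule <- function(regimen, responder, horizon,
                                p_prog = NULL, split = NULL, h_die = NULL,
                                jump_cycle = NULL, p_pps, q_x) {
  sched <- list(regimen = regimen, responder = responder, horizon = horizon,
                p_prog = p_prog, split = split, h_die = h_die,
                jump_cycle = jump_cycle, p_pps = p_pps, q_x = q_x)
  probs <- c(sched$p_prog, sched$h_die, sched$p_pps, sched$q_x, sched$split)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    abort("transition schedule contains probabilities outside [0, 1].")
  }
  structure(sched, class = "transition_schedule")
}

#' Build the transition schedule for a decision-tree cell
#'
#' Converts the stratum's survival inputs into per-cycle transition
#' probabilities for one (regimen, responder status) cell:
#'
#' * Responders face a constant per-cycle progression probability derived
#'   from the exponential fit ([fit_exponential()]) to the arm's PFS
#'   anchors, applied from cycle 1 onward by default
#'   (`options.responder_pfs_mode = "from_cycle_1"`; the alternative
#'   `"after_12m"` keeps responders progression-free for the first 12
#'   cycles).
#' * Nonresponders split into a dying stream and a progressing stream
#'   according to [nonresponder_split()] on the arm's 12-month anchors. The
#'   dying stream follows the exponential shape implied by the OS anchor,
#'   rescaled so its cumulative mortality reaches one at cycle 12 (any
#'   residue is forced to death at the 12-month boundary). The progressing
#'   stream moves deterministically to the progression state at the start of
#'   the cycle after the mean time to progression (default month 9).
#' * The progression state carries the constant post-progression death
#'   probability ([post_progression_death_prob()]).
#' * Every alive state additionally carries per-cycle other-cause mortality,
#'   applied after the disease event within each cycle.
#'
#' @param params A `parameter_set`.
#' @param regimen Regimen name (must have survival inputs under
#'   `survival.arms`).
#' @param responder Logical responder status.
#' @return A `transition_schedule`.
#' @export
build_schedule <- function(params, regimen, responder) {
  horizon <- as.integer(params$economics$horizon_cycles)
  arm <- params$survival$arms[[regimen]]
  if (is.null(arm)) {
    abort(sprintf("configuration error: missing field `survival.arms.%s`.", regimen))
  }
  qx <- params$mortality$monthly_other_cause_death
  if (length(qx) == 1) {
    qx <- rep(qx, horizon)
  } else if (length(qx) < horizon) {
    abort("configuration error: `mortality.monthly_other_cause_death` schedule is shorter than the horizon.")
  } else {
    qx <- qx[seq_len(horizon)]
  }
  p_pps <- post_progression_death_prob(params$survival$mean_post_progression_survival)

  if (responder) {
    lambda <- fit_exponential(arm$pfs_anchors)
    p <- 1 - exp(-lambda)
    p_prog <- switch(params$options$responder_pfs_mode,
      from_cycle_1 = rep(p, horizon),
      after_12m = c(rep(0, min(12L, horizon)), rep(p, max(0L, horizon - 12L)))
    )
    return(transition_schedule(regimen, TRUE, horizon,
                               p_prog = p_prog, p_pps = p_pps, q_x = qx))
  }

  split <- nonresponder_split(arm$pfs12, arm$os12)
  # dying stream: exponential shape from the OS anchor, cumulative incidence
  # rescaled to reach 1 at the 12-month boundary
  lam_os <- -log(arm$os12) / 12
  t12 <- min(12L, horizon)
  tt <- 0:t12
  cdf <- if (lam_os > 0) {
    (1 - exp(-lam_os * tt)) / (1 - exp(-lam_os * 12))
  } else {
    tt / 12
  }
  if (t12 == 12L) cdf[t12 + 1] <- 1
  h <- (cdf[-1] - cdf[-length(cdf)]) / (1 - cdf[-length(cdf)])
  h[!is.finite(h)] <- 1
  h_die <- c(pmin(pmax(h, 0), 1), rep(0, horizon - t12))

  tbar <- params$survival$mean_time_to_progression_nonresp
  jump_cycle <- as.integer(floor(tbar + 1e-9)) + 1L

  transition_schedule(regimen, FALSE, horizon,
                      split = split, h_die = h_die, jump_cycle = jump_cycle,
                      p_pps = p_pps, q_x = qx)
}

#' Build all schedules needed by an initial distribution
#'
#' One [build_schedule()] call per (regimen, responder) cell of `dist`,
#' returned as a named list keyed `"<regimen>.responder"` /
#' `"<regimen>.nonresponder"` as expected by [run_cohort()].
#'
#' @param params A `parameter_set`.
#' @param dist An `initial_distribution`.
#' @return A named list of `transition_schedule` objects.
#' @export
build_schedules <- function(params, dist) {
  keys <- unique(paste0(dist$regimen, ".", ifelse(dist$responder, "responder", "nonresponder")))
  scheds <- lapply(keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    build_schedule(params, parts[[1]], identical(parts[[2]], "responder"))
  })
  setNames(scheds, keys)
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("<transition_schedule> %s, %s, %d cycles\n",
              x$regimen, if (x$responder) "responder" else "nonresponder", x$horizon))
  if (x$responder) {
    cat(sprintf("  per-cycle progression: %.5f (first nonzero)\n",
                x$p_prog[which(x$p_prog > 0)[1]] %||% 0))
  } else {
    cat(sprintf("  nonresponder split: death %.3f / progression %.3f; jump at cycle %d\n",
                x$split[["p_death"]], x$split[["p_progress"]], x$jump_cycle))
  }
  cat(sprintf("  post-progression death: %.5f per cycle\n", x$p_pps))
  invisible(x)
}

#' Export a schedule as a per-cycle tibble
#'
#' @param x A `transition_schedule`.
#' @param ... Unused.
#' @return A tibble with one row per cycle and the per-cycle probabilities.
#' @export
tidy.transition_schedule <- function(x, ...) {
  tibble(
    cycle = seq_len(x$horizon),
    regimen = x$regimen,
    responder = x$responder,
    p_progression = if (x$responder) x$p_prog else
      as.numeric(seq_len(x$horizon) == (x$jump_cycle %||% Inf)) * x$split[["p_progress"]],
    p_death_disease = if (x$responder) 0 else x$h_die * x$split[["p_death"]],
    p_death_progression = x$p_pps,
    p_death_other = x$q_x
  )
}
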