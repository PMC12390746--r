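markov_states <- c("response", "stable", "progression", "death_disease", "death_other")

# evolve one sub-cohort stream over the horizon; returns occupancy + event
# flows per cycle. stream_type is one of "responder", "nonresponder_dying",
# "nonresponder_progressing".
evolve_stream <- function(stream_type, mass, sched, horizon) {
  occ <- matrix(0, nrow = horizon + 1, ncol = 5,
                dimnames = list(NULL, markov_states))
  flows <- matrix(0, nrow = horizon + 1, ncol = 3,
                  dimnames = list(NULL, c("new_progression", "new_death_disease",
                                          "new_death_other")))
  occ[1, if (stream_type == "responder") "response" else "stable"] <- mass
  for (t in seq_len(horizon)) {
    o <- occ[t, ]
    e_prog <- 0
    e_dd <- o[["progression"]] * sched$p_pps  # progression-state deaths first
    o[["progression"]] <- o[["progression"]] - e_dd
    if (stream_type == "responder") {
      e_prog <- o[["response"]] * sched$p_prog[t]
      o[["response"]] <- o[["response"]] - e_prog
    } else if (stream_type == "nonresponder_dying") {
      e <- o[["stable"]] * sched$h_die[t]
      o[["stable"]] <- o[["stable"]] - e
      e_dd <- e_dd + e
    } else if (stream_type == "nonresponder_progressing" &&
               identical(t, as.integer(sched$jump_cycle))) {
      e_prog <- o[["stable"]]
      o[["stable"]] <- 0
    }
    o[["progression"]] <- o[["progression"]] + e_prog
    o[["death_disease"]] <- o[["death_disease"]] + e_dd
    # other-cause mortality on every survivor of the cycle's disease events
    qx <- sched$q_x[t]
    alive <- c("response", "stable", "progression")
    e_do <- sum(o[alive]) * qx
    o[alive] <- o[alive] * (1 - qx)
    o[["death_other"]] <- o[["death_other"]] + e_do
    occ[t + 1, ] <- o
    flows[t + 1, ] <- c(e_prog, e_dd, e_do)
  }
  cbind(cycle = 0:horizon, occ, flows)
}

# expand initial-distribution cells into streams with masses
expand_streams <- function(dist, schedules) {
  rows <- purrr::pmap(dist, function(regimen, responder, mass) {
    key <- paste0(regimen, ".", if (responder) "responder" else "nonresponder")
    sched <- schedules[[key]]
    if (is.null(sched)) {
      abort(sprintf("configuration error: no transition schedule for cell `%s`.", key))
    }
    if (responder) {
      tibble(regimen = regimen, responder = TRUE,
             stream_type = "responder", mass = mass, key = key)
    } else {
      tibble(regimen = regimen, responder = FALSE,
             stream_type = c("nonresponder_dying", "nonresponder_progressing"),
             mass = mass * c(sched$split[["p_death"]], sched$split[["p_progress"]]),
             key = key)
    }
  })
  purrr::list_rbind(rows) |> filter(.data$mass > 0)
}

#' Run the cohort through the Markov model
#'
#' Evolves every (regimen, responder status) sub-cohort of the initial
#' distribution independently through the five health states
#' (response-on-treatment, stable nonresponse, progression, disease death,
#' other-cause death) in monthly cycles, using the per-cell transition
#' schedules. Nonresponder cells are split into their dying and progressing
#' streams on entry. Death states are absorbing; each trace row conserves
#' its stream mass and the cohort total stays one.
#'
#' @param dist An [initial_distribution()].
#' @param schedules Named schedule list from [build_schedules()].
#' @param horizon Number of monthly cycles; defaults to the schedules'
#'   horizon. Schedules shorter than `horizon` are an error.
#' @return A `cohort_trace` tibble with one row per stream and cycle
#'   (columns `regimen`, `responder`, `stream_type`, `cycle`, the five state
#'   occupancies, and per-cycle event inflows `new_progression`,
#'   `new_death_disease`, `new_death_other`), carrying the one-time
#'   tree-stage cost and strategy label as attributes.
#' @export
#' @examples
#' p <- generate_parameter_set("LT1", seed = 1)
#' d <- initial_distribution(p, "CURRENT_PRACTICE")
#' tr <- run_cohort(d, build_schedules(p, d))
run_cohort <- function(dist, schedules, horizon = NULL) {
  horizon <- as.integer(horizon %||% schedules[[1]]$horizon)
  if (horizon < 1) abort("`horizon` must be >= 1 cycle.")
  short <- purrr::map_dbl(schedules, "horizon") < horizon
  if (any(short)) {
    abort(sprintf("configuration error: schedule `%s` is shorter than the horizon.",
                  names(schedules)[short][[1]]))
  }
  streams <- expand_streams(dist, schedules)
  pieces <- purrr::pmap(streams, function(regimen, responder, stream_type, mass, key) {
    m <- evolve_stream(stream_type, mass, schedules[[key]], horizon)
    out <- as_tibble(as.data.frame(m))
    out$regimen <- regimen
    out$responder <- responder
    out$stream_type <- stream_type
    out[c("regimen", "responder", "stream_type", "cycle", markov_states,
          "new_progression", "new_death_disease", "new_death_other")]
  })
  trace <- purrr::list_rbind(pieces)

  totals <- trace |>
    group_by(.data$cycle) |>
    summarise(total = sum(.data$response + .data$stable + .data$progression +
                            .data$death_disease + .data$death_other),
              .groups = "drop")
  stopifnot(all(abs(totals$total - sum(dist$mass)) < 1e-10))

  structure(trace,
            class = c("cohort_trace", class(trace)),
            one_time_cost = attr(dist, "one_time_cost") %||% 0,
            strategy = attr(dist, "strategy"),
            group = attr(dist, "group"),
            horizon = horizon)
}

#' Undiscounted life-years of a cohort trace
#'
#' Sum over cycles 1..T of alive-state occupancy, divided by 12.
#'
#' @param trace A `cohort_trace`.
#' @return Life-years per patient (undiscounted).
#' @export
life_years <- function(trace) {
  trace |>
    filter(.data$cycle >= 1) |>
    summarise(ly = sum(.data$response + .data$stable + .data$progression) / 12) |>
    pull(.data$ly)
}

#' Aggregate a trace over streams
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A tibble with one row per cycle and total occupancy per state.
#' @export
tidy.cohort_trace <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$cycle) |>
    summarise(across(all_of(markov_states), sum), .groups = "drop")
}

#' Plot state occupancy over time
#'
#' Stacked-area chart of cohort occupancy per health state across the
#' horizon, aggregated over sub-cohort streams.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(all_of(markov_states),
                        names_to = "state", values_to = "occupancy") |>
    mutate(state = factor(.data$state, levels = rev(markov_states)))
  ggplot(long, aes(x = .data$cycle, y = .data$occupancy, fill = .data$state)) +
    geom_area() +
    labs(x = "cycle (months)", y = "cohort fraction", fill = "health state",
         title = paste0("Cohort trace", if (!is.null(attr(object, "strategy")))
           paste0(" — ", attr(object, "strategy")))) +
    theme_minimal()
}
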