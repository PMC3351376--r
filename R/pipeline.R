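#' Run the full population state model on one experiment
#'
#' Chains the whole analysis: normalize counts, compute expansion rates,
#' classify them against the neutral calibration, decode hidden states,
#' extract adaptive events, suggest sampling points and summarize the
#' dynamics.
#'
#' @param history A \code{\link{population_history}}.
#' @param cal A \code{neutral_calibration}.
#' @param params Model parameters; default
#'   \code{\link{default_psm_parameters}()}.
#' @param alpha,tails,dist Classifier settings (see
#'   \code{\link{classify_rates}}).
#' @return An object of class \code{psm_report}: a list with the source
#'   \code{history}, \code{rates}, \code{emissions}, \code{states},
#'   \code{events}, \code{sampling}, \code{dynamics} and the long per-point
#'   \code{table} (see \code{\link{write_prediction_report}}).
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   events = data.frame(subpopulation = "red", start_gen = 40, s = 0.1)))
#' cal <- calibrate_neutral(lapply(simulate_neutral_histories(2), history_rates))
#' run_psm(sim$history, cal)
#' @export
run_psm <- function(history, cal, params = default_psm_parameters(),
                    alpha = 0.10, tails = 1, dist = "t") {
  validate_population_history(history)
  rates <- history_rates(history)
  emissions <- classify_rates(rates, cal, alpha = alpha, tails = tails,
                              dist = dist)
  states <- decode_states(emissions, params)
  events <- extract_events(states)
  sampling <- suggest_sampling_points(states, emissions)
  dynamics <- if (nrow(events) > 0)
    summarize_dynamics(events, rates, history)
  else suppressWarnings(summarize_dynamics(events, rates, history))
  gens <- history$generations
  n <- length(gens)
  if (nrow(events) > 0) events$event_id <- seq_len(nrow(events))
  rows <- lapply(history$labels, function(lab) {
    ev_id <- rep(NA_integer_, n)
    ev <- events[events$subpopulation == lab, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      pts <- (ev$start_index[i]:ev$end_index[i]) + 1L
      ev_id[pts] <- ev$event_id[i]
    }
    sug <- sampling$suggested_index[sampling$subpopulation == lab] + 1L
    data.frame(
      time_index = seq_len(n) - 1L,
      generation = gens,
      subpopulation = lab,
      emission = c(NA_character_, emissions$symbols[, lab]),
      state = c(NA_character_, states$states[, lab]),
      event_id = ev_id,
      is_sampling_point = seq_len(n) %in% sug,
      stringsAsFactors = FALSE)
  })
  structure(list(history = history, rates = rates, emissions = emissions,
                 states = states, events = events, sampling = sampling,
                 dynamics = dynamics, table = do.call(rbind, rows),
                 alpha = alpha, tails = tails),
            class = "psm_report")
}

#' @export
print.psm_report <- function(x, ...) {
  print(x$history)
  print(x$emissions)
  cat(sprintf("  adaptive events: %d\n", nrow(x$events)))
  if (nrow(x$events) > 0) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %s: generations %g-%g (%d points)\n",
                  x$events$subpopulation[i], x$events$start_gen[i],
                  x$events$end_gen[i], x$events$duration_points[i]))
    cat("  sampling suggestions:\n")
    for (i in seq_len(nrow(x$sampling)))
      cat(sprintf("    %s: generation %g (index %d)\n",
                  x$sampling$subpopulation[i],
                  x$sampling$suggested_generation[i],
                  x$sampling$suggested_index[i]))
  }
  invisible(x)
}
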