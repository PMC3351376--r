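#' Suggest sampling points for mutant isolation
#'
#' After an adaptive event the expanding mutant is assumed to reach its
#' highest frequency just before its subpopulation starts to contract. For
#' each event, the subpopulation's emission sequence is scanned forward from
#' the event's end until the first significant negative slope (symbol N) at
#' position i; the suggested sample is i - 1. If no N occurs before the
#' series ends (an expansion that overruns the vessel), the final time point
#' is suggested. A suggestion that would precede the event's start is
#' clamped to the event's end, since a sample taken before the expansion
#' cannot hold the mutant at its maximum.
#'
#' @param states A \code{psm_states} object (or matrix/vector over A/N).
#' @param emissions The matching \code{psm_emissions} (or matrix/vector over
#'   P/N/Z), same shape.
#' @param generations Optional generation vector (length one more than the
#'   sequences) used to report \code{suggested_generation}.
#' @return A data frame with one row per adaptive event:
#'   \code{subpopulation}, \code{start_index}, \code{end_index},
#'   \code{suggested_index} (same 1-based interval axis as the events;
#'   index k attaches to the sample at \code{generations[k + 1]}) and
#'   \code{suggested_generation}. Zero rows when there are no events.
#' @examples
#' suggest_sampling_points(c("N","N","A","A","A","N","N"),
#'                         c("Z","Z","P","P","P","N","Z"))
#' @export
suggest_sampling_points <- function(states, emissions, generations = NULL) {
  sm <- as_state_matrix(states)
  em <- as_emission_matrix(emissions)
  if (!identical(dim(sm$states), dim(em$symbols)))
    stop("states and emissions must have the same shape")
  if (is.null(generations)) generations <- sm$generations
  if (is.null(generations)) generations <- em$generations
  events <- extract_events(sm$states, generations)
  n <- nrow(sm$states)
  if (nrow(events) == 0) {
    return(data.frame(subpopulation = character(), start_index = integer(),
                      end_index = integer(), suggested_index = integer(),
                      suggested_generation = numeric(),
                      stringsAsFactors = FALSE))
  }
  sug <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    lab <- events$subpopulation[i]
    e <- events$end_index[i]
    sym <- em$symbols[, lab]
    hit <- which(sym[e:n] == "N")
    if (length(hit) == 0) {
      sug[i] <- n
    } else {
      s <- e + hit[1] - 1L - 1L       # index of first N, minus one
      if (s < events$start_index[i]) s <- e
      sug[i] <- s
    }
  }
  out <- data.frame(subpopulation = events$subpopulation,
                    start_index = events$start_index,
                    end_index = events$end_index,
                    suggested_index = sug,
                    stringsAsFactors = FALSE)
  out$suggested_generation <- if (!is.null(generations))
    generations[out$suggested_index + 1L] else NA_real_
  # A suggestion should not land inside a later event of the same
  # subpopulation; possible when expansions chain back-to-back.
  for (i in seq_len(nrow(out))) {
    later <- events$subpopulation == out$subpopulation[i] &
      events$start_index > out$end_index[i] &
      events$start_index <= out$suggested_index[i] &
      events$end_index >= out$suggested_index[i]
    if (any(later))
      warning("sampling suggestion for ", out$subpopulation[i],
              " at index ", out$suggested_index[i],
              " falls inside a subsequent adaptive event")
  }
  out
}
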