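#' Score decoded states against human annotation
#'
#' Pools every classified time point of every subpopulation and returns the
#' confusion fractions between the model states and the human annotation:
#' TP (both A), TN (both N), FP (model A, annotation N) and FN (model N,
#' annotation A). Decoded state at sequence index k is compared against the
#' annotation at time point k + 1, the sample at which that state is
#' reported after the back-shift. Since human annotation is itself
#' imperfect, these fractions measure model-annotator agreement rather than
#' truth.
#'
#' @param predicted A \code{psm_states} object (or character matrix over
#'   A/N, \code{(n-1) x J}).
#' @param annotated An \code{annotated_history} (or character \code{n x J}
#'   annotation matrix).
#' @return A named list of class \code{psm_error_rates} with fractions
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn} (summing to 1) and the count
#'   \code{n_points}.
#' @export
compare_annotations <- function(predicted, annotated) {
  pm <- as_state_matrix(predicted)$states
  ann <- if (inherits(annotated, "annotated_history")) annotated$states
         else as.matrix(annotated)
  if (nrow(ann) != nrow(pm) + 1L || ncol(ann) != ncol(pm))
    stop("annotation matrix (", nrow(ann), " x ", ncol(ann),
         ") does not align with predicted states (", nrow(pm), " x ",
         ncol(pm), "): expected one more row and equal columns")
  ref <- ann[-1L, , drop = FALSE]   # annotations at time points 2..n
  n <- length(ref)
  out <- list(tp = sum(pm == "A" & ref == "A") / n,
              tn = sum(pm == "N" & ref == "N") / n,
              fp = sum(pm == "A" & ref == "N") / n,
              fn = sum(pm == "N" & ref == "A") / n,
              n_points = n)
  class(out) <- "psm_error_rates"
  out
}

#' @export
print.psm_error_rates <- function(x, ...) {
  cat(sprintf("Model vs annotation over %d points:\n", x$n_points))
  cat(sprintf("  TP %.3f  TN %.3f  FP %.3f  FN %.3f  (accuracy %.3f)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn))
  invisible(x)
}

#' Population-dynamics summary of one experiment
#'
#' Computes the per-experiment statistics used to compare evolutionary
#' dynamics across systems: the number of adaptive events per generation per
#' colored subpopulation, the mean and SD of the expansion rate over
#' intervals inside adaptive events ("rate of PEX"), and the mean and SD of
#' event length. Event length is measured in sampling points, matching the
#' scale on which events are decoded; a per-generation length is also
#' returned for convenience.
#'
#' @param events Event data frame from \code{\link{extract_events}}.
#' @param rates The matching \code{psm_rates}.
#' @param history The source \code{population_history}.
#' @return A named list of class \code{psm_dynamics} with
#'   \code{ae_per_gen_color}, \code{rate_of_pex_mean}, \code{rate_of_pex_sd},
#'   \code{ae_length_mean}, \code{ae_length_sd},
#'   \code{ae_length_gens_mean} and \code{n_events}. All zero (with a
#'   warning) when there are no events.
#' @export
summarize_dynamics <- function(events, rates, history) {
  stopifnot(inherits(rates, "psm_rates"))
  validate_population_history(history)
  J <- length(history$labels)
  total_gens <- max(history$generations) - min(history$generations)
  if (nrow(events) == 0) {
    warning("no adaptive events; dynamics summary is all zero")
    out <- list(ae_per_gen_color = 0, rate_of_pex_mean = 0,
                rate_of_pex_sd = 0, ae_length_mean = 0, ae_length_sd = 0,
                ae_length_gens_mean = 0, n_events = 0L)
    class(out) <- "psm_dynamics"
    return(out)
  }
  ev_rates <- unlist(lapply(seq_len(nrow(events)), function(i) {
    rates$r[events$start_index[i]:events$end_index[i],
            events$subpopulation[i]]
  }))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- list(
    ae_per_gen_color = nrow(events) / (total_gens * J),
    rate_of_pex_mean = mean(ev_rates),
    rate_of_pex_sd = sd0(ev_rates),
    ae_length_mean = mean(events$duration_points),
    ae_length_sd = sd0(events$duration_points),
    ae_length_gens_mean = mean(events$duration_gens),
    n_events = nrow(events))
  class(out) <- "psm_dynamics"
  out
}

#' @export
print.psm_dynamics <- function(x, ...) {
  cat(sprintf("Dynamics: %d events, AE/gen-color %.4g\n",
              x$n_events, x$ae_per_gen_color))
  cat(sprintf("  rate of PEX %.4g (%.4g), AE length %.3g (%.3g) points\n",
              x$rate_of_pex_mean, x$rate_of_pex_sd,
              x$ae_length_mean, x$ae_length_sd))
  invisible(x)
}

#' Length-weighted distribution of adaptive events across subpopulations
#'
#' Each subpopulation's share of the adaptive-event "mass" of an experiment,
#' weighting events by their length in points and normalizing so the shares
#' sum to one. A consistent bias of this distribution toward one label
#' across replicate experiments suggests a jackpot mutant (a beneficial
#' mutation predating selective exposure) or a non-neutral label.
#'
#' @param events Event data frame from \code{\link{extract_events}}.
#' @param labels Subpopulation labels defining the output order (labels with
#'   no events get share 0); defaults to the labels present in
#'   \code{events}.
#' @return Named numeric vector of shares summing to 1.
#' @export
event_distribution <- function(events, labels = NULL) {
  if (nrow(events) == 0)
    stop("degenerate input: no adaptive events to distribute")
  if (is.null(labels)) labels <- unique(events$subpopulation)
  mass <- vapply(labels, function(lab) {
    sum(events$duration_points[events$subpopulation == lab])
  }, numeric(1))
  mass / sum(mass)
}
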