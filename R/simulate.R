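#' Configuration for the chemostat sweep simulator
#'
#' Describes a simulated VERT experiment: several fluorescently labeled,
#' initially isogenic subpopulations at equal starting proportions, sampled
#' by FACS at regular generation intervals, with beneficial mutants arising
#' at planned times inside chosen subpopulations. Mutant lineages grow by
#' relative fitness s per generation in competition with the rest of the
#' vessel (logistic frequency dynamics arise from normalization), and the
#' FACS measurement adds multinomial counting noise plus optional Gaussian
#' jitter on the observed proportions.
#'
#' @param labels Character vector of subpopulation labels (J >= 2); default
#'   \code{c("red", "green", "yellow")}.
#' @param n_points Number of FACS samples; default 30.
#' @param gens_per_point Generations between consecutive samples; default 10
#'   (a daily sample of a slow continuous culture).
#' @param events Data frame with columns \code{subpopulation},
#'   \code{start_gen}, \code{s}: each row plants one beneficial mutant of
#'   selection coefficient \code{s} (per generation) in the given
#'   subpopulation at the given generation. Default: none (a neutrality
#'   experiment).
#' @param mutant_init Initial frequency of a new mutant within its host
#'   subpopulation; default 1e-4.
#' @param total_counts Total FACS events counted per sample; default 1e5.
#' @param noise_sd Gaussian measurement noise on observed proportions;
#'   default 0.005.
#' @param detect_threshold Mutant frequency within its host subpopulation
#'   above which the ground-truth state is A (while still expanding);
#'   default 0.05 — below that, the slope signal drowns in realistic noise.
#' @param min_gain Minimum population-wide mutant frequency gain per
#'   generation for the mutant to count as "still expanding"; default 1e-3.
#' @param seed Integer seed making the simulation reproducible; default 1.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(labels = c("red", "green", "yellow"),
                       n_points = 30, gens_per_point = 10,
                       events = NULL, mutant_init = 1e-4,
                       total_counts = 1e5, noise_sd = 0.005,
                       detect_threshold = 0.05, min_gain = 1e-3,
                       seed = 1) {
  if (length(labels) < 2) stop("need at least 2 subpopulations")
  if (is.null(events))
    events <- data.frame(subpopulation = character(), start_gen = numeric(),
                         s = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("subpopulation", "start_gen", "s") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(!events$subpopulation %in% labels))
      stop("event subpopulation not among labels")
    if (any(events$start_gen < 0))
      stop("impossible event plan: start_gen before 0")
    if (any(events$s < 0)) stop("selection coefficients must be >= 0")
  }
  if (noise_sd < 0 || total_counts <= 0 || n_points < 2 ||
      gens_per_point <= 0 || mutant_init <= 0 || mutant_init >= 1)
    stop("invalid simulation configuration")
  structure(list(labels = labels, n_points = as.integer(n_points),
                 gens_per_point = gens_per_point, events = events,
                 mutant_init = mutant_init, total_counts = total_counts,
                 noise_sd = noise_sd, detect_threshold = detect_threshold,
                 min_gain = min_gain, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a VERT experiment with known ground truth
#'
#' Runs the lineage-competition dynamics of \code{\link{sim_config}} and
#' returns both the observed FACS history and the ground-truth annotation.
#' A subpopulation's true state at a sample is A when at least one of its
#' mutant lineages has risen above the detectability threshold within the
#' subpopulation and is still gaining population-wide frequency; otherwise
#' N. The first sample is always N (nothing expands at inoculation).
#'
#' Deterministic given \code{config$seed}: the same configuration always
#' yields identical output.
#'
#' @param config A \code{sim_config}.
#' @param experiment_id Identifier for the generated history.
#' @return A list with elements \code{history}
#'   (\code{\link{population_history}} of observed counts), \code{truth}
#'   (\code{\link{annotated_history}} carrying the ground-truth states) and
#'   \code{true_proportions} (\code{n x J} matrix of noise-free
#'   subpopulation proportions).
#' @export
simulate_experiment <- function(config, experiment_id = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- length(config$labels)
  n <- config$n_points
  times <- (seq_len(n) - 1) * config$gens_per_point
  ev <- config$events
  ev <- ev[order(ev$start_gen), , drop = FALSE]
  # Lineage table: resident lineage per subpopulation (fitness 0) plus one
  # lineage per planted mutant. Abundances are relative; only ratios matter.
  lin <- data.frame(host = config$labels, w = 0,
                    a = rep(1 / J, J), stringsAsFactors = FALSE)
  lin$mutant <- FALSE
  t_now <- 0
  pending <- seq_len(nrow(ev))
  frac_lineage <- matrix(0, n, 0)
  lineage_rows <- list()
  snapshots <- vector("list", n)
  advance <- function(lin, dt) {
    lin$a <- lin$a * exp(lin$w * dt)
    lin$a <- lin$a / sum(lin$a)   # renormalize for numerical stability
    lin
  }
  next_change <- function() if (length(pending)) ev$start_gen[pending[1]] else Inf
  for (i in seq_len(n)) {
    t_target <- times[i]
    while (next_change() <= t_target) {
      k <- pending[1]
      lin <- advance(lin, ev$start_gen[k] - t_now)
      t_now <- ev$start_gen[k]
      host_row <- which(lin$host == ev$subpopulation[k] & !lin$mutant)[1]
      m0 <- config$mutant_init * lin$a[host_row]
      lin$a[host_row] <- lin$a[host_row] - m0
      lin <- rbind(lin, data.frame(host = ev$subpopulation[k], w = ev$s[k],
                                   a = m0, mutant = TRUE,
                                   stringsAsFactors = FALSE))
      pending <- pending[-1]
    }
    lin <- advance(lin, t_target - t_now)
    t_now <- t_target
    snapshots[[i]] <- lin
  }
  n_lineages <- nrow(snapshots[[n]])
  # Per-sample lineage frequencies (absent lineages are 0 before arising).
  freq <- matrix(0, n, n_lineages)
  for (i in seq_len(n)) {
    li <- snapshots[[i]]
    freq[i, seq_len(nrow(li))] <- li$a / sum(li$a)
  }
  meta <- snapshots[[n]][, c("host", "w", "mutant")]
  true_prop <- sapply(config$labels, function(lab) {
    rowSums(freq[, meta$host == lab, drop = FALSE])
  })
  # Ground truth per subpopulation and sample.
  states <- matrix("N", n, J, dimnames = list(NULL, config$labels))
  for (m in which(meta$mutant)) {
    within <- freq[, m] / true_prop[, meta$host[m]]
    gain <- c(0, diff(freq[, m])) / config$gens_per_point
    adaptive <- within >= config$detect_threshold & gain >= config$min_gain
    adaptive[1] <- FALSE
    states[adaptive, meta$host[m]] <- "A"
  }
  # FACS observation: multinomial counting noise, then Gaussian jitter on
  # the observed proportions.
  counts <- matrix(0, n, J, dimnames = list(NULL, config$labels))
  for (i in seq_len(n)) {
    obs <- stats::rmultinom(1, size = config$total_counts,
                            prob = true_prop[i, ])[, 1]
    if (config$noise_sd > 0) {
      obs <- obs + config$total_counts *
        stats::rnorm(J, mean = 0, sd = config$noise_sd)
      obs <- pmax(obs, 1)
    }
    counts[i, ] <- obs
  }
  history <- population_history(times, counts, experiment_id = experiment_id)
  list(history = history,
       truth = annotated_history(history, states),
       true_proportions = true_prop)
}

#' Simulate a set of neutrality experiments
#'
#' Convenience wrapper running \code{\link{simulate_experiment}} with no
#' planted mutants, for classifier calibration.
#'
#' @param n_experiments Number of independent neutral histories.
#' @param config Base \code{sim_config} (its \code{events} are ignored).
#' @return A list of \code{population_history} objects.
#' @export
simulate_neutral_histories <- function(n_experiments = 4,
                                       config = sim_config()) {
  lapply(seq_len(n_experiments), function(k) {
    cfg <- config
    cfg$events <- cfg$events[0, , drop = FALSE]
    cfg$seed <- config$seed + k - 1L
    simulate_experiment(cfg, experiment_id = paste0("neutral", k))$history
  })
}

#' Simulate annotated histories from known model parameters
#'
#' Generates training material whose hidden states and emission symbols are
#' drawn from a given population state model, then builds FACS count data
#' that the statistical classifier maps back onto exactly those symbols.
#' Used to check that supervised training recovers the generating
#' parameters.
#'
#' FACS proportion data is compositional: the initial-fraction-weighted
#' slopes of the normalized trajectories sum to zero at every step, so a set
#' of independently drawn signal trajectories cannot be realized as counts
#' on its own. Each generated history therefore carries an extra balancing
#' \code{"reference"} column absorbing the residual; it is annotated N
#' throughout and should be excluded from training via the \code{columns}
#' argument of \code{\link{train_supervised}}.
#'
#' Hidden chains start in state N and evolve with the nominal switching
#' probabilities (the run-length penalty shapes decoding, not the
#' generative chain, and supervised training estimates the nominal values).
#' Symbols map to slopes comfortably away from the classifier threshold:
#' P and N to +/- \code{slope} with small jitter, Z to a small slope well
#' inside the acceptance region.
#'
#' @param params Generating \code{psm_parameters}.
#' @param cal The \code{neutral_calibration} that will be used to classify
#'   the data (defines the significance threshold to stay clear of).
#' @param n_histories Number of independent histories.
#' @param n_points Samples per history.
#' @param n_signal Number of model-generated signal columns per history.
#' @param gens_per_point Generations between samples; default 2.
#' @param slope Magnitude of a significant slope; default 0.012.
#' @param alpha,tails Classifier settings the data must satisfy.
#' @param seed Integer seed.
#' @return A list of \code{annotated_history} objects; the attribute
#'   \code{"signal_labels"} names the model-generated columns.
#' @export
simulate_annotated_histories <- function(params, cal, n_histories = 10,
                                         n_points = 26, n_signal = 2,
                                         gens_per_point = 2, slope = 0.012,
                                         alpha = 0.10, tails = 1, seed = 1) {
  stopifnot(inherits(params, "psm_parameters"),
            inherits(cal, "neutral_calibration"))
  set.seed(seed)
  p_level <- if (tails == 1) 1 - alpha else 1 - alpha / 2
  thr <- stats::qt(p_level, df = cal$n_neutral - 1) *
    cal$sigma_r / sqrt(cal$n_neutral)
  if (slope < 2 * thr)
    stop("slope magnitude too close to the significance threshold (",
         signif(thr, 3), ")")
  z_band <- 0.5 * thr
  signal_labels <- paste0("s", seq_len(n_signal))
  f0 <- 0.3 / n_signal      # initial fraction per signal column
  out <- vector("list", n_histories)
  for (h in seq_len(n_histories)) {
    times <- (seq_len(n_points) - 1) * gens_per_point
    P <- matrix(1, n_points, n_signal)
    ann <- matrix("N", n_points, n_signal + 1,
                  dimnames = list(NULL, c(signal_labels, "reference")))
    for (j in seq_len(n_signal)) {
      state <- "N"
      for (k in seq_len(n_points - 1)) {
        p_switch <- if (state == "A") params$p_AN0 else params$p_NA0
        if (stats::runif(1) < p_switch) state <- if (state == "A") "N" else "A"
        e <- if (state == "A") params$e_A else params$e_N
        sym <- sample(PSM_SYMBOLS, 1, prob = e)
        r <- switch(sym,
                    P = slope + stats::runif(1, -0.08, 0.08) * slope,
                    N = -slope + stats::runif(1, -0.08, 0.08) * slope,
                    Z = stats::runif(1, -z_band, z_band))
        P[k + 1, j] <- P[k, j] + r * gens_per_point
        ann[k, j] <- state
      }
      ann[n_points, j] <- ann[n_points - 1, j]
    }
    # Constant-total composition: reference column absorbs the imbalance,
    # so the realized normalized trajectories equal P exactly.
    frac <- cbind(f0 * P, 1 - rowSums(f0 * P))
    if (any(frac <= 0))
      stop("trajectory drifted out of range; shorten histories or reduce slope")
    counts <- frac * 1e6
    colnames(counts) <- c(signal_labels, "reference")
    hist <- population_history(times, counts,
                               experiment_id = paste0("trainsim", h))
    out[[h]] <- annotated_history(hist, ann)
  }
  attr(out, "signal_labels") <- signal_labels
  out
}
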