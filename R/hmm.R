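# Emission alphabet order used throughout: N, Z, P.
PSM_SYMBOLS <- c("N", "Z", "P")

# Counter cap before exponentiation; exp(-50) ~ 2e-22, indistinguishable
# from 0 for any decision while avoiding pointless underflow of long runs.
PSM_COUNTER_CAP <- 50L

#' Population state model parameters
#'
#' The model has two hidden states: A (the subpopulation is undergoing an
#' adaptive expansion) and N (it is not). Its free parameters are the nominal
#' switching probabilities \code{p_AN0} (A to N) and \code{p_NA0} (N to A)
#' and one emission distribution over the classifier symbols \{N, Z, P\} per
#' state. The staying probabilities are the complements
#' \eqn{P_{AA} = 1 - P_{AN}} and \eqn{P_{NN} = 1 - P_{NA}}.
#'
#' @param p_AN0 Nominal A-to-N transition probability, in (0, 1).
#' @param p_NA0 Nominal N-to-A transition probability, in (0, 1).
#' @param e_A Named numeric vector: emission probabilities of N, Z, P in
#'   state A; must sum to 1.
#' @param e_N Emission probabilities in state N; must sum to 1.
#' @return An object of class \code{psm_parameters}.
#' @seealso \code{\link{default_psm_parameters}} for the reference values
#'   trained on annotated multicolor yeast chemostats.
#' @export
psm_parameters <- function(p_AN0, p_NA0, e_A, e_N) {
  norm_e <- function(e, what) {
    if (is.null(names(e))) names(e) <- PSM_SYMBOLS
    if (!setequal(names(e), PSM_SYMBOLS))
      stop(what, " must be named with symbols N, Z, P")
    e <- e[PSM_SYMBOLS]
    if (any(e < 0) || any(e > 1) || abs(sum(e) - 1) > 1e-9)
      stop(what, " must be a probability distribution summing to 1")
    e
  }
  for (p in c(p_AN0, p_NA0))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("nominal transition probabilities must lie in (0, 1)")
  structure(list(p_AN0 = as.numeric(p_AN0), p_NA0 = as.numeric(p_NA0),
                 e_A = norm_e(e_A, "e_A"), e_N = norm_e(e_N, "e_N")),
            class = "psm_parameters")
}

#' Reference model parameters
#'
#' The switching probabilities and emission distributions obtained by
#' supervised training on annotated multicolor yeast glucose-limited
#' chemostat experiments. These ship as the default so that decoding works
#' out of the box; retrain with \code{\link{train_supervised}} when annotated
#' data for a new species or condition is available.
#'
#' @return A \code{psm_parameters} object with \code{p_AN0} = 0.154,
#'   \code{p_NA0} = 0.079, \code{e_A} = (N 0.102, Z 0.150, P 0.748) and
#'   \code{e_N} = (N 0.434, Z 0.337, P 0.229).
#' @export
default_psm_parameters <- function() {
  psm_parameters(p_AN0 = 0.154, p_NA0 = 0.079,
                 e_A = c(N = 0.102, Z = 0.150, P = 0.748),
                 e_N = c(N = 0.434, Z = 0.337, P = 0.229))
}

#' @export
print.psm_parameters <- function(x, ...) {
  cat("Population state model parameters\n")
  cat(sprintf("  transitions: p_AN0 = %.4g, p_NA0 = %.4g\n", x$p_AN0, x$p_NA0))
  cat(sprintf("  e_A: N %.3f  Z %.3f  P %.3f\n",
              x$e_A["N"], x$e_A["Z"], x$e_A["P"]))
  cat(sprintf("  e_N: N %.3f  Z %.3f  P %.3f\n",
              x$e_N["N"], x$e_N["Z"], x$e_N["P"]))
  invisible(x)
}

#' Run-length-penalized transition probabilities
#'
#' Sustained runs of like symbols make leaving the current dynamic regime
#' less likely: after \code{c_p} contiguous P symbols the A-to-N probability
#' decays as \eqn{P_{AN} = P_{AN}^\circ e^{-C_P}}, and after \code{c_notp}
#' contiguous N/Z symbols the N-to-A probability decays as
#' \eqn{P_{NA} = P_{NA}^\circ e^{-C_{!P}}}. The staying probabilities are the
#' complements. This run-length dependence is a deliberate departure from a
#' time-homogeneous Markov chain: an expansion that has survived drift keeps
#' expanding non-randomly for a while.
#'
#' @param params A \code{psm_parameters} object.
#' @param c_p Non-negative count of contiguous P symbols seen so far.
#' @param c_notp Non-negative count of contiguous N/Z symbols seen so far.
#' @return Named numeric vector with elements \code{p_AN}, \code{p_NA},
#'   \code{p_AA}, \code{p_NN}.
#' @examples
#' effective_transitions(default_psm_parameters(), c_p = 2, c_notp = 0)
#' @export
effective_transitions <- function(params, c_p = 0, c_notp = 0) {
  stopifnot(inherits(params, "psm_parameters"), c_p >= 0, c_notp >= 0)
  p_an <- params$p_AN0 * exp(-min(c_p, PSM_COUNTER_CAP))
  p_na <- params$p_NA0 * exp(-min(c_notp, PSM_COUNTER_CAP))
  c(p_AN = p_an, p_NA = p_na, p_AA = 1 - p_an, p_NN = 1 - p_na)
}

#' Advance the run-length counters by one emission symbol
#'
#' A P symbol extends the positive run and resets the non-positive run;
#' an N or Z symbol does the opposite. At most one counter is ever positive.
#'
#' @param counters Named integer vector \code{c(c_p = , c_notp = )}.
#' @param symbol One of \code{"P"}, \code{"N"}, \code{"Z"}.
#' @return Updated counter vector.
#' @export
update_counters <- function(counters = c(c_p = 0L, c_notp = 0L), symbol) {
  if (!symbol %in% PSM_SYMBOLS)
    stop("unknown emission symbol: ", symbol)
  if (symbol == "P")
    c(c_p = unname(counters["c_p"]) + 1L, c_notp = 0L)
  else
    c(c_p = 0L, c_notp = unname(counters["c_notp"]) + 1L)
}

emission_prob <- function(params, state, symbol) {
  if (state == "A") params$e_A[[symbol]] else params$e_N[[symbol]]
}

# Greedy forward decode of one symbol vector; returns the pre-shift state
# vector. Maintains a single path: at each step the effective (penalized)
# transition probabilities are computed from the run counters accumulated
# over symbols strictly before the decision, the likelihoods of staying vs
# switching are compared (ties stay), and only then do the counters absorb
# the current symbol.
decode_one <- function(symbols, params) {
  n <- length(symbols)
  out <- character(n)
  state <- "N"   # populations are not expanding at inoculation
  counters <- c(c_p = 0L, c_notp = 0L)
  for (i in seq_len(n)) {
    s <- symbols[i]
    tr <- effective_transitions(params, counters["c_p"], counters["c_notp"])
    other <- if (state == "A") "N" else "A"
    p_stay <- if (state == "A") tr[["p_AA"]] else tr[["p_NN"]]
    p_switch <- if (state == "A") tr[["p_AN"]] else tr[["p_NA"]]
    stay <- p_stay * emission_prob(params, state, s)
    switch. <- p_switch * emission_prob(params, other, s)
    if (switch. > stay) state <- other
    out[i] <- state
    counters <- update_counters(counters, s)
  }
  out
}

backshift <- function(states) {
  n <- length(states)
  if (n <= 1) return(states)
  c(states[-1], states[n])
}

#' Decode emission sequences into hidden population states
#'
#' Finds the most likely A/N state path for each subpopulation's emission
#' symbols by the Viterbi algorithm and applies the back-shift: each decoded
#' state is translated one time point earlier (the last position repeats the
#' final decoded state), an empirical correction that improves alignment
#' with human annotation. All paths start in state N, reflecting that no
#' population is expanding immediately after inoculation.
#'
#' The transition probabilities vary along the sequence: at every step they
#' are penalized by the run-length counters accumulated over the symbols
#' strictly before that step (see \code{\link{effective_transitions}}).
#' Because the counters depend only on the emission symbols, never on the
#' hidden path, the per-step transition matrices are known up front and the
#' standard Viterbi recursion applies unchanged; the decoded path maximizes
#' the joint likelihood of states and symbols under the penalized model.
#'
#' \code{method = "greedy"} instead commits to the locally best choice
#' (stay vs switch) at every step along a single maintained path, ties
#' staying. It is provided for studying how local decisions differ from
#' global decoding; note that with the reference parameters the stay term
#' always dominates pointwise (\eqn{P_{NN} e_N(S) > P_{NA} e_A(S)} for every
#' symbol), so the greedy path never leaves N and detects nothing — only
#' path-level likelihood accumulation makes the model switch states.
#'
#' @param emissions A \code{psm_emissions} object, or a character matrix /
#'   vector over \{P, N, Z\}.
#' @param params A \code{psm_parameters} object; default
#'   \code{\link{default_psm_parameters}()}.
#' @param shift Apply the back-shift (default TRUE).
#' @param method \code{"viterbi"} (default) or \code{"greedy"}.
#' @return An object of class \code{psm_states}: a list with \code{states}
#'   (character matrix over \{A, N\}, same shape as the emission symbols),
#'   \code{generations} (if known) and \code{labels}.
#' @examples
#' decode_states(c("Z", "Z", "P", "P", "P", "P", "N", "Z"), shift = FALSE)
#' @export
decode_states <- function(emissions, params = default_psm_parameters(),
                          shift = TRUE, method = c("viterbi", "greedy")) {
  method <- match.arg(method)
  em <- as_emission_matrix(emissions)
  if (nrow(em$symbols) == 0)
    stop("cannot decode an empty emission sequence")
  decoder <- if (method == "viterbi") viterbi_one else decode_one
  dec <- apply(em$symbols, 2, decoder, params = params)
  if (is.null(dim(dec)))
    dec <- matrix(dec, nrow = 1, dimnames = list(NULL, em$labels))
  if (shift) dec <- apply(dec, 2, backshift)
  if (is.null(dim(dec)))
    dec <- matrix(dec, nrow = 1, dimnames = list(NULL, em$labels))
  colnames(dec) <- em$labels
  structure(list(states = dec, generations = em$generations,
                 labels = em$labels),
            class = "psm_states")
}

# Accept psm_emissions, a matrix, or a single vector of symbols.
as_emission_matrix <- function(emissions) {
  if (inherits(emissions, "psm_emissions"))
    return(list(symbols = emissions$symbols,
                generations = emissions$generations,
                labels = emissions$labels))
  m <- if (is.matrix(emissions)) emissions else matrix(emissions, ncol = 1)
  if (is.null(colnames(m))) colnames(m) <- paste0("pop", seq_len(ncol(m)))
  bad <- setdiff(unique(as.vector(m)), PSM_SYMBOLS)
  if (length(bad) > 0)
    stop("emission symbols must be P, N or Z; found: ",
         paste(bad, collapse = ", "))
  list(symbols = m, generations = NULL, labels = colnames(m))
}

#' @export
print.psm_states <- function(x, ...) {
  cat(sprintf("Decoded states: %d intervals x %d subpopulations (%d in state A)\n",
              nrow(x$states), ncol(x$states), sum(x$states == "A")))
  invisible(x)
}

# Viterbi decode of one symbol vector with per-step penalized transition
# matrices; returns the pre-shift state path.
viterbi_one <- function(symbols, params) {
  n <- length(symbols)
  states <- c("A", "N")
  # Counter trajectory is emission-driven: counters[i, ] are the run counts
  # in force when deciding symbol i (accumulated over symbols 1..i-1).
  cp <- cn <- integer(n)
  ctr <- c(c_p = 0L, c_notp = 0L)
  for (i in seq_len(n)) {
    cp[i] <- ctr["c_p"]; cn[i] <- ctr["c_notp"]
    ctr <- update_counters(ctr, symbols[i])
  }
  logp <- matrix(-Inf, n, 2, dimnames = list(NULL, states))
  back <- matrix(NA_character_, n, 2, dimnames = list(NULL, states))
  for (i in seq_len(n)) {
    tr <- effective_transitions(params, cp[i], cn[i])
    A <- log(matrix(c(tr["p_AA"], tr["p_NA"], tr["p_AN"], tr["p_NN"]),
                    2, 2, dimnames = list(states, states)))
    for (s in states) {
      e <- log(emission_prob(params, s, symbols[i]))
      if (i == 1) {
        logp[1, s] <- A["N", s] + e   # all paths start in N
        back[1, s] <- "N"
      } else {
        cand <- logp[i - 1, ] + A[, s]
        best <- states[which.max(cand)]
        logp[i, s] <- cand[best] + e
        back[i, s] <- best
      }
    }
  }
  path <- character(n)
  path[n] <- states[which.max(logp[n, ])]
  for (i in rev(seq_len(n - 1))) path[i] <- back[i + 1, path[i + 1]]
  path
}

#' Train model parameters from annotated histories
#'
#' Supervised estimation by counting: the nominal switching probabilities
#' are the observed fractions of A-to-N (and N-to-A) transitions among
#' occupancies of the source state that have a successor, and each state's
#' emission distribution is the observed symbol frequency while in that
#' state. Emissions are derived from the raw counts with the statistical
#' classifier, so training needs a neutral calibration. Annotated state at
#' time point k is paired with the slope classified over the interval
#' (k, k+1); this pairing is the exact inverse of the decoder's back-shift,
#' so a decoder trained this way reproduces its training annotations.
#'
#' A Laplace-style pseudocount (default 0.5) is added to every transition
#' and emission tally so that small annotated sets cannot produce zero
#' probabilities; with \code{pseudocount = 0} a state never visited (or
#' never followed) is an error.
#'
#' @param training An \code{annotated_history} or a list of them.
#' @param cal A \code{neutral_calibration} used to classify the slopes.
#' @param alpha,tails,dist Classifier settings (see
#'   \code{\link{classify_rates}}).
#' @param pseudocount Non-negative tally added to every count; default 0.5.
#' @param columns Optional character vector restricting training to the named
#'   subpopulations (e.g. to exclude an unlabeled reference pool); default
#'   all.
#' @return A \code{psm_parameters} object.
#' @export
train_supervised <- function(training, cal, alpha = 0.10, tails = 1,
                             dist = c("t", "gaussian"), pseudocount = 0.5,
                             columns = NULL) {
  dist <- match.arg(dist)
  if (inherits(training, "annotated_history")) training <- list(training)
  if (length(training) == 0)
    stop("training error: empty training set")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  tally <- list(
    trans = matrix(pseudocount, 2, 2, dimnames = list(c("A", "N"), c("A", "N"))),
    emit = matrix(pseudocount, 2, 3,
                  dimnames = list(c("A", "N"), PSM_SYMBOLS)))
  for (ah in training) {
    stopifnot(inherits(ah, "annotated_history"))
    em <- classify_rates(history_rates(ah$history), cal,
                         alpha = alpha, tails = tails, dist = dist)
    use <- if (is.null(columns)) ah$history$labels
           else intersect(ah$history$labels, columns)
    n <- length(ah$history$generations)
    for (lab in use) {
      st <- ah$states[seq_len(n - 1), lab]   # state at the interval's start
      sy <- em$symbols[, lab]
      for (k in seq_len(n - 1)) {
        tally$emit[st[k], sy[k]] <- tally$emit[st[k], sy[k]] + 1
        if (k < n - 1)
          tally$trans[st[k], st[k + 1]] <- tally$trans[st[k], st[k + 1]] + 1
      }
    }
  }
  from_a <- sum(tally$trans["A", ]); from_n <- sum(tally$trans["N", ])
  if (from_a == 0 || from_n == 0)
    stop("training error: a hidden state is never visited; supply more data ",
         "or a positive pseudocount")
  if (any(rowSums(tally$emit) == 0))
    stop("training error: a hidden state emits no symbols; supply more data ",
         "or a positive pseudocount")
  psm_parameters(
    p_AN0 = tally$trans["A", "N"] / from_a,
    p_NA0 = tally$trans["N", "A"] / from_n,
    e_A = tally$emit["A", ] / sum(tally$emit["A", ]),
    e_N = tally$emit["N", ] / sum(tally$emit["N", ]))
}

#' Extract adaptive events from decoded states
#'
#' An adaptive event is a maximal contiguous run of decoded A states for one
#' subpopulation. Indices are on the interval axis (1-based, inclusive both
#' ends); index k attaches to the sample taken at generation
#' \code{generations[k + 1]}.
#'
#' @param states A \code{psm_states} object, or a character matrix/vector
#'   over \{A, N\}.
#' @param generations Optional numeric vector of generations (length one more
#'   than the state sequence); taken from \code{states} when available.
#' @return A data frame with one row per event: \code{subpopulation},
#'   \code{start_index}, \code{end_index}, \code{start_gen}, \code{end_gen},
#'   \code{duration_points}, \code{duration_gens}.
#' @examples
#' extract_events(c("N", "N", "A", "A", "A", "N", "N"), 0:7 * 10)
#' @export
extract_events <- function(states, generations = NULL) {
  sm <- as_state_matrix(states)
  if (is.null(generations)) generations <- sm$generations
  events <- list()
  for (lab in sm$labels) {
    v <- sm$states[, lab]
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values == "A"
    if (!any(keep)) next
    ev <- data.frame(subpopulation = lab,
                     start_index = starts[keep], end_index = ends[keep],
                     stringsAsFactors = FALSE)
    events[[lab]] <- ev
  }
  if (length(events) == 0) {
    return(data.frame(subpopulation = character(), start_index = integer(),
                      end_index = integer(), start_gen = numeric(),
                      end_gen = numeric(), duration_points = integer(),
                      duration_gens = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out$duration_points <- out$end_index - out$start_index + 1L
  if (!is.null(generations)) {
    out$start_gen <- generations[out$start_index + 1L]
    out$end_gen <- generations[out$end_index + 1L]
    out$duration_gens <- out$end_gen - out$start_gen
  } else {
    out$start_gen <- out$end_gen <- out$duration_gens <- NA_real_
  }
  out[, c("subpopulation", "start_index", "end_index", "start_gen",
          "end_gen", "duration_points", "duration_gens")]
}

as_state_matrix <- function(states) {
  if (inherits(states, "psm_states"))
    return(list(states = states$states, generations = states$generations,
                labels = states$labels))
  m <- if (is.matrix(states)) states else matrix(states, ncol = 1)
  if (is.null(colnames(m))) colnames(m) <- paste0("pop", seq_len(ncol(m)))
  bad <- setdiff(unique(as.vector(m)), c("A", "N"))
  if (length(bad) > 0)
    stop("states must be A or N; found: ", paste(bad, collapse = ", "))
  list(states = m, generations = NULL, labels = colnames(m))
}
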