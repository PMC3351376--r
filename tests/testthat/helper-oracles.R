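# Independent oracles and fixture builders shared across the test files.
# The oracles are deliberately written from scratch (different algorithmic
# structure and code path) so that agreement with the package is a real
# cross-check, not a tautology.

# --- decoding oracles -------------------------------------------------------

# Run counters in force before each decision, recomputed inline.
oracle_counters <- function(symbols) {
  n <- length(symbols)
  cp <- cn <- integer(n)
  p <- 0L; q <- 0L
  for (i in seq_len(n)) {
    cp[i] <- p; cn[i] <- q
    if (symbols[i] == "P") { p <- p + 1L; q <- 0L } else { q <- q + 1L; p <- 0L }
  }
  list(cp = cp, cn = cn)
}

oracle_emit <- function(params, state, sym) {
  if (state == "A") params$e_A[[sym]] else params$e_N[[sym]]
}

# Step-by-step trace keeping, at every step, the best-scoring full path into
# each terminal state (path-list pruning rather than backpointer matrices).
# Pre-shift; all paths start from state N before the first symbol.
oracle_decode <- function(symbols, params) {
  ctr <- oracle_counters(symbols)
  best <- list(N = list(states = character(0), ll = 0), A = NULL)
  for (i in seq_along(symbols)) {
    p_an <- params$p_AN0 * exp(-min(ctr$cp[i], 50))
    p_na <- params$p_NA0 * exp(-min(ctr$cn[i], 50))
    trans <- list(N = c(N = 1 - p_na, A = p_na),
                  A = c(A = 1 - p_an, N = p_an))
    nxt <- list(N = NULL, A = NULL)
    for (from in c("N", "A")) {
      if (is.null(best[[from]])) next
      for (to in c("N", "A")) {
        ll <- best[[from]]$ll + log(trans[[from]][[to]]) +
          log(oracle_emit(params, to, symbols[i]))
        if (is.null(nxt[[to]]) || ll > nxt[[to]]$ll)
          nxt[[to]] <- list(states = c(best[[from]]$states, to), ll = ll)
      }
    }
    best <- nxt
  }
  if (best$N$ll >= best$A$ll) best$N$states else best$A$states
}

# Exhaustive enumeration of all 2^n state paths (short sequences only).
brute_decode <- function(symbols, params) {
  n <- length(symbols)
  stopifnot(n <= 12)
  ctr <- oracle_counters(symbols)
  grid <- as.matrix(expand.grid(rep(list(c("A", "N")), n),
                                stringsAsFactors = FALSE))
  ll <- apply(grid, 1, function(path) {
    prev <- "N"; total <- 0
    for (i in seq_len(n)) {
      p_an <- params$p_AN0 * exp(-min(ctr$cp[i], 50))
      p_na <- params$p_NA0 * exp(-min(ctr$cn[i], 50))
      tr <- if (prev == "A") {
        if (path[i] == "A") 1 - p_an else p_an
      } else {
        if (path[i] == "A") p_na else 1 - p_na
      }
      total <- total + log(tr) + log(oracle_emit(params, path[i], symbols[i]))
      prev <- path[i]
    }
    total
  })
  unname(grid[which.max(ll), ])
}

random_emissions <- function(n, prob = c(N = 0.3, Z = 0.3, P = 0.4)) {
  sample(names(prob), n, replace = TRUE, prob = prob)
}

random_psm_parameters <- function() {
  e <- function() { x <- stats::runif(3, 0.05, 1); x / sum(x) }
  psm_parameters(p_AN0 = stats::runif(1, 0.02, 0.6),
                 p_NA0 = stats::runif(1, 0.02, 0.6),
                 e_A = stats::setNames(e(), c("N", "Z", "P")),
                 e_N = stats::setNames(e(), c("N", "Z", "P")))
}

# --- fixture builders -------------------------------------------------------

toy_history <- function(n = 6, J = 3, seed = 1) {
  set.seed(seed)
  counts <- matrix(stats::runif(n * J, 50, 500), n, J,
                   dimnames = list(NULL, paste0("c", seq_len(J))))
  population_history((seq_len(n) - 1) * 10, counts, experiment_id = "toy")
}

# A psm_rates object holding given slope values directly.
rates_from_slopes <- function(slopes) {
  m <- if (is.matrix(slopes)) slopes else matrix(slopes, ncol = 1)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  structure(list(r = m, generations = (0:nrow(m)) * 10,
                 labels = colnames(m)),
            class = c("psm_rates"))
}

table1_calibration <- function() neutral_calibration(0, 0.018, 64)
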