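#' Normalize FACS counts to proportion trajectories
#'
#' Converts raw per-subpopulation FACS counts into trajectories that start at
#' 1.0 for every subpopulation: the per-time-point population fraction of
#' subpopulation j, divided by its fraction in the inoculum,
#' \deqn{P_{ji} = \frac{x_{ji} / \sum_j x_{ji}}{x_{j0} / \sum_j x_{j0}}.}
#' Normalizing by the initial fraction puts all subpopulations on a common
#' scale regardless of their seeding proportion, so that expansions and
#' contractions are directly comparable across labels.
#'
#' @param history A \code{\link{population_history}}.
#' @return An object of class \code{psm_trajectories}: a list with
#'   \code{P} (\code{n x J} matrix of normalized proportions, first row all
#'   1.0), \code{generations} and \code{labels}.
#' @examples
#' h <- population_history(c(0, 10), cbind(a = c(100, 150), b = c(100, 50)))
#' compute_proportions(h)$P
#' @export
compute_proportions <- function(history) {
  validate_population_history(history)
  x <- history$counts
  tot <- rowSums(x)
  if (any(tot <= 0))
    stop("degenerate input: zero total count at time point(s) ",
         paste(which(tot <= 0), collapse = ", "))
  if (any(x[1, ] <= 0))
    stop("cannot calibrate proportions: subpopulation(s) ",
         paste(colnames(x)[x[1, ] <= 0], collapse = ", "),
         " have zero count at the first time point")
  frac <- x / tot
  P <- sweep(frac, 2, frac[1, ], "/")
  structure(list(P = P, generations = history$generations,
                 labels = history$labels),
            class = "psm_trajectories")
}

#' Per-interval expansion rates of normalized trajectories
#'
#' The population expansion rate for subpopulation j over the interval ending
#' at sample i is the slope of the normalized proportion per generation,
#' \deqn{r_{pe,ij} = (P_{ji} - P_{j,i-1}) / (t_i - t_{i-1}),}
#' where \eqn{t_i} counts generations elapsed (sampling intervals need not be
#' equally spaced). These slopes are the measured variable of the population
#' state model.
#'
#' @param traj A \code{psm_trajectories} object from
#'   \code{\link{compute_proportions}}.
#' @return An object of class \code{psm_rates}: a list with \code{r}
#'   (\code{(n-1) x J} matrix, row k = slope over the interval from sample k
#'   to sample k+1), \code{generations} (length n, from the source history)
#'   and \code{labels}.
#' @export
compute_expansion_rates <- function(traj) {
  stopifnot(inherits(traj, "psm_trajectories"))
  dt <- diff(traj$generations)
  if (any(dt <= 0))
    stop("generations must be strictly increasing (zero-length interval)")
  r <- apply(traj$P, 2, diff) / dt
  if (is.null(dim(r))) r <- matrix(r, nrow = 1, dimnames = list(NULL, traj$labels))
  structure(list(r = r, generations = traj$generations,
                 labels = traj$labels),
            class = "psm_rates")
}

#' Rates straight from a history
#'
#' Convenience composition of \code{\link{compute_proportions}} and
#' \code{\link{compute_expansion_rates}}.
#' @param history A \code{\link{population_history}}.
#' @return A \code{psm_rates} object.
#' @export
history_rates <- function(history) {
  compute_expansion_rates(compute_proportions(history))
}

#' Estimate slope noise from neutrality experiments
#'
#' Neutrality experiments are control runs in which no adaptive events are
#' expected, so every observed slope reflects only measurement noise, drift
#' and label effects. Pooling their slopes gives the mean (\code{mu_r}) and
#' sample standard deviation (\code{sigma_r}) of the neutral expansion rate,
#' against which experimental slopes are tested. Fluorophores with a fitness
#' cost show up as a nonzero \code{mu_r}; the calibration is specific to the
#' instrument and label set and should be recomputed for each setup.
#'
#' @param neutral_rates A \code{psm_rates} object or a list of them, from
#'   neutrality experiments.
#' @return An object of class \code{neutral_calibration}: a list with
#'   \code{mu_r}, \code{sigma_r} (both 1/generation) and \code{n_neutral},
#'   the pooled number of slope measurements.
#' @examples
#' h <- population_history(c(0, 10, 20),
#'                         cbind(a = c(100, 101, 99), b = c(100, 99, 101)))
#' calibrate_neutral(history_rates(h))
#' @export
calibrate_neutral <- function(neutral_rates) {
  if (inherits(neutral_rates, "psm_rates")) neutral_rates <- list(neutral_rates)
  if (length(neutral_rates) == 0)
    stop("calibration error: no neutral rate series supplied")
  slopes <- unlist(lapply(neutral_rates, function(rs) {
    stopifnot(inherits(rs, "psm_rates"))
    as.vector(rs$r)
  }))
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) < 2)
    stop("calibration error: need at least 2 pooled neutral slopes, got ",
         length(slopes))
  sigma <- stats::sd(slopes)
  if (sigma == 0)
    stop("calibration error: neutral slopes have zero variance (sigma_r = 0)")
  structure(list(mu_r = mean(slopes), sigma_r = sigma,
                 n_neutral = length(slopes)),
            class = "neutral_calibration")
}

#' @export
print.neutral_calibration <- function(x, ...) {
  cat(sprintf(
    "Neutral calibration: mu_r = %.4g, sigma_r = %.4g (%d measurements)\n",
    x$mu_r, x$sigma_r, x$n_neutral))
  invisible(x)
}

#' Assemble a neutral calibration from known values
#'
#' @param mu_r Mean neutral slope (1/generation).
#' @param sigma_r Standard deviation of neutral slopes; must be positive.
#' @param n_neutral Number of pooled slope measurements (>= 2).
#' @return A \code{neutral_calibration} object.
#' @export
neutral_calibration <- function(mu_r, sigma_r, n_neutral) {
  if (!is.finite(sigma_r) || sigma_r <= 0)
    stop("calibration error: sigma_r must be positive")
  n_neutral <- as.integer(n_neutral)
  if (is.na(n_neutral) || n_neutral < 2)
    stop("calibration error: n_neutral must be >= 2")
  structure(list(mu_r = as.numeric(mu_r), sigma_r = as.numeric(sigma_r),
                 n_neutral = n_neutral),
            class = "neutral_calibration")
}

#' Classify expansion rates into emission symbols
#'
#' Each slope is tested against the neutral calibration with the statistic
#' \deqn{T = \frac{r_{pe,ij} - \mu_r}{\sigma_r / \sqrt{n}},}
#' where n is the number of neutral measurements behind the calibration.
#' Slopes for which the null hypothesis of neutrality is rejected at level
#' \code{alpha} are emitted as \code{"P"} (significant positive slope) or
#' \code{"N"} (significant negative slope) according to the sign of
#' \eqn{r - \mu_r}; all other slopes are emitted as \code{"Z"}. A slope
#' exactly at the critical value is not rejected. The reference distribution
#' is Student's t with \code{n_neutral - 1} degrees of freedom by default; a
#' Gaussian may be used instead for large calibration sets.
#'
#' @param rates A \code{psm_rates} object.
#' @param cal A \code{neutral_calibration}.
#' @param alpha Significance level in (0, 1); default 0.10.
#' @param tails 1 (default) for the single-tailed critical value
#'   \eqn{t_{1-\alpha}}, 2 for the two-tailed value \eqn{t_{1-\alpha/2}}.
#' @param dist \code{"t"} (default) or \code{"gaussian"}.
#' @return An object of class \code{psm_emissions}: a list with
#'   \code{symbols} (\code{(n-1) x J} character matrix over P/N/Z, aligned
#'   with the rate intervals), \code{generations}, \code{labels},
#'   \code{alpha}, \code{tails}.
#' @export
classify_rates <- function(rates, cal, alpha = 0.10, tails = 1,
                           dist = c("t", "gaussian")) {
  stopifnot(inherits(rates, "psm_rates"), inherits(cal, "neutral_calibration"))
  dist <- match.arg(dist)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must be a single value in (0, 1)")
  if (!tails %in% c(1, 2))
    stop("parameter error: tails must be 1 or 2")
  if (cal$sigma_r <= 0)
    stop("calibration error: sigma_r must be positive")
  p_level <- if (tails == 1) 1 - alpha else 1 - alpha / 2
  crit <- if (dist == "t") stats::qt(p_level, df = cal$n_neutral - 1)
          else stats::qnorm(p_level)
  T <- (rates$r - cal$mu_r) / (cal$sigma_r / sqrt(cal$n_neutral))
  sym <- matrix("Z", nrow(rates$r), ncol(rates$r),
                dimnames = dimnames(rates$r))
  sym[T > crit] <- "P"
  sym[T < -crit] <- "N"
  structure(list(symbols = sym, generations = rates$generations,
                 labels = rates$labels, alpha = alpha, tails = tails),
            class = "psm_emissions")
}

#' @export
print.psm_emissions <- function(x, ...) {
  tab <- table(factor(x$symbols, levels = c("P", "N", "Z")))
  cat(sprintf("Emission sequences (alpha = %g, %d-tailed): %d intervals x %d subpopulations\n",
              x$alpha, x$tails, nrow(x$symbols), ncol(x$symbols)))
  cat(sprintf("  P: %d  N: %d  Z: %d\n", tab["P"], tab["N"], tab["Z"]))
  invisible(x)
}
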