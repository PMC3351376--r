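#' Construct a FACS population history
#'
#' A population history is the raw record of a VERT (Visualizing Evolution in
#' Real Time) experiment: at each sampled time point, the number of
#' generations elapsed and one FACS count per fluorescently labeled
#' subpopulation.
#'
#' @param generations Numeric vector of length \code{n}: generations elapsed
#'   at each sample. Must be non-negative and strictly increasing.
#' @param counts Numeric \code{n x J} matrix (or data frame) of non-negative
#'   FACS counts, one column per labeled subpopulation. Column names give the
#'   subpopulation labels; unnamed columns are labeled \code{pop1..popJ}.
#' @param experiment_id Character scalar identifying the experiment.
#' @return An object of class \code{population_history}: a list with elements
#'   \code{experiment_id}, \code{labels}, \code{generations} and
#'   \code{counts} (matrix with column names equal to \code{labels}).
#' @examples
#' h <- population_history(c(0, 10, 20),
#'                         cbind(red = c(100, 150, 200),
#'                               green = c(100, 50, 30)))
#' h
#' @export
population_history <- function(generations, counts,
                               experiment_id = "experiment") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  generations <- as.numeric(generations)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("pop", seq_len(ncol(counts)))
  }
  obj <- structure(
    list(experiment_id = as.character(experiment_id)[1],
         labels = colnames(counts),
         generations = generations,
         counts = counts),
    class = "population_history")
  validate_population_history(obj)
  obj
}

validate_population_history <- function(h) {
  n <- length(h$generations)
  if (n < 2L)
    stop("population history needs at least 2 time points, got ", n)
  if (ncol(h$counts) < 2L)
    stop("population history needs at least 2 subpopulations, got ",
         ncol(h$counts))
  if (nrow(h$counts) != n)
    stop("counts have ", nrow(h$counts), " rows but there are ", n,
         " generation values")
  if (anyNA(h$generations) || anyNA(h$counts))
    stop("missing values are not allowed in a population history")
  if (any(h$generations < 0))
    stop("generations must be non-negative")
  if (any(diff(h$generations) <= 0))
    stop("generations must be strictly increasing")
  if (any(h$counts < 0))
    stop("FACS counts must be non-negative")
  if (any(rowSums(h$counts) <= 0))
    stop("every time point must have a positive total count")
  invisible(h)
}

#' @export
print.population_history <- function(x, ...) {
  cat("Population history:", x$experiment_id, "\n")
  cat(sprintf("  %d time points, %.0f-%.0f generations\n",
              length(x$generations), min(x$generations), max(x$generations)))
  cat("  subpopulations:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Attach human state annotations to a population history
#'
#' Annotated histories pair every time point of every subpopulation with a
#' human call of \code{"A"} (adaptive event in progress) or \code{"N"}
#' (no expansion). They are the training and validation material for the
#' population state model.
#'
#' @param history A \code{\link{population_history}}.
#' @param states Character \code{n x J} matrix over \code{{"A","N"}},
#'   dimensions matching \code{history}.
#' @return An object of class \code{annotated_history}: a list with elements
#'   \code{history} and \code{states}.
#' @export
annotated_history <- function(history, states) {
  validate_population_history(history)
  states <- as.matrix(states)
  if (is.null(colnames(states))) colnames(states) <- history$labels
  obj <- structure(list(history = history, states = states),
                   class = "annotated_history")
  validate_annotated_history(obj)
  obj
}

validate_annotated_history <- function(a) {
  h <- a$history
  if (!identical(dim(a$states),
                 c(length(h$generations), length(h$labels))))
    stop("annotation matrix dimensions (", nrow(a$states), " x ",
         ncol(a$states), ") do not match the history (",
         length(h$generations), " x ", length(h$labels), ")")
  bad <- setdiff(unique(as.vector(a$states)), c("A", "N"))
  if (length(bad) > 0)
    stop("annotation symbols must be 'A' or 'N'; found: ",
         paste(bad, collapse = ", "))
  invisible(a)
}

#' @export
print.annotated_history <- function(x, ...) {
  print(x$history)
  n_a <- sum(x$states == "A")
  cat(sprintf("  annotations: %d of %d points in state A\n",
              n_a, length(x$states)))
  invisible(x)
}
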