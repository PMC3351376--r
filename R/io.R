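#' Read a FACS population history from CSV
#'
#' Expected dialect: a header row; first column \code{generation}, then one
#' count column per subpopulation named by its label. Column order defines
#' the subpopulation order throughout the analysis.
#'
#' @param path Path to a CSV file.
#' @param experiment_id Identifier; defaults to the file name without
#'   extension.
#' @return A \code{\link{population_history}}.
#' @export
read_population_history <- function(path, experiment_id = NULL) {
  df <- read_history_csv(path)
  if (is.null(experiment_id))
    experiment_id <- sub("\\.[^.]*$", "", basename(path))
  count_cols <- setdiff(names(df), "generation")
  count_cols <- count_cols[!grepl("_state$", count_cols)]
  if (length(count_cols) < 2)
    stop("format error: ", path, " needs at least 2 subpopulation columns")
  population_history(df$generation,
                     as.matrix(df[count_cols]),
                     experiment_id = experiment_id)
}

read_history_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"generation" %in% names(df))
    stop("format error: ", path, " has no 'generation' column")
  df
}

#' Write a population history to CSV
#'
#' @param history A \code{\link{population_history}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_population_history <- function(history, path) {
  validate_population_history(history)
  df <- data.frame(generation = history$generations, check.names = FALSE)
  df[history$labels] <- as.data.frame(history$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotated history from CSV
#'
#' Same dialect as \code{\link{read_population_history}} plus one
#' \code{<label>_state} column of A/N symbols per subpopulation.
#'
#' @inheritParams read_population_history
#' @return An \code{\link{annotated_history}}.
#' @export
read_annotated_history <- function(path, experiment_id = NULL) {
  history <- read_population_history(path, experiment_id = experiment_id)
  df <- read_history_csv(path)
  state_cols <- paste0(history$labels, "_state")
  missing <- setdiff(state_cols, names(df))
  if (length(missing) > 0)
    stop("format error: missing annotation column(s): ",
         paste(missing, collapse = ", "))
  states <- as.matrix(df[state_cols])
  colnames(states) <- history$labels
  annotated_history(history, states)
}

#' Write an annotated history to CSV
#'
#' @param ah An \code{\link{annotated_history}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_history <- function(ah, path) {
  validate_annotated_history(ah)
  h <- ah$history
  df <- data.frame(generation = h$generations, check.names = FALSE)
  df[h$labels] <- as.data.frame(h$counts)
  df[paste0(h$labels, "_state")] <- as.data.frame(ah$states)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a neutral calibration (YAML)
#'
#' A calibration file holds the three numbers \code{mu_r}, \code{sigma_r}
#' and \code{n_neutral}.
#'
#' @param path File path.
#' @return \code{read_neutral_calibration}: a \code{neutral_calibration}.
#' @export
read_neutral_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  for (f in c("mu_r", "sigma_r", "n_neutral"))
    if (is.null(y[[f]])) stop("format error: calibration file lacks ", f)
  neutral_calibration(y$mu_r, y$sigma_r, y$n_neutral)
}

#' @rdname read_neutral_calibration
#' @param cal A \code{neutral_calibration}.
#' @export
write_neutral_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "neutral_calibration"))
  yaml::write_yaml(list(mu_r = cal$mu_r, sigma_r = cal$sigma_r,
                        n_neutral = cal$n_neutral), path, precision = 15)
  invisible(path)
}

#' Read or write model parameters (YAML)
#'
#' Parameter files carry \code{p_AN0}, \code{p_NA0} and the two emission
#' maps \code{e_A} and \code{e_N} keyed by symbol.
#'
#' @param path File path.
#' @return \code{read_psm_parameters}: a \code{psm_parameters}.
#' @export
read_psm_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  for (f in c("p_AN0", "p_NA0", "e_A", "e_N"))
    if (is.null(y[[f]])) stop("format error: parameter file lacks ", f)
  # tolerate limited-precision serializations: renormalize near-1 sums
  fix <- function(e) {
    e <- unlist(e)
    if (abs(sum(e) - 1) > 1e-6)
      stop("format error: emission probabilities must sum to 1")
    e / sum(e)
  }
  psm_parameters(y$p_AN0, y$p_NA0, fix(y$e_A), fix(y$e_N))
}

#' @rdname read_psm_parameters
#' @param params A \code{psm_parameters}.
#' @export
write_psm_parameters <- function(params, path) {
  stopifnot(inherits(params, "psm_parameters"))
  yaml::write_yaml(list(p_AN0 = params$p_AN0, p_NA0 = params$p_NA0,
                        e_A = as.list(params$e_A),
                        e_N = as.list(params$e_N)), path, precision = 15)
  invisible(path)
}

#' Serialize a prediction report
#'
#' Writes the per-time-point long table (CSV) and, optionally, a JSON
#' document carrying the same table plus the event and sampling tables.
#' The long table has one row per time point per subpopulation with
#' columns \code{time_index} (0-based), \code{generation},
#' \code{subpopulation}, \code{emission}, \code{state}, \code{event_id}
#' and \code{is_sampling_point}; the first time point of each
#' subpopulation has no slope, hence empty emission and state.
#'
#' @param report A \code{psm_report} from \code{\link{run_psm}}.
#' @param path Output CSV path.
#' @param json_path Optional JSON output path.
#' @return \code{path}, invisibly.
#' @export
write_prediction_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "psm_report"))
  utils::write.csv(report$table, path, row.names = FALSE, quote = FALSE,
                   na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(experiment_id = report$history$experiment_id,
           points = report$table, events = report$events,
           sampling = report$sampling),
      json_path, dataframe = "rows", na = "null", auto_unbox = TRUE,
      digits = NA)
  }
  invisible(path)
}
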