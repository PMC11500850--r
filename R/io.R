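# Plain-text serialisation: JSON-lines for whole trials, CSV for
# per-timestep inspection, JSON for simulator configuration.

#' Write / read sequence records as JSON lines
#'
#' One trial per line; observations are stored row-wise at full precision.
#'
#' @param records A `sequence_record` or list of them.
#' @param path Output file path.
#' @return `read_sequences_jsonl()` returns a list of `sequence_record`s
#'   (without the noise-free world trajectory, which is not serialised).
#' @export
write_sequences_jsonl <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (rec in records) {
    x <- list(sequence_type = rec$sequence_type,
              actor_shape = rec$actor_shape,
              patient_shape = rec$patient_shape,
              contact_time = rec$contact_time,
              policies = rec$policies,
              event_labels = rec$event_labels,
              observations = unname(apply(rec$observations, 1L, c,
                                          simplify = FALSE)))
    writeLines(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, na = "null"),
               con)
  }
  invisible(path)
}

#' @rdname write_sequences_jsonl
#' @export
read_sequences_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    om <- x$observations                 # simplified matrix, or list of rows
    if (is.list(om)) om <- do.call(rbind, om)
    obs <- matrix(as.numeric(om), ncol = OBS_DIM,
                  dimnames = list(NULL, observation_names()))
    structure(list(observations = obs, policies = x$policies,
                   event_labels = x$event_labels,
                   contact_time = if (is.null(x$contact_time)) NA_integer_
                                  else as.integer(x$contact_time),
                   actor_shape = x$actor_shape,
                   patient_shape = x$patient_shape,
                   sequence_type = x$sequence_type, world = NULL),
              class = "sequence_record")
  })
}

#' Flatten a trial to a per-timestep data frame
#'
#' @param rec A `sequence_record`.
#' @param trial_id Optional identifier column.
#' @return Data frame with one row per timestep: the 18 observation
#'   components, the policy and the ground-truth event label.
#' @export
sequence_to_df <- function(rec, trial_id = NA) {
  df <- as.data.frame(rec$observations)
  df$t <- seq_len(nrow(df))
  df$policy <- rec$policies
  df$event_label <- rec$event_labels
  df$trial <- trial_id
  df[, c("trial", "t", "policy", "event_label", observation_names())]
}

#' Export a gaze trace to a per-timestep data frame
#'
#' @param trace A `gaze_trace` from [run_test_trial()].
#' @param trial_id Optional identifier column.
#' @return Data frame with the four event posteriors, the three expected
#'   free energies, the chosen policy and the ground-truth label per
#'   timestep.
#' @export
trace_to_df <- function(trace, trial_id = NA) {
  data.frame(trial = trial_id, t = seq_along(trace$chosen),
             trace$posteriors, EFE = trace$efe, chosen = trace$chosen,
             true_label = trace$event_labels)
}

#' Write / read a simulator configuration file
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @return `read_sim_config()` returns the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$noise <- unclass(x$noise)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(speed_min = x$speed_min, speed_max = x$speed_max,
             contact_threshold = x$contact_threshold,
             min_start_distance = x$min_start_distance,
             min_length = x$min_length, max_length = x$max_length,
             margin = x$margin, patient_shape = x$patient_shape,
             noise = noise_config(x$noise$sigma_fixated, x$noise$sigma_other))
}
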