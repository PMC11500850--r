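# Event schema densities: for each of the four events, three learnable
# components (start, dynamics, end), each predicting a diagonal Gaussian
# over the next observation.

#' Initialise the event density models
#'
#' Creates the 12 component networks (4 events x start/dynamics/end). The
#' start component is conditioned on the gaze policy alone; dynamics and end
#' components additionally receive an observation (the previous observation,
#' or the within-event reference observation, respectively).
#'
#' @param seed Seed for the parameter initialisation.
#' @param hidden Hidden width of each component network.
#' @param var_floor Additive floor on every predicted variance.
#' @param obs_dim Observation dimensionality (18 for the full scenario).
#' @return An `event_models` object.
#' @examples
#' m <- event_models_init(seed = 1)
#' predict_start(m, "still", "actor")
#' @export
event_models_init <- function(seed = 1, hidden = 32L, var_floor = 1e-4,
                              obs_dim = OBS_DIM) {
  stream <- rng_stream(derive_seed(seed, 11))
  pol_rows <- obs_dim + 1:3
  nets <- lapply(setNames(EVENTS, EVENTS), function(ev) {
    list(start = gdn_init(3L, obs_dim, hidden, var_floor, stream,
                          policy_rows = 1:3),
         dynamics = gdn_init(obs_dim + 3L, obs_dim, hidden, var_floor, stream,
                             policy_rows = pol_rows),
         end = gdn_init(obs_dim + 3L, obs_dim, hidden, var_floor, stream,
                        policy_rows = pol_rows))
  })
  structure(list(nets = nets, events = EVENTS,
                 obs_dim = as.integer(obs_dim),
                 hidden = as.integer(hidden), var_floor = var_floor,
                 n_sequences_trained = 0L),
            class = "event_models")
}

#' @export
print.event_models <- function(x, ...) {
  cat(sprintf(
    "<event_models> %d events x 3 components, hidden width %d, trained on %d sequences\n",
    length(x$events), x$hidden, x$n_sequences_trained))
  invisible(x)
}

new_prediction <- function(mean, var) {
  stopifnot(length(mean) == length(var), all(var > 0), all(is.finite(mean)))
  structure(list(mean = mean, var = var), class = "gaussian_prediction")
}

#' @export
print.gaussian_prediction <- function(x, ...) {
  cat(sprintf("<gaussian_prediction> %d dims, mean sd range [%.3g, %.3g]\n",
              length(x$mean), sqrt(min(x$var)), sqrt(max(x$var))))
  invisible(x)
}

#' Component predictions
#'
#' `predict_start(models, event, policy)` gives the density of an event's
#' first observation given the gaze policy; `predict_dynamics()` the density
#' of the next observation given the previous one within the event;
#' `predict_end()` the density of the event's boundary observation given a
#' reference observation from inside the event.
#'
#' @param models An [event_models_init()] object (or a manual stand-in built
#'   with [manual_event_models()]).
#' @param event One of `event_names()`.
#' @param policy One of `policy_names()`.
#' @return A `gaussian_prediction` (list with `mean` and `var`).
#' @export
predict_start <- function(models, event, policy) UseMethod("predict_start")

#' @rdname predict_start
#' @param prev_obs Previous observation vector (dynamics input).
#' @export
predict_dynamics <- function(models, event, prev_obs, policy) {
  UseMethod("predict_dynamics")
}

#' @rdname predict_start
#' @param ref_obs Reference observation from inside the event (end input).
#' @export
predict_end <- function(models, event, ref_obs, policy) {
  UseMethod("predict_end")
}

check_event_policy <- function(models, event, policy) {
  if (!event %in% models$events) stop("unknown event: ", event)
  if (!policy %in% POLICIES) stop("unknown policy: ", policy)
}

#' @export
predict_start.event_models <- function(models, event, policy) {
  check_event_policy(models, event, policy)
  out <- gdn_forward(models$nets[[event]]$start, policy_onehot(policy))
  new_prediction(drop(out$mean), drop(out$var))
}

#' @export
predict_dynamics.event_models <- function(models, event, prev_obs, policy) {
  check_event_policy(models, event, policy)
  stopifnot(length(prev_obs) == models$obs_dim)
  x <- matrix(c(prev_obs, policy_onehot(policy)), 1L)
  out <- gdn_forward(models$nets[[event]]$dynamics, x)
  new_prediction(drop(out$mean), drop(out$var))
}

#' @export
predict_end.event_models <- function(models, event, ref_obs, policy) {
  check_event_policy(models, event, policy)
  stopifnot(length(ref_obs) == models$obs_dim)
  x <- matrix(c(ref_obs, policy_onehot(policy)), 1L)
  out <- gdn_forward(models$nets[[event]]$end, x)
  new_prediction(drop(out$mean), drop(out$var))
}

#' Diagonal-Gaussian log density
#'
#' @param obs Observation vector.
#' @param prediction A `gaussian_prediction`.
#' @return The log density of `obs` under the prediction.
#' @examples
#' p <- manual_prediction(0, 1)
#' gaussian_log_density(0, p)  # -0.5 * log(2 * pi)
#' @export
gaussian_log_density <- function(obs, prediction) {
  stopifnot(length(obs) == length(prediction$mean))
  if (any(prediction$var <= 0)) stop("non-positive predicted variance")
  -0.5 * sum(log(2 * pi * prediction$var) +
               (obs - prediction$mean)^2 / prediction$var)
}

#' Fit the density components on labelled sequences
#'
#' Supervised fitting: each sequence is decomposed into per-component batches
#' (using its ground-truth event labels) and each component with data
#' receives one optimiser update per sequence, minimising the negative
#' log-likelihood of its targets.
#'
#' @param models An `event_models` object.
#' @param sequences List of `sequence_record`s carrying event labels.
#' @param control A [fit_control()].
#' @param quiet Suppress the empty-batch warning bookkeeping message.
#' @return List with the updated `models` and a `loss_log` data frame
#'   (sequence index, event, kind, per-step NLL).
#' @export
fit_components <- function(models, sequences, control = fit_control(),
                           quiet = TRUE) {
  stopifnot(inherits(models, "event_models"))
  if (inherits(sequences, "sequence_record")) sequences <- list(sequences)
  log_rows <- vector("list", 0L)
  if (is.null(models$replay)) models$replay <- list()
  for (s in seq_along(sequences)) {
    batches <- training_batches(sequences[[s]])
    for (b in batches) {
      net <- models$nets[[b$event]][[b$kind]]
      # batch over the recent replay window; boundary components receive
      # only one or two rows per sequence, dynamics windows mix the policy
      # and geometry regimes of several recent sequences
      key <- paste(b$event, b$kind, sep = ".")
      win <- if (b$kind == "dynamics") control$dyn_replay_size
             else control$replay_size
      buf <- models$replay[[key]]
      X <- rbind(buf$X, b$X); Y <- rbind(buf$Y, b$Y)
      keep <- seq_len(nrow(X)) > nrow(X) - win
      models$replay[[key]] <- list(X = X[keep, , drop = FALSE],
                                   Y = Y[keep, , drop = FALSE])
      X <- models$replay[[key]]$X; Y <- models$replay[[key]]$Y
      loss <- NA_real_
      # components present in fewer sequences (reach, transport) catch up to
      # the most-updated component of the same kind, so that calibration
      # progresses at the same rate for all events
      peers <- vapply(models$nets, function(ev) ev[[b$kind]]$adam$t, numeric(1))
      n_up <- max(control$updates_per_sequence,
                  min(3L * control$updates_per_sequence,
                      max(peers) - net$adam$t))
      for (k in seq_len(n_up)) {
        step <- gdn_adam_step(net, X, Y, control)
        net <- step$net
        loss <- step$loss
        if (step$skipped) {
          warning("non-finite gradient for ", b$event, "/", b$kind,
                  " at sequence ", s, "; update skipped")
          break
        }
      }
      models$nets[[b$event]][[b$kind]] <- net
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(sequence = s, event = b$event, kind = b$kind,
                   n = nrow(X), nll = loss)
    }
    models$n_sequences_trained <- models$n_sequences_trained + 1L
  }
  list(models = models, loss_log = do.call(rbind, log_rows))
}

#' Average held-out per-step dynamics log-likelihood
#'
#' Diagnostic used to verify that fitting improves the dynamics components:
#' the mean log density of within-event transitions under each event's
#' dynamics model, over a list of held-out labelled sequences.
#'
#' @inheritParams fit_components
#' @return Named numeric vector, one value per event (NA if no data).
#' @export
heldout_dynamics_loglik <- function(models, sequences) {
  tot <- setNames(numeric(length(models$events)), models$events)
  cnt <- setNames(numeric(length(models$events)), models$events)
  for (rec in sequences) {
    batches <- training_batches(rec)
    for (b in batches) {
      if (b$kind != "dynamics") next
      out <- gdn_forward(models$nets[[b$event]]$dynamics, b$X)
      ll <- -0.5 * rowSums(log(2 * pi * out$var) + (b$Y - out$mean)^2 / out$var)
      tot[b$event] <- tot[b$event] + sum(ll)
      cnt[b$event] <- cnt[b$event] + length(ll)
    }
  }
  ifelse(cnt > 0, tot / pmax(cnt, 1), NA_real_)
}

#' Hand-specified event models
#'
#' Builds a stand-in for trained models from explicitly given component
#' densities, for worked examples and oracle checks. Each component is
#' either a fixed `list(mean =, var =)` or a function
#' `function(ref_obs, policy)` returning one.
#'
#' @param components Nested list `components[[event]][[kind]]` with kinds
#'   `start`, `dynamics`, `end`.
#' @param obs_dim Observation dimensionality of the component densities.
#' @return A `manual_event_models` object usable wherever trained models are.
#' @examples
#' comp <- list(mean = 0, var = 1)
#' m <- manual_event_models(
#'   lapply(setNames(nm = c("a", "b")),
#'          function(e) list(start = comp, dynamics = comp, end = comp)),
#'   obs_dim = 1)
#' predict_start(m, "a", "actor")
#' @export
manual_event_models <- function(components, obs_dim = 1L) {
  stopifnot(length(components) >= 2,
            all(vapply(components, function(x)
      all(c("start", "dynamics", "end") %in% names(x)), logical(1))))
  structure(list(components = components, events = names(components),
                 obs_dim = as.integer(obs_dim)),
            class = "manual_event_models")
}

#' @rdname manual_event_models
#' @param mean,var Mean vector and variance vector of a fixed component.
#' @export
manual_prediction <- function(mean, var) new_prediction(mean, var)

manual_eval <- function(comp, ref_obs, policy) {
  p <- if (is.function(comp)) comp(ref_obs, policy) else comp
  new_prediction(p$mean, p$var)
}

#' @export
predict_start.manual_event_models <- function(models, event, policy) {
  manual_eval(models$components[[event]]$start, NULL, policy)
}

#' @export
predict_dynamics.manual_event_models <- function(models, event, prev_obs, policy) {
  manual_eval(models$components[[event]]$dynamics, prev_obs, policy)
}

#' @export
predict_end.manual_event_models <- function(models, event, ref_obs, policy) {
  manual_eval(models$components[[event]]$end, ref_obs, policy)
}

#' Save or load model checkpoints
#'
#' Checkpoints are a structured JSON text format holding every network
#' parameter at full precision plus the architecture configuration.
#'
#' @param models An `event_models` object.
#' @param path File path for the checkpoint.
#' @return `load_models()` returns the restored `event_models`.
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "event_models"))
  ser <- models
  strip <- function(net) net[c(GDN_PAR, "skip", "skip_dims", "var_floor",
                               "in_dim", "out_dim")]
  ser$nets <- lapply(ser$nets, function(ev) lapply(ev, strip))
  ser$replay <- NULL
  jsonlite::write_json(unclass(ser), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  revive <- function(net) {
    for (p in c("W1", "W2", "Wm", "Wv", "Ws")) net[[p]] <- as.matrix(net[[p]])
    net$skip_dims <- as.integer(net$skip_dims)
    net$adam <- list(t = 0)
    net
  }
  nets <- lapply(raw$nets, function(ev) lapply(ev, revive))
  structure(list(nets = nets, events = raw$events,
                 obs_dim = as.integer(raw$obs_dim),
                 hidden = as.integer(raw$hidden), var_floor = raw$var_floor,
                 n_sequences_trained = as.integer(raw$n_sequences_trained)),
            class = "event_models")
}
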