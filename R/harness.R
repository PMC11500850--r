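# Developmental training curriculum and test protocol.
#
# Training interleaves phases of supervised density fitting (sequences drawn
# uniformly from still / random-motion / full-grasp, each viewed under one
# random fixed gaze policy) with test phases that mimic the infant
# experiments: 12 trials per actor shape and condition, gaze chosen online
# by expected free energy, and (optionally) the agency estimate adapted
# retrospectively after every trial.

#' Training schedule
#'
#' @param n_phases Number of training phases (30 in the full protocol).
#' @param sequences_per_phase Sequences per phase (100 in the full protocol).
#' @param mix Sampling probabilities of the three training sequence types.
#' @param schedule A [shape_schedule()] spanning `n_phases` (built
#'   automatically if omitted).
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(n_phases = 30L, sequences_per_phase = 100L,
                           mix = c(still = 1 / 3, random_motion = 1 / 3,
                                   full_grasp = 1 / 3),
                           schedule = NULL) {
  stopifnot(abs(sum(mix) - 1) < 1e-9,
            all(names(mix) %in% c("still", "random_motion", "full_grasp")))
  if (is.null(schedule)) schedule <- shape_schedule(n_phases)
  stopifnot(schedule$n_phases == n_phases)
  structure(list(n_phases = as.integer(n_phases),
                 sequences_per_phase = as.integer(sequences_per_phase),
                 mix = mix, shape_schedule = schedule),
            class = "train_schedule")
}

# One training sequence: type from the mix, shape from the schedule,
# fixed random gaze policy.
sample_training_sequence <- function(phase, schedule, config, streams) {
  type <- stream_sample(streams$world, names(schedule$mix), 1)
  purpose <- if (type == "full_grasp") "grasp_sequence" else "random_motion"
  shape <- sample_actor_shape(phase, schedule$shape_schedule, purpose,
                              streams$world)
  generate_sequence(type, shape, config = config, streams = streams)
}

#' Run the developmental training schedule
#'
#' For each phase, samples `sequences_per_phase` labelled sequences per the
#' mix and shape schedule and updates the density components after each
#' sequence; a checkpoint (a full copy of the models) is kept per phase.
#'
#' @param models Fresh or resumed `event_models`.
#' @param schedule A [train_schedule()].
#' @param config A [sim_config()].
#' @param seed Master seed for the training stimuli.
#' @param control A [fit_control()].
#' @param checkpoint_dir Optional directory to also write JSON checkpoints.
#' @param verbose Print a line per phase.
#' @return List with `checkpoints` (one `event_models` per phase) and the
#'   concatenated `loss_log`.
#' @export
run_training <- function(models, schedule, config = sim_config(), seed = 1,
                         control = fit_control(), checkpoint_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(schedule, "train_schedule"))
  streams <- make_streams(derive_seed(seed, 101))
  checkpoints <- vector("list", schedule$n_phases)
  logs <- vector("list", schedule$n_phases)
  for (phase in seq_len(schedule$n_phases)) {
    seqs <- lapply(seq_len(schedule$sequences_per_phase), function(i)
      sample_training_sequence(phase, schedule, config, streams))
    fit <- fit_components(models, seqs, control)
    models <- fit$models
    fit$loss_log$phase <- phase
    logs[[phase]] <- fit$loss_log
    checkpoints[[phase]] <- models
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_models(models, file.path(checkpoint_dir,
                                    sprintf("phase_%03d.json", phase)))
    }
    if (verbose) {
      message(sprintf("phase %d/%d: mean NLL %.2f", phase, schedule$n_phases,
                      mean(fit$loss_log$nll, na.rm = TRUE)))
    }
  }
  list(checkpoints = checkpoints, loss_log = do.call(rbind, logs))
}

#' Test condition
#'
#' @param actor_shape Tested actor shape in \[0, 1\].
#' @param effect `"with_action_effect"` (full grasping stimuli) or
#'   `"without_action_effect"` (reach-only stimuli, cut off at contact).
#' @param coherence_enabled Adapt the agency estimate after each trial?
#' @param n_trials Trials per test phase (12 in the protocol).
#' @return A `test_condition` list.
#' @export
test_condition <- function(actor_shape,
                           effect = c("with_action_effect", "without_action_effect"),
                           coherence_enabled = TRUE, n_trials = 12L) {
  effect <- match.arg(effect)
  stopifnot(actor_shape >= 0, actor_shape <= 1)
  structure(list(actor_shape = actor_shape, effect = effect,
                 coherence_enabled = coherence_enabled,
                 n_trials = as.integer(n_trials)),
            class = "test_condition")
}

condition_sequence_type <- function(condition) {
  if (condition$effect == "with_action_effect") "full_grasp" else "reach_only"
}

#' Run one test trial
#'
#' Simulates the stimulus for the condition and runs the observer online: at
#' each timestep the observation is rendered under the previously chosen
#' gaze policy with the current agency estimate substituted, the event
#' posterior is updated, and the next gaze policy is selected by expected
#' free energy. If the condition enables coherence optimisation, the agency
#' estimate is adapted after the trial.
#'
#' @param models Trained `event_models`.
#' @param condition A [test_condition()].
#' @param ae_state Current [agency_estimate()] (initialised to the actor
#'   shape at the first of the 12 trials).
#' @param config A [sim_config()].
#' @param streams Streams from `make_streams()` (or pass `seed`).
#' @param seed Master seed used when `streams` is missing.
#' @param prior Transition prior.
#' @param horizon A [horizon_config()].
#' @param adapt An [adaptation_config()].
#' @param initial_policy Gaze policy at trial onset (the observer starts on
#'   the actor).
#' @return List with the `gaze_trace` and the (possibly updated)
#'   `agency_estimate`.
#' @export
run_test_trial <- function(models, condition, ae_state, config = sim_config(),
                           streams = NULL, seed = NULL,
                           prior = transition_prior(events = models$events),
                           horizon = horizon_config(),
                           adapt = adaptation_config(),
                           initial_policy = "actor") {
  stopifnot(inherits(models, "event_models"),
            inherits(ae_state, "agency_estimate"))
  if (is.null(streams)) {
    if (is.null(seed)) stop("provide either `streams` or `seed`")
    streams <- make_streams(seed)
  }
  world <- world_trajectory(condition_sequence_type(condition), config,
                            streams$world)
  len <- length(world$labels)
  evs <- models$events
  n <- length(evs)
  start_pred <- precompute_start(models)
  start_entropy <- precompute_start_entropy(models)
  lprior <- log(prior)

  obs <- matrix(NA_real_, len, models$obs_dim)
  chosen <- character(len)
  rendered <- character(len)
  posteriors <- matrix(NA_real_, len, n, dimnames = list(NULL, evs))
  efes <- matrix(NA_real_, len, 3L, dimnames = list(NULL, POLICIES))
  pol <- initial_policy
  lalpha <- numeric(n)
  for (t in seq_len(len)) {
    rendered[t] <- pol
    obs[t, ] <- render_observation(world_row(world, t), ae_state$value,
                                   config$patient_shape, pol, config$noise,
                                   streams$noise)
    if (t == 1L) {
      la <- vapply(seq_len(n), function(i) {
        sp <- start_pred[[pol]][[evs[i]]]
        diag_logdens(obs[1, ], sp$mean, sp$var)
      }, numeric(1)) - log(n)
      lalpha <- la - logsumexp(la)
    } else {
      tab <- step_table_fast(models, obs[t, ], obs[t - 1, ], pol, start_pred)
      M <- tab + lprior + rep(lalpha, each = n)
      lalpha <- apply(M, 1L, logsumexp) - logsumexp(M)
    }
    posteriors[t, ] <- exp(lalpha)
    efes[t, ] <- efe_table_fast(models, posteriors[t, ], obs[t, ], prior,
                                horizon$tau, start_entropy)
    pol <- POLICIES[which.min(efes[t, ])]
    chosen[t] <- pol
  }
  trace <- structure(list(chosen = chosen, rendered_policies = rendered,
                          contact_time = world$contact_time,
                          posteriors = posteriors, efe = efes,
                          event_labels = world$labels,
                          observations = obs,
                          actor_shape = condition$actor_shape,
                          ae_value = ae_state$value),
                     class = "gaze_trace")
  if (condition$coherence_enabled) {
    ae_state <- adapt_agency(obs, rendered, ae_state, adapt, models, prior)
  }
  list(trace = trace, ae_state = ae_state)
}

#' @export
print.gaze_trace <- function(x, ...) {
  fg <- first_patient_gaze(x)
  cat(sprintf("<gaze_trace> %d timesteps, contact %s, first patient gaze %s\n",
              length(x$chosen),
              ifelse(is.na(x$contact_time), "none", x$contact_time),
              ifelse(is.na(fg), "never", fg)))
  invisible(x)
}

#' First patient fixation
#'
#' @param trace A `gaze_trace`.
#' @param min_run Minimum number of consecutive patient choices for a look
#'   to count as a fixation (default 1: the first patient choice).
#' @return Earliest timestep starting such a run, or `NA` if none.
#' @export
first_patient_gaze <- function(trace, min_run = 1L) {
  r <- rle(trace$chosen == "patient")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit)) ends[hit[1L]] - r$lengths[hit[1L]] + 1L else NA_integer_
}

#' Gaze-arrival delta
#'
#' Contact time minus the arrival of the gaze at the patient, in timesteps:
#' positive values mean the gaze arrived at the patient before the actor did
#' (predictive), negative values mean tracking/reactive gaze. The measure
#' mirrors the infant paradigm, which scores gaze *shifts* from the actor to
#' the goal: the counted patient fixation must follow an actor fixation
#' (a trial in which the gaze parks on the goal from the start carries no
#' shift to score), must be held when the actor reaches the patient (or be
#' the first fixation after it) -- an early glance that wanders back to the
#' actor long before contact does not count -- and must last at least
#' `min_run` timesteps, since single-timestep blips at near-tied expected
#' free energies are not fixations.
#'
#' @param trace A `gaze_trace` from a trial containing a reach.
#' @param min_run Minimum length of a patient run to count as a fixation.
#' @param slack A patient fixation ending at most `slack` timesteps before
#'   contact still counts as held through contact.
#' @return Signed timestep count, or `NA` if no qualifying actor-to-patient
#'   shift occurred.
#' @export
gaze_arrival_delta <- function(trace, min_run = 3L, slack = 5L) {
  if (is.na(trace$contact_time)) stop("trace has no contact time")
  r <- rle(trace$chosen)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  actor_runs <- which(r$values == "actor")
  if (!length(actor_runs)) return(NA_integer_)
  ok <- r$values == "patient" & r$lengths >= min_run &
    ends >= trace$contact_time - slack &
    starts > starts[actor_runs[1L]]
  if (!any(ok)) return(NA_integer_)
  as.integer(trace$contact_time - starts[which(ok)[1L]])
}

#' Mean inferred reach probability during the reach
#'
#' @param trace A `gaze_trace`.
#' @return Mean posterior probability of the reach event over timesteps whose
#'   ground-truth label is reach.
#' @export
mean_reach_probability <- function(trace) {
  idx <- trace$event_labels == "reach"
  mean(trace$posteriors[idx, "reach"])
}

#' Run a full test phase (12 trials of one actor)
#'
#' The agency estimate starts at the actor's shape and persists across the
#' trials of the phase (adapted after each trial when coherence is enabled).
#'
#' @inheritParams run_test_trial
#' @param seed Master seed for this phase's stimuli.
#' @return List with `trials` (gaze traces) and a per-trial `metrics` data
#'   frame (first patient gaze, gaze-arrival delta, mean reach posterior,
#'   agency estimate before/after).
#' @export
run_test_phase <- function(models, condition, config = sim_config(), seed = 1,
                           prior = transition_prior(events = models$events),
                           horizon = horizon_config(),
                           adapt = adaptation_config()) {
  streams <- make_streams(derive_seed(seed, 211))
  ae_state <- agency_estimate(condition$actor_shape)
  trials <- vector("list", condition$n_trials)
  rows <- vector("list", condition$n_trials)
  for (i in seq_len(condition$n_trials)) {
    ae_before <- ae_state$value
    out <- run_test_trial(models, condition, ae_state, config, streams,
                          prior = prior, horizon = horizon, adapt = adapt)
    trials[[i]] <- out$trace
    ae_state <- out$ae_state
    rows[[i]] <- data.frame(
      trial = i, actor_shape = condition$actor_shape,
      effect = condition$effect, coherence = condition$coherence_enabled,
      length = length(out$trace$chosen),
      contact_time = out$trace$contact_time,
      first_patient_gaze = first_patient_gaze(out$trace),
      gaze_arrival_delta = gaze_arrival_delta(out$trace),
      mean_p_reach = mean_reach_probability(out$trace),
      ae_before = ae_before, ae_after = ae_state$value)
  }
  list(trials = trials, metrics = do.call(rbind, rows),
       ae_state = ae_state)
}

#' Experiment configuration
#'
#' @param seeds Master seeds, one independent model per seed (20 in the full
#'   protocol).
#' @param schedule A [train_schedule()].
#' @param conditions List of [test_condition()]s evaluated after each phase.
#' @param config A [sim_config()].
#' @param control A [fit_control()].
#' @param horizon A [horizon_config()].
#' @param adapt An [adaptation_config()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seeds = 1:20, schedule = train_schedule(),
                              conditions = default_conditions(),
                              config = sim_config(), control = fit_control(),
                              horizon = horizon_config(),
                              adapt = adaptation_config()) {
  structure(list(seeds = seeds, schedule = schedule, conditions = conditions,
                 config = config, control = control, horizon = horizon,
                 adapt = adapt),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param shapes Actor shapes tested (0 to 1 in steps of 0.1 by default).
#' @export
default_conditions <- function(shapes = seq(0, 1, by = 0.1)) {
  out <- list()
  for (s in shapes) {
    for (eff in c("with_action_effect", "without_action_effect")) {
      for (coh in c(TRUE, FALSE)) {
        out[[length(out) + 1L]] <- test_condition(s, eff, coh)
      }
    }
  }
  out
}

#' Run the full training + testing experiment
#'
#' For each seed: initialise fresh models, run the training phases, and
#' after every phase evaluate all test conditions (12 trials each, agency
#' estimate reset per condition and phase). Metrics are pooled over seeds.
#'
#' @param exp_config An [experiment_config()].
#' @param out_dir Optional directory for CSV outputs (`metrics.csv` and
#'   `ae_trajectory.csv`).
#' @param verbose Print progress lines.
#' @return A `metrics` data frame with one row per tested trial (keyed by
#'   seed, phase, condition, trial). Failed seeds are dropped with a
#'   warning.
#' @export
run_full_experiment <- function(exp_config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(exp_config, "experiment_config"))
  all_rows <- list()
  for (seed in exp_config$seeds) {
    rows <- tryCatch(
      run_experiment_seed(exp_config, seed, verbose),
      error = function(e) {
        warning("seed ", seed, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rows)) all_rows[[length(all_rows) + 1L]] <- rows
  }
  metrics <- do.call(rbind, all_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    ae <- metrics[, c("seed", "phase", "actor_shape", "effect", "coherence",
                      "trial", "ae_before", "ae_after")]
    write.csv(ae, file.path(out_dir, "ae_trajectory.csv"), row.names = FALSE)
  }
  metrics
}

run_experiment_seed <- function(exp_config, seed, verbose = FALSE) {
  models <- event_models_init(seed = derive_seed(seed, 31))
  schedule <- exp_config$schedule
  streams <- make_streams(derive_seed(seed, 101))
  rows <- list()
  for (phase in seq_len(schedule$n_phases)) {
    seqs <- lapply(seq_len(schedule$sequences_per_phase), function(i)
      sample_training_sequence(phase, schedule, exp_config$config, streams))
    models <- fit_components(models, seqs, exp_config$control)$models
    for (ci in seq_along(exp_config$conditions)) {
      cond <- exp_config$conditions[[ci]]
      phase_seed <- derive_seed(seed, 10000 + phase * 100 + ci)
      res <- run_test_phase(models, cond, exp_config$config, phase_seed,
                            horizon = exp_config$horizon,
                            adapt = exp_config$adapt)
      m <- res$metrics
      m$seed <- seed
      m$phase <- phase
      rows[[length(rows) + 1L]] <- m
    }
    if (verbose) {
      message(sprintf("seed %s phase %d/%d done", seed, phase,
                      schedule$n_phases))
    }
  }
  do.call(rbind, rows)
}

#' Criterion phase: earliest phase with mostly-predictive gaze
#'
#' Scalar summary of the developmental curves: the earliest phase at which
#' at least `min_trials` of the phase's trials have a strictly positive
#' gaze-arrival delta (gaze on the patient before contact).
#'
#' @param metrics Metrics data frame from [run_full_experiment()] or
#'   [run_test_phase()], already subset to one condition (and one seed, or
#'   pooled as desired).
#' @param min_trials Required number of predictive trials (7 of 12 by
#'   default).
#' @return The earliest qualifying phase index, or `Inf` if none qualifies.
#' @export
criterion_phase <- function(metrics, min_trials = 7L) {
  phases <- sort(unique(metrics$phase))
  for (ph in phases) {
    m <- metrics[metrics$phase == ph, ]
    npred <- sum(!is.na(m$gaze_arrival_delta) & m$gaze_arrival_delta > 0)
    if (npred >= min_trials) return(ph)
  }
  Inf
}

#' Event-label recovery of the trained filter
#'
#' Diagnostic reproducing the event-identification analysis: simulates
#' full-grasp trials, renders them noise-free (or noisily) under a fixed
#' gaze policy, runs the event filter, and scores the fraction of
#' non-boundary timesteps whose maximum-posterior event matches the
#' ground-truth label. Non-boundary timesteps are those more than
#' `boundary_window` steps away from a label change (the sticky transition
#' prior makes the filter lag a boundary by a few steps by design).
#'
#' @param models Trained `event_models`.
#' @param actor_shape Actor shape of the simulated trials.
#' @param n_trials Number of trials to average over.
#' @param seed Master seed for the stimuli.
#' @param config A [sim_config()].
#' @param noiseless Render observations without sensory noise?
#' @param policy Fixed gaze policy used for rendering and filtering.
#' @param boundary_window Exclusion half-width around label changes.
#' @return List with the overall `accuracy`, per-trial accuracies, and the
#'   mean posterior probability of reach during reach (`p_reach`).
#' @export
label_recovery <- function(models, actor_shape = 0.2, n_trials = 10,
                           seed = 1, config = sim_config(), noiseless = TRUE,
                           policy = "actor", boundary_window = 3L) {
  accs <- numeric(n_trials)
  preach <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    streams <- make_streams(derive_seed(seed, 900 + i))
    world <- world_trajectory("full_grasp", config, streams$world)
    len <- length(world$labels)
    obs <- matrix(NA_real_, len, models$obs_dim)
    for (t in seq_len(len)) {
      w <- world_row(world, t)
      obs[t, ] <- if (noiseless) {
        noiseless_observation(w, actor_shape, config$patient_shape)
      } else {
        render_observation(w, actor_shape, config$patient_shape, policy,
                           config$noise, streams$noise)
      }
    }
    fs <- filter_sequence(obs, rep(policy, len), models)
    pred <- colnames(fs$posteriors)[max.col(fs$posteriors)]
    lab <- world$labels
    keep <- rep(TRUE, len)
    for (b in which(lab[-1L] != lab[-len])) {
      keep[max(1L, b - boundary_window):min(len, b + boundary_window)] <- FALSE
    }
    accs[i] <- mean(pred[keep] == lab[keep])
    preach[i] <- mean(fs$posteriors[lab == "reach", "reach"])
  }
  list(accuracy = mean(accs), per_trial = accs, p_reach = mean(preach))
}

#' Canonical test conditions for the developmental contrasts
#'
#' The six condition cells needed for the headline contrasts: hand (0.2) and
#' claw (0.8) with action effect and no coherence (event-probability
#' development), stranger-hand (0.4) and claw (0.8) with coherence enabled
#' under both effect conditions (gaze development), and claw with effect
#' and coherence enabled (retrospective adaptation).
#'
#' @param n_trials Trials per test phase.
#' @return List of [test_condition()]s.
#' @export
pattern_conditions <- function(n_trials = 12L) {
  list(
    test_condition(0.2, "with_action_effect", FALSE, n_trials),
    test_condition(0.8, "with_action_effect", FALSE, n_trials),
    test_condition(0.8, "with_action_effect", TRUE, n_trials),
    test_condition(0.4, "with_action_effect", TRUE, n_trials),
    test_condition(0.4, "without_action_effect", TRUE, n_trials),
    test_condition(0.8, "without_action_effect", TRUE, n_trials))
}

#' Run the reduced developmental protocol
#'
#' Trains one model on a shortened curriculum and evaluates the canonical
#' [pattern_conditions()] after every phase. This is the problem size used
#' throughout the package's own analyses: it preserves the per-phase
#' sequence volume of the full protocol (which the gaze behaviour is
#' sensitive to) while shortening the developmental axis.
#'
#' @param seed Master seed (training stimuli, initialisation, test phases).
#' @param n_phases,sequences_per_phase Reduced curriculum size.
#' @param n_trials Trials per condition and phase.
#' @param config A [sim_config()].
#' @param verbose Print progress.
#' @return List with `checkpoints` (per phase), `final` (last checkpoint)
#'   and `metrics` (per-trial rows across phases and conditions).
#' @export
run_reduced_protocol <- function(seed = 1, n_phases = 12L,
                                 sequences_per_phase = 100L, n_trials = 12L,
                                 config = sim_config(), verbose = FALSE) {
  sched <- train_schedule(n_phases, sequences_per_phase)
  tr <- run_training(event_models_init(seed = seed), sched, config = config,
                     seed = seed, verbose = verbose)
  cells <- pattern_conditions(n_trials)
  rows <- list()
  for (phase in seq_len(n_phases)) {
    for (ci in seq_along(cells)) {
      res <- run_test_phase(tr$checkpoints[[phase]], cells[[ci]], config,
                            seed = derive_seed(seed, 20000 + phase * 100 + ci))
      m <- res$metrics
      m$phase <- phase
      m$seed <- seed
      rows[[length(rows) + 1L]] <- m
    }
    if (verbose) message("test phases after phase ", phase, " done")
  }
  list(checkpoints = tr$checkpoints,
       final = tr$checkpoints[[n_phases]],
       metrics = do.call(rbind, rows))
}

# subset helper for one condition cell
cell_metrics <- function(metrics, actor_shape, effect, coherence) {
  metrics[metrics$actor_shape == actor_shape & metrics$effect == effect &
            metrics$coherence == coherence, , drop = FALSE]
}
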