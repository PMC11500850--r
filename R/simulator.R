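# Two-entity event scenario simulator.
#
# World geometry: an axis-aligned unit cube. Entities spawn uniformly inside
# a small margin from the walls with a minimum initial actor-patient distance
# so that reach events span many timesteps. Speeds are constant per event.
# Four event types:
#   still     - both entities motionless
#   random    - actor drifts in a fixed random direction (reflected at the
#               walls), patient motionless
#   reach     - actor moves straight toward the patient until contact
#   transport - actor and patient move together toward a random goal
# Velocities are headings: the velocity stored at timestep t is the
# displacement the entity undergoes from t to t+1, governed by the event
# label at t. The first observation of a new event therefore already carries
# that event's velocity (e.g. the contact observation of a grasp carries the
# nascent transport velocity of both entities).

#' Simulator configuration
#'
#' @param speed_min,speed_max Per-event constant speed range in workspace
#'   units per timestep.
#' @param contact_threshold Distance below which actor and patient count as
#'   in contact (ends a reach; also the goal-arrival criterion).
#' @param min_start_distance Minimum initial actor-patient distance.
#' @param min_length,max_length Bounds on total sequence length (timesteps).
#' @param margin Entities spawn uniformly in `[margin, 1 - margin]^3`.
#' @param patient_shape Patient shape written to every observation
#'   (a generic object, fixed at 0.5).
#' @param noise A [noise_config()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(speed_min = 0.004, speed_max = 0.012,
                       contact_threshold = 0.01, min_start_distance = 0.4,
                       min_length = 100L, max_length = 270L, margin = 0.05,
                       patient_shape = 0.5, noise = noise_config()) {
  stopifnot(speed_min > 0, speed_max > speed_min,
            contact_threshold > 0, min_length < max_length)
  structure(list(speed_min = speed_min, speed_max = speed_max,
                 contact_threshold = contact_threshold,
                 min_start_distance = min_start_distance,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 margin = margin, patient_shape = patient_shape,
                 noise = noise),
            class = "sim_config")
}

SEQUENCE_TYPES <- c("still", "random_motion", "full_grasp", "reach_only")

#' Developmental actor-shape schedule
#'
#' Grasping actors are drawn from a truncated Normal around the canonical
#' hand shape early in training; over phases an increasing share is drawn
#' uniformly on \[0, 1\], so late training shows hand-like through claw-like
#' actors reaching and grasping. Random-motion (and still) actors are a 50/50
#' mix of the hand and claw modes throughout.
#'
#' @param n_phases Number of training phases the schedule spans.
#' @param hand_mean,hand_sd Hand-shape distribution (defaults 0.2, 0.1).
#' @param claw_mean Claw-shape centre (default 0.8, same sd as the hand).
#' @return A `shape_schedule` with a `uniform_mix_weight(phase)` function
#'   rising from 0 (phase 1) to 1 (final phase). The rise is quadratic, so
#'   grasping actors stay hand-dominated through the middle of training and
#'   unfamiliar shapes arrive mostly in late phases.
#' @export
shape_schedule <- function(n_phases = 30L, hand_mean = 0.2, hand_sd = 0.1,
                           claw_mean = 0.8) {
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases >= 1)
  structure(list(
    n_phases = n_phases, hand_mean = hand_mean, hand_sd = hand_sd,
    claw_mean = claw_mean,
    uniform_mix_weight = function(phase) {
      if (n_phases == 1L) 1 else ((phase - 1) / (n_phases - 1))^2
    }), class = "shape_schedule")
}

# Normal(mean, sd) truncated to [0, 1] by rejection.
truncnorm01 <- function(stream, mean, sd) {
  repeat {
    x <- stream_rnorm(stream, 1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

#' Sample an actor shape for a training sequence
#'
#' @param phase Training phase index (1-based).
#' @param schedule A [shape_schedule()].
#' @param purpose `"grasp_sequence"` (hand-dominated early, mixing toward
#'   uniform) or `"random_motion"` (50/50 hand/claw throughout).
#' @param stream An [rng_stream()].
#' @return A shape value in \[0, 1\].
#' @export
sample_actor_shape <- function(phase, schedule, purpose = c("grasp_sequence", "random_motion"),
                               stream) {
  purpose <- match.arg(purpose)
  if (phase < 1 || phase > schedule$n_phases) {
    stop("phase must be in [1, ", schedule$n_phases, "]")
  }
  if (purpose == "grasp_sequence") {
    w <- schedule$uniform_mix_weight(phase)
    if (stream_runif(stream, 1) < w) {
      stream_runif(stream, 1)
    } else {
      truncnorm01(stream, schedule$hand_mean, schedule$hand_sd)
    }
  } else {
    centre <- if (stream_runif(stream, 1) < 0.5) schedule$hand_mean else schedule$claw_mean
    truncnorm01(stream, centre, schedule$hand_sd)
  }
}

# Uniform direction on the unit sphere.
random_direction <- function(stream) {
  repeat {
    v <- stream_rnorm(stream, 3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Advance a position by v, reflecting at the unit-cube walls. Returns the
# new position and (possibly sign-flipped) velocity.
reflect_step <- function(pos, v) {
  p <- pos + v
  for (k in 1:3) {
    if (p[k] > 1) { p[k] <- 2 - p[k]; v[k] <- -v[k] }
    if (p[k] < 0) { p[k] <- -p[k]; v[k] <- -v[k] }
  }
  list(pos = p, v = v)
}

sample_positions <- function(config, stream, min_distance) {
  lo <- config$margin; hi <- 1 - config$margin
  repeat {
    a <- stream_runif(stream, 3, lo, hi)
    p <- stream_runif(stream, 3, lo, hi)
    if (sqrt(sum((a - p)^2)) >= min_distance) return(list(actor = a, patient = p))
  }
}

# Build the noise-free world trajectory for one sequence. Returns positions
# and headings (T x 3 matrices), per-timestep labels, and the contact time.
world_trajectory <- function(sequence_type, config, stream) {
  switch(sequence_type,
    still = {
      len <- stream_int(stream, config$min_length, config$max_length)
      st <- sample_positions(config, stream, config$min_start_distance)
      list(actor_pos = matrix(st$actor, len, 3, byrow = TRUE),
           patient_pos = matrix(st$patient, len, 3, byrow = TRUE),
           actor_vel = matrix(0, len, 3), patient_vel = matrix(0, len, 3),
           labels = rep("still", len), contact_time = NA_integer_)
    },
    random_motion = {
      l_rand <- stream_int(stream, 50L, 200L)
      l_still <- stream_int(stream, max(10L, config$min_length - l_rand),
                            config$max_length - l_rand)
      len <- l_rand + l_still
      st <- sample_positions(config, stream, config$min_start_distance)
      ap <- matrix(NA_real_, len, 3); av <- matrix(0, len, 3)
      ap[1, ] <- st$actor
      v <- random_direction(stream) *
        stream_runif(stream, 1, config$speed_min, config$speed_max)
      for (t in seq_len(len)) {
        if (t <= l_rand) {           # actor drifts, reflecting at walls
          av[t, ] <- v
          if (t < len) {
            stp <- reflect_step(ap[t, ], v)
            ap[t + 1, ] <- stp$pos; v <- stp$v
          }
        } else if (t < len) {
          ap[t + 1, ] <- ap[t, ]
        }
      }
      list(actor_pos = ap,
           patient_pos = matrix(st$patient, len, 3, byrow = TRUE),
           actor_vel = av, patient_vel = matrix(0, len, 3),
           labels = c(rep("random", l_rand), rep("still", l_still)),
           contact_time = NA_integer_)
    },
    reach_only = {
      # Pick a length for which a constant speed inside the configured range
      # puts contact exactly on the final timestep.
      repeat {
        st <- sample_positions(config, stream, config$min_start_distance)
        d0 <- sqrt(sum((st$patient - st$actor)^2))
        lo <- max(config$min_length, ceiling(1.5 + (d0 - config$contact_threshold) / config$speed_max))
        hi <- min(config$max_length, floor(1.5 + (d0 - config$contact_threshold) / config$speed_min))
        if (lo <= hi) break
      }
      len <- stream_int(stream, lo, hi)
      speed <- (d0 - config$contact_threshold) / (len - 1.5)
      traj <- reach_segment(st$actor, st$patient, speed, len, config)
      stopifnot(traj$contact == len)
      list(actor_pos = traj$ap, patient_pos = matrix(st$patient, len, 3, byrow = TRUE),
           actor_vel = traj$av, patient_vel = matrix(0, len, 3),
           labels = rep("reach", len), contact_time = as.integer(len))
    },
    full_grasp = {
      st <- sample_positions(config, stream, config$min_start_distance)
      d0 <- sqrt(sum((st$patient - st$actor)^2))
      # keep the reach at most ~180 steps so transport + tail still fit
      speed <- stream_runif(stream, 1,
                            max(config$speed_min, (d0 - config$contact_threshold) / 179),
                            config$speed_max)
      reach_len <- 1L + ceiling((d0 - config$contact_threshold) / speed)
      rs <- reach_segment(st$actor, st$patient, speed, reach_len, config)
      ctime <- rs$contact                       # first timestep in contact
      n_reach <- ctime - 1L                     # timesteps labelled reach
      # transport toward a goal reachable at an in-range constant speed
      repeat {
        goal <- stream_runif(stream, 3, config$margin, 1 - config$margin)
        gdist <- sqrt(sum((goal - rs$ap[ctime, ])^2))
        lt_lo <- max(20L, ceiling(gdist / config$speed_max))
        lt_hi <- min(80L, 260L - n_reach, floor(gdist / config$speed_min))
        if (lt_lo <= lt_hi) break
      }
      l_t <- stream_int(stream, lt_lo, lt_hi)
      v_t <- (goal - rs$ap[ctime, ]) / l_t
      l_tail <- stream_int(stream, max(10L, config$min_length - n_reach - l_t),
                           config$max_length - n_reach - l_t)
      len <- n_reach + l_t + l_tail
      ap <- matrix(NA_real_, len, 3); pp <- matrix(NA_real_, len, 3)
      av <- matrix(0, len, 3); pv <- matrix(0, len, 3)
      ap[1:ctime, ] <- rs$ap[1:ctime, ]; av[1:n_reach, ] <- rs$av[1:n_reach, ]
      pp[1:ctime, ] <- matrix(st$patient, ctime, 3, byrow = TRUE)
      for (t in ctime:(ctime + l_t - 1L)) {     # joint transport
        av[t, ] <- v_t; pv[t, ] <- v_t
        ap[t + 1L, ] <- ap[t, ] + v_t; pp[t + 1L, ] <- pp[t, ] + v_t
      }
      b <- ctime + l_t                          # first random-tail timestep
      v <- random_direction(stream) *
        stream_runif(stream, 1, config$speed_min, config$speed_max)
      for (t in b:len) {
        av[t, ] <- v
        if (t < len) {
          stp <- reflect_step(ap[t, ], v)
          ap[t + 1L, ] <- stp$pos; v <- stp$v
        }
        pp[t, ] <- pp[b, ]
      }
      list(actor_pos = ap, patient_pos = pp, actor_vel = av, patient_vel = pv,
           labels = c(rep("reach", n_reach), rep("transport", l_t),
                      rep("random", l_tail)),
           contact_time = as.integer(ctime))
    },
    stop("unknown sequence_type: ", sequence_type)
  )
}

# Straight-line reach of `len` timesteps; contact is the first timestep with
# distance below the threshold.
reach_segment <- function(actor0, patient, speed, len, config) {
  u <- (patient - actor0) / sqrt(sum((patient - actor0)^2))
  ap <- matrix(NA_real_, len, 3)
  av <- matrix(u * speed, len, 3, byrow = TRUE)
  ap[1, ] <- actor0
  contact <- NA_integer_
  for (t in seq_len(len)) {
    if (is.na(contact) && sqrt(sum((patient - ap[t, ])^2)) < config$contact_threshold) {
      contact <- t
    }
    if (t < len) ap[t + 1, ] <- ap[t, ] + u * speed
  }
  list(ap = ap, av = av, contact = contact)
}

world_row <- function(world, t) {
  list(actor_position = world$actor_pos[t, ],
       patient_position = world$patient_pos[t, ],
       actor_velocity = world$actor_vel[t, ],
       patient_velocity = world$patient_vel[t, ])
}

#' Generate a complete event sequence
#'
#' Simulates the world dynamics for one sequence, assigns per-timestep event
#' labels, and renders gaze-dependent noisy observations. With
#' `policy_mode = "fixed_random"` a single gaze policy is drawn uniformly and
#' held for the whole sequence (the regime used during model training).
#'
#' @param sequence_type One of `"still"`, `"random_motion"`, `"full_grasp"`,
#'   `"reach_only"`.
#' @param actor_shape Actor shape / prior agency value in \[0, 1\], written to
#'   the agency slot of every observation.
#' @param patient_shape Patient shape in \[0, 1\]; defaults to the configured
#'   generic object.
#' @param policy_mode `"fixed_random"` (one policy for the whole sequence) or
#'   `"given"` with an explicit `policies` vector.
#' @param config A [sim_config()].
#' @param streams Streams from `make_streams()`, or a master seed via `seed`.
#' @param seed Master seed used when `streams` is missing.
#' @param policies Explicit per-timestep policy vector for
#'   `policy_mode = "given"` (recycled if length 1).
#' @return A `sequence_record`: list with `observations` (T x 18 matrix),
#'   `policies`, `event_labels`, `contact_time`, `actor_shape`,
#'   `patient_shape`, `sequence_type` and the noise-free `world` trajectory.
#' @examples
#' rec <- generate_sequence("full_grasp", actor_shape = 0.2, seed = 1)
#' table(rec$event_labels)
#' @export
generate_sequence <- function(sequence_type, actor_shape, patient_shape = NULL,
                              policy_mode = c("fixed_random", "given"),
                              config = sim_config(), streams = NULL, seed = NULL,
                              policies = NULL) {
  policy_mode <- match.arg(policy_mode)
  stopifnot(sequence_type %in% SEQUENCE_TYPES,
            actor_shape >= 0, actor_shape <= 1)
  if (is.null(streams)) {
    if (is.null(seed)) stop("provide either `streams` or `seed`")
    streams <- make_streams(seed)
  }
  if (is.null(patient_shape)) patient_shape <- config$patient_shape
  world <- world_trajectory(sequence_type, config, streams$world)
  len <- length(world$labels)
  if (policy_mode == "fixed_random") {
    policies <- rep(stream_sample(streams$policy, POLICIES), len)
  } else {
    stopifnot(!is.null(policies))
    policies <- rep(policies, length.out = len)
    stopifnot(all(policies %in% POLICIES))
  }
  obs <- matrix(NA_real_, len, OBS_DIM, dimnames = list(NULL, observation_names()))
  for (t in seq_len(len)) {
    obs[t, ] <- render_observation(world_row(world, t), actor_shape,
                                   patient_shape, policies[t],
                                   config$noise, streams$noise)
  }
  structure(list(observations = obs, policies = policies,
                 event_labels = world$labels,
                 contact_time = world$contact_time,
                 actor_shape = actor_shape, patient_shape = patient_shape,
                 sequence_type = sequence_type, world = world),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  ct <- if (is.na(x$contact_time)) "none" else x$contact_time
  cat(sprintf("<sequence_record> %s, %d timesteps, actor shape %.2f, contact: %s\n",
              x$sequence_type, length(x$event_labels), x$actor_shape, ct))
  cat("  events:", paste(rle(x$event_labels)$values, collapse = " -> "), "\n")
  invisible(x)
}
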