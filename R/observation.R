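# The 18-dimensional observation vector and its gaze-dependent rendering.

# Component layout of an observation vector.
OBS_ACTOR_POS <- 1:3
OBS_PATIENT_POS <- 4:6
OBS_ACTOR_VEL <- 7:9
OBS_PATIENT_VEL <- 10:12
OBS_REL_POS <- 13:15
OBS_DISTANCE <- 16L
OBS_AGENCY <- 17L
OBS_SHAPE <- 18L
OBS_DIM <- 18L

#' Names of the observation-vector components
#'
#' An observation is an 18-dimensional numeric vector: actor and patient
#' positions and velocities (3 components each), the patient-minus-actor
#' relative position, their Euclidean distance, the actor's agency estimate
#' and the patient's shape. The last two slots are internal estimates and are
#' never perturbed by sensory noise.
#'
#' @return Character vector of length 18.
#' @examples
#' observation_names()
#' @export
observation_names <- function() {
  c(paste0("actor_pos_", c("x", "y", "z")),
    paste0("patient_pos_", c("x", "y", "z")),
    paste0("actor_vel_", c("x", "y", "z")),
    paste0("patient_vel_", c("x", "y", "z")),
    paste0("rel_pos_", c("x", "y", "z")),
    "distance", "agency", "patient_shape")
}

#' Gaze-dependent sensory noise configuration
#'
#' Fixating an entity sharpens its sensory signal: position and velocity
#' components of the fixated entity receive zero-mean Gaussian noise with
#' standard deviation `sigma_fixated`, those of the other entity with
#' `sigma_other`. Under the "elsewhere" policy both entities receive
#' `sigma_other`.
#'
#' @param sigma_fixated Noise sd for the fixated entity (default 0.001).
#' @param sigma_other Noise sd for the non-fixated entity (default 0.1).
#' @return A `noise_config` list.
#' @export
noise_config <- function(sigma_fixated = 0.001, sigma_other = 0.1) {
  stopifnot(sigma_fixated > 0, sigma_other > 0, sigma_fixated <= sigma_other)
  structure(list(sigma_fixated = sigma_fixated, sigma_other = sigma_other),
            class = "noise_config")
}

#' Render a noisy observation from a world state
#'
#' Adds independent Gaussian noise to the 12 position/velocity components
#' according to the gaze policy, then recomputes the relative position and
#' distance from the noisy positions so the observation stays internally
#' consistent. The agency and patient-shape slots pass through noise-free.
#'
#' @param world A `world_state` (see [generate_sequence()]) or any list with
#'   `actor_position`, `patient_position`, `actor_velocity`,
#'   `patient_velocity` 3-vectors.
#' @param agency_value Actor agency estimate in \[0, 1\] written to slot 17.
#' @param patient_shape Patient shape in \[0, 1\] written to slot 18.
#' @param policy One of `"actor"`, `"patient"`, `"elsewhere"`.
#' @param noise A [noise_config()].
#' @param stream An [rng_stream()] for the noise draws.
#' @return Named numeric vector of length 18.
#' @export
render_observation <- function(world, agency_value, patient_shape, policy,
                               noise = noise_config(), stream) {
  stopifnot(agency_value >= 0, agency_value <= 1,
            patient_shape >= 0, patient_shape <= 1,
            policy %in% POLICIES)
  sd_actor <- if (policy == "actor") noise$sigma_fixated else noise$sigma_other
  sd_patient <- if (policy == "patient") noise$sigma_fixated else noise$sigma_other
  eps <- stream_rnorm(stream, 12L)
  ap <- world$actor_position + eps[1:3] * sd_actor
  pp <- world$patient_position + eps[4:6] * sd_patient
  av <- world$actor_velocity + eps[7:9] * sd_actor
  pv <- world$patient_velocity + eps[10:12] * sd_patient
  rel <- pp - ap
  o <- c(ap, pp, av, pv, rel, sqrt(sum(rel^2)), agency_value, patient_shape)
  names(o) <- observation_names()
  o
}

# Noise-free observation for a row of a world trajectory (used by label
# recovery checks and by tests).
noiseless_observation <- function(world, agency_value, patient_shape) {
  rel <- world$patient_position - world$actor_position
  o <- c(world$actor_position, world$patient_position,
         world$actor_velocity, world$patient_velocity,
         rel, sqrt(sum(rel^2)), agency_value, patient_shape)
  names(o) <- observation_names()
  o
}
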