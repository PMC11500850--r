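# Retrospective coherence optimisation: after a complete trial, the actor's
# agency estimate is adapted by momentum gradient descent on the negative
# sequence log-likelihood, with the candidate estimate substituted into the
# agency slot of every observation (the model applies its own estimate; the
# sensed value is discarded during testing). Density-network parameters stay
# frozen; the gradient flows through the full filter recursion.

#' Agency estimate state
#'
#' @param value Current agency estimate in \[0, 1\].
#' @param momentum_buffer Accumulated momentum term (0 for a fresh actor).
#' @return An `agency_estimate` object.
#' @export
agency_estimate <- function(value, momentum_buffer = 0) {
  stopifnot(value >= 0, value <= 1, is.finite(momentum_buffer))
  structure(list(value = value, momentum_buffer = momentum_buffer),
            class = "agency_estimate")
}

#' @export
print.agency_estimate <- function(x, ...) {
  cat(sprintf("<agency_estimate> %.4f (momentum buffer %.3g)\n",
              x$value, x$momentum_buffer))
  invisible(x)
}

#' Settings for the per-trial agency adaptation
#'
#' @param learning_rate Gradient-descent step size (default 1e-5).
#' @param momentum Classical momentum rate (default 0.3).
#' @param n_steps Update steps per trial (default 5); the loss and gradient
#'   are recomputed at each step.
#' @return An `adaptation_config` list.
#' @export
adaptation_config <- function(learning_rate = 1e-5, momentum = 0.3,
                              n_steps = 5L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, n_steps >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 n_steps = as.integer(n_steps)),
            class = "adaptation_config")
}

substitute_agency <- function(observations, ae) {
  observations <- as.matrix(observations)
  observations[, OBS_AGENCY] <- ae
  observations
}

#' Coherence loss of a trial at a candidate agency estimate
#'
#' The negative sequence log-likelihood of the trial with `ae` substituted
#' into the agency slot of every observation.
#'
#' @param observations T x 18 observation matrix of a complete trial.
#' @param policies Per-timestep gaze policies of the trial.
#' @param ae Candidate agency estimate in \[0, 1\].
#' @param models Event models.
#' @param prior Transition prior.
#' @return The scalar loss (lower = more coherent interpretation).
#' @export
coherence_loss <- function(observations, policies, ae, models,
                           prior = transition_prior(events = models$events)) {
  obs <- substitute_agency(observations, ae)
  -sequence_log_likelihood(obs, policies, models, prior)
}

#' @rdname coherence_loss
#' @return `coherence_loss_grad()` returns a list with the `loss` and its
#'   analytic derivative `grad` with respect to `ae`.
#' @export
coherence_loss_grad <- function(observations, policies, ae, models,
                                prior = transition_prior(events = models$events)) {
  stopifnot(inherits(models, "event_models"))
  obs <- substitute_agency(observations, ae)
  res <- seq_loglik_grad_ae(obs, policies, models, prior)
  list(loss = -res$log_likelihood, grad = -res$grad_ae)
}

#' Adapt the agency estimate after a trial
#'
#' Runs `n_steps` iterations of momentum gradient descent on the coherence
#' loss: the buffer accumulates `momentum * buffer + grad`, the value moves
#' by `-learning_rate * buffer` and is clipped to \[0, 1\]. A non-finite
#' gradient aborts the adaptation for this trial, keeping the previous
#' estimate.
#'
#' @inheritParams coherence_loss
#' @param ae_state An [agency_estimate()].
#' @param config An [adaptation_config()].
#' @return The updated `agency_estimate`.
#' @export
adapt_agency <- function(observations, policies, ae_state,
                         config = adaptation_config(), models,
                         prior = transition_prior(events = models$events)) {
  stopifnot(inherits(ae_state, "agency_estimate"))
  value <- ae_state$value
  buffer <- ae_state$momentum_buffer
  for (k in seq_len(config$n_steps)) {
    g <- coherence_loss_grad(observations, policies, value, models, prior)$grad
    if (!is.finite(g)) {
      warning("non-finite coherence gradient; adaptation aborted for this trial")
      return(ae_state)
    }
    buffer <- config$momentum * buffer + g
    value <- min(1, max(0, value - config$learning_rate * buffer))
  }
  agency_estimate(value, buffer)
}
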