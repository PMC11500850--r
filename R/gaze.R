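# Active-inference gaze selection.
#
# With an approximately uniform preference over outcomes, expected free
# energy reduces to the anticipated observation entropy: the within-event
# term averages each event's dynamics-prediction entropy under the current
# posterior; with a one-boundary horizon (tau = 1) an anticipated transition
# term adds the end-density entropy of the current event and the start-
# density entropy of the successor, weighted by the normalised off-diagonal
# transition prior. The candidate policy enters through the policy input of
# the density networks, which learned the gaze-dependent noise structure
# during training.

#' Entropy of a diagonal-Gaussian prediction
#'
#' Closed form: `sum_k 0.5 * log(2 * pi * e * v_k)`.
#'
#' @param prediction A `gaussian_prediction`.
#' @return The differential entropy in nats.
#' @examples
#' predictive_entropy(manual_prediction(0, 1))  # 0.5 * log(2 * pi * e)
#' @export
predictive_entropy <- function(prediction) {
  0.5 * sum(log(2 * pi * exp(1) * prediction$var))
}

#' Planning horizon for gaze selection
#'
#' @param tau Number of future event boundaries considered: 0 (within-event
#'   uncertainty only) or 1 (also the next anticipated boundary; the
#'   default).
#' @return A `horizon_config` list.
#' @export
horizon_config <- function(tau = 1L) {
  tau <- as.integer(tau)
  if (!tau %in% c(0L, 1L)) {
    stop("tau must be 0 or 1; longer boundary horizons are not supported")
  }
  structure(list(tau = tau), class = "horizon_config")
}

#' Expected free energy of a gaze policy
#'
#' @param policy Candidate gaze policy.
#' @param posterior Current `event_posterior`.
#' @param o_t Current observation vector.
#' @param models Event models.
#' @param prior Transition prior (weights the anticipated successor event).
#' @param horizon A [horizon_config()].
#' @return The expected free energy (anticipated entropy, nats).
#' @export
expected_free_energy <- function(policy, posterior, o_t, models,
                                 prior = transition_prior(events = models$events),
                                 horizon = horizon_config()) {
  stopifnot(policy %in% POLICIES)
  evs <- models$events
  p <- unclass(posterior)[evs]
  efe <- 0
  for (i in seq_along(evs)) {
    if (p[i] <= 0) next
    h_dyn <- predictive_entropy(predict_dynamics(models, evs[i], o_t, policy))
    term <- h_dyn
    if (horizon$tau >= 1L) {
      h_end <- predictive_entropy(predict_end(models, evs[i], o_t, policy))
      w <- prior[, i]
      w[i] <- 0
      w <- w / sum(w)
      h_next <- 0
      for (j in seq_along(evs)) {
        if (j == i) next
        h_next <- h_next + w[j] *
          (h_end + predictive_entropy(predict_start(models, evs[j], policy)))
      }
      term <- term + h_next
    }
    efe <- efe + p[i] * term
  }
  unname(efe)
}

#' Expected free energy of all three policies
#'
#' @inheritParams expected_free_energy
#' @return Named numeric vector over `actor`, `patient`, `elsewhere`.
#' @export
efe_table <- function(posterior, o_t, models,
                      prior = transition_prior(events = models$events),
                      horizon = horizon_config()) {
  vapply(setNames(POLICIES, POLICIES), function(pl)
    expected_free_energy(pl, posterior, o_t, models, prior, horizon),
    numeric(1))
}

#' Select the gaze policy minimising expected free energy
#'
#' Ties break deterministically in the order actor, patient, elsewhere
#' (first minimum wins).
#'
#' @inheritParams expected_free_energy
#' @return The selected policy name.
#' @export
select_gaze <- function(posterior, o_t, models,
                        prior = transition_prior(events = models$events),
                        horizon = horizon_config()) {
  tab <- efe_table(posterior, o_t, models, prior, horizon)
  POLICIES[which.min(tab)]
}

# ---------------------------------------------------------------------------
# Fast EFE for trained models: one batched network call per (event,
# component) covering all three candidate policies; start entropies are
# policy-only and precomputed once per trial.

# 3-row input matrix: o_t paired with each policy one-hot.
efe_inputs <- function(o_t) {
  cbind(matrix(o_t, 3L, length(o_t), byrow = TRUE), diag(3))
}

precompute_start_entropy <- function(models) {
  sapply(setNames(POLICIES, POLICIES), function(p) {
    vapply(setNames(models$events, models$events), function(ev) {
      out <- gdn_forward(models$nets[[ev]]$start, policy_onehot(p))
      0.5 * sum(log(2 * pi * exp(1) * out$var))
    }, numeric(1))
  })  # events x policies
}

efe_table_fast <- function(models, posterior, o_t, prior, tau, start_entropy) {
  evs <- models$events
  n <- length(evs)
  X <- efe_inputs(o_t)
  efe <- numeric(3L)
  for (i in seq_len(n)) {
    p_i <- posterior[i]
    if (p_i <= 0) next
    dyn <- gdn_forward(models$nets[[evs[i]]]$dynamics, X)
    term <- 0.5 * rowSums(log(2 * pi * exp(1) * dyn$var))
    if (tau >= 1L) {
      endo <- gdn_forward(models$nets[[evs[i]]]$end, X)
      h_end <- 0.5 * rowSums(log(2 * pi * exp(1) * endo$var))
      w <- prior[, i]; w[i] <- 0; w <- w / sum(w)
      h_start <- drop(t(start_entropy[-i, , drop = FALSE]) %*% w[-i])
      term <- term + h_end + h_start
    }
    efe <- efe + p_i * term
  }
  setNames(efe, POLICIES)
}
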