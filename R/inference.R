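# Recursive Bayesian inference over events.
#
# The filter tracks P[e_i(t) | o(1..t), pi(0..t-1)]. At each step the
# likelihood of the new observation under "event stays" is the event's
# dynamics density, and under "event changes" the product of the new event's
# start density and the old event's end density; a sticky transition prior
# (90% self-transition by default) weighs the two. All accumulation happens
# in log space via log-sum-exp.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Sticky event-transition prior
#'
#' @param self_probability Probability that the event at `t` equals the event
#'   at `t - 1` (default 0.9); the remainder is shared uniformly among the
#'   other events.
#' @param events Event names (defaults to the four canonical events).
#' @return A square matrix `P[i, j] = P(event i at t | event j at t - 1)`
#'   whose columns sum to 1.
#' @examples
#' transition_prior()
#' @export
transition_prior <- function(self_probability = 0.9, events = EVENTS) {
  n <- length(events)
  stopifnot(self_probability > 0, self_probability <= 1, n >= 2)
  off <- (1 - self_probability) / (n - 1)
  m <- matrix(off, n, n, dimnames = list(events, events))
  diag(m) <- self_probability
  m
}

as_posterior <- function(p, events) {
  p <- p / sum(p)
  structure(setNames(p, events), class = "event_posterior")
}

#' Posterior after the first observation
#'
#' The sequence-initial posterior is proportional to each event's start
#' density at the first observation times a uniform event prior.
#'
#' @param o1 First observation vector.
#' @param pi0 Gaze policy under which `o1` was observed.
#' @param models Event models.
#' @return An `event_posterior` (named probability vector summing to 1).
#' @export
initial_posterior <- function(o1, pi0, models) {
  la <- vapply(models$events, function(ev)
    gaussian_log_density(o1, predict_start(models, ev, pi0)), numeric(1))
  la <- la - log(length(la))
  if (all(!is.finite(la))) {
    warning("all start likelihoods underflowed; returning uniform posterior")
    return(as_posterior(rep(1, length(la)), models$events))
  }
  as_posterior(exp(la - logsumexp(la)), models$events)
}

#' Per-step event-pair log-likelihood table
#'
#' Entry `[i, j]` is the log-likelihood of observing `o_t` given that event
#' `i` holds at `t` and event `j` held at `t - 1`: the dynamics density of
#' `i` on the diagonal, and the product of start density of `i` and end
#' density of `j` off the diagonal.
#'
#' @param o_t,o_tm1 Consecutive observation vectors.
#' @param pi_tm1 Policy under which `o_t` was observed.
#' @param models Event models.
#' @return A log-likelihood matrix with events as rows (new) and columns
#'   (previous).
#' @export
step_likelihoods <- function(o_t, o_tm1, pi_tm1, models) {
  evs <- models$events
  n <- length(evs)
  l_dyn <- vapply(evs, function(ev)
    gaussian_log_density(o_t, predict_dynamics(models, ev, o_tm1, pi_tm1)),
    numeric(1))
  l_start <- vapply(evs, function(ev)
    gaussian_log_density(o_t, predict_start(models, ev, pi_tm1)), numeric(1))
  l_end <- vapply(evs, function(ev)
    gaussian_log_density(o_t, predict_end(models, ev, o_tm1, pi_tm1)),
    numeric(1))
  tab <- outer(l_start, l_end, "+")
  diag(tab) <- l_dyn
  dimnames(tab) <- list(evs, evs)
  tab
}

#' One filter update
#'
#' Marginalises the step likelihood table over the previous posterior and the
#' sticky transition prior and renormalises (Bayes), in log space.
#'
#' @param prev Previous `event_posterior`.
#' @param table Log-likelihood table from [step_likelihoods()].
#' @param prior Transition prior from [transition_prior()].
#' @return Updated `event_posterior`.
#' @export
update_posterior <- function(prev, table, prior) {
  lp <- log(unclass(prev))
  M <- table + log(prior) + rep(lp, each = nrow(table))
  l_t <- logsumexp(M)
  if (!is.finite(l_t)) {
    warning("total posterior mass underflowed; returning uniform posterior")
    return(as_posterior(rep(1, nrow(table)), rownames(table)))
  }
  la <- apply(M, 1L, logsumexp) - l_t
  as_posterior(exp(la), rownames(table))
}

#' Filter a whole sequence
#'
#' Runs the recursive event filter over a trial, returning the posterior
#' trace and the per-step predictive log-likelihood
#' `log P[o(t) | o(1..t-1), pi(0..t-1)]` whose sum is the sequence
#' log-likelihood used by the coherence mechanism.
#'
#' @param observations T x D observation matrix (rows are timesteps).
#' @param policies Character vector; `policies[t]` is the policy under which
#'   row `t` was observed.
#' @param models Event models.
#' @param prior Transition prior.
#' @return List with `posteriors` (T x n_events matrix), `log_predictive`
#'   (length-T vector) and `log_likelihood` (their sum).
#' @export
filter_sequence <- function(observations, policies, models,
                            prior = transition_prior(events = models$events)) {
  observations <- as.matrix(observations)
  len <- nrow(observations)
  stopifnot(length(policies) == len)
  if (inherits(models, "event_models")) {
    return(filter_fast(observations, policies, models, prior))
  }
  evs <- models$events
  post <- matrix(NA_real_, len, length(evs), dimnames = list(NULL, evs))
  lpred <- numeric(len)

  la <- vapply(evs, function(ev)
    gaussian_log_density(observations[1, ], predict_start(models, ev, policies[1])),
    numeric(1)) - log(length(evs))
  lpred[1] <- logsumexp(la)
  lalpha <- la - lpred[1]
  post[1, ] <- exp(lalpha)
  lprior <- log(prior)
  for (t in seq_len(len)[-1]) {
    tab <- step_likelihoods(observations[t, ], observations[t - 1, ],
                            policies[t], models)
    M <- tab + lprior + rep(lalpha, each = length(evs))
    lpred[t] <- logsumexp(M)
    lalpha <- apply(M, 1L, logsumexp) - lpred[t]
    post[t, ] <- exp(lalpha)
  }
  list(posteriors = post, log_predictive = lpred,
       log_likelihood = sum(lpred))
}

#' Sequence log-likelihood
#'
#' `sum_t log P[o(t) | o(1..t-1), pi(0..t-1)]` under the event filter; the
#' first term is the uniform mixture of the start densities.
#'
#' @inheritParams filter_sequence
#' @return A single log-likelihood value.
#' @export
sequence_log_likelihood <- function(observations, policies, models,
                                    prior = transition_prior(events = models$events)) {
  filter_sequence(observations, policies, models, prior)$log_likelihood
}

# ---------------------------------------------------------------------------
# Fast path for trained models: the same recursion with direct network calls
# and start predictions precomputed per policy (they depend on the policy
# alone).

precompute_start <- function(models) {
  lapply(setNames(POLICIES, POLICIES), function(p) {
    lapply(setNames(models$events, models$events), function(ev) {
      out <- gdn_forward(models$nets[[ev]]$start, policy_onehot(p))
      list(mean = drop(out$mean), var = drop(out$var))
    })
  })
}

diag_logdens <- function(o, mu, v) {
  -0.5 * sum(log(2 * pi * v) + (o - mu)^2 / v)
}

# Log-likelihood table for one step from precomputed start predictions.
# Dynamics variances come from the shared variance model.
step_table_fast <- function(models, o_t, o_tm1, pol, start_pred) {
  evs <- models$events
  n <- length(evs)
  x <- matrix(c(o_tm1, policy_onehot(pol)), 1L)
  tab <- matrix(NA_real_, n, n)
  l_start <- numeric(n); l_end <- numeric(n)
  for (j in seq_len(n)) {
    dj <- gdn_forward(models$nets[[evs[j]]]$dynamics, x)
    tab[j, j] <- diag_logdens(o_t, drop(dj$mean), drop(dj$var))
    ej <- gdn_forward(models$nets[[evs[j]]]$end, x)
    l_end[j] <- diag_logdens(o_t, drop(ej$mean), drop(ej$var))
    sp <- start_pred[[pol]][[evs[j]]]
    l_start[j] <- diag_logdens(o_t, sp$mean, sp$var)
  }
  off <- outer(l_start, l_end, "+")
  tab[is.na(tab)] <- off[is.na(tab)]
  tab
}

filter_fast <- function(observations, policies, models, prior) {
  evs <- models$events
  n <- length(evs)
  len <- nrow(observations)
  start_pred <- precompute_start(models)
  post <- matrix(NA_real_, len, n, dimnames = list(NULL, evs))
  lpred <- numeric(len)
  la <- vapply(seq_len(n), function(i) {
    sp <- start_pred[[policies[1]]][[evs[i]]]
    diag_logdens(observations[1, ], sp$mean, sp$var)
  }, numeric(1)) - log(n)
  lpred[1] <- logsumexp(la)
  lalpha <- la - lpred[1]
  post[1, ] <- exp(lalpha)
  lprior <- log(prior)
  for (t in seq_len(len)[-1]) {
    tab <- step_table_fast(models, observations[t, ], observations[t - 1, ],
                           policies[t], start_pred)
    M <- tab + lprior + rep(lalpha, each = n)
    lpred[t] <- logsumexp(M)
    lalpha <- apply(M, 1L, logsumexp) - lpred[t]
    post[t, ] <- exp(lalpha)
  }
  list(posteriors = post, log_predictive = lpred, log_likelihood = sum(lpred))
}

# ---------------------------------------------------------------------------
# Fast filter for trained models, optionally with the forward-mode derivative
# of the sequence log-likelihood with respect to the agency slot. The agency
# value enters every observation (as filtering target and as network input),
# so tangents are propagated with d(obs)/d(ae) = e_agency at every timestep.

# Log density and its tangent given prediction tangents and the target
# tangent d(obs)/d(ae) = e_agency (only the agency component is non-zero).
logdens_tangent <- function(o, mu, v, dmu, dv, dobs_agency) {
  r <- o - mu
  d <- sum(-r / v * (-dmu)) - 0.5 * sum(dv / v) + 0.5 * sum(r^2 * dv / v^2)
  # target contribution: only the agency slot of o moves with ae
  d + (-(r[OBS_AGENCY]) / v[OBS_AGENCY]) * dobs_agency
}

# Forward filter over an ae-substituted trial with analytic d(loglik)/d(ae).
# observations must already carry ae in the agency slot.
seq_loglik_grad_ae <- function(observations, policies, models, prior) {
  stopifnot(inherits(models, "event_models"))
  evs <- models$events
  n <- length(evs)
  len <- nrow(observations)
  lprior <- log(prior)
  pol1h <- policy_onehot(policies)
  e_ag <- numeric(models$obs_dim + 3L)
  e_ag[OBS_AGENCY] <- 1

  # start predictions depend on the policy only: precompute per policy
  start_pred <- lapply(setNames(POLICIES, POLICIES), function(p) {
    lapply(setNames(evs, evs), function(ev)
      gdn_forward(models$nets[[ev]]$start, policy_onehot(p)))
  })

  la <- numeric(n); dla <- numeric(n)
  o1 <- observations[1, ]
  for (i in seq_len(n)) {
    sp <- start_pred[[policies[1]]][[evs[i]]]
    mu <- drop(sp$mean); v <- drop(sp$var)
    la[i] <- -0.5 * sum(log(2 * pi * v) + (o1 - mu)^2 / v) - log(n)
    dla[i] <- -(o1[OBS_AGENCY] - mu[OBS_AGENCY]) / v[OBS_AGENCY]
  }
  l1 <- logsumexp(la)
  w <- exp(la - l1)
  loglik <- l1
  dloglik <- sum(w * dla)
  lalpha <- la - l1
  dlalpha <- dla - dloglik

  for (t in seq_len(len)[-1]) {
    o_t <- observations[t, ]
    x <- matrix(c(observations[t - 1, ], pol1h[t, ]), 1L)
    dx <- matrix(e_ag, 1L)
    tab <- matrix(NA_real_, n, n)
    dtab <- matrix(NA_real_, n, n)
    l_start_t <- numeric(n); d_start_t <- numeric(n)
    for (i in seq_len(n)) {
      sp <- start_pred[[policies[t]]][[evs[i]]]
      mu <- drop(sp$mean); v <- drop(sp$var)
      l_start_t[i] <- -0.5 * sum(log(2 * pi * v) + (o_t - mu)^2 / v)
      d_start_t[i] <- -(o_t[OBS_AGENCY] - mu[OBS_AGENCY]) / v[OBS_AGENCY]
    }
    l_end <- numeric(n); d_end <- numeric(n)
    for (j in seq_len(n)) {
      dj <- gdn_jvp(models$nets[[evs[j]]]$dynamics, x, dx)
      mu <- drop(dj$mean); v <- drop(dj$var)
      dmu <- drop(dj$dmean); dv <- drop(dj$dvar)
      tab[j, j] <- -0.5 * sum(log(2 * pi * v) + (o_t - mu)^2 / v)
      dtab[j, j] <- logdens_tangent(o_t, mu, v, dmu, dv, 1)
      ej <- gdn_jvp(models$nets[[evs[j]]]$end, x, dx)
      mu <- drop(ej$mean); v <- drop(ej$var)
      l_end[j] <- -0.5 * sum(log(2 * pi * v) + (o_t - mu)^2 / v)
      d_end[j] <- logdens_tangent(o_t, mu, v, drop(ej$dmean), drop(ej$dvar), 1)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          tab[i, j] <- l_start_t[i] + l_end[j]
          dtab[i, j] <- d_start_t[i] + d_end[j]
        }
      }
    }
    M <- tab + lprior + rep(lalpha, each = n)
    dM <- dtab + rep(dlalpha, each = n)
    l_t <- logsumexp(M)
    wfull <- exp(M - l_t)
    dl_t <- sum(wfull * dM)
    row_ls <- apply(M, 1L, logsumexp)
    wrow <- exp(M - row_ls)           # row-normalised weights
    dlrow <- rowSums(wrow * dM)
    loglik <- loglik + l_t
    dloglik <- dloglik + dl_t
    lalpha <- row_ls - l_t
    dlalpha <- dlrow - dl_t
  }
  list(log_likelihood = loglik, grad_ae = dloglik)
}
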