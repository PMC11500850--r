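# Shared oracles and fixtures, all built in code.

lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# A manual two-to-four event model with fixed 1-dim Gaussian components.
# `spec` is a named list event -> list(start=, dynamics=, end=) where each
# entry is c(mean, var).
toy_models <- function(spec) {
  comps <- lapply(spec, function(ev)
    lapply(ev, function(p) list(mean = p[1], var = p[2])))
  manual_event_models(comps, obs_dim = 1L)
}

# identical components for every event: perfectly symmetric model
symmetric_toy <- function(events = c("A", "B"), mean = 0, var = 1) {
  spec <- setNames(lapply(events, function(e)
    list(start = c(mean, var), dynamics = c(mean, var), end = c(mean, var))),
    events)
  toy_models(spec)
}

# Brute-force sequence likelihood: enumerate every event path, accumulate
# start/dynamics/end likelihoods and the sticky transition prior.
enumerate_log_evidence <- function(obs, policies, models, prior) {
  evs <- models$events
  n <- length(evs)
  len <- nrow(obs)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), len))
  terms <- apply(grid, 1L, function(path) {
    lp <- -log(n) + gaussian_log_density(
      obs[1, ], predict_start(models, evs[path[1]], policies[1]))
    for (t in seq_len(len)[-1]) {
      i <- path[t]; j <- path[t - 1]
      lp <- lp + log(prior[i, j])
      lp <- lp + if (i == j) {
        gaussian_log_density(obs[t, ],
          predict_dynamics(models, evs[i], obs[t - 1, ], policies[t]))
      } else {
        gaussian_log_density(obs[t, ],
          predict_start(models, evs[i], policies[t])) +
        gaussian_log_density(obs[t, ],
          predict_end(models, evs[j], obs[t - 1, ], policies[t]))
      }
    }
    lp
  })
  list(log_evidence = lse(terms),
       last_posterior = vapply(seq_len(n), function(i)
         exp(lse(terms[grid[[len]] == i]) - lse(terms)), numeric(1)))
}

# Lazy cross-file cache (helpers are sourced once per test run).
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small trained model for component-level behavioural checks.
smoke_models <- function() {
  cached_fixture("smoke", {
    sched <- train_schedule(3L, 40L)
    run_training(event_models_init(seed = 3), sched, seed = 3)$checkpoints[[3]]
  })
}

# The reduced developmental protocol shared by the acceptance checks.
reduced_protocol <- function() {
  cached_fixture("protocol", run_reduced_protocol(seed = 1))
}
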