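test_that("predictive entropy has the closed form and matches sampling", {
  expect_equal(predictive_entropy(manual_prediction(0, 1)),
               0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(0.5 * log(2 * pi * exp(1)), 1.4189, tolerance = 1e-4)
  # doubling every variance of an 18-dim prediction adds (18/2) log 2
  v <- rexp(18) + 0.1
  p1 <- manual_prediction(numeric(18), v)
  p2 <- manual_prediction(numeric(18), 2 * v)
  expect_equal(predictive_entropy(p2) - predictive_entropy(p1),
               9 * log(2), tolerance = 1e-12)
  # Monte-Carlo entropy estimate, 3 dims, 1e5 samples
  set.seed(31)
  mu <- c(0.5, -1, 2); vv <- c(0.2, 1.5, 0.05)
  p <- manual_prediction(mu, vv)
  x <- cbind(rnorm(1e5, mu[1], sqrt(vv[1])), rnorm(1e5, mu[2], sqrt(vv[2])),
             rnorm(1e5, mu[3], sqrt(vv[3])))
  mc <- -mean(apply(x, 1, gaussian_log_density, prediction = p))
  expect_equal(predictive_entropy(p), mc,
               tolerance = 0.02 * abs(predictive_entropy(p)))
})

test_that("expected free energy matches hand computation on a toy model", {
  # policy-dependent entropies via function-valued components
  comp <- function(base) {
    function(ref, policy) {
      v <- base * c(actor = 1, patient = 2, elsewhere = 4)[[policy]]
      list(mean = 0, var = v)
    }
  }
  comps <- list(
    A = list(start = comp(1), dynamics = comp(0.5), end = comp(2)),
    B = list(start = comp(3), dynamics = comp(1), end = comp(1)))
  m <- manual_event_models(comps, obs_dim = 1)
  prior <- transition_prior(0.9, c("A", "B"))
  post <- structure(setNames(c(0.7, 0.3), c("A", "B")),
                    class = "event_posterior")
  H <- function(v) 0.5 * log(2 * pi * exp(1) * v)
  for (pol in policy_names()) {
    k <- c(actor = 1, patient = 2, elsewhere = 4)[[pol]]
    manual <- 0.7 * (H(0.5 * k) + (H(2 * k) + H(3 * k))) +
      0.3 * (H(1 * k) + (H(1 * k) + H(1 * k)))
    expect_equal(expected_free_energy(pol, post, 0, m, prior,
                                      horizon_config(1)), manual,
                 tolerance = 1e-12)
    # tau = 0 drops the boundary term
    manual0 <- 0.7 * H(0.5 * k) + 0.3 * H(1 * k)
    expect_equal(expected_free_energy(pol, post, 0, m, prior,
                                      horizon_config(0)), manual0,
                 tolerance = 1e-12)
  }
  # all-equal entropies across policies produce exact ties; actor wins
  m2 <- symmetric_toy(c("A", "B"))
  expect_identical(select_gaze(post, 0, m2, prior), "actor")
})

test_that("gaze selection takes the arg-min with deterministic tie-breaks", {
  # engineered EFE ordering: patient's variance smallest under patient policy
  comp <- function(scale) {
    function(ref, policy) {
      v <- scale * c(actor = 1, patient = 0.5, elsewhere = 2)[[policy]]
      list(mean = 0, var = v)
    }
  }
  comps <- list(A = list(start = comp(1), dynamics = comp(1), end = comp(1)),
                B = list(start = comp(1), dynamics = comp(1), end = comp(1)))
  m <- manual_event_models(comps, obs_dim = 1)
  prior <- transition_prior(0.9, c("A", "B"))
  post <- structure(setNames(c(0.5, 0.5), c("A", "B")),
                    class = "event_posterior")
  tab <- efe_table(post, 0, m, prior)
  expect_identical(names(which.min(tab)), "patient")
  expect_identical(select_gaze(post, 0, m, prior), "patient")
  expect_lt(tab["patient"], tab["actor"])
  expect_lt(tab["actor"], tab["elsewhere"])
})

test_that("expected free energy is invariant under event relabelling", {
  spec <- list(A = list(start = c(0, 1), dynamics = c(0, 0.4), end = c(0, 2)),
               B = list(start = c(1, 3), dynamics = c(1, 0.7), end = c(1, 1)))
  m <- toy_models(spec)
  m_swapped <- toy_models(spec[c("B", "A")])
  prior <- transition_prior(0.9, c("A", "B"))
  prior_swapped <- transition_prior(0.9, c("B", "A"))
  post <- structure(setNames(c(0.8, 0.2), c("A", "B")),
                    class = "event_posterior")
  post_swapped <- structure(setNames(c(0.2, 0.8), c("B", "A")),
                            class = "event_posterior")
  for (pol in policy_names()) {
    expect_equal(
      expected_free_energy(pol, post, 0.1, m, prior),
      expected_free_energy(pol, post_swapped, 0.1, m_swapped, prior_swapped),
      tolerance = 1e-12)
  }
})

test_that("inflating predictive variances never lowers expected free energy", {
  spec <- list(A = list(start = c(0, 1), dynamics = c(0, 0.4), end = c(0, 2)),
               B = list(start = c(1, 3), dynamics = c(1, 0.7), end = c(1, 1)))
  post <- structure(setNames(c(0.6, 0.4), c("A", "B")),
                    class = "event_posterior")
  prior <- transition_prior(0.9, c("A", "B"))
  base <- expected_free_energy("elsewhere", post, 0, toy_models(spec), prior)
  for (k in c(1.5, 4, 10)) {
    inflated <- lapply(spec, function(ev) lapply(ev, function(p)
      c(p[1], p[2] * k)))
    expect_gt(expected_free_energy("elsewhere", post, 0,
                                   toy_models(inflated), prior), base)
  }
})

test_that("a trained model prefers the patient late in a recognised reach", {
  protocol <- reduced_protocol()
  mod <- protocol$final
  post <- structure(setNames(c(0, 0, 1, 0), event_names()),
                    class = "event_posterior")
  prior <- transition_prior()
  wins <- 0L
  for (i in 1:12) {
    rec <- generate_sequence("full_grasp", 0.2, seed = 8200 + i)
    t_late <- rec$contact_time - 5L
    o <- rec$observations[t_late, ]
    tab <- efe_table(post, o, mod, prior, horizon_config(1))
    wins <- wins + (tab["patient"] < tab["actor"])
  }
  expect_gt(wins, 6)
})
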