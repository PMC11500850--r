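test_that("initial posterior follows Bayes over start densities", {
  m <- symmetric_toy(c("A", "B", "C", "D"))
  p <- initial_posterior(0.2, "actor", m)
  expect_equal(unclass(p), setNames(rep(0.25, 4), c("A", "B", "C", "D")))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # one start density is e^2 times the others at the observation
  spec <- list(
    still = list(start = c(0, 1), dynamics = c(0, 1), end = c(0, 1)),
    random = list(start = c(2, 1), dynamics = c(0, 1), end = c(0, 1)),
    reach = list(start = c(2, 1), dynamics = c(0, 1), end = c(0, 1)),
    transport = list(start = c(2, 1), dynamics = c(0, 1), end = c(0, 1)))
  m2 <- toy_models(spec)
  p2 <- initial_posterior(0, "actor", m2)   # logdens gap is exactly 2
  expect_equal(unname(p2["still"]), exp(2) / (exp(2) + 3), tolerance = 1e-12)
})

test_that("step likelihood tables match hand computation", {
  m <- symmetric_toy(c("A", "B"))
  tab <- step_likelihoods(0.5, 0.1, "actor", m)
  # with identical densities everywhere, all diagonal entries agree and all
  # off-diagonal entries agree (the latter are start x end products)
  expect_true(all(diag(tab) == tab[1, 1]))
  expect_true(all(tab[row(tab) != col(tab)] == tab[1, 2]))
  expect_equal(tab[1, 2], 2 * dnorm(0.5, 0, 1, log = TRUE), tolerance = 1e-12)
  expect_equal(tab[1, 1], dnorm(0.5, 0, 1, log = TRUE), tolerance = 1e-12)

  spec <- list(A = list(start = c(1, 2), dynamics = c(0, 0.5), end = c(-1, 1)),
               B = list(start = c(0, 1), dynamics = c(2, 4), end = c(0.5, 3)))
  m2 <- toy_models(spec)
  tab2 <- step_likelihoods(0.3, 0, "patient", m2)
  expect_equal(tab2["A", "A"], dnorm(0.3, 0, sqrt(0.5), log = TRUE))
  expect_equal(tab2["B", "B"], dnorm(0.3, 2, 2, log = TRUE))
  expect_equal(tab2["A", "B"], dnorm(0.3, 1, sqrt(2), log = TRUE) +
                 dnorm(0.3, 0.5, sqrt(3), log = TRUE))
  expect_equal(tab2["B", "A"], dnorm(0.3, 0, 1, log = TRUE) +
                 dnorm(0.3, -1, 1, log = TRUE))
  # extreme observations stay finite in log space
  expect_true(all(is.finite(step_likelihoods(50, -50, "actor", m2))))
})

test_that("posterior updates implement the sticky-prior Bayes rule", {
  events <- event_names()
  prior <- transition_prior(0.9)
  tab <- matrix(0, 4, 4, dimnames = list(events, events))
  uniform <- structure(setNames(rep(0.25, 4), events), class = "event_posterior")
  expect_equal(unclass(update_posterior(uniform, tab, prior)),
               setNames(rep(0.25, 4), events), tolerance = 1e-12)

  prev <- structure(setNames(c(1, 0, 0, 0), events), class = "event_posterior")
  post <- update_posterior(prev, tab, prior)
  expect_equal(unclass(post),
               setNames(c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3), events),
               tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-9)
})

test_that("the recursive filter equals exhaustive path enumeration", {
  prior2 <- transition_prior(0.9, c("A", "B"))
  set.seed(21)
  for (rep in 1:3) {
    spec <- list(
      A = list(start = c(rnorm(1), rexp(1) + 0.2),
               dynamics = c(rnorm(1), rexp(1) + 0.2),
               end = c(rnorm(1), rexp(1) + 0.2)),
      B = list(start = c(rnorm(1), rexp(1) + 0.2),
               dynamics = c(rnorm(1), rexp(1) + 0.2),
               end = c(rnorm(1), rexp(1) + 0.2)))
    m <- toy_models(spec)
    for (len in c(3L, 6L)) {
      obs <- matrix(rnorm(len), ncol = 1)
      pols <- sample(policy_names(), len, replace = TRUE)
      oracle <- enumerate_log_evidence(obs, pols, m, prior2)
      fs <- filter_sequence(obs, pols, m, prior2)
      expect_equal(fs$log_likelihood, oracle$log_evidence, tolerance = 1e-8)
      expect_equal(unname(fs$posteriors[len, ]), oracle$last_posterior,
                   tolerance = 1e-8)
      expect_equal(sequence_log_likelihood(obs, pols, m, prior2),
                   oracle$log_evidence, tolerance = 1e-8)
    }
  }
})

test_that("a single-timestep trial reduces to the uniform start mixture", {
  spec <- list(A = list(start = c(0, 1), dynamics = c(0, 1), end = c(0, 1)),
               B = list(start = c(1, 4), dynamics = c(0, 1), end = c(0, 1)))
  m <- toy_models(spec)
  ll <- sequence_log_likelihood(matrix(0.4), "actor", m,
                                transition_prior(0.9, c("A", "B")))
  expect_equal(ll, log(0.5 * dnorm(0.4, 0, 1) + 0.5 * dnorm(0.4, 1, 2)),
               tolerance = 1e-12)
})

test_that("filtering a simulated trial keeps the posterior normalised and finite", {
  m <- event_models_init(seed = 5)
  rec <- generate_sequence("full_grasp", 0.2, seed = 99)
  fs <- filter_sequence(rec$observations, rec$policies, m)
  expect_true(all(abs(rowSums(fs$posteriors) - 1) < 1e-9))
  expect_true(all(is.finite(fs$log_predictive)))
  # observations far outside the predicted range stay finite in log space
  extreme <- rec$observations
  extreme[10, 1:6] <- extreme[10, 1:6] + 5
  fs2 <- filter_sequence(extreme, rec$policies, m)
  expect_true(all(is.finite(fs2$log_predictive)))
})
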