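test_that("gaussian_log_density matches the textbook formula", {
  expect_equal(gaussian_log_density(0, manual_prediction(0, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_log_density(1, manual_prediction(0, 1)),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  # random 18-dim instances against the dnorm oracle
  set.seed(5)
  for (k in 1:20) {
    mu <- rnorm(18)
    v <- rexp(18) + 0.01
    o <- rnorm(18, mu, sqrt(v))
    expect_equal(gaussian_log_density(o, manual_prediction(mu, v)),
                 sum(dnorm(o, mu, sqrt(v), log = TRUE)), tolerance = 1e-10)
  }
  expect_error(gaussian_log_density(0, structure(
    list(mean = 0, var = -1), class = "gaussian_prediction")))
})

test_that("the density integrates to one", {
  # grid integration in 1 dim
  p <- manual_prediction(0.3, 0.25)
  xs <- seq(-5, 6, length.out = 20001)
  dens <- exp(vapply(xs, gaussian_log_density, numeric(1), prediction = p))
  expect_equal(sum(dens) * diff(xs)[1], 1, tolerance = 1e-4)
  # Monte-Carlo importance check in 2 dims: E_q[p/q] = 1 with q wider than p
  set.seed(9)
  p2 <- manual_prediction(c(0.1, -0.4), c(0.3, 0.8))
  q_sd <- c(1.2, 1.8)
  x <- cbind(rnorm(1e5, 0.1, q_sd[1]), rnorm(1e5, -0.4, q_sd[2]))
  lw <- apply(x, 1, gaussian_log_density, prediction = p2) -
    (dnorm(x[, 1], 0.1, q_sd[1], log = TRUE) +
       dnorm(x[, 2], -0.4, q_sd[2], log = TRUE))
  expect_equal(mean(exp(lw)), 1, tolerance = 0.01)
})

test_that("untrained components give valid, deterministic predictions", {
  m <- event_models_init(seed = 2)
  for (ev in event_names()) {
    for (pol in policy_names()) {
      p <- predict_start(m, ev, pol)
      expect_length(p$mean, 18)
      expect_true(all(is.finite(p$mean)) && all(p$var > 0))
    }
  }
  o <- rnorm(18)
  a <- predict_dynamics(m, "reach", o, "actor")
  b <- predict_dynamics(m, "reach", o, "actor")
  expect_identical(a, b)
  e1 <- predict_end(m, "transport", o, "patient")
  expect_true(all(e1$var > 0))
  # signature safety: wrong input dimensionality is rejected
  expect_error(predict_dynamics(m, "reach", o[1:5], "actor"))
  expect_error(predict_end(m, "reach", o[1:5], "actor"))
  expect_error(predict_start(m, "flying", "actor"))
  expect_error(predict_start(m, "reach", "nowhere"))
})

test_that("fitting reduces held-out dynamics NLL and is deterministic", {
  seqs <- lapply(1:30, function(i)
    generate_sequence(c("still", "random_motion", "full_grasp")[(i %% 3) + 1],
                      0.2, seed = 3000 + i))
  heldout <- lapply(1:6, function(i)
    generate_sequence(c("still", "random_motion", "full_grasp")[(i %% 3) + 1],
                      0.2, seed = 4000 + i))
  m0 <- event_models_init(seed = 4)
  before <- heldout_dynamics_loglik(m0, heldout)
  fit <- fit_components(m0, seqs)
  after <- heldout_dynamics_loglik(fit$models, heldout)
  expect_true(all(after > before))
  expect_true(all(c("sequence", "event", "kind", "nll") %in%
                    colnames(fit$loss_log)))

  fit2 <- fit_components(event_models_init(seed = 4), seqs)
  expect_identical(fit$models$nets$reach$dynamics$W1,
                   fit2$models$nets$reach$dynamics$W1)
})

test_that("training on still-only data leaves reach components unchanged", {
  m0 <- event_models_init(seed = 6)
  stills <- lapply(1:5, function(i)
    generate_sequence("still", 0.5, seed = 5000 + i))
  m1 <- fit_components(m0, stills)$models
  for (kind in c("start", "dynamics", "end")) {
    expect_identical(m0$nets$reach[[kind]]$W1, m1$nets$reach[[kind]]$W1)
    expect_false(identical(m0$nets$still[[kind]], m1$nets$still[[kind]]) &&
                   kind == "dynamics")
  }
  expect_false(identical(m0$nets$still$dynamics$W1, m1$nets$still$dynamics$W1))
})

test_that("trained still dynamics track a motionless world", {
  mod <- reduced_protocol()$final
  rec <- generate_sequence("still", 0.3, seed = 777)
  o <- rec$observations[10, ]
  p <- predict_dynamics(mod, "still", o, rec$policies[10])
  # position means stay within 3 predicted sd of the previous position
  idx <- 1:6
  expect_true(all(abs(p$mean[idx] - o[idx]) < 3 * sqrt(p$var[idx])))
  # velocity means are near zero relative to the predicted spread
  s <- predict_start(mod, "still", "actor")
  vel <- 7:12
  expect_true(all(abs(s$mean[vel]) < 3 * sqrt(s$var[vel])))
})

test_that("model checkpoints round-trip through JSON", {
  mod <- smoke_models()
  path <- tempfile(fileext = ".json")
  save_models(mod, path)
  back <- load_models(path)
  o <- generate_sequence("full_grasp", 0.2, seed = 88)$observations[5, ]
  for (ev in event_names()) {
    expect_equal(predict_dynamics(mod, ev, o, "patient"),
                 predict_dynamics(back, ev, o, "patient"), tolerance = 1e-12)
    expect_equal(predict_start(mod, ev, "elsewhere"),
                 predict_start(back, ev, "elsewhere"), tolerance = 1e-12)
  }
  unlink(path)
})

test_that("held-out dynamics predictions are calibrated after training", {
  protocol <- reduced_protocol()
  mod <- protocol$final
  heldout <- lapply(1:8, function(i)
    generate_sequence(c("random_motion", "full_grasp")[(i %% 2) + 1],
                      0.3, seed = 6000 + i))
  for (ev in event_names()) {
    inside <- 0L; total <- 0L
    for (rec in heldout) {
      lab <- rec$event_labels
      idx <- which(lab == ev & c(FALSE, lab[-length(lab)] == ev))
      for (t in head(idx, 30)) {
        p <- predict_dynamics(mod, ev, rec$observations[t - 1, ],
                              rec$policies[t])
        z <- abs(rec$observations[t, ] - p$mean) / sqrt(p$var)
        inside <- inside + sum(z < qnorm(0.995))
        total <- total + length(z)
      }
    }
    if (total > 0) expect_gte(inside / total, 0.8)
  }
})
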