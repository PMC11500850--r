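test_that("sequences respect type structure, lengths and world invariants", {
  expected_orders <- list(
    still = "still",
    random_motion = c("random", "still"),
    full_grasp = c("reach", "transport", "random"),
    reach_only = "reach")
  for (type in names(expected_orders)) {
    for (seed in 1:8) {
      rec <- generate_sequence(type, actor_shape = 0.3, seed = 100 * seed + 7)
      len <- length(rec$event_labels)
      expect_gte(len, 100)
      expect_lte(len, 270)
      expect_equal(nrow(rec$observations), len)
      expect_equal(length(rec$policies), len)
      expect_identical(rle(rec$event_labels)$values, expected_orders[[type]])
      w <- rec$world
      expect_true(all(w$actor_pos >= 0 & w$actor_pos <= 1))
      expect_true(all(w$patient_pos >= 0 & w$patient_pos <= 1))
      d <- sqrt(rowSums((w$actor_pos - w$patient_pos)^2))
      if (type %in% c("full_grasp", "reach_only")) {
        ct <- rec$contact_time
        expect_false(is.na(ct))
        expect_lt(d[ct], 0.01)
        expect_gte(d[ct - 1], 0.01)
        if (type == "reach_only") expect_identical(ct, len)
      } else {
        expect_true(is.na(rec$contact_time))
      }
      # heading/label agreement
      reach_t <- which(rec$event_labels == "reach")
      if (length(reach_t)) {
        expect_true(all(w$patient_vel[reach_t, ] == 0))
      }
      tr <- which(rec$event_labels == "transport")
      if (length(tr)) {
        expect_equal(w$actor_vel[tr, ], w$patient_vel[tr, ])
        # true displacements are equal at every transport step
        stepped <- tr[tr < len]
        expect_equal(w$actor_pos[stepped + 1, ] - w$actor_pos[stepped, ],
                     w$patient_pos[stepped + 1, ] - w$patient_pos[stepped, ])
      }
      if (type == "still") {
        expect_true(all(w$actor_vel == 0) && all(w$patient_vel == 0))
        expect_true(all(abs(diff(w$actor_pos)) == 0))
      }
    }
  }
})

test_that("identical seeds give bit-identical sequence records", {
  a <- generate_sequence("full_grasp", 0.25, seed = 42)
  b <- generate_sequence("full_grasp", 0.25, seed = 42)
  expect_identical(a$observations, b$observations)
  expect_identical(a$policies, b$policies)
  expect_identical(a$event_labels, b$event_labels)
  c <- generate_sequence("full_grasp", 0.25, seed = 43)
  expect_false(identical(a$observations, c$observations))
})

test_that("rendered observations have consistent geometry and calibrated noise", {
  world <- list(actor_position = c(0, 0, 0), patient_position = c(3, 4, 0),
                actor_velocity = c(0, 0, 0), patient_velocity = c(0, 0, 0))
  tiny <- noise_config(1e-12, 1e-12)
  s <- rng_stream(1)
  o <- render_observation(world, 0.3, 0.5, "actor", tiny, s)
  expect_equal(unname(o[13:15]), c(3, 4, 0), tolerance = 1e-9)
  expect_equal(unname(o[16]), 5, tolerance = 1e-9)
  expect_identical(unname(o[17]), 0.3)
  expect_identical(unname(o[18]), 0.5)

  # empirical sd of position components matches the configured sigmas
  nc <- noise_config(0.001, 0.1)
  s <- rng_stream(7)
  draws <- t(vapply(1:10000, function(i)
    render_observation(world, 0.3, 0.5, "actor", nc, s), numeric(18)))
  expect_equal(sd(draws[, 1]), 0.001, tolerance = 0.05)
  expect_equal(sd(draws[, 4]), 0.1, tolerance = 0.05)
  # variance of fixated components approximates sigma_fixated^2
  expect_lt(var(draws[, 1]), var(draws[, 4]))
  # internal estimates are never perturbed
  expect_true(all(draws[, 17] == 0.3) && all(draws[, 18] == 0.5))

  # under "elsewhere" both entities are noisy at sigma_other
  s <- rng_stream(8)
  draws <- t(vapply(1:10000, function(i)
    render_observation(world, 0.3, 0.5, "elsewhere", nc, s), numeric(18)))
  expect_equal(sd(draws[, 1]), 0.1, tolerance = 0.05)
  expect_equal(sd(draws[, 4]), 0.1, tolerance = 0.05)
})

test_that("actor shapes follow the developmental schedule", {
  sched <- shape_schedule(30)
  s <- rng_stream(11)
  early <- vapply(1:20000, function(i)
    sample_actor_shape(1, sched, "grasp_sequence", s), numeric(1))
  # phase 1: Normal(0.2, 0.1^2) truncated to [0, 1]; truncation shifts the
  # mean up a touch and shrinks the sd
  z <- pnorm(8) - pnorm(-2)
  m_th <- 0.2 + 0.1 * dnorm(-2) / z
  sd_th <- 0.1 * sqrt(1 + (-2) * dnorm(-2) / z - (dnorm(-2) / z)^2)
  expect_equal(mean(early), m_th, tolerance = 0.01)
  expect_equal(sd(early), sd_th, tolerance = 0.02)

  late <- vapply(1:20000, function(i)
    sample_actor_shape(30, sched, "grasp_sequence", s), numeric(1))
  # final phase: approximately Uniform(0, 1)
  expect_equal(mean(late), 0.5, tolerance = 0.02)
  expect_equal(var(late), 1 / 12, tolerance = 0.03)
  expect_gt(mean(late > 0.6), 0.35)

  rm_draws <- vapply(1:20000, function(i)
    sample_actor_shape(5, sched, "random_motion", s), numeric(1))
  # two modes near 0.2 and 0.8 with equal mass
  expect_equal(mean(rm_draws < 0.5), 0.5, tolerance = 0.02)
  expect_equal(mean(rm_draws[rm_draws < 0.5]), 0.2, tolerance = 0.05)
  expect_equal(mean(rm_draws[rm_draws > 0.5]), 0.8, tolerance = 0.05)

  # mix weight is non-decreasing, 0 at phase 1, 1 at the last phase
  w <- vapply(1:30, sched$uniform_mix_weight, numeric(1))
  expect_identical(w[1], 0)
  expect_identical(w[30], 1)
  expect_true(all(diff(w) >= 0))
  expect_error(sample_actor_shape(31, sched, "grasp_sequence", s))
})
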