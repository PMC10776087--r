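# Synthetic gait generator: determinism, latent-parameter recovery, and the
# degenerate limits that pin the construction down.

test_that("identical seed and config give byte-identical output", {
  cfg <- tiny_sim_config(seed = 42)
  a <- simulate_pass(cfg, animal = 1, pass_id = 1, condition = "control")
  b <- simulate_pass(cfg, animal = 1, pass_id = 1, condition = "control")
  expect_identical(a, b)

  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
})

test_that("adding animals does not perturb earlier animals' draws", {
  small <- tiny_sim_config(seed = 8)
  big <- sim_config(seed = 8, n_animals = 4L, passes_per_animal = 2L,
                    steps_per_pass = 6L)
  ev_small <- simulate_cohort(small)$events
  ev_big <- simulate_cohort(big)$events %>% dplyr::filter(animal <= 2)
  expect_identical(ev_small, ev_big)
})

test_that("degenerate von Mises limit collapses phases onto the pair mean", {
  cfg <- sim_config(seed = 4, n_animals = 1L, passes_per_animal = 1L,
                    steps_per_pass = 50L,
                    pair_phase_kappa = c(control = 1e6, silenced = 1e6),
                    p_irregular_uniform = c(control = 0, silenced = 0))
  sim <- simulate_pass(cfg, 1, 1, "control")
  ph <- cohort_phases(sim$events)$phases %>%
    dplyr::filter(pair == "hindlimb")
  expect_gt(nrow(ph), 40)
  expect_true(all(abs(ph$phi - 0.5) < 0.01))
})

test_that("recovered phases equal the latent draws exactly", {
  cfg <- tiny_sim_config(seed = 13)
  sim <- simulate_cohort(cfg)
  rec <- cohort_phases(sim$events)$phases
  joined <- dplyr::inner_join(
    rec, sim$truth$phases,
    by = c("animal", "pass_id", "condition", "pair", cycle = "step"),
    suffix = c("_rec", "_true"))
  expect_gt(nrow(joined), 100)
  expect_lt(max(abs(joined$phi_rec - joined$phi_true)), 1e-12)
})

test_that("recovered stance, swing and speed equal ground truth when noiseless", {
  cfg <- sim_config(seed = 6, n_animals = 1L, passes_per_animal = 1L,
                    steps_per_pass = 10L, placement_noise_sd = 0,
                    stance_noise_sd = 0)
  sim <- simulate_pass(cfg, 1, 1, "control")
  lh <- build_step_cycles(sim$events) %>% dplyr::filter(limb == "LH")
  truth <- sim$truth$steps
  expect_equal(lh$stance_time, truth$stance[seq_len(nrow(lh))],
               tolerance = 1e-12)
  expect_equal(lh$swing_time, truth$swing[seq_len(nrow(lh))],
               tolerance = 1e-12)
  expect_equal(lh$speed, truth$speed[seq_len(nrow(lh))], tolerance = 1e-9)
  # constant latent speed propagates to the pass average
  cfg2 <- sim_config(seed = 6, n_animals = 1L, passes_per_animal = 1L,
                     steps_per_pass = 10L, placement_noise_sd = 0,
                     speed_sd = 0)
  sim2 <- simulate_pass(cfg2, 1, 1, "control")
  cyc2 <- build_step_cycles(sim2$events)
  expect_equal(pass_average_speed(cyc2), cfg2$speed_mean, tolerance = 1e-9)
})

test_that("phase dispersion decreases monotonically in kappa", {
  disp <- vapply(c(2, 8, 50), function(k) {
    set.seed(101)
    circular_summary(rvonmises_cycles(10000, 0.5, k))$circular_sd
  }, numeric(1))
  expect_true(all(diff(disp) < 0))
})

test_that("empirical dorsal rate sits inside the binomial 99% CI", {
  p_d <- 0.2
  cfg <- sim_config(seed = 77, n_animals = 4L, passes_per_animal = 4L,
                    steps_per_pass = 25L,
                    p_dorsal = c(control = p_d, silenced = p_d))
  sim <- simulate_cohort(cfg, conditions = "control")
  dorsal <- sim$truth$dorsal
  n <- nrow(dorsal)
  k <- sum(dorsal$dorsal)
  ci <- qnorm(c(0.005, 0.995), p_d, sqrt(p_d * (1 - p_d) / n))
  expect_gt(k / n, ci[1])
  expect_lt(k / n, ci[2])
})

test_that("trajectory construction realises the configured angle model", {
  cfg <- sim_config(seed = 2, frame_rate = 400, camera_noise_sd = 0)
  cyc <- tibble::tibble(start_contact = c(0, 0.5), end_contact = c(0.5, 1))
  traj <- simulate_joint_trajectories(cfg, cyc)
  ang <- compute_joint_angles(traj)
  truth <- dplyr::filter(traj, camera == 1)
  expect_lt(max(abs(ang$proximal - truth$proximal_true)), 1e-6)
  expect_lt(max(abs(ang$distal - truth$distal_true)), 1e-6)

  # configured proximal excursion recovered within 1 degree, noiseless
  ext <- find_peaks_troughs(ang, cyc)
  prox <- dplyr::filter(ext, angle == "proximal")
  expect_true(all(abs(prox$excursion - cfg$proximal_excursion) < 1))

  # a zero intralimb offset reads as in-phase coordination
  cfg0 <- sim_config(seed = 2, frame_rate = 400, intralimb_peak_offset = 0)
  ang0 <- compute_joint_angles(simulate_joint_trajectories(cfg0, cyc))
  ip0 <- intralimb_phase(ang0, cyc)
  expect_equal(ip0$psi_folded[1], 1.0, tolerance = 0.02)
})

test_that("camera averaging is the arithmetic mean of per-camera angles", {
  cfg <- sim_config(seed = 3, frame_rate = 100, camera_noise_sd = 0.05)
  cyc <- tibble::tibble(start_contact = 0, end_contact = 0.5)
  traj <- simulate_joint_trajectories(cfg, cyc)
  avg <- compute_joint_angles(traj)
  per_cam <- lapply(split(traj, traj$camera), compute_joint_angles)
  expect_equal(avg$proximal,
               (per_cam[[1]]$proximal + per_cam[[2]]$proximal) / 2,
               tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(pair_phase_kappa = c(control = -1, silenced = 2)),
               "kappa")
  expect_error(sim_config(p_dorsal = c(control = 1.5, silenced = 0)),
               "probabilities")
  expect_error(sim_config(speed_mean = -10), "speed_mean")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(steps_per_pass = 1), "steps_per_pass")
  expect_error(sim_config(pair_phase_mu = c(hindlimb = 1.2, forelimb = 0.5,
                                            homolateral = 0.5,
                                            heterolateral = 0)),
               "phase means")
  expect_error(simulate_pass(tiny_sim_config(), 1, 1, "unknown_condition"),
               "condition")
})
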