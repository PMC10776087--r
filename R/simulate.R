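# Seeded synthetic gait generator. One pass = one crossing of the walkway by
# one animal. The left hindlimb is the lead limb; trailing limb contacts are
# constructed from the lead stride and a drawn pair phase, so the analysis-side
# phase formula recovers the latent phase exactly.

LIMB_LEVELS <- c("LF", "RF", "LH", "RH")

stance_law <- function(v, cfg) cfg$stance_a * exp(-cfg$stance_b * v) + cfg$stance_c

#' Simulate one locomotor pass
#'
#' Generates footfall events for the four limbs of one animal crossing the
#' walkway once, together with the latent ground truth. The left hindlimb
#' leads: its contact times accumulate drawn stride times (stance from the
#' speed-decay law plus a drawn swing). Each trailing limb's contact inside a
#' lead stride is placed at the drawn pair phase, a von Mises draw around the
#' configured pair mean mixed with a uniform irregular component. The right
#' forelimb is placed through the heterolateral pair and the left forelimb
#' through the homolateral pair; forelimb-forelimb alternation is emergent.
#'
#' @param config A [sim_config()] object.
#' @param animal Integer animal id.
#' @param pass_id Integer pass id.
#' @param condition Condition label; must appear in the config's per-condition
#'   parameter vectors.
#' @param timepoint Timepoint label attached to the events (defaults to the
#'   condition label).
#' @return A list with `events` (tibble of footfall events: `animal`,
#'   `timepoint`, `pass_id`, `surface`, `limb`, `contact_time`,
#'   `liftoff_time`, `x`, `y`, `placement`) and `truth` (list of tibbles
#'   `steps`, `phases`, `dorsal`, `passes` holding the latent draws).
#' @examples
#' sim <- simulate_pass(sim_config(seed = 1), animal = 1, pass_id = 1,
#'                      condition = "control")
#' @export
simulate_pass <- function(config, animal, pass_id, condition,
                          timepoint = condition) {
  stopifnot(inherits(config, "gait_sim_config"))
  validate_sim_config(config)
  if (!condition %in% names(config$pair_phase_kappa)) {
    abort(paste0("condition '", condition, "' has no configured parameters"))
  }
  cidx <- match(condition, names(config$pair_phase_kappa))
  with_preserved_seed(pass_seed(config$seed, animal, pass_id, cidx), {
    simulate_pass_impl(config, animal, pass_id, condition, timepoint)
  })
}

simulate_pass_impl <- function(cfg, animal, pass_id, condition, timepoint) {
  n <- cfg$steps_per_pass
  kappa <- cfg$pair_phase_kappa[[condition]]
  p_unif <- cfg$p_irregular_uniform[[condition]]
  p_dorsal <- cfg$p_dorsal[[condition]]

  track_width <- max(1, rnorm(1, cfg$track_width_mean, cfg$track_width_sd))
  # n strides need n + 1 contacts; the final contact reuses the last speed
  v <- pmax(5, rnorm(n, cfg$speed_mean, cfg$speed_sd))
  v_all <- c(v, v[n])
  stance <- pmax(0.01, stance_law(v_all, cfg) + rnorm(n + 1, 0, cfg$stance_noise_sd))
  swing <- pmax(0.005, rnorm(n, cfg$swing_mean, cfg$swing_sd))
  stride <- stance[seq_len(n)] + swing

  lead_contact <- 0.5 + c(0, cumsum(stride))      # n + 1 contacts
  lead_x <- 2 + c(0, cumsum(v * stride))

  draw_phases <- function(mu) {
    irregular <- runif(n) < p_unif
    phi <- rvonmises_cycles(n, mu, kappa)
    phi[irregular] <- runif(sum(irregular))
    list(phi = phi, irregular = irregular)
  }
  hl <- draw_phases(cfg$pair_phase_mu[["hindlimb"]])
  homo <- draw_phases(cfg$pair_phase_mu[["homolateral"]])
  het <- draw_phases(cfg$pair_phase_mu[["heterolateral"]])

  trail_events <- function(limb, phi) {
    tau <- lead_contact[seq_len(n)] + phi * stride
    gap <- diff(c(tau, tau[n] + stats::median(stride)))
    st <- pmax(0.01, stance_law(v, cfg) + rnorm(n, 0, cfg$stance_noise_sd))
    st <- pmin(st, 0.9 * gap)
    x <- lead_x[seq_len(n)] + phi * v * stride +
      if (limb %in% c("LF", "RF")) cfg$forelimb_offset else 0
    tibble(limb = limb, step = seq_len(n), contact_time = tau,
           liftoff_time = tau + st,
           x = x + rnorm(n, 0, cfg$placement_noise_sd))
  }

  lead_tb <- tibble(limb = "LH", step = seq_len(n + 1),
                    contact_time = lead_contact,
                    liftoff_time = lead_contact + stance,
                    x = lead_x + rnorm(n + 1, 0, cfg$placement_noise_sd))
  rh_tb <- trail_events("RH", hl$phi)
  lf_tb <- trail_events("LF", homo$phi)
  rf_tb <- trail_events("RF", het$phi)

  events <- bind_rows(lead_tb, rh_tb, lf_tb, rf_tb) %>%
    mutate(
      y = dplyr::if_else(.data$limb %in% c("LH", "LF"),
                         track_width / 2, -track_width / 2) +
        rnorm(dplyr::n(), 0, cfg$placement_noise_sd),
      placement = "plantar"
    )
  hind <- events$limb %in% c("LH", "RH")
  events$placement[hind] <- dplyr::if_else(
    runif(sum(hind)) < p_dorsal, "dorsal", "plantar")
  dorsal_truth <- events %>%
    filter(.data$limb %in% c("LH", "RH")) %>%
    mutate(animal = animal, pass_id = pass_id, condition = condition,
           dorsal = .data$placement == "dorsal") %>%
    select("animal", "pass_id", "condition", "limb", "step", "dorsal")

  events <- events %>%
    mutate(animal = animal, timepoint = timepoint, pass_id = pass_id,
           surface = cfg$surface, condition = condition) %>%
    select("animal", "timepoint", "condition", "pass_id", "surface", "limb",
           "step", "contact_time", "liftoff_time", "x", "y", "placement") %>%
    arrange(.data$contact_time, .data$limb)

  truth <- list(
    steps = tibble(animal = animal, pass_id = pass_id, condition = condition,
                   step = seq_len(n), speed = v,
                   stance = stance[seq_len(n)], swing = swing,
                   stride = stride,
                   contact_time = lead_contact[seq_len(n)]),
    phases = bind_rows(
      tibble(pair = "hindlimb", step = seq_len(n), phi = hl$phi,
             irregular_component = hl$irregular),
      tibble(pair = "homolateral", step = seq_len(n), phi = homo$phi,
             irregular_component = homo$irregular),
      tibble(pair = "heterolateral", step = seq_len(n), phi = het$phi,
             irregular_component = het$irregular)
    ) %>% mutate(animal = animal, pass_id = pass_id, condition = condition),
    dorsal = dorsal_truth,
    passes = tibble(animal = animal, pass_id = pass_id, condition = condition,
                    track_width = track_width)
  )
  list(events = events, truth = truth)
}

#' Simulate a full cohort
#'
#' Runs [simulate_pass()] for every animal, pass and condition in the
#' configuration and row-binds the results. Sub-seeds are derived per
#' (animal, pass, condition), so the draws for any unit are independent of
#' how many other units are simulated.
#'
#' @param config A [sim_config()] object.
#' @param conditions Conditions to simulate (default: all in the config).
#' @return A list with `events` (one footfall tibble) and `truth` (list of
#'   combined ground-truth tibbles).
#' @export
simulate_cohort <- function(config, conditions = config$conditions) {
  grid <- tidyr::expand_grid(condition = conditions,
                             animal = seq_len(config$n_animals),
                             pass_id = seq_len(config$passes_per_animal))
  sims <- purrr::pmap(grid, function(condition, animal, pass_id) {
    simulate_pass(config, animal, pass_id, condition)
  })
  list(
    events = purrr::map(sims, "events") %>% list_rbind(),
    truth = list(
      steps = purrr::map(sims, ~ .x$truth$steps) %>% list_rbind(),
      phases = purrr::map(sims, ~ .x$truth$phases) %>% list_rbind(),
      dorsal = purrr::map(sims, ~ .x$truth$dorsal) %>% list_rbind(),
      passes = purrr::map(sims, ~ .x$truth$passes) %>% list_rbind()
    )
  )
}

#' Simulate two-camera joint-marker trajectories
#'
#' Generates per-frame 2D coordinates of the iliac crest, hip, ankle and toe
#' markers for each supplied step cycle, for two sagittal cameras. The
#' proximal (iliac crest - hip - ankle) and distal (hip - ankle - toe) angles
#' follow cosine waveforms that are periodic with the step cycle, have the
#' configured excursions, and whose distal peak lags the proximal peak by
#' `intralimb_peak_offset` cycles. Camera 1 is noiseless; camera 2 adds
#' independent Gaussian marker noise of SD `camera_noise_sd`.
#'
#' @param config A [sim_config()] object.
#' @param cycles A tibble of step cycles with at least `start_contact` and
#'   `end_contact` columns (e.g. from [build_step_cycles()]), or the ground
#'   truth `steps` table (columns `contact_time`, `stride`).
#' @return A tibble with columns `camera`, `cycle`, `time`, and marker
#'   coordinates `crest_x` ... `toe_y` (cm), plus the true per-frame
#'   `proximal_true` and `distal_true` angles in degrees.
#' @export
simulate_joint_trajectories <- function(config, cycles) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (nrow(cycles) == 0) abort("cycles must be non-empty")
  if (any(config$segment_lengths <= 0)) abort("segment lengths must be positive")
  if (!all(c("start_contact", "end_contact") %in% names(cycles))) {
    if (all(c("contact_time", "stride") %in% names(cycles))) {
      cycles <- cycles %>%
        mutate(start_contact = .data$contact_time,
               end_contact = .data$contact_time + .data$stride)
    } else {
      abort("cycles must carry start_contact/end_contact or contact_time/stride")
    }
  }
  L <- config$segment_lengths
  fr <- config$frame_rate
  frames <- purrr::map(seq_len(nrow(cycles)), function(i) {
    t0 <- cycles$start_contact[i]
    t1 <- cycles$end_contact[i]
    t <- seq(t0, t1 - 1 / (2 * fr), by = 1 / fr)
    u <- (t - t0) / (t1 - t0)
    prox <- config$proximal_mean +
      (config$proximal_excursion / 2) * cos(2 * pi * (u - 0.25))
    dist <- config$distal_mean +
      (config$distal_excursion / 2) * cos(2 * pi * (u - 0.25 -
                                                      config$intralimb_peak_offset))
    tibble(cycle = i, time = t, proximal_true = prox, distal_true = dist)
  }) %>% list_rbind()

  pr <- frames$proximal_true * pi / 180
  dr <- frames$distal_true * pi / 180
  crest <- cbind(0, 10 + numeric(nrow(frames)))
  hip <- cbind(crest[, 1], crest[, 2] - L[["crest_hip"]])
  a2 <- pi / 2 - pr                         # hip -> ankle direction
  ankle <- hip + L[["hip_ankle"]] * cbind(cos(a2), sin(a2))
  a3 <- a2 + pi - dr                        # ankle -> toe direction
  toe <- ankle + L[["ankle_toe"]] * cbind(cos(a3), sin(a3))

  cam1 <- frames %>%
    mutate(camera = 1L,
           crest_x = crest[, 1], crest_y = crest[, 2],
           hip_x = hip[, 1], hip_y = hip[, 2],
           ankle_x = ankle[, 1], ankle_y = ankle[, 2],
           toe_x = toe[, 1], toe_y = toe[, 2])
  cam2 <- with_preserved_seed(pass_seed(config$seed, 0L, 0L, 5L), {
    noisy <- function(v) v + rnorm(length(v), 0, config$camera_noise_sd)
    cam1 %>% mutate(camera = 2L,
                    across(c("crest_x", "crest_y", "hip_x", "hip_y",
                             "ankle_x", "ankle_y", "toe_x", "toe_y"), noisy))
  })
  bind_rows(cam1, cam2) %>%
    select("camera", "cycle", "time", dplyr::everything())
}

# ordinal open-field locomotor scores (inputs to the pipeline, generated here
# only so that summaries are testable without recordings)
simulate_bbb <- function(config,
                         control_timepoints = c("PD2", "PD3", "PostD2"),
                         dox_timepoints = c("D2D5", "D2D8", "D3D5", "D3D8",
                                            "D3D14"),
                         control_mean = 12, control_sd = 0.5,
                         dox_mean = 13.5, dox_sd = 1.8) {
  grid <- tidyr::expand_grid(
    animal = seq_len(config$n_animals),
    timepoint = c(control_timepoints, dox_timepoints),
    side = c("left", "right")
  ) %>%
    mutate(condition = dplyr::if_else(.data$timepoint %in% control_timepoints,
                                      "control", "silenced"))
  with_preserved_seed(pass_seed(config$seed, 0L, 0L, 3L), {
    grid %>%
      mutate(score = pmin(21, pmax(0, round(
        rnorm(dplyr::n(),
              dplyr::if_else(.data$condition == "control",
                             control_mean, dox_mean),
              dplyr::if_else(.data$condition == "control",
                             control_sd, dox_sd))))))
  })
}

# horizontal-ladder foot-slip counts: five trials in each direction
simulate_ladder <- function(config, control_mean = 8.5, dox_mean = 6.3,
                            slip_sd = 1.5, n_trials = 10L) {
  grid <- tidyr::expand_grid(
    animal = seq_len(config$n_animals),
    condition = c("control", "silenced"),
    limb = c("LH", "RH"),
    trial = seq_len(n_trials)
  )
  with_preserved_seed(pass_seed(config$seed, 0L, 0L, 4L), {
    grid %>%
      mutate(footfalls = pmax(0, round(
        rnorm(dplyr::n(),
              dplyr::if_else(.data$condition == "control",
                             control_mean, dox_mean), slip_sd))))
  })
}

#' Write a complete synthetic fixture set
#'
#' Simulates a cohort plus kinematic trajectories, BBB scores and ladder
#' foot-slip counts, and writes them as delimited-text tables in the
#' documented schemas, together with a JSON ground-truth ledger, a copy of
#' the configuration and a checksum manifest.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (`file`, `md5`, `bytes`).
#' @export
write_fixtures <- function(config, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", dir))
  }
  sim <- simulate_cohort(config)
  cyc <- sim$truth$steps %>%
    filter(.data$animal == 1, .data$pass_id == 1,
           .data$condition == config$conditions[1])
  traj <- simulate_joint_trajectories(config, cyc) %>%
    select(-"proximal_true", -"distal_true") %>%
    mutate(limb = "LH")
  bbb <- simulate_bbb(config)
  ladder <- simulate_ladder(config)

  paths <- c(
    footfalls = file.path(dir, "footfalls.csv"),
    trajectories = file.path(dir, "trajectories.csv"),
    bbb = file.path(dir, "bbb.csv"),
    ladder = file.path(dir, "ladder.csv")
  )
  write_gait_table(sim$events, paths[["footfalls"]], schema = "footfalls")
  write_gait_table(traj, paths[["trajectories"]], schema = "trajectories")
  write_gait_table(bbb, paths[["bbb"]], schema = "bbb")
  write_gait_table(ladder, paths[["ladder"]], schema = "ladder")

  ledger_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, ledger_path, digits = NA, pretty = TRUE)
  config_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(config), config_path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)

  files <- c(paths, ledger = ledger_path, config = config_path)
  manifest <- tibble(
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))),
    bytes = unname(file.size(unname(files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
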