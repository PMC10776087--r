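# Simulation configuration for the synthetic gait generator.

#' Configuration for the synthetic gait generator
#'
#' Builds a validated configuration for [simulate_pass()],
#' [simulate_cohort()], [simulate_joint_trajectories()] and
#' [write_fixtures()]. The defaults describe an overground locomotor
#' assessment of adult rats: four limbs stepping at ~50-100 cm/s, limb pairs
#' coupled through a von Mises phase distribution (alternation at 0.5 cycles
#' for the left-right pairs, synchrony at 0 for the heterolateral
#' hindlimb-forelimb pair) contaminated by a uniform "irregular" component,
#' stance time decaying exponentially with speed, and an optional probability
#' of dorsal paw placement on hindlimb steps.
#'
#' @param seed Integer seed; all draws derive from it hierarchically per
#'   animal/pass so adding animals never perturbs earlier animals.
#' @param n_animals,passes_per_animal,steps_per_pass Cohort dimensions. Each
#'   pass yields `steps_per_pass` lead-limb (left hindlimb) strides.
#' @param conditions Character vector of condition labels; each must have an
#'   entry in `pair_phase_kappa`, `p_irregular_uniform` and `p_dorsal`.
#' @param surface Walking-surface label attached to generated events
#'   (`"low_cof"` or `"high_cof"`).
#' @param speed_mean,speed_sd Per-step instantaneous speed distribution, cm/s.
#' @param stance_a,stance_b,stance_c Stance-time decay law
#'   `stance = a * exp(-b * speed) + c` in seconds (a, c) and per-(cm/s) (b).
#' @param stance_noise_sd Gaussian noise added to stance times, s.
#' @param swing_mean,swing_sd Swing-time distribution, s.
#' @param pair_phase_mu Named numeric of mean phases (cycles in `[0, 1)`) for
#'   the `hindlimb`, `forelimb`, `homolateral` and `heterolateral` pairs.
#' @param pair_phase_kappa Named numeric, von Mises concentration per
#'   condition.
#' @param p_irregular_uniform Named numeric, per-condition mixture weight of
#'   the uniform irregular phase component.
#' @param p_dorsal Named numeric, per-condition probability that a hindlimb
#'   step is dorsal.
#' @param track_width_mean,track_width_sd Rear track width distribution, cm.
#' @param placement_noise_sd Lateral paw-placement noise, cm.
#' @param forelimb_offset Longitudinal lead of the forelimbs over the
#'   hindlimbs, cm.
#' @param segment_lengths Named numeric of hindlimb segment lengths in cm:
#'   `crest_hip`, `hip_ankle`, `ankle_toe`.
#' @param frame_rate Kinematic sampling rate, Hz.
#' @param proximal_mean,proximal_excursion Mean and peak-to-trough excursion
#'   of the proximal (iliac crest - hip - ankle) angle, degrees.
#' @param distal_mean,distal_excursion Same for the distal
#'   (hip - ankle - toe) angle, degrees.
#' @param intralimb_peak_offset Lag of the distal peak behind the proximal
#'   peak, cycles.
#' @param camera_noise_sd Independent Gaussian marker noise of the second
#'   camera, cm.
#' @return A list of class `gait_sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_animals = 2)
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 8L,
                       passes_per_animal = 4L,
                       steps_per_pass = 8L,
                       conditions = c("control", "silenced"),
                       surface = "high_cof",
                       speed_mean = 67, speed_sd = 19,
                       stance_a = 0.3, stance_b = 0.02, stance_c = 0.05,
                       stance_noise_sd = 0,
                       swing_mean = 0.094, swing_sd = 0.008,
                       pair_phase_mu = c(hindlimb = 0.5, forelimb = 0.5,
                                         homolateral = 0.5, heterolateral = 0),
                       pair_phase_kappa = c(control = 50, silenced = 2),
                       p_irregular_uniform = c(control = 0.02, silenced = 0.10),
                       p_dorsal = c(control = 0, silenced = 0),
                       track_width_mean = 4.55, track_width_sd = 0.45,
                       placement_noise_sd = 0.15,
                       forelimb_offset = 8,
                       segment_lengths = c(crest_hip = 2.5, hip_ankle = 3.5,
                                           ankle_toe = 2.8),
                       frame_rate = 200,
                       proximal_mean = 110, proximal_excursion = 45,
                       distal_mean = 100, distal_excursion = 90,
                       intralimb_peak_offset = 0.12,
                       camera_noise_sd = 0) {
  cfg <- structure(
    list(seed = as.integer(seed), n_animals = as.integer(n_animals),
         passes_per_animal = as.integer(passes_per_animal),
         steps_per_pass = as.integer(steps_per_pass),
         conditions = conditions, surface = surface,
         speed_mean = speed_mean, speed_sd = speed_sd,
         stance_a = stance_a, stance_b = stance_b, stance_c = stance_c,
         stance_noise_sd = stance_noise_sd,
         swing_mean = swing_mean, swing_sd = swing_sd,
         pair_phase_mu = pair_phase_mu,
         pair_phase_kappa = pair_phase_kappa,
         p_irregular_uniform = p_irregular_uniform,
         p_dorsal = p_dorsal,
         track_width_mean = track_width_mean,
         track_width_sd = track_width_sd,
         placement_noise_sd = placement_noise_sd,
         forelimb_offset = forelimb_offset,
         segment_lengths = segment_lengths,
         frame_rate = frame_rate,
         proximal_mean = proximal_mean,
         proximal_excursion = proximal_excursion,
         distal_mean = distal_mean, distal_excursion = distal_excursion,
         intralimb_peak_offset = intralimb_peak_offset,
         camera_noise_sd = camera_noise_sd),
    class = "gait_sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[!(names(cfg) %in% c("conditions", "surface"))])
  if (any(!is.finite(num))) abort("all numeric configuration values must be finite")
  probs <- c(cfg$p_irregular_uniform, cfg$p_dorsal)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(cfg$pair_phase_kappa < 0)) abort("kappa must be >= 0")
  if (cfg$speed_mean <= 0) abort("speed_mean must be positive")
  if (cfg$stance_a < 0 || cfg$stance_c < 0) abort("stance decay a and c must be >= 0")
  if (cfg$frame_rate <= 0) abort("frame_rate must be positive")
  if (any(cfg$pair_phase_mu < 0 | cfg$pair_phase_mu >= 1)) {
    abort("pair phase means must lie in [0, 1)")
  }
  if (any(cfg$segment_lengths <= 0)) abort("segment lengths must be positive")
  need <- c("hindlimb", "forelimb", "homolateral", "heterolateral")
  if (!all(need %in% names(cfg$pair_phase_mu))) {
    abort("pair_phase_mu must name all four limb pairs")
  }
  for (fld in c("pair_phase_kappa", "p_irregular_uniform", "p_dorsal")) {
    if (!all(cfg$conditions %in% names(cfg[[fld]]))) {
      abort(paste0(fld, " must have an entry for every condition"))
    }
  }
  if (cfg$steps_per_pass < 2) abort("steps_per_pass must be at least 2")
  cfg
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat("Synthetic gait configuration\n")
  cat(sprintf("  %d animal(s) x %d pass(es) x %d step(s); conditions: %s\n",
              x$n_animals, x$passes_per_animal, x$steps_per_pass,
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  speed %.0f +/- %.0f cm/s; stance = %.3g exp(-%.3g v) + %.3g s\n",
              x$speed_mean, x$speed_sd, x$stance_a, x$stance_b, x$stance_c))
  cat(sprintf("  kappa: %s; uniform weight: %s; p(dorsal): %s\n",
              paste(names(x$pair_phase_kappa), x$pair_phase_kappa,
                    sep = "=", collapse = " "),
              paste(x$p_irregular_uniform, collapse = "/"),
              paste(x$p_dorsal, collapse = "/")))
  invisible(x)
}

# deterministic sub-seed for (animal, pass, condition): a fixed hash of the
# global seed so adding animals or passes never shifts other units' draws
pass_seed <- function(seed, animal, pass_id, condition_index = 1L) {
  h <- (as.double(seed) * 2654435761 + animal * 40503 +
          pass_id * 9973 + condition_index * 7919) %% 2147483647
  as.integer(h)
}
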