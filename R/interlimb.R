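# Interlimb phase: one phase value per lead-limb stride, the control-derived
# variability bounds, and the irregular-step classification.

PAIR_LEVELS <- c("hindlimb", "forelimb", "homolateral", "heterolateral")

# lead/trail limb conventions, relative to the left hindlimb for every pair
# that involves a hindlimb (the left forelimb leads the forelimb pair)
pair_limbs <- function(pair) {
  switch(pair,
    hindlimb = c(lead = "LH", trail = "RH"),
    forelimb = c(lead = "LF", trail = "RF"),
    homolateral = c(lead = "LH", trail = "LF"),
    heterolateral = c(lead = "LH", trail = "RF"),
    abort(paste0("unknown limb pair: ", pair))
  )
}

#' Compute limb-pair phase values
#'
#' For each lead-limb stride `[t_i, t_(i+1))`, the phase is the fraction of
#' the stride at which the trailing limb makes its initial contact:
#' `phi = (t* - t_i) / (t_(i+1) - t_i)` for the first trailing contact `t*`
#' inside the stride. Phase 0.5 is alternation; 0 (equivalently 1) is
#' synchrony. Lead cycles containing no trailing contact yield no point; at
#' most one point is produced per lead cycle (first trailing contact wins).
#' The dorsal flag is copied from the lead limb's initiating contact, so in
#' the left-hindlimb-lead convention it marks left-hindlimb dorsal steps.
#'
#' @param lead_cycles Step cycles of the lead limb ([build_step_cycles()]
#'   output filtered to one limb), ordered and non-overlapping.
#' @param trail_events Footfall events of the trailing limb, ordered by
#'   contact time.
#' @param pair Pair label: `"hindlimb"`, `"forelimb"`, `"homolateral"` or
#'   `"heterolateral"`.
#' @return A tibble with one row per phased lead cycle: identifier columns,
#'   `pair`, `cycle`, `phi`, `transformed_phase`, `dorsal`.
#' @export
compute_pair_phase <- function(lead_cycles, trail_events, pair) {
  limbs <- pair_limbs(pair)
  if (nrow(lead_cycles) == 0) {
    return(tibble(pair = character(), cycle = integer(), phi = numeric(),
                  transformed_phase = numeric(), dorsal = logical()))
  }
  if (any(lead_cycles$stride_time <= 0)) abort("zero-length lead stride")
  if (is.unsorted(lead_cycles$start_contact, strictly = TRUE)) {
    abort("lead cycles must be ordered and non-overlapping")
  }
  trail_t <- sort(trail_events$contact_time)
  id_cols <- intersect(c("animal", "timepoint", "condition", "pass_id",
                         "surface"), names(lead_cycles))

  # first trailing contact with start <= t* < end, via a findInterval sweep
  idx <- findInterval(lead_cycles$start_contact, trail_t,
                      left.open = TRUE) + 1L
  tstar <- ifelse(idx <= length(trail_t), trail_t[idx], NA_real_)
  # findInterval with left.open counts t < start strictly; a trailing contact
  # exactly at the lead contact (phase 0) is therefore picked up
  tstar[!is.na(tstar) & tstar >= lead_cycles$end_contact] <- NA_real_

  out <- lead_cycles %>%
    mutate(pair = pair,
           phi = (tstar - .data$start_contact) / .data$stride_time,
           dorsal = .data$placement == "dorsal") %>%
    filter(!is.na(.data$phi)) %>%
    mutate(transformed_phase = transform_phase(.data$phi)) %>%
    select(all_of(id_cols), "pair", "cycle", "phi", "transformed_phase",
           "dorsal")
  if (pair == "forelimb" && any(out$dorsal)) {
    abort("dorsal placements are not defined for the forelimb pair")
  }
  out
}

#' Transform a circular phase to the linear plotting scale
#'
#' Maps a phase in cycles onto `[0, 1)` by reduction mod 1: synchrony sits at
#' the 0/1 endpoints and alternation at 0.5, and the map is a bijection on
#' `[0, 1)`. This is the transformation used when circular phase data are
#' plotted on a linear axis.
#'
#' @param phi Numeric phases in cycles (any finite values).
#' @return Phases in `[0, 1)`.
#' @examples
#' transform_phase(c(0.5, 1, -0.25))
#' @export
transform_phase <- function(phi) {
  if (any(!is.finite(phi))) abort("phases must be finite")
  phi %% 1
}

#' Control-derived variability bounds for a limb pair
#'
#' Summarises control-timepoint phases into a center and spread; test steps
#' further than `2 * sd` from the center (wrap-aware) are classed irregular by
#' [classify_irregular()]. The default `"linear"` method takes the arithmetic
#' mean and SD of transformed phases, matching linear phase plots; the
#' `"circular"` method uses the circular mean direction and circular SD
#' (`sqrt(-2 log R) / (2 pi)` cycles).
#'
#' @param phases Control phases in cycles (at least 2).
#' @param pair Pair label recorded in the result.
#' @param method `"linear"` or `"circular"`.
#' @return A one-row tibble of class `gait_bounds`: `pair`, `method`,
#'   `center`, `sd`, `half_width` (= 2 sd), `lower`, `upper` (mod 1), `n`.
#' @examples
#' control_bounds(c(0.45, 0.50, 0.55), pair = "hindlimb")
#' @export
control_bounds <- function(phases, pair = "hindlimb",
                           method = c("linear", "circular")) {
  method <- match.arg(method)
  if (length(phases) < 2) abort("need at least 2 control phases")
  if (any(!is.finite(phases))) abort("phases must be finite")
  if (method == "linear") {
    p <- transform_phase(phases)
    center <- mean(p)
    s <- stats::sd(p)
  } else {
    cs <- circular_summary(phases)
    if (!cs$mean_defined) {
      abort("circular mean undefined: resultant length is zero")
    }
    center <- cs$mean_direction
    s <- cs$circular_sd
  }
  structure(
    tibble(pair = pair, method = method, center = center, sd = s,
           half_width = 2 * s,
           lower = (center - 2 * s) %% 1, upper = (center + 2 * s) %% 1,
           n = length(phases)),
    class = c("gait_bounds", class(tibble()))
  )
}

# shortest distance between two phases around the circle, cycles
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Classify irregular steps against control bounds
#'
#' A phase point is irregular when its wrap-aware distance to the control
#' center, `min(|d|, 1 - |d|)`, exceeds the bounds' half-width (2 control
#' SDs) — the criterion drawn as shaded "outside normal variability" boxes on
#' linear phase plots.
#'
#' @param points A phase tibble from [compute_pair_phase()] (needs `pair` and
#'   `transformed_phase`).
#' @param bounds A [control_bounds()] result for the same pair.
#' @return The `points` tibble with an added/overwritten logical `irregular`
#'   column, plus attributes; use [irregular_counts()] for the k/n summary.
#' @export
classify_irregular <- function(points, bounds) {
  stopifnot(is.data.frame(points), is.data.frame(bounds))
  if (nrow(bounds) != 1) abort("bounds must be a single row")
  if ("pair" %in% names(points) &&
      any(points$pair != bounds$pair)) {
    abort("pair mismatch between phase points and bounds")
  }
  mutate(points,
         irregular = circular_distance(.data$transformed_phase,
                                       bounds$center) > bounds$half_width)
}

#' Irregular-step count summary
#'
#' Summarises classified phase points into counts of irregular steps (k of n,
#' with percentage), optionally by grouping columns, in the shape consumed by
#' [two_proportion_z()].
#'
#' @param points Output of [classify_irregular()].
#' @param ... Grouping columns (tidy-eval), e.g. `timepoint, pair`.
#' @return A tibble with the grouping columns plus `k`, `n`, `percent`.
#' @export
irregular_counts <- function(points, ...) {
  points %>%
    group_by(...) %>%
    summarise(k = sum(.data$irregular), n = dplyr::n(),
              percent = 100 * .data$k / .data$n, .groups = "drop")
}

#' Join pair phases per lead stride
#'
#' One row per lead hindlimb cycle, with that cycle's available pair phases
#' side by side — the representation behind phase-versus-phase coupling
#' plots. Missing pairs are left `NA`, never imputed.
#'
#' @param points Phase points across pairs (must carry `pass_id`, `cycle`,
#'   `pair`, `transformed_phase`, and `animal`/`timepoint` if present).
#' @return A tibble with one row per (pass, lead cycle) and one phase column
#'   per pair (`hindlimb`, `forelimb`, `homolateral`, `heterolateral`).
#' @export
pair_coupling_table <- function(points) {
  key_cols <- intersect(c("animal", "timepoint", "condition", "surface",
                          "pass_id", "cycle"), names(points))
  if (!all(c("pass_id", "cycle") %in% key_cols)) {
    abort("phase points must carry pass and cycle indices")
  }
  dup <- points %>%
    count(across(all_of(c(key_cols, "pair")))) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate phase value for a (pass, cycle, pair) epoch")
  }
  points %>%
    select(all_of(key_cols), "pair", "transformed_phase") %>%
    tidyr::pivot_wider(names_from = "pair",
                       values_from = "transformed_phase") %>%
    arrange(across(all_of(key_cols)))
}
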