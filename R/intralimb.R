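# Intralimb coordination: the two-angle hindlimb model (proximal = iliac
# crest - hip - ankle, distal = hip - ankle - toe), per-cycle excursions, and
# the proximal-distal peak-timing phase.

# planar angle (degrees) at vertex B of the triple A-B-C
vertex_angle <- function(ax, ay, bx, by, cx, cy) {
  ux <- ax - bx
  uy <- ay - by
  vx <- cx - bx
  vy <- cy - by
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  bad <- which(nu == 0 | nv == 0)
  if (length(bad) > 0) {
    abort(paste0("coincident markers (zero-length segment) at frame ",
                 bad[1]))
  }
  acos(pmin(1, pmax(-1, (ux * vx + uy * vy) / (nu * nv)))) * 180 / pi
}

#' Compute proximal and distal joint angles from marker trajectories
#'
#' For every frame, the proximal angle is the planar angle at the hip between
#' the iliac crest and the ankle, and the distal angle the planar angle at
#' the ankle between the hip and the toe. When several cameras are present
#' the per-frame angles (not the coordinates) are averaged across cameras.
#'
#' @param trajectories A tibble of marker frames with columns `camera`,
#'   `time`, `crest_x`, `crest_y`, `hip_x`, `hip_y`, `ankle_x`, `ankle_y`,
#'   `toe_x`, `toe_y` (cm).
#' @return An angle-series tibble: `time`, `proximal`, `distal` (degrees).
#' @export
compute_joint_angles <- function(trajectories) {
  need <- c("camera", "time", "crest_x", "crest_y", "hip_x", "hip_y",
            "ankle_x", "ankle_y", "toe_x", "toe_y")
  missing_cols <- setdiff(need, names(trajectories))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectories are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- trajectories %>% count(.data$camera)
  if (length(unique(counts$n)) > 1) {
    abort("cameras report different frame counts")
  }
  per_cam <- trajectories %>%
    group_by(.data$camera) %>%
    arrange(.data$time, .by_group = TRUE) %>%
    mutate(
      frame = row_number(),
      proximal = vertex_angle(.data$crest_x, .data$crest_y,
                              .data$hip_x, .data$hip_y,
                              .data$ankle_x, .data$ankle_y),
      distal = vertex_angle(.data$hip_x, .data$hip_y,
                            .data$ankle_x, .data$ankle_y,
                            .data$toe_x, .data$toe_y)
    ) %>%
    ungroup()
  per_cam %>%
    group_by(.data$frame) %>%
    summarise(time = first(.data$time),
              proximal = mean(.data$proximal),
              distal = mean(.data$distal), .groups = "drop") %>%
    select("time", "proximal", "distal") %>%
    arrange(.data$time)
}

#' Per-cycle angle extrema and excursions
#'
#' Locates, for each step cycle window `[start_contact, end_contact)` and each
#' angle, the single maximum (peak extension) and minimum (peak flexion) — the
#' global extrema within the window, ties broken by the earliest frame — and
#' the excursion (max minus min).
#'
#' @param angles An angle series from [compute_joint_angles()].
#' @param cycles Step cycles with `start_contact` and `end_contact`.
#' @return A tibble with one row per cycle and angle: `cycle`, `angle`,
#'   `peak_time`, `peak_value`, `trough_time`, `trough_value`, `excursion`.
#' @export
find_peaks_troughs <- function(angles, cycles) {
  long <- angles %>%
    tidyr::pivot_longer(c("proximal", "distal"), names_to = "angle",
                        values_to = "value")
  purrr::map(seq_len(nrow(cycles)), function(i) {
    win <- long %>%
      filter(.data$time >= cycles$start_contact[i],
             .data$time < cycles$end_contact[i])
    if (nrow(win) < 6) {  # < 3 frames per angle
      abort(paste0("cycle window ", i, " contains fewer than 3 frames"))
    }
    win %>%
      group_by(.data$angle) %>%
      summarise(
        peak_time = .data$time[which.max(.data$value)],
        peak_value = max(.data$value),
        trough_time = .data$time[which.min(.data$value)],
        trough_value = min(.data$value),
        excursion = .data$peak_value - .data$trough_value,
        .groups = "drop"
      ) %>%
      mutate(cycle = i)
  }) %>%
    list_rbind() %>%
    select("cycle", "angle", "peak_time", "peak_value", "trough_time",
           "trough_value", "excursion")
}

#' Fold an intralimb phase onto the 0.5-1 scale
#'
#' Intralimb phases live on a circle where 0 and 1 both mean in-phase joint
#' motion; folding by `psi' = psi` if `psi >= 0.5` else `1 - psi` maps the
#' raw value onto `[0.5, 1]` so that in-phase coordination reads as 1 and
#' anti-phase as 0.5 on a contiguous linear scale. The fold is idempotent.
#'
#' @param psi Phases in cycles on `[0, 1)`.
#' @return Folded values in `[0.5, 1]`.
#' @examples
#' fold_intralimb(c(0, 0.1, 0.9))
#' @export
fold_intralimb <- function(psi) {
  psi <- psi %% 1
  ifelse(psi >= 0.5, psi, 1 - psi)
}

#' Proximal-distal intralimb phase per step cycle
#'
#' Within each step cycle the lead angle is whichever of the proximal or
#' distal angle peaks first. The phase is the delay of the other angle's peak
#' divided by the lead angle's peak-to-peak duration (to its peak in the next
#' cycle): `psi = (t_second - t_lead) / (t_lead_next - t_lead)`, reported both
#' raw and folded onto `[0.5, 1]` ([fold_intralimb()]), where 1 indicates
#' in-phase and 0.5 anti-phase joint coordination. The last cycle, which has
#' no following peak, and cycles without both peaks yield `NA` rows rather
#' than errors.
#'
#' @param angles An angle series from [compute_joint_angles()].
#' @param cycles Step cycles with `start_contact` and `end_contact`.
#' @return A tibble with one row per cycle: `cycle`, `lead_angle`, `psi`,
#'   `psi_folded`.
#' @export
intralimb_phase <- function(angles, cycles) {
  ext <- find_peaks_troughs(angles, cycles)
  peaks <- ext %>%
    select("cycle", "angle", "peak_time") %>%
    tidyr::pivot_wider(names_from = "angle", values_from = "peak_time")
  n <- nrow(peaks)
  purrr::map(seq_len(n), function(i) {
    p <- peaks$proximal[i]
    d <- peaks$distal[i]
    if (is.na(p) || is.na(d)) {
      return(tibble(cycle = i, lead_angle = NA_character_,
                    psi = NA_real_, psi_folded = NA_real_))
    }
    lead_angle <- if (p <= d) "proximal" else "distal"
    t_lead <- min(p, d)
    t_second <- max(p, d)
    t_lead_next <- if (i < n) {
      if (lead_angle == "proximal") peaks$proximal[i + 1] else peaks$distal[i + 1]
    } else NA_real_
    if (is.na(t_lead_next) || t_lead_next <= t_lead) {
      return(tibble(cycle = i, lead_angle = lead_angle,
                    psi = NA_real_, psi_folded = NA_real_))
    }
    psi <- (t_second - t_lead) / (t_lead_next - t_lead)
    tibble(cycle = i, lead_angle = lead_angle, psi = psi,
           psi_folded = fold_intralimb(psi))
  }) %>%
    list_rbind()
}
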