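# Postural stability metrics from paw-placement coordinates. X is the
# direction of travel, Y lateral, both in centimeters.

#' Gait angle from paw-placement geometry
#'
#' Angle indexing how far outside the line of travel a hindlimb is planted.
#' The default `"progression"` definition forms the right triangle whose legs
#' are the longitudinal and lateral separations between a reference hindlimb
#' contact `P1` and the intervening contralateral hindlimb contact `Q`:
#' `theta = atan2(|yQ - yP1|, |xQ - xP1|)` in degrees, 0 when the paws land
#' in line with travel and 90 when stacked laterally. The alternative
#' `"vertex"` definition returns the angle at `Q` of the triangle
#' `P1 - Q - P2` formed with the reference limb's next contact `P2`.
#'
#' @param p1 Reference hindlimb contact, numeric `c(x, y)`.
#' @param q Contralateral hindlimb contact between the two reference
#'   contacts, `c(x, y)`.
#' @param p2 Next contact of the reference hindlimb (required for the
#'   `"vertex"` definition).
#' @param definition `"progression"` (default) or `"vertex"`.
#' @return Angle in degrees.
#' @examples
#' gait_angle(c(0, 0), c(6.2, 4.5))
#' @export
gait_angle <- function(p1, q, p2 = NULL,
                       definition = c("progression", "vertex")) {
  definition <- match.arg(definition)
  if (definition == "progression") {
    dx <- abs(q[1] - p1[1])
    dy <- abs(q[2] - p1[2])
    if (dx == 0) {
      warn("zero longitudinal separation between contacts; gait angle is 90")
      return(90)
    }
    atan2(dy, dx) * 180 / pi
  } else {
    if (is.null(p2)) abort("the vertex definition requires p2")
    u <- p1 - q
    v <- p2 - q
    acos(min(1, max(-1, sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) *
      180 / pi
  }
}

#' Diagonal support length
#'
#' Euclidean distance between the initial contacts of a diagonal limb pair
#' within one step epoch (conventionally left hindlimb and right forelimb,
#' consistent with the left-hindlimb-lead phase convention).
#'
#' @param hind,fore Contact coordinates `c(x, y)` of the diagonal pair.
#' @return Distance in cm.
#' @examples
#' diagonal_length(c(0, 0), c(3, 4))
#' @export
diagonal_length <- function(hind, fore) {
  sqrt(sum((hind - fore)^2))
}

#' Rear track width
#'
#' Absolute lateral separation between a left hindlimb contact and the
#' subsequent right hindlimb contact: `|y_LH - y_RH|`.
#'
#' @param y_lh,y_rh Lateral (Y) coordinates of consecutive left and right
#'   hindlimb contacts, cm.
#' @return Width in cm.
#' @examples
#' rear_track_width(2.3, -2.25)
#' @export
rear_track_width <- function(y_lh, y_rh) {
  abs(y_lh - y_rh)
}

#' Per-pass postural stability metrics
#'
#' Computes the three paw-placement geometry metrics over the footfall events
#' of each pass: gait angles for each reference hindlimb (kept separate),
#' diagonal lengths between each left hindlimb contact and the nearest
#' following right forelimb contact, and rear track widths between each left
#' hindlimb contact and the subsequent right hindlimb contact.
#'
#' @param events Footfall events (one or more passes) with `limb`,
#'   `contact_time`, `x`, `y` and identifier columns.
#' @param definition Gait-angle definition, passed to [gait_angle()].
#' @return A tibble with one row per pass: mean `gait_angle_left`,
#'   `gait_angle_right` (degrees), `diagonal_length` and `rear_track_width`
#'   (cm), with `NA` where a pass lacks the needed contacts.
#' @export
posture_metrics <- function(events, definition = "progression") {
  id_cols <- intersect(c("animal", "timepoint", "condition", "pass_id",
                         "surface"), names(events))
  events %>%
    group_by(across(all_of(id_cols))) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$contact_time)
      lh <- filter(df, .data$limb == "LH")
      rh <- filter(df, .data$limb == "RH")
      rf <- filter(df, .data$limb == "RF")

      angle_for <- function(ref, other) {
        if (nrow(ref) < 2 || nrow(other) < 1) return(NA_real_)
        vals <- purrr::map_dbl(seq_len(nrow(ref) - 1), function(i) {
          between <- other %>%
            filter(.data$contact_time >= ref$contact_time[i],
                   .data$contact_time < ref$contact_time[i + 1])
          if (nrow(between) == 0) return(NA_real_)
          q <- c(between$x[1], between$y[1])
          suppressWarnings(gait_angle(
            c(ref$x[i], ref$y[i]), q,
            p2 = c(ref$x[i + 1], ref$y[i + 1]), definition = definition))
        })
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }

      diag_for <- function() {
        if (nrow(lh) < 1 || nrow(rf) < 1) return(NA_real_)
        vals <- purrr::map_dbl(seq_len(nrow(lh)), function(i) {
          nxt <- rf %>% filter(.data$contact_time >= lh$contact_time[i])
          if (nrow(nxt) == 0) return(NA_real_)
          diagonal_length(c(lh$x[i], lh$y[i]), c(nxt$x[1], nxt$y[1]))
        })
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }

      width_for <- function() {
        if (nrow(lh) < 1 || nrow(rh) < 1) return(NA_real_)
        vals <- purrr::map_dbl(seq_len(nrow(lh)), function(i) {
          nxt <- rh %>% filter(.data$contact_time >= lh$contact_time[i])
          if (nrow(nxt) == 0) return(NA_real_)
          rear_track_width(lh$y[i], nxt$y[1])
        })
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }

      tibble(
        gait_angle_left = angle_for(lh, rh),
        gait_angle_right = angle_for(rh, lh),
        diagonal_length = diag_for(),
        rear_track_width = width_for()
      )
    }) %>%
    ungroup()
}
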