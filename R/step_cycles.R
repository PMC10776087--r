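# Per-limb step cycles from footfall events, and pass-level speed.

#' Build per-limb step cycles from footfall events
#'
#' A step cycle (stride) runs from one initial contact of a limb to its next
#' initial contact. Stance is contact to lift-off, swing is lift-off to the
#' next contact, and the stride distance is the Euclidean displacement between
#' the two contacts' paw placements. The trailing incomplete cycle of each
#' limb is dropped, and a cycle inherits the placement (plantar/dorsal) of its
#' initiating contact. Cycles follow the half-open convention: a cycle owns
#' its starting contact, not its ending one.
#'
#' @param events Footfall events for one pass: a tibble with columns `limb`,
#'   `contact_time`, `liftoff_time`, `x`, `y`, `placement` (and any identifier
#'   columns such as `animal`, `timepoint`, `pass_id`, which are carried
#'   through from the initiating contact).
#' @return A tibble with one row per cycle: `limb`, `cycle`, `start_contact`,
#'   `end_contact`, `stance_time`, `swing_time`, `stride_time`,
#'   `stride_distance`, `stride_frequency`, `speed`, `duty_cycle`,
#'   `placement`.
#' @examples
#' ev <- tibble::tibble(limb = "LH", contact_time = c(0, 0.3),
#'                      liftoff_time = c(0.2, 0.5), x = c(0, 9), y = 0,
#'                      placement = "plantar")
#' build_step_cycles(ev)
#' @export
build_step_cycles <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("limb", "contact_time", "liftoff_time", "x", "y", "placement")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  id_cols <- intersect(c("animal", "timepoint", "condition", "pass_id",
                         "surface"), names(events))
  pass_label <- if ("pass_id" %in% names(events)) {
    paste(unique(events$pass_id), collapse = ",")
  } else "<unknown>"

  # contacts must arrive in temporal order within each limb of a pass
  order_check <- events %>%
    group_by(across(all_of(c(id_cols, "limb")))) %>%
    summarise(ok = !is.unsorted(.data$contact_time, strictly = TRUE),
              .groups = "drop")
  if (any(!order_check$ok)) {
    bad <- order_check$limb[!order_check$ok]
    abort(paste0("non-monotonic contact times for limb ",
                 paste(unique(bad), collapse = ", "),
                 " in pass ", pass_label))
  }

  events %>%
    group_by(across(all_of(c(id_cols, "limb")))) %>%
    arrange(.data$contact_time, .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      m <- nrow(df) - 1
      if (m < 1) {
        return(tibble(cycle = integer(), start_contact = double(),
                      end_contact = double(), stance_time = double(),
                      swing_time = double(), stride_time = double(),
                      stride_distance = double(), placement = character()))
      }
      start <- df$contact_time[seq_len(m)]
      end <- df$contact_time[seq_len(m) + 1]
      lift <- df$liftoff_time[seq_len(m)]
      if (any(is.finite(lift) & lift >= end)) {
        abort(paste0("lift-off at or after the next contact (overlapping ",
                     "stance) for limb ", key$limb, " in pass ", pass_label))
      }
      stance <- lift - start
      tibble(
        cycle = seq_len(m),
        start_contact = start, end_contact = end,
        stance_time = stance, swing_time = end - lift,
        stride_time = end - start,
        stride_distance = sqrt(diff(df$x)^2 + diff(df$y)^2),
        placement = df$placement[seq_len(m)]
      )
    }) %>%
    ungroup() %>%
    mutate(
      stride_frequency = 1 / .data$stride_time,
      speed = .data$stride_distance / .data$stride_time,
      duty_cycle = .data$stance_time / .data$stride_time
    ) %>%
    select(all_of(id_cols), "limb", "cycle", "start_contact", "end_contact",
           "stance_time", "swing_time", "stride_time", "stride_distance",
           "stride_frequency", "speed", "duty_cycle", "placement")
}

#' Pass-average instantaneous speed
#'
#' Mean of the per-cycle speeds (stride distance over stride time) across a
#' pass. Hindlimb cycles only by default, matching the convention that speed
#' summaries track the hindlimbs.
#'
#' @param cycles A step-cycle tibble from [build_step_cycles()].
#' @param limbs Limbs to include (default `c("LH", "RH")`; pass all four limb
#'   labels to average every cycle).
#' @return Mean speed in cm/s.
#' @export
pass_average_speed <- function(cycles, limbs = c("LH", "RH")) {
  cycles <- filter(cycles, .data$limb %in% limbs)
  if (nrow(cycles) == 0) abort("no cycles available to average")
  mean(cycles$speed)
}
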