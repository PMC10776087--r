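# Gross coordination indices: regularity index (RI), coordinated pattern
# index (CPI), plantar stepping index (PSI), dorsal stepping index (DSI) and
# dorsal sidedness, plus BBB-score and ladder foot-slip summaries.

#' Normal step-sequence pattern sets
#'
#' The four-limb placement orders treated as "normal" step sequences. Normal
#' rats express four such orders; the default set comprises the two alternate
#' and the two cruciate sequences from the footprint-analysis literature, and
#' the rotary pair is available via `include_rotary`. The choice is
#' configurable wherever patterns are consumed.
#'
#' @param include_rotary Also include the two rotary sequences.
#' @return A named list of character vectors of limb labels.
#' @export
normal_step_patterns <- function(include_rotary = FALSE) {
  pats <- list(
    alternate_a = c("RF", "LH", "LF", "RH"),
    alternate_b = c("LF", "RH", "RF", "LH"),
    cruciate_a = c("RF", "LF", "RH", "LH"),
    cruciate_b = c("LF", "RF", "LH", "RH")
  )
  if (include_rotary) {
    pats <- c(pats, list(rotary_a = c("RF", "LF", "LH", "RH"),
                         rotary_b = c("LF", "RF", "RH", "LH")))
  }
  pats
}

# greedy non-overlapping left-to-right matching with earliest-start priority:
# returns a logical vector marking placements that belong to a matched pattern
match_step_patterns <- function(limb_seq, patterns) {
  n <- length(limb_seq)
  matched <- logical(n)
  i <- 1L
  while (i <= n - 3L) {
    window <- limb_seq[i:(i + 3L)]
    hit <- any(vapply(patterns, function(p) all(window == p), logical(1)))
    if (hit) {
      matched[i:(i + 3L)] <- TRUE
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  matched
}

#' Regularity index
#'
#' Percentage of plantar paw placements that participate in a normal
#' step-sequence pattern: patterns are matched greedily, left to right and
#' non-overlapping, over the temporally ordered plantar placements of a pass,
#' and `RI = 100 * patterned placements / total plantar placements`.
#'
#' @param limb_seq Character vector of limb labels (`LF`, `RF`, `LH`, `RH`)
#'   for the plantar placements of one pass, in temporal order.
#' @param patterns Pattern set (default [normal_step_patterns()]).
#' @return A one-row tibble: `ri`, `n_patterned`, `n_total`.
#' @examples
#' regularity_index(rep(c("RF", "LH", "LF", "RH"), 3))
#' @export
regularity_index <- function(limb_seq, patterns = normal_step_patterns()) {
  if (length(limb_seq) == 0) abort("empty pass: no plantar placements")
  if (!all(limb_seq %in% LIMB_LEVELS)) {
    abort(paste0("unknown limb label(s): ",
                 paste(setdiff(limb_seq, LIMB_LEVELS), collapse = ", ")))
  }
  if (length(patterns) == 0) abort("pattern set must be non-empty")
  matched <- match_step_patterns(limb_seq, patterns)
  tibble(ri = 100 * sum(matched) / length(limb_seq),
         n_patterned = sum(matched), n_total = length(limb_seq))
}

#' Coordinated pattern index
#'
#' Like the regularity index but over all step cycles, dorsal and plantar
#' alike: `CPI = 100 * correctly patterned cycles / total cycles`. CPI
#' credits coordination regardless of the animal's ability to attain plantar
#' placement, so with dorsal steps present CPI can reach 100 while RI cannot.
#'
#' @param limb_seq Character vector of limb labels for all step cycles of a
#'   pass (plantar and dorsal), in temporal order.
#' @param patterns Pattern set (default [normal_step_patterns()]).
#' @return A one-row tibble: `cpi`, `n_patterned`, `n_total`.
#' @export
coordinated_pattern_index <- function(limb_seq,
                                      patterns = normal_step_patterns()) {
  res <- regularity_index(limb_seq, patterns)
  tibble(cpi = res$ri, n_patterned = res$n_patterned, n_total = res$n_total)
}

#' Plantar stepping index
#'
#' Hindlimb plantar steps as a percentage of forelimb plantar steps:
#' `PSI = 100 * HL plantar / FL plantar`. Not capped at 100.
#'
#' @param hl_plantar,fl_plantar Counts of hindlimb and forelimb plantar
#'   steps; `fl_plantar` must be positive.
#' @return PSI as a percentage.
#' @examples
#' plantar_stepping_index(40, 50)
#' @export
plantar_stepping_index <- function(hl_plantar, fl_plantar) {
  if (fl_plantar <= 0) abort("forelimb plantar count must be positive")
  if (hl_plantar < 0) abort("counts cannot be negative")
  100 * hl_plantar / fl_plantar
}

#' Dorsal stepping index
#'
#' Dorsal hindlimb steps as a percentage of all hindlimb steps:
#' `DSI = 100 * dorsal / total`. Zero in uninjured animals.
#'
#' @param dorsal,total Dorsal and total hindlimb step counts,
#'   `0 <= dorsal <= total`.
#' @return DSI as a percentage.
#' @export
dorsal_stepping_index <- function(dorsal, total) {
  if (dorsal < 0 || total < 0) abort("counts cannot be negative")
  if (dorsal > total) abort("dorsal steps cannot exceed total steps")
  if (total == 0) return(0)
  100 * dorsal / total
}

#' Dorsal step sidedness
#'
#' Splits the dorsal steps into the percentage occurring on the right and on
#' the left hindlimb; the two percentages sum to 100 whenever any dorsal
#' steps exist.
#'
#' @param right_dorsal,left_dorsal Dorsal step counts per hindlimb.
#' @return A one-row tibble `sidedness_right`, `sidedness_left` (percent), or
#'   `NA` values flagged `defined = FALSE` when there are no dorsal steps.
#' @export
dorsal_sidedness <- function(right_dorsal, left_dorsal) {
  if (right_dorsal < 0 || left_dorsal < 0) abort("counts cannot be negative")
  tot <- right_dorsal + left_dorsal
  if (tot == 0) {
    return(tibble(sidedness_right = NA_real_, sidedness_left = NA_real_,
                  defined = FALSE))
  }
  tibble(sidedness_right = 100 * right_dorsal / tot,
         sidedness_left = 100 * left_dorsal / tot, defined = TRUE)
}

#' Count BBB scores beyond control variability
#'
#' Counts test scores exceeding the range of the control scores. The default
#' rule flags scores strictly greater than the control maximum (the shaded
#' "beyond control variability" region of raw-score plots); the alternative
#' flags scores above the control mean + 2 SD. Returns counts in the shape
#' consumed by [two_proportion_z()].
#'
#' @param test_scores Numeric test scores (e.g. BBB, 0-21).
#' @param control_scores Numeric control scores defining the bound.
#' @param rule `"max"` (default) or `"mean_2sd"`.
#' @return A one-row tibble: `k` (beyond), `n` (total tests), `bound`,
#'   `percent`.
#' @export
bbb_beyond_control <- function(test_scores, control_scores,
                               rule = c("max", "mean_2sd")) {
  rule <- match.arg(rule)
  if (length(control_scores) == 0) abort("control score set is empty")
  bound <- switch(rule,
    max = max(control_scores),
    mean_2sd = mean(control_scores) + 2 * stats::sd(control_scores)
  )
  k <- sum(test_scores > bound)
  tibble(k = k, n = length(test_scores), bound = bound,
         percent = 100 * k / length(test_scores))
}

#' Summarise ladder foot-slip counts
#'
#' Per-animal, per-limb mean and SD of foot-slip (footfall) counts across
#' trials, within each condition. Left and right hindlimbs are never
#' combined. A single trial is reported with SD 0 and flagged by its `n`.
#'
#' @param records A tibble with columns `animal`, `condition` (or
#'   `timepoint`), `limb`, `trial`, `footfalls`.
#' @return A tibble with one row per animal/limb/condition: `mean_footfalls`,
#'   `sd_footfalls`, `n_trials`.
#' @export
ladder_summary <- function(records) {
  need <- c("animal", "limb", "footfalls")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("ladder records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$footfalls < 0)) abort("footfall counts cannot be negative")
  grp <- intersect(c("animal", "condition", "timepoint", "limb"),
                   names(records))
  records %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      mean_footfalls = mean(.data$footfalls),
      sd_footfalls = if (dplyr::n() > 1) stats::sd(.data$footfalls) else 0,
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Full coordination index report for one animal/timepoint
#'
#' Derives RI, CPI, PSI, DSI and dorsal sidedness from a step-cycle table
#' (cycles of all four limbs, with `placement` flags), keeping the underlying
#' counts so every index can be re-derived from the report.
#'
#' @param cycles Step cycles from [build_step_cycles()] for one
#'   animal/timepoint, with `limb`, `start_contact`, `placement` columns.
#' @param patterns Pattern set (default [normal_step_patterns()]).
#' @return A one-row tibble with the indices and their underlying counts.
#' @export
index_report <- function(cycles, patterns = normal_step_patterns()) {
  cycles <- arrange(cycles, .data$start_contact)
  hind <- filter(cycles, .data$limb %in% c("LH", "RH"))
  fore <- filter(cycles, .data$limb %in% c("LF", "RF"))
  plantar <- filter(cycles, .data$placement == "plantar")
  ri_res <- regularity_index(plantar$limb, patterns)
  cpi_res <- coordinated_pattern_index(cycles$limb, patterns)
  hl_plantar <- sum(hind$placement == "plantar")
  fl_plantar <- sum(fore$placement == "plantar")
  n_dorsal <- sum(hind$placement == "dorsal")
  side <- dorsal_sidedness(
    right_dorsal = sum(hind$placement == "dorsal" & hind$limb == "RH"),
    left_dorsal = sum(hind$placement == "dorsal" & hind$limb == "LH")
  )
  tibble(
    ri = ri_res$ri, ri_patterned = ri_res$n_patterned,
    ri_total = ri_res$n_total,
    cpi = cpi_res$cpi, cpi_patterned = cpi_res$n_patterned,
    cpi_total = cpi_res$n_total,
    psi = if (fl_plantar > 0) plantar_stepping_index(hl_plantar, fl_plantar)
          else NA_real_,
    hl_plantar = hl_plantar, fl_plantar = fl_plantar,
    dsi = dorsal_stepping_index(n_dorsal, nrow(hind)),
    n_dorsal = n_dorsal, n_hindlimb = nrow(hind),
    sidedness_right = side$sidedness_right,
    sidedness_left = side$sidedness_left
  )
}
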