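# End-to-end analysis: footfall events -> step cycles -> pair phases ->
# control bounds -> irregular classification -> proportion tests, indices,
# posture and speed fits, assembled into a single report object.

# phases of all four pairs for one pass, relative to the left hindlimb
pass_pair_phases <- function(cycles, events,
                             pairs = PAIR_LEVELS) {
  purrr::map(pairs, function(pair) {
    limbs <- pair_limbs(pair)
    lead_cycles <- filter(cycles, .data$limb == limbs[["lead"]])
    trail_ev <- filter(events, .data$limb == limbs[["trail"]])
    compute_pair_phase(lead_cycles, trail_ev, pair)
  }) %>% list_rbind()
}

#' Compute pair phases for a cohort of passes
#'
#' Builds step cycles per pass and derives the four limb-pair phase tables
#' (hindlimb, forelimb, homolateral, heterolateral), all relative to the
#' left-hindlimb lead convention.
#'
#' @param events Footfall events for one or more passes.
#' @param pairs Pairs to compute (default all four).
#' @return A list with `cycles` (step cycles) and `phases` (phase points).
#' @export
cohort_phases <- function(events, pairs = PAIR_LEVELS) {
  id_cols <- intersect(c("animal", "timepoint", "condition", "pass_id",
                         "surface"), names(events))
  split_keys <- events %>% distinct(across(all_of(id_cols)))
  parts <- purrr::map(seq_len(nrow(split_keys)), function(i) {
    key <- split_keys[i, ]
    ev <- dplyr::semi_join(events, key, by = id_cols)
    cyc <- build_step_cycles(ev)
    list(cycles = cyc, phases = pass_pair_phases(cyc, ev, pairs))
  })
  list(cycles = purrr::map(parts, "cycles") %>% list_rbind(),
       phases = purrr::map(parts, "phases") %>% list_rbind())
}

#' Run the full gait-analysis pipeline
#'
#' Orchestrates the complete analysis over a footfall table (plus optional
#' BBB and ladder tables): step cycles and spatiotemporal indices, limb-pair
#' phases, control-derived variability bounds and irregular-step
#' classification, per-timepoint irregular counts with two-proportion z tests
#' against the designated control, coordination indices, postural metrics and
#' speed-relationship fits.
#'
#' @param config A [run_config()]/[read_run_config()] object, or a named list
#'   coercible to one.
#' @param events Optional footfall tibble; when missing, read from
#'   `config$footfalls`.
#' @return An object of class `gait_report`: a list of tidy tables
#'   (`cycles`, `phases`, `bounds`, `irregular_counts`, `phase_tests`,
#'   `indices`, `posture`, `speed_fits`, `circular`, plus `bbb`/`ladder`
#'   summaries when inputs are given) and `provenance`.
#' @export
run_pipeline <- function(config, events = NULL) {
  if (!inherits(config, "gait_run_config")) config <- run_config(config)
  if (is.null(events)) {
    if (is.null(config$footfalls)) abort("no footfall events supplied")
    events <- read_footfalls(config$footfalls)
  }
  unknown_tp <- setdiff(unique(events$timepoint), names(config$condition_map))
  if (length(unknown_tp) > 0) {
    abort(paste0("timepoint(s) missing from condition_map: ",
                 paste(unknown_tp, collapse = ", ")))
  }
  events$condition <- unname(config$condition_map[events$timepoint])

  ph <- cohort_phases(events)
  cycles <- ph$cycles
  phases <- ph$phases

  control_phases <- filter(phases,
                           .data$timepoint %in% config$control_timepoints)
  if (nrow(control_phases) == 0) {
    abort("no phase points at the designated control timepoints")
  }
  bounds <- control_phases %>%
    group_by(.data$pair) %>%
    dplyr::group_modify(function(df, key) {
      control_bounds(df$transformed_phase, pair = key$pair,
                     method = config$bounds_method) %>%
        select(-"pair")
    }) %>%
    ungroup()

  phases <- phases %>%
    group_by(.data$pair) %>%
    dplyr::group_modify(function(df, key) {
      b <- filter(bounds, .data$pair == key$pair)
      classify_irregular(mutate(df, pair = key$pair), b) %>%
        select(-"pair")
    }) %>%
    ungroup() %>%
    select("pair", dplyr::everything())

  counts <- irregular_counts(phases, .data$pair, .data$timepoint,
                             .data$condition)

  control_counts <- counts %>%
    filter(.data$timepoint %in% config$control_timepoints) %>%
    group_by(.data$pair) %>%
    summarise(k = sum(.data$k), n = sum(.data$n), .groups = "drop")
  phase_tests <- counts %>%
    filter(!.data$timepoint %in% config$control_timepoints) %>%
    group_by(.data$pair, .data$timepoint) %>%
    dplyr::group_modify(function(df, key) {
      ctl <- filter(control_counts, .data$pair == key$pair)
      # both proportions at a boundary (e.g. zero irregular steps anywhere)
      # leaves nothing to standardise; report an NA row rather than abort
      tryCatch(
        tidy(two_proportion_z(ctl$k, ctl$n, df$k, df$n,
                              variant = config$z_variant)),
        error = function(e) {
          tibble(estimate = df$k / df$n - ctl$k / ctl$n,
                 statistic = NA_real_, p.value = NA_real_,
                 x1 = ctl$k, n1 = ctl$n, x2 = df$k, n2 = df$n,
                 variant = config$z_variant)
        })
    }) %>%
    ungroup()

  circular <- phases %>%
    group_by(.data$pair, .data$timepoint, .data$condition) %>%
    dplyr::group_modify(~ circular_summary(.x$phi)) %>%
    ungroup()

  patterns <- normal_step_patterns(config$include_rotary_patterns)
  indices <- cycles %>%
    group_by(.data$animal, .data$timepoint, .data$condition) %>%
    dplyr::group_modify(~ index_report(.x, patterns)) %>%
    ungroup()

  posture <- posture_metrics(events)

  hind_cycles <- filter(cycles, .data$limb %in% c("LH", "RH"))
  speed_fits <- purrr::imap(
    c(stance_time = "expdecay", stride_time = "expdecay",
      stride_distance = "linear", stride_frequency = "linear"),
    function(kind, metric) {
      fit_speed_relationship(hind_cycles, !!rlang::sym(metric), kind = kind)
    })

  report <- list(
    cycles = cycles, phases = phases, bounds = bounds,
    irregular_counts = counts, phase_tests = phase_tests,
    circular = circular, indices = indices, posture = posture,
    speed_fits = speed_fits,
    provenance = list(
      seed = config$seed,
      z_variant = config$z_variant,
      bounds_method = config$bounds_method,
      control_timepoints = config$control_timepoints,
      n_events = nrow(events),
      package_version = as.character(utils::packageVersion("gaitphase")),
      config_hash = unname(digest_config(config))
    )
  )
  if (!is.null(config$bbb)) {
    bbb <- read_scores(config$bbb, "bbb")
    bbb$condition <- unname(config$condition_map[bbb$timepoint])
    ctl <- bbb$score[bbb$timepoint %in% config$control_timepoints]
    tst <- bbb$score[!bbb$timepoint %in% config$control_timepoints]
    report$bbb <- list(scores = bbb,
                       beyond_control = bbb_beyond_control(tst, ctl))
  }
  if (!is.null(config$ladder)) {
    report$ladder <- ladder_summary(read_scores(config$ladder, "ladder"))
  }
  structure(report, class = "gait_report")
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), tmp)
  tools::md5sum(tmp)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("Gait analysis report\n")
  cat(sprintf("  %d step cycles, %d phase points across %d pair(s)\n",
              nrow(x$cycles), nrow(x$phases),
              length(unique(x$phases$pair))))
  cat(sprintf("  irregular steps: %s\n",
              paste(sprintf("%s %s %.1f%%", x$irregular_counts$pair,
                            x$irregular_counts$timepoint,
                            x$irregular_counts$percent), collapse = "; ")))
  invisible(x)
}

#' Write a gait report to disk
#'
#' Writes the report's tidy tables as CSV files and a JSON summary
#' (irregular counts, tests, indices, fits, provenance) into a directory.
#'
#' @param report A `gait_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create output directory: ", dir))
  paths <- character(0)
  for (nm in c("cycles", "phases", "bounds", "irregular_counts",
               "phase_tests", "circular", "indices", "posture")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(report[[nm]], p)
    paths <- c(paths, p)
  }
  summary <- list(
    irregular_counts = report$irregular_counts,
    phase_tests = report$phase_tests,
    speed_fits = purrr::imap(report$speed_fits, function(f, nm) {
      list(kind = f$kind, coefficients = as.list(f$coefficients),
           r_squared = f$r.squared, n = f$n)
    }),
    provenance = report$provenance
  )
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(summary, jp, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, jp))
}
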