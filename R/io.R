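# Delimited-text readers and writers for the documented table schemas, plus
# run-configuration handling. Files carry a one-line header and a leading
# `# units:` metadata comment; comma and tab dialects are both accepted.

SCHEMA_UNITS <- c(
  footfalls = "contact_time=s liftoff_time=s x=cm y=cm",
  trajectories = "time=s coordinates=cm",
  bbb = "score=BBB(0-21)",
  ladder = "footfalls=count"
)

SCHEMA_COLUMNS <- list(
  footfalls = c("animal", "timepoint", "pass_id", "limb", "contact_time",
                "liftoff_time", "x", "y", "placement"),
  trajectories = c("camera", "time", "crest_x", "crest_y", "hip_x", "hip_y",
                   "ankle_x", "ankle_y", "toe_x", "toe_y"),
  bbb = c("animal", "timepoint", "side", "score"),
  ladder = c("animal", "condition", "limb", "trial", "footfalls")
)

#' Write a gait table in the documented schema
#'
#' Writes a delimited-text table with a `# units:` metadata line followed by
#' a header row, the format produced by [write_fixtures()] and accepted by
#' the readers.
#'
#' @param df The table.
#' @param path Output path.
#' @param schema One of `"footfalls"`, `"trajectories"`, `"bbb"`, `"ladder"`.
#' @param delim Field delimiter (`","` default, `"\t"` accepted).
#' @return The path, invisibly.
#' @export
write_gait_table <- function(df, path, schema = names(SCHEMA_UNITS),
                             delim = ",") {
  schema <- match.arg(schema)
  missing_cols <- setdiff(SCHEMA_COLUMNS[[schema]], names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("cannot write ", schema, " table: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# units: ", SCHEMA_UNITS[[schema]]), con)
  readr::write_delim(df, con, delim = delim, na = "", eol = "\n")
  invisible(path)
}

read_gait_delim <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path, n_max = 25)
  first_data <- lines[!startsWith(lines, "#")][1]
  if (is.na(first_data)) abort(paste0("no data rows in ", path))
  delim <- if (grepl("\t", first_data)) "\t" else ","
  readr::read_delim(path, delim = delim, comment = "#",
                    show_col_types = FALSE, progress = FALSE)
}

check_columns <- function(df, schema, path) {
  missing_cols <- setdiff(SCHEMA_COLUMNS[[schema]], names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

row_error <- function(path, rows, msg) {
  abort(paste0(path, ": ", msg, " (row ", paste(head(rows, 5), collapse = ", "),
               if (length(rows) > 5) ", ..." else "", ")"))
}

#' Read a footfall event table
#'
#' Reads and validates a footfall table: one row per paw contact with
#' identifiers, limb label, contact/lift-off times (s), paw placement
#' coordinates (cm) and the plantar/dorsal flag. Dorsal placements are only
#' legal on hindlimbs; lift-off must follow contact. Validation failures name
#' the offending rows.
#'
#' @param path Path to a comma- or tab-delimited file with a header row and
#'   optional `#` metadata lines.
#' @return A validated tibble of footfall events.
#' @export
read_footfalls <- function(path) {
  df <- check_columns(read_gait_delim(path), "footfalls", path)
  bad <- which(!df$limb %in% LIMB_LEVELS)
  if (length(bad) > 0) row_error(path, bad, "unknown limb label")
  bad <- which(!df$placement %in% c("plantar", "dorsal"))
  if (length(bad) > 0) row_error(path, bad, "placement must be plantar or dorsal")
  bad <- which(df$placement == "dorsal" & !df$limb %in% c("LH", "RH"))
  if (length(bad) > 0) {
    row_error(path, bad, "dorsal placement on a forelimb")
  }
  bad <- which(!is.finite(df$contact_time))
  if (length(bad) > 0) row_error(path, bad, "non-finite contact time")
  bad <- which(is.finite(df$liftoff_time) &
                 df$liftoff_time <= df$contact_time)
  if (length(bad) > 0) row_error(path, bad, "lift-off not after contact")
  as_tibble(df)
}

#' Read a joint-marker trajectory table
#'
#' Reads per-frame 2D marker coordinates (iliac crest, hip, ankle, toe) for
#' one or more sagittal cameras.
#'
#' @param path Path to a delimited trajectory file.
#' @return A validated tibble of trajectory frames.
#' @export
read_trajectories <- function(path) {
  df <- check_columns(read_gait_delim(path), "trajectories", path)
  coords <- unlist(df[, c("crest_x", "crest_y", "hip_x", "hip_y",
                          "ankle_x", "ankle_y", "toe_x", "toe_y")])
  if (any(!is.finite(coords))) {
    row_error(path,
              which(!stats::complete.cases(
                df[, SCHEMA_COLUMNS$trajectories[-(1:2)]])),
              "non-finite marker coordinate")
  }
  as_tibble(df)
}

#' Read BBB score or ladder foot-slip tables
#'
#' @param path Path to a delimited score file.
#' @param type `"bbb"` (columns `animal`, `timepoint`, `side`, `score`) or
#'   `"ladder"` (columns `animal`, `condition`, `limb`, `trial`,
#'   `footfalls`).
#' @return A validated tibble.
#' @export
read_scores <- function(path, type = c("bbb", "ladder")) {
  type <- match.arg(type)
  df <- check_columns(read_gait_delim(path), type, path)
  if (type == "bbb") {
    bad <- which(df$score < 0 | df$score > 21 | df$score != round(df$score))
    if (length(bad) > 0) row_error(path, bad, "score must be an integer in 0-21")
    bad <- which(!df$side %in% c("left", "right"))
    if (length(bad) > 0) row_error(path, bad, "side must be left or right")
  } else {
    bad <- which(df$footfalls < 0)
    if (length(bad) > 0) row_error(path, bad, "negative footfall count")
    bad <- which(!df$limb %in% c("LH", "RH"))
    if (length(bad) > 0) row_error(path, bad, "ladder limb must be LH or RH")
  }
  as_tibble(df)
}

#' Read a run configuration (YAML or JSON)
#'
#' Loads an analysis run configuration mapping timepoints to conditions and
#' naming the control timepoints whose phases define the variability bounds.
#' Free-form timepoint labels are supported; only the mapping matters.
#'
#' Recognised fields: `footfalls` (path), `trajectories`, `bbb`, `ladder`
#' (optional paths), `condition_map` (named: timepoint -> condition label),
#' `control_timepoints` (character), `bounds_method` (`linear`/`circular`),
#' `z_variant` (`pooled`/`unpooled`), `include_rotary_patterns` (logical),
#' `out_dir` (optional), `seed` (integer).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `gait_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  run_config(raw, base_dir = dirname(path))
}

#' Build a run configuration from a list
#'
#' @param x Named list of configuration fields (see [read_run_config()]).
#' @param base_dir Directory against which relative paths are resolved.
#' @return A validated list of class `gait_run_config`.
#' @export
run_config <- function(x, base_dir = ".") {
  defaults <- list(
    footfalls = NULL, trajectories = NULL, bbb = NULL, ladder = NULL,
    condition_map = NULL, control_timepoints = NULL,
    bounds_method = "linear", z_variant = "pooled",
    include_rotary_patterns = FALSE, out_dir = NULL, seed = 1L
  )
  cfg <- modifyList(defaults, x[!vapply(x, is.null, logical(1))])
  if (is.null(cfg$condition_map) || is.null(names(cfg$condition_map))) {
    abort("config must provide a named condition_map (timepoint -> condition)")
  }
  cfg$condition_map <- unlist(cfg$condition_map)
  if (is.null(cfg$control_timepoints)) {
    abort("config must name the control timepoints for variability bounds")
  }
  missing_tp <- setdiff(cfg$control_timepoints, names(cfg$condition_map))
  if (length(missing_tp) > 0) {
    abort(paste0("control timepoint(s) absent from condition_map: ",
                 paste(missing_tp, collapse = ", ")))
  }
  if (!cfg$bounds_method %in% c("linear", "circular")) {
    abort("bounds_method must be 'linear' or 'circular'")
  }
  if (!cfg$z_variant %in% c("pooled", "unpooled")) {
    abort("z_variant must be 'pooled' or 'unpooled'")
  }
  for (fld in c("footfalls", "trajectories", "bbb", "ladder")) {
    if (!is.null(cfg[[fld]]) && !file.exists(cfg[[fld]])) {
      candidate <- file.path(base_dir, cfg[[fld]])
      if (file.exists(candidate)) cfg[[fld]] <- candidate
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "gait_run_config")
}

#' Printed figure-caption count table
#'
#' The irregular-step and beyond-control-variability count table transcribed
#' from published figure captions of the locomotor study this package
#' re-implements, with the printed z statistic, the printed precision and the
#' variance variant under which each value reproduces. Used to validate
#' [two_proportion_z()] against printed results.
#'
#' @return A tibble with columns `comparison`, `x1`, `n1`, `x2`, `n2`,
#'   `variant`, `z_printed`, `digits`.
#' @export
ldpn_count_table <- function() {
  path <- system.file("extdata", "ldpn_phase_counts.csv",
                      package = "gaitphase", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
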