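# Plain-text table formats for every stage. All tables are CSV/TSV with a
# header; time-series files additionally accept xvg-style comment lines
# starting with '#' or '@'. Units travel with the data (a mandatory `unit`
# column for transition times) so no conversion ever happens silently.

#' Read censored transition outcomes from CSV
#'
#' Expected header: `trajectory_id, observed, event_time, total_time, unit`.
#' `observed` rows must carry an `event_time`; censored rows must not.
#' Duplicated trajectory ids produce a warning but rows are kept.
#'
#' @param path CSV file path.
#' @return A [transition_data()] tibble.
#' @export
read_transitions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    abort(sprintf("'%s' contains no transition records.", path),
          class = "mdinfer_input_error")
  }
  req <- c("trajectory_id", "observed", "event_time", "total_time", "unit")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(sprintf("'%s' is missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "mdinfer_input_error")
  }
  obs <- as.logical(df$observed)
  bad <- which(obs & is.na(df$event_time))
  if (length(bad)) {
    abort(sprintf(
      "'%s': observed rows without event_time (rows %s).",
      path, paste(bad, collapse = ", ")), class = "mdinfer_input_error")
  }
  bad <- which(obs & df$event_time > df$total_time)
  if (length(bad)) {
    abort(sprintf(
      "'%s': event_time exceeds total_time (rows %s).",
      path, paste(bad, collapse = ", ")), class = "mdinfer_input_error")
  }
  if (anyDuplicated(df$trajectory_id)) {
    warn(sprintf("'%s': duplicated trajectory_id values; rows kept.", path))
  }
  units <- unique(df$unit)
  if (length(units) != 1L) {
    abort(sprintf("'%s': mixed time units (%s); convert first.", path,
                  paste(units, collapse = ", ")),
          class = "mdinfer_input_error")
  }
  et <- ifelse(obs, df$event_time, NA_real_)
  out <- transition_data(obs, et, df$total_time, unit = units)
  out$trajectory_id <- df$trajectory_id
  out
}

#' Write transition outcomes to CSV
#' @param data A [transition_data()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(data, path) {
  data <- validate_transitions(data)
  out <- tibble(
    trajectory_id = data$trajectory_id,
    observed = data$observed,
    event_time = data$event_time,
    total_time = data$total_time,
    unit = time_unit(data)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read forward/reverse work values from CSV
#'
#' Two columns: `direction` (`forward`/`reverse`) and `work` (kJ/mol).
#'
#' @param path CSV file path.
#' @param temperature Temperature in kelvin attached to the work set.
#' @return A [work_set()].
#' @export
read_works <- function(path, temperature = 298) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("direction", "work") %in% names(df))) {
    abort(sprintf("'%s' needs columns direction, work.", path),
          class = "mdinfer_input_error")
  }
  bad <- setdiff(unique(df$direction), c("forward", "reverse"))
  if (length(bad)) {
    abort(sprintf("'%s': unknown direction values: %s", path,
                  paste(bad, collapse = ", ")),
          class = "mdinfer_input_error")
  }
  work_set(df$work[df$direction == "forward"],
           df$work[df$direction == "reverse"],
           temperature = temperature)
}

#' Write a work set to CSV
#' @param works A [work_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_works <- function(works, path) {
  readr::write_csv(as_tibble(works)[, c("direction", "work")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a two-column time series (xvg-style)
#'
#' Whitespace-separated `time value` rows; lines starting with `#` or `@`
#' are ignored, matching common simulation-analysis exports.
#'
#' @param path File path.
#' @return Tibble `time`, `value`.
#' @export
read_series <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    abort(sprintf("'%s' contains no data rows.", path),
          class = "mdinfer_input_error")
  }
  con <- textConnection(lines[keep])
  on.exit(close(con))
  df <- utils::read.table(con, col.names = c("time", "value"))
  as_tibble(df)
}

#' Write a two-column time series
#' @param series Tibble with `time` and `value` columns (or a numeric
#'   vector, in which case `time` is the 0-based index).
#' @param path Output path.
#' @param comment Optional comment line written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, comment = NULL) {
  if (is.numeric(series)) {
    series <- tibble(time = seq_along(series) - 1, value = series)
  }
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, paste(series$time, series$value))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read umbrella windows via a manifest
#'
#' The manifest is a CSV with columns `file`, `center`, `force_constant`
#' and optionally `discard_fraction`; `file` paths are resolved relative
#' to the manifest location. Each window file is a `time value` series
#' ([read_series()]).
#'
#' @param manifest_path Path to the manifest CSV.
#' @return List of [umbrella_window()] objects.
#' @export
read_windows <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  req <- c("file", "center", "force_constant")
  if (!all(req %in% names(man))) {
    abort(sprintf("'%s' needs columns file, center, force_constant.",
                  manifest_path), class = "mdinfer_input_error")
  }
  base <- dirname(manifest_path)
  purrr::pmap(man, function(file, center, force_constant, ...) {
    extra <- list(...)
    s <- read_series(file.path(base, file))
    umbrella_window(s$value, center = center,
                    force_constant = force_constant,
                    discard_fraction = extra$discard_fraction %||% 0)
  })
}

#' Write umbrella windows and their manifest
#' @param windows List of [umbrella_window()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_windows <- function(windows, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("window_%02d.tsv", seq_along(windows))
  purrr::walk2(windows, files, function(w, f) {
    write_series(tibble(time = seq_along(w$samples) - 1,
                        value = w$samples),
                 file.path(dir, f),
                 comment = sprintf("center %g force_constant %g",
                                   w$center, w$force_constant))
  })
  man <- tibble(
    file = files,
    center = purrr::map_dbl(windows, "center"),
    force_constant = purrr::map_dbl(windows, "force_constant"),
    discard_fraction = purrr::map_dbl(windows, "discard_fraction")
  )
  mp <- file.path(dir, "windows.csv")
  readr::write_csv(man, mp, progress = FALSE)
  invisible(mp)
}

#' Read particle positions from CSV
#'
#' Columns `frame, particle, x, y, z` and optionally unwrapped
#' `xu, yu, zu`.
#'
#' @param path CSV path.
#' @param l_box,dt Optional box edge and frame time attached as attributes.
#' @return Tibble of positions.
#' @export
read_positions <- function(path, l_box = NULL, dt = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("frame", "particle")
  if (!all(req %in% names(df)) ||
      !(all(c("x", "y", "z") %in% names(df)) ||
        all(c("xu", "yu", "zu") %in% names(df)))) {
    abort(sprintf("'%s' needs frame, particle and x/y/z (or xu/yu/zu).",
                  path), class = "mdinfer_input_error")
  }
  attr(df, "l_box") <- l_box
  attr(df, "dt") <- dt
  df
}

#' Write particle positions to CSV
#' @param positions Tibble of positions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  readr::write_csv(as_tibble(positions), path, progress = FALSE)
  invisible(path)
}

#' Read replicate estimates from CSV
#' @param path CSV with a `value` column.
#' @return Numeric vector.
#' @export
read_replicates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"value" %in% names(df)) {
    abort(sprintf("'%s' needs a `value` column.", path),
          class = "mdinfer_input_error")
  }
  df$value
}
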