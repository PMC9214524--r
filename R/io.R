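#' Read a trajectory table
#'
#' Reads a delimited-text trajectory table (comma-separated, header row)
#' with required columns `droplet_id, t, x, y`, optional `z` (3D) and
#' orientation columns `nx, ny[, nz]`.  Rows are sorted by
#' `(droplet_id, t)`; duplicate timestamps within a droplet are rejected
#' with the offending line numbers.
#'
#' @param path File path.
#' @return A data frame of class `"capp_trajectory"`.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("droplet_id", "t", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  ord <- order(df$droplet_id, df$t)
  lines_orig <- seq_len(nrow(df)) + 1L  # header is line 1
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("droplet_id", "t")])
  if (any(dup)) {
    stop(sprintf("'%s': duplicate timestamp for droplet %s at line %d",
                 path, df$droplet_id[dup][1L], lines_orig[ord][dup][1L]))
  }
  rownames(df) <- NULL
  class(df) <- c("capp_trajectory", "data.frame")
  df
}

# full-precision numeric formatting so that read(write(x)) is exact
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a trajectory table
#'
#' Comma-separated with header; doubles are written with 17 significant
#' digits so a read-back reproduces them exactly.
#'
#' @param trajectories Trajectory data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- as.data.frame(trajectories)
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an event table
#'
#' One row per interaction event: ids, incidence angle, time lag, outcome,
#' maximum turn rate.  An empty event list produces a header-only file.
#'
#' @param events List of `"interaction_event"` objects or an
#'   [events_table()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- if (is.data.frame(events)) events else events_table(events)
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path File path written by [write_events()].
#' @return Data frame with one row per event.
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an MSD curve
#'
#' Writes the lag/MSD/exponent table with the detected crossovers and
#' plateau as constant columns; absent regimes are written as `NA`.
#'
#' @param curve An [ensemble_msd()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msd <- function(curve, path) {
  cg <- detect_caging(curve)
  df <- as.data.frame(curve)
  df$crossover_to_caging <- cg$crossover_to_caging
  df$crossover_to_escape <- cg$crossover_to_escape
  df$plateau_height <- cg$plateau_height
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MSD curve
#'
#' @param path File path written by [write_msd()].
#' @return A data frame of class `"msd_curve"`.
#' @export
read_msd <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- df[, c("lag", "msd", "exponent")]
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Write a profile series in long format
#'
#' @param ps A [profile_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(ps, path) {
  utils::write.csv(format_full(as.data.frame(ps)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile series from a long-format file
#'
#' @param path File with columns `t, x, intensity`.
#' @return A [profile_series()].
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t", "x", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  profile_series(df)
}
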