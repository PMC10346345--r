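# Delimited-file I/O: motion/force time series, cycle-level feature tables,
# and whole-session fixtures (BrainVision EEG + TSV kinematics + JSON ground
# truth).

#' Read a uniformly sampled time series from a delimited file
#'
#' @param path file path; tab- or comma-delimited with a header row.
#' @param time_col,value_col column names holding time (s) and signal values.
#' @param side,kind passed to [motion_series()].
#' @param sep field separator; `NULL` picks TSV for `.tsv` files and comma
#'   otherwise.
#' @return A [motion_series()].
#' @export
read_timeseries_tsv <- function(path, time_col = "time", value_col = "value",
                                side = "right", kind = "marker", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE)
  for (col in c(time_col, value_col)) {
    if (!col %in% names(df)) stop("missing column: ", col)
  }
  motion_series(df[[time_col]], df[[value_col]], side = side, kind = kind)
}

#' Write a motion series to a TSV file
#'
#' @param series a [motion_series()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_timeseries_tsv <- function(series, path) {
  stopifnot(inherits(series, "motion_series"))
  df <- data.frame(time = series$time, value = series$values)
  write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cycle-level feature table to TSV
#'
#' One row per gait cycle; the metadata columns `subject`, `condition` and
#' `cycle_index` come first, followed by the `<channel>__<feature>` columns.
#' Values are written with 12 significant digits so that the round-trip
#' through [read_feature_table()] is lossless at that precision.
#'
#' @param table data frame as produced by [build_feature_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("duplicate column names")
  out <- table
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("subject", "cycle_index")
  for (j in which(num)) {
    out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cycle-level feature table from TSV
#'
#' @param path file written by [write_feature_table()].
#' @return A data frame with metadata columns and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  df
}

#' Write a synthetic session to disk
#'
#' Writes the EEG as a BrainVision triplet, heel-marker and GRF series as
#' TSV files, and the ground truth (true heel-strike times, condition,
#' artifact log) as a JSON sidecar.
#'
#' @param session a `gait_session` from [generate_session()].
#' @param dir output directory (created if needed).
#' @param basename file stem; defaults to `subject<ID>_<condition>`.
#' @return Invisibly, the list of written paths.
#' @export
write_session <- function(session, dir, basename = NULL) {
  stopifnot(inherits(session, "gait_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(basename)) {
    basename <- sprintf("subject%02d_%s", session$subject_id,
                        session$condition)
  }
  stem <- file.path(dir, basename)
  paths <- list(vhdr = paste0(stem, ".vhdr"))
  write_brainvision(session$eeg, stem)
  for (nm in c("heel_z_left", "heel_z_right", "grf_left", "grf_right")) {
    p <- paste0(stem, "_", nm, ".tsv")
    write_timeseries_tsv(session[[nm]], p)
    paths[[nm]] <- p
  }
  gt <- list(subject_id = session$subject_id, condition = session$condition,
             true_events = session$true_events,
             artifact_log = session$artifact_log)
  paths$json <- paste0(stem, "_truth.json")
  jsonlite::write_json(gt, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic session written by [write_session()]
#'
#' @param dir directory holding the files.
#' @param basename file stem used when writing.
#' @return A `gait_session`.
#' @export
read_session <- function(dir, basename) {
  stem <- file.path(dir, basename)
  eeg <- read_brainvision(paste0(stem, ".vhdr"))
  gt <- jsonlite::read_json(paste0(stem, "_truth.json"),
                            simplifyVector = TRUE)
  out <- list(
    eeg = eeg,
    heel_z_left = read_timeseries_tsv(paste0(stem, "_heel_z_left.tsv"),
                                      side = "left", kind = "marker"),
    heel_z_right = read_timeseries_tsv(paste0(stem, "_heel_z_right.tsv"),
                                       side = "right", kind = "marker"),
    grf_left = read_timeseries_tsv(paste0(stem, "_grf_left.tsv"),
                                   side = "left", kind = "force"),
    grf_right = read_timeseries_tsv(paste0(stem, "_grf_right.tsv"),
                                    side = "right", kind = "force"),
    true_events = gt$true_events, condition = gt$condition,
    subject_id = gt$subject_id, artifact_log = gt$artifact_log)
  class(out) <- "gait_session"
  out
}
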