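## File formats: IMU CSV (t,ax,ay,az,gx,gy,gz), annotations JSON, scores JSON.

#' Construct an IMU recording
#'
#' @param data Data frame with columns `t` (s), `ax, ay, az` (m/s^2),
#'   `gx, gy, gz` (rad/s), uniformly sampled.
#' @param site `"wrist"` or `"sternum"`.
#' @param fs Sample rate (Hz); checked against `t`.
#' @return A tibble of class `imu_recording` with attributes `site` and `fs`.
#' @export
imu_recording <- function(data, site = c("wrist", "sternum"), fs = NULL) {
  site <- match.arg(site)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(data))) {
    stop("IMU data must have columns ", paste(need, collapse = ", "))
  }
  data <- tibble::as_tibble(data)[need]
  if (!all(is.finite(as.matrix(data)))) stop("IMU data must be finite")
  dt <- diff(data$t)
  if (length(dt) > 0L) {
    if (any(dt <= 0)) stop("`t` must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6) stop("sampling must be uniform (within 1e-6 s)")
    fs_obs <- 1 / stats::median(dt)
    if (is.null(fs)) fs <- fs_obs
    if (abs(fs - fs_obs) > 1e-3 * fs) stop("`fs` inconsistent with time stamps")
  }
  structure(data, site = site, fs = fs,
            class = c("imu_recording", class(data)))
}

imu_fs <- function(rec) attr(rec, "fs")
imu_site <- function(rec) attr(rec, "site")

#' Read / write an IMU stream as CSV
#'
#' Columns `t,ax,ay,az,gx,gy,gz` in s, m/s^2 and rad/s, with a header row.
#'
#' @param rec An [imu_recording()].
#' @param path File path.
#' @param site,fs Passed to [imu_recording()] when reading.
#' @return `write_imu_csv` returns `path` invisibly; `read_imu_csv` an
#'   `imu_recording`.
#' @export
write_imu_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, site = "wrist", fs = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  imu_recording(df, site = site, fs = fs)
}

#' Read / write linear-movement annotations as JSON
#'
#' A JSON array of objects `{"start_s": ..., "end_s": ..., "kind": "linear"}`.
#'
#' @param intervals Tibble with `start_s`, `end_s`, `kind`.
#' @param path File path.
#' @return `write_annotations_json` returns `path` invisibly;
#'   `read_annotations_json` a tibble.
#' @export
write_annotations_json <- function(intervals, path) {
  jsonlite::write_json(intervals, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_annotations_json
#' @export
read_annotations_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(), kind = character()))
  }
  tibble::as_tibble(df)
}

#' Read / write clinical scores as JSON
#'
#' Keys `fma_ue, wmft_pt_median, wmft_fas, mal_aou, mal_qom`; synthetic
#' records additionally carry `theta`.
#'
#' @param scores Named list of scores.
#' @param path File path.
#' @param theta Optional ground-truth impairment to include.
#' @return `write_scores_json` returns `path` invisibly; `read_scores_json`
#'   a named list.
#' @export
write_scores_json <- function(scores, path, theta = NULL) {
  x <- scores
  if (!is.null(theta)) x$theta <- theta
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scores_json
#' @export
read_scores_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write one subject's files into a directory
#'
#' Emits `wrist.csv`, `sternum.csv`, `annotations.json`, `scores.json`.
#'
#' @param record A `subject_record`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_subject <- function(record, dir) {
  stopifnot(inherits(record, "subject_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_imu_csv(record$wrist, file.path(dir, "wrist.csv"))
  write_imu_csv(record$sternum, file.path(dir, "sternum.csv"))
  write_annotations_json(record$linear_intervals, file.path(dir, "annotations.json"))
  write_scores_json(record$scores, file.path(dir, "scores.json"), theta = record$theta)
  invisible(dir)
}

#' Read one subject's files from a directory
#'
#' @param dir Directory written by [write_subject()].
#' @param subject_id Id to attach (defaults to the directory name).
#' @return A `subject_record` (without generator truth).
#' @export
read_subject <- function(dir, subject_id = basename(dir)) {
  wrist <- read_imu_csv(file.path(dir, "wrist.csv"), site = "wrist")
  sternum <- read_imu_csv(file.path(dir, "sternum.csv"), site = "sternum")
  scores <- read_scores_json(file.path(dir, "scores.json"))
  theta <- scores$theta
  scores$theta <- NULL
  structure(list(
    subject_id = subject_id,
    wrist = wrist, sternum = sternum,
    linear_intervals = read_annotations_json(file.path(dir, "annotations.json")),
    scores = scores, theta = theta,
    fs = imu_fs(wrist), duration_s = max(wrist$t),
    spec = NULL, truth = NULL
  ), class = "subject_record")
}
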