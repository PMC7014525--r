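#' Construct an IMU recording
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `t` (seconds), `ax`, `ay`, `az` (acceleration, g) and `gx`, `gy`, `gz`
#' (angular rate, deg/s), plus a `sample_rate_hz` attribute and free-form
#' `meta` annotations (horse id, session, condition). The z axis is the
#' dorso-ventral axis of the horse; gravity at rest reads +1 g on `az`.
#'
#' @param accel data frame or matrix with columns/channels `ax`, `ay`, `az`
#'   in g.
#' @param gyro data frame or matrix with columns `gx`, `gy`, `gz` in deg/s.
#' @param sample_rate_hz sampling rate in Hz (nominally 100).
#' @param meta named list of free-form annotations.
#' @return an `imu_recording` tibble.
#' @export
imu_recording <- function(accel, gyro, sample_rate_hz = 100, meta = list()) {
  accel <- as.data.frame(accel)
  gyro <- as.data.frame(gyro)
  if (!all(c("ax", "ay", "az") %in% names(accel))) {
    names(accel) <- c("ax", "ay", "az")[seq_along(accel)]
  }
  if (!all(c("gx", "gy", "gz") %in% names(gyro))) {
    names(gyro) <- c("gx", "gy", "gz")[seq_along(gyro)]
  }
  stopifnot(
    ncol(accel) == 3, ncol(gyro) == 3,
    nrow(accel) == nrow(gyro), nrow(accel) >= 1
  )
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  n <- nrow(accel)
  rec <- tibble::tibble(
    t = (seq_len(n) - 1) / sample_rate_hz,
    ax = accel$ax, ay = accel$ay, az = accel$az,
    gx = gyro$gx, gy = gyro$gy, gz = gyro$gz
  )
  new_imu_recording(rec, sample_rate_hz, meta)
}

new_imu_recording <- function(df, sample_rate_hz, meta = list()) {
  structure(
    df,
    sample_rate_hz = as.numeric(sample_rate_hz),
    meta = meta,
    class = c("imu_recording", class(tibble::tibble()))
  )
}

#' Sampling rate of a recording
#' @param rec an `imu_recording`.
#' @return sampling rate in Hz.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate_hz")

imu_channels <- c("ax", "ay", "az", "gx", "gy", "gz")
recording_cols <- c("t", imu_channels)

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz (%.2f s)\n",
    nrow(x), sample_rate(x), nrow(x) / sample_rate(x)
  ))
  NextMethod()
}

#' Read an IMU recording from CSV
#'
#' The dialect is comma-separated with a dot decimal mark, one header line
#' `t,ax,ay,az,gx,gy,gz` (seconds, g, deg/s), preceded by optional
#' `# key=value` comment lines; `# sample_rate_hz=100` carries the sampling
#' rate. When absent, the rate is inferred from the time column. Timestamps
#' must be strictly increasing and uniform to within 10% of the nominal
#' sample period.
#'
#' @param path path to a recording CSV.
#' @return an `imu_recording`.
#' @export
read_imu_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty recording file: ", path, call. = FALSE)
  }
  meta <- parse_meta_comments(lines)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(recording_cols, names(df))
  if (length(missing) > 0) {
    stop("recording CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("recording has no samples: ", path, call. = FALSE)
  rate <- if (!is.null(meta$sample_rate_hz)) {
    as.numeric(meta$sample_rate_hz)
  } else {
    infer_sample_rate(df$t)
  }
  check_uniform_time(df$t, rate)
  meta$sample_rate_hz <- NULL
  new_imu_recording(
    tibble::as_tibble(df[recording_cols]), rate, meta
  )
}

parse_meta_comments <- function(lines) {
  com <- grep("^#", lines, value = TRUE)
  kv <- regmatches(
    com,
    regexec("^#[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", com)
  )
  kv <- kv[lengths(kv) == 3]
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
}

infer_sample_rate <- function(t) {
  if (length(t) < 2) stop("cannot infer sampling rate from one sample",
                          call. = FALSE)
  1 / stats::median(diff(t))
}

check_uniform_time <- function(t, rate) {
  if (length(t) < 2) return(invisible(TRUE))
  dt <- diff(t)
  period <- 1 / rate
  if (any(dt <= 0)) stop("timestamps are not strictly increasing",
                         call. = FALSE)
  if (max(abs(dt - period)) > 0.1 * period) {
    stop(sprintf(
      "non-uniform timestamps: max deviation %.3g s exceeds 10%% of the %.3g s sample period",
      max(abs(dt - period)), period
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_recording()]; the sampling rate and any meta
#' annotations are stored as `# key=value` comment lines above the header.
#'
#' @param rec an `imu_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec) == 0) stop("refusing to write a recording with 0 samples",
                           call. = FALSE)
  meta <- c(list(sample_rate_hz = sample_rate(rec)), attr(rec, "meta"))
  header <- sprintf("# %s=%s", names(meta), vapply(meta, format, ""))
  readr::write_lines(header, path)
  readr::write_csv(tibble::as_tibble(rec)[recording_cols], path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Validate an IMU recording against the sensor specification
#'
#' Checks each sample against the sensor's measurement ranges
#' (acceleration within \eqn{\pm 8} g, angular rate within \eqn{\pm 2000}
#' deg/s), flags non-finite samples, and checks the sampling rate.
#' Violations are reported as findings, never silently clipped, and do not
#' block downstream processing: the ranges are a sensor spec, not a data
#' filter.
#'
#' @param rec an `imu_recording`.
#' @return a tibble of findings with columns `channel`, `index`, `rule`
#'   and `value`; zero rows iff the recording is fully in spec.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  finding <- function(channel, index, rule, value) {
    tibble::tibble(channel = channel, index = as.integer(index),
                   rule = rule, value = as.numeric(value))
  }
  out <- list()
  rate <- sample_rate(rec)
  if (!is.finite(rate) || rate <= 0) {
    out <- c(out, list(finding("sample_rate_hz", NA, "sampling rate must be > 0",
                               rate)))
  }
  limits <- c(ax = 8, ay = 8, az = 8, gx = 2000, gy = 2000, gz = 2000)
  units <- c(ax = "g", ay = "g", az = "g", gx = "dps", gy = "dps", gz = "dps")
  for (ch in imu_channels) {
    x <- rec[[ch]]
    bad <- which(!is.finite(x))
    if (length(bad)) {
      out <- c(out, list(finding(ch, bad, "non-finite sample", x[bad])))
    }
    oor <- which(is.finite(x) & abs(x) > limits[[ch]])
    if (length(oor)) {
      rule <- sprintf("outside sensor range ±%g %s", limits[[ch]],
                      units[[ch]])
      out <- c(out, list(finding(ch, oor, rule, x[oor])))
    }
  }
  if (length(out) == 0) {
    finding(character(), integer(), character(), numeric())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), .data$channel, .data$index)
  }
}

feature_names <- function() sprintf("f%03d", 0:605)
dataset_id_cols <- c("horse_id", "source", "speed_mps")

#' Read / write a stride dataset
#'
#' A stride dataset is a tibble with one row per stride: `horse_id`,
#' `source` (`"straight"` or `"curved"`), the reference `speed_mps`
#' (m/s, > 0), and the 606 feature columns `f000..f605` holding the
#' channel-major flattening of the 6 x 101 window (see [featurize()]).
#' Extra in-memory columns (e.g. simulation ground truth) are not part of
#' the on-disk format and are dropped by [write_stride_dataset()].
#'
#' @param path path to a stride-dataset CSV.
#' @return a stride-dataset tibble.
#' @export
read_stride_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c(dataset_id_cols, feature_names())
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) > 0 || length(extra) > 0) {
    stop(sprintf(
      "stride-dataset CSV must have exactly the %d columns %s,f000..f605 (%d missing, %d unexpected)",
      length(expected), paste(dataset_id_cols, collapse = ","),
      length(missing), length(extra)
    ), call. = FALSE)
  }
  check_speeds(df$speed_mps)
  tibble::as_tibble(df[expected])
}

#' @rdname read_stride_dataset
#' @param dataset a stride-dataset tibble.
#' @export
write_stride_dataset <- function(dataset, path) {
  dataset <- check_stride_dataset(dataset)
  readr::write_csv(dataset[c(dataset_id_cols, feature_names())], path,
                   progress = FALSE)
  invisible(path)
}

check_speeds <- function(speed) {
  if (any(!is.finite(speed) | speed <= 0)) {
    stop("every reference speed must be finite and > 0", call. = FALSE)
  }
  invisible(speed)
}

check_stride_dataset <- function(dataset, min_rows = 0) {
  missing <- setdiff(c(dataset_id_cols, feature_names()), names(dataset))
  if (length(missing) > 0) {
    stop("not a stride dataset; missing column(s): ",
         paste(utils::head(missing, 4), collapse = ", "),
         if (length(missing) > 4) ", ...", call. = FALSE)
  }
  if (nrow(dataset) < min_rows) {
    stop("stride dataset must have at least ", min_rows, " strides",
         call. = FALSE)
  }
  check_speeds(dataset$speed_mps)
  tibble::as_tibble(dataset)
}

#' Feature matrix of a stride dataset
#' @param dataset a stride-dataset tibble.
#' @return numeric matrix, one row per stride, 606 columns.
#' @export
stride_features <- function(dataset) {
  dataset <- check_stride_dataset(dataset)
  as.matrix(dataset[feature_names()])
}
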