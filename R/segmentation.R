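#' Segmentation configuration
#'
#' Controls stride-anchor detection on the dorso-ventral (z) acceleration
#' axis and window extraction. The defaults are tuned for canter: the
#' minimum peak separation of 0.35 s sits below the shortest plausible
#' canter stride, and the 1 g prominence floor rejects within-stride
#' secondary oscillations while keeping the main impact peak.
#'
#' @param min_peak_separation_s minimum time between stride anchors
#'   (seconds, >= 0).
#' @param min_prominence minimum topographic prominence of an anchor peak
#'   (g).
#' @param window_len samples per stride window (default 101: one anchor
#'   sample plus the next 100, i.e. 1 s at 100 Hz).
#' @param allow_overlap if `TRUE` (default) a window is cut at every
#'   detected peak even when consecutive peaks are closer than
#'   `window_len`, so windows may overlap and a window may contain more
#'   than one stride cycle; if `FALSE`, peaks falling inside the previous
#'   window are skipped.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(min_peak_separation_s = 0.35,
                                min_prominence = 1.0,
                                window_len = 101L,
                                allow_overlap = TRUE) {
  stopifnot(
    min_peak_separation_s >= 0,
    min_prominence >= 0,
    window_len >= 2,
    is.logical(allow_overlap)
  )
  structure(
    list(
      min_peak_separation_s = min_peak_separation_s,
      min_prominence = min_prominence,
      window_len = as.integer(window_len),
      allow_overlap = isTRUE(allow_overlap)
    ),
    class = "segmentation_config"
  )
}

#' Detect stride anchor peaks on the dorso-ventral acceleration axis
#'
#' Finds local maxima of the raw (unfiltered) `az` channel whose
#' topographic prominence is at least `cfg$min_prominence` and which are
#' separated by at least `cfg$min_peak_separation_s`. When two candidate
#' peaks are closer than the minimum separation the higher one wins.
#' Peaks with fewer than `window_len - 1` samples remaining before the end
#' of the recording are dropped, so every returned anchor supports a full
#' window.
#'
#' Prominence-based selection makes the result invariant to adding a
#' constant offset to `az` (e.g. a gravity bias).
#'
#' @param rec an `imu_recording`.
#' @param cfg a [segmentation_config()].
#' @return strictly increasing integer vector of 1-based anchor sample
#'   indices (possibly empty).
#' @export
detect_stride_peaks <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  z <- rec$az
  n <- length(z)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(z))) < 0) + 1L # strict rise then non-rise
  cand <- cand[z[cand] > z[cand - 1L] & z[cand] >= z[cand + 1L]]
  if (length(cand) == 0) return(integer())
  prom <- peak_prominence(z, cand)
  cand <- cand[prom >= cfg$min_prominence]
  if (length(cand) == 0) return(integer())
  min_sep <- cfg$min_peak_separation_s * sample_rate(rec)
  keep <- enforce_separation(cand, z[cand], min_sep)
  keep <- keep[keep + cfg$window_len - 1L <= n]
  keep
}

# Topographic prominence of each candidate local maximum: height above the
# higher of the two minima separating it from the nearest higher terrain
# (or the signal edge).
peak_prominence <- function(z, peaks) {
  vapply(peaks, function(p) {
    h <- z[p]
    left <- z[seq_len(p - 1L)]
    higher_l <- which(left > h)
    base_l <- min(z[(if (length(higher_l)) max(higher_l) else 1L):p])
    right <- z[seq.int(p + 1L, length(z))]
    higher_r <- which(right > h)
    end_r <- if (length(higher_r)) p + min(higher_r) else length(z)
    base_r <- min(z[p:end_r])
    h - max(base_l, base_r)
  }, numeric(1))
}

# Greedy tallest-first thinning: keep peaks in decreasing height order,
# dropping any candidate within min_sep samples of an already-kept peak.
enforce_separation <- function(idx, height, min_sep) {
  if (min_sep <= 0 || length(idx) < 2) return(sort(idx))
  ord <- order(height, decreasing = TRUE)
  kept <- integer()
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Cut fixed-length stride windows at anchor peaks
#'
#' Each window is a pure slice of the raw recording: 6 channels (rows in
#' canonical order `ax, ay, az, gx, gy, gz`) by `window_len` consecutive
#' samples, columns spanning the closed interval
#' `[anchor, anchor + window_len - 1]`. No resampling and no amplitude
#' normalisation are applied, so a fast stride packs more cycles into the
#' same 101 columns than a slow one — the window's implicit duration
#' information.
#'
#' @param rec an `imu_recording`.
#' @param peaks anchor indices from [detect_stride_peaks()].
#' @param cfg a [segmentation_config()].
#' @return a tibble with one row per window: `anchor` (1-based sample
#'   index), `t_anchor` (seconds) and `window` (list column of 6 x
#'   `window_len` matrices with rownames `ax..gz`).
#' @export
extract_windows <- function(rec, peaks, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  peaks <- as.integer(peaks)
  n <- nrow(rec)
  wl <- cfg$window_len
  if (any(peaks < 1L | peaks + wl - 1L > n)) {
    stop("peak(s) too close to the recording end: need ", wl - 1,
         " samples after each anchor", call. = FALSE)
  }
  if (!cfg$allow_overlap && length(peaks) > 1) {
    kept <- peaks[1]
    for (p in peaks[-1]) {
      if (p >= kept[length(kept)] + wl) kept <- c(kept, p)
    }
    peaks <- kept
  }
  chans <- t(as.matrix(tibble::as_tibble(rec)[imu_channels]))
  rownames(chans) <- imu_channels
  tibble::tibble(
    anchor = peaks,
    t_anchor = rec$t[peaks],
    window = lapply(peaks, function(p) chans[, p:(p + wl - 1L), drop = FALSE])
  )
}

#' Average speed along a curved path
#'
#' For the curved-path reference protocol the travelled distance is the
#' circumference of the circle marked out on the ground
#' (`distance = 2 * pi * radius`) and the average speed is distance over
#' the chronometer transit time.
#'
#' @param radius_m circle radius in metres (> 0).
#' @param transit_time_s time spent in the curve in seconds (> 0).
#' @return average speed in m/s.
#' @export
curve_average_speed <- function(radius_m, transit_time_s) {
  if (any(!is.finite(radius_m) | radius_m <= 0)) {
    stop("`radius_m` must be positive", call. = FALSE)
  }
  if (any(!is.finite(transit_time_s) | transit_time_s <= 0)) {
    stop("`transit_time_s` must be positive", call. = FALSE)
  }
  2 * pi * radius_m / transit_time_s
}

#' Attach reference speeds to extracted windows
#'
#' Straight-path mode pairs one externally measured speed with each window,
#' element-wise. Curved-path mode broadcasts a single average speed (from
#' [curve_average_speed()]) to every window of the group, mirroring how a
#' chronometer-timed curve assigns the same speed to all strides within it.
#'
#' @param windows a window tibble from [extract_windows()].
#' @param speeds straight mode: numeric vector, one speed (m/s) per window;
#'   curved mode: a single average speed.
#' @param mode `"straight"` or `"curved"`.
#' @param horse_id identifier recorded in the dataset.
#' @return a stride-dataset tibble (`horse_id`, `source`, `speed_mps`,
#'   `f000..f605`).
#' @export
attach_reference_speeds <- function(windows, speeds,
                                    mode = c("straight", "curved"),
                                    horse_id = "horse") {
  mode <- match.arg(mode)
  n <- nrow(windows)
  if (n == 0) stop("no windows to label", call. = FALSE)
  if (mode == "straight") {
    if (length(speeds) != n) {
      stop(sprintf(
        "straight mode needs one speed per window: got %d speeds for %d windows",
        length(speeds), n
      ), call. = FALSE)
    }
  } else {
    if (length(speeds) != 1) {
      stop("curved mode broadcasts a single average speed", call. = FALSE)
    }
    speeds <- rep(speeds, n)
  }
  check_speeds(speeds)
  feats <- do.call(rbind, lapply(windows$window, featurize))
  dplyr::bind_cols(
    tibble::tibble(
      horse_id = horse_id,
      source = mode,
      speed_mps = as.numeric(speeds)
    ),
    tibble::as_tibble(feats)
  )
}

#' Segment a recording into a labelled stride dataset
#'
#' Convenience wrapper: [detect_stride_peaks()], [extract_windows()],
#' [attach_reference_speeds()].
#'
#' @inheritParams attach_reference_speeds
#' @inheritParams detect_stride_peaks
#' @return a stride-dataset tibble.
#' @export
segment_recording <- function(rec, speeds, mode = c("straight", "curved"),
                              cfg = segmentation_config(),
                              horse_id = "horse") {
  peaks <- detect_stride_peaks(rec, cfg)
  if (length(peaks) == 0) stop("no stride peaks detected", call. = FALSE)
  attach_reference_speeds(extract_windows(rec, peaks, cfg), speeds,
                          mode = mode, horse_id = horse_id)
}
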