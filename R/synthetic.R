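#' Synthetic canter simulation settings
#'
#' Parameters of the canter-like signal generator. The dorso-ventral
#' acceleration is a two-harmonic periodic waveform whose frequency and
#' peak amplitude both grow affinely with speed, riding on 1 g of gravity;
#' the remaining channels carry phase-shifted harmonics of the same
#' oscillation. Faster gaits therefore pack more cycles and larger
#' excursions into a fixed 101-sample window — the property the window
#' model exploits.
#'
#' Defaults (one-time choices, documented in the methods vignette):
#' speeds span 4-9 m/s; stride frequency `f = 1.4 + 0.12 v` Hz; peak
#' amplitude `a = 0.5 + 0.25 v` g with a 5% log-normal per-recording
#' jitter (movement vigour varies between horses and passes at equal
#' speed); white measurement noise of 0.05 g / 2 deg/s; about 10% of
#' strides come from the curved-path protocol, where the label is the
#' broadcast curve-average speed while the true speed fluctuates by ~3%
#' within the curve.
#'
#' @param speed_range_mps admissible true speeds (m/s).
#' @param freq_intercept,freq_slope stride frequency model `f = i + s*v`
#'   (Hz; slope per m/s).
#' @param amp_intercept,amp_slope dorso-ventral peak amplitude model
#'   `a = i + s*v` (g).
#' @param amp_jitter_sd sd of the per-recording log-normal amplitude
#'   jitter.
#' @param noise_sd_accel accelerometer noise sd (g).
#' @param noise_sd_gyro gyroscope noise sd (deg/s).
#' @param gravity_g static gravity on the z axis (g).
#' @param sample_rate_hz sampling rate (Hz).
#' @param curve_fraction share of recordings generated under the
#'   curved-path protocol.
#' @param curve_speed_cv relative sd of the within-curve speed
#'   fluctuation.
#' @param curve_radius_m radius of the simulated curve (m).
#' @param ref_error_rel relative accuracy of the straight-path reference
#'   system (sd of the multiplicative speed error).
#' @param chrono_rel_sd relative sd of the curve chronometer timing
#'   error.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(speed_range_mps = c(4, 9),
                              freq_intercept = 1.4, freq_slope = 0.12,
                              amp_intercept = 0.5, amp_slope = 0.25,
                              amp_jitter_sd = 0.05,
                              noise_sd_accel = 0.05, noise_sd_gyro = 2,
                              gravity_g = 1.0, sample_rate_hz = 100,
                              curve_fraction = 0.1,
                              curve_speed_cv = 0.03,
                              curve_radius_m = 10,
                              ref_error_rel = 0.014,
                              chrono_rel_sd = 0.005) {
  stopifnot(
    length(speed_range_mps) == 2, all(speed_range_mps > 0),
    speed_range_mps[1] < speed_range_mps[2],
    noise_sd_accel >= 0, noise_sd_gyro >= 0, amp_jitter_sd >= 0,
    sample_rate_hz > 0, curve_fraction >= 0, curve_fraction <= 1,
    curve_radius_m > 0
  )
  f <- freq_intercept + freq_slope * speed_range_mps
  if (any(f <= 0.5) || any(f >= 4)) {
    stop("stride frequencies over the speed range must stay within (0.5, 4) Hz",
         call. = FALSE)
  }
  structure(
    list(
      speed_range_mps = speed_range_mps,
      freq_intercept = freq_intercept, freq_slope = freq_slope,
      amp_intercept = amp_intercept, amp_slope = amp_slope,
      amp_jitter_sd = amp_jitter_sd,
      noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
      gravity_g = gravity_g, sample_rate_hz = sample_rate_hz,
      curve_fraction = curve_fraction, curve_speed_cv = curve_speed_cv,
      curve_radius_m = curve_radius_m,
      ref_error_rel = ref_error_rel, chrono_rel_sd = chrono_rel_sd
    ),
    class = "simulation_config"
  )
}

# Periodic canter waveform, unit peak at phase 0; the second harmonic
# gives each cycle the asymmetric, multi-peaked look of canter without
# creating secondary maxima of comparable prominence.
canter_waveform <- function(theta) (cos(theta) + 0.4 * cos(2 * theta)) / 1.4

#' Simulate a canter-like IMU recording with known ground truth
#'
#' Generates a six-channel recording at `cfg$sample_rate_hz`. The phase
#' advances as the integral of the speed-dependent stride frequency, so
#' `speed_mps` may be a scalar (constant speed) or a per-sample vector
#' (e.g. the fluctuating speed within a curve). Ground truth lists each
#' oscillation peak (the stride anchor a detector should find) with its
#' sample index and the true speed at that instant.
#'
#' @param speed_mps true speed, scalar or one value per sample (m/s);
#'   must lie within `cfg$speed_range_mps`.
#' @param duration_s recording length in seconds (> 0).
#' @param cfg a [simulation_config()].
#' @param seed integer seed; the same seed reproduces the recording
#'   exactly.
#' @param yaw_rate_dps constant yaw-rate offset (deg/s), nonzero on a
#'   curve.
#' @param meta extra annotations stored in the recording.
#' @return a list with `recording` (an `imu_recording`) and `truth`
#'   (tibble of `peak_index`, `time_s`, `speed_mps`).
#' @export
simulate_canter <- function(speed_mps, duration_s,
                            cfg = simulation_config(), seed = 1,
                            yaw_rate_dps = 0, meta = list()) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  fs <- cfg$sample_rate_hz
  n <- as.integer(round(duration_s * fs))
  if (n < 2) stop("duration too short at this sampling rate", call. = FALSE)
  v <- if (length(speed_mps) == 1) rep(speed_mps, n) else speed_mps
  if (length(v) != n) {
    stop("`speed_mps` must be scalar or one value per sample (", n, ")",
         call. = FALSE)
  }
  rng <- cfg$speed_range_mps
  if (any(v < rng[1] - 1e-9) || any(v > rng[2] + 1e-9)) {
    stop(sprintf("speed outside the configured range [%g, %g] m/s",
                 rng[1], rng[2]), call. = FALSE)
  }
  withr::with_seed(seed, {
    freq <- cfg$freq_intercept + cfg$freq_slope * v
    theta0 <- -0.3 * 2 * pi
    theta <- theta0 + 2 * pi * cumsum(freq) / fs
    amp <- (cfg$amp_intercept + cfg$amp_slope * v) *
      exp(stats::rnorm(1, 0, cfg$amp_jitter_sd))
    az <- cfg$gravity_g + amp * canter_waveform(theta) +
      stats::rnorm(n, 0, cfg$noise_sd_accel)
    ax <- 0.45 * amp * sin(theta + 0.6) + 0.15 * amp * sin(2 * theta + 1.1) +
      stats::rnorm(n, 0, cfg$noise_sd_accel)
    ay <- 0.2 * amp * sin(theta + 2.0) +
      stats::rnorm(n, 0, cfg$noise_sd_accel)
    gx <- (20 + 8 * v) * sin(theta + 1.3) +
      stats::rnorm(n, 0, cfg$noise_sd_gyro)
    gy <- (30 + 10 * v) * (sin(theta + 0.4) + 0.3 * sin(2 * theta + 2.2)) +
      stats::rnorm(n, 0, cfg$noise_sd_gyro)
    gz <- yaw_rate_dps + (10 + 3 * v) * sin(theta + 2.7) +
      stats::rnorm(n, 0, cfg$noise_sd_gyro)
    rec <- imu_recording(
      accel = data.frame(ax = ax, ay = ay, az = az),
      gyro = data.frame(gx = gx, gy = gy, gz = gz),
      sample_rate_hz = fs, meta = meta
    )
    # waveform peaks sit exactly at phase multiples of 2*pi
    ks <- seq.int(0, max(0, floor(theta[n] / (2 * pi))))
    ks <- ks[2 * pi * ks >= theta[1]]
    t_grid <- (seq_len(n) - 1) / fs
    peak_t <- stats::approx(theta, t_grid, xout = 2 * pi * ks)$y
    peak_i <- pmin(pmax(as.integer(round(peak_t * fs)) + 1L, 1L), n)
    truth <- tibble::tibble(
      peak_index = peak_i,
      time_s = t_grid[peak_i],
      speed_mps = v[peak_i]
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate a labelled stride dataset
#'
#' Draws recording-level speeds uniformly from the configured range, runs
#' the full front end (simulate, detect peaks, cut windows) and labels the
#' windows the way the two reference protocols do. Straight-path
#' recordings (constant speed) get the true per-stride speed. Curve
#' recordings (fraction `cfg$curve_fraction`) have a speed that fluctuates
#' by `cfg$curve_speed_cv` around the commanded value; the label is the
#' circumference-over-transit-time average, broadcast to every stride of
#' the curve, while the true speed at each anchor is retained in
#' `speed_true_mps`.
#'
#' @param n_strides number of strides to produce (>= 1).
#' @param cfg a [simulation_config()].
#' @param seed master seed.
#' @param seg_cfg a [segmentation_config()] used to cut the windows.
#' @return a stride-dataset tibble with the extra columns
#'   `speed_true_mps` (simulation ground truth) and `recording_id`.
#' @export
simulate_dataset <- function(n_strides, cfg = simulation_config(), seed = 1,
                             seg_cfg = segmentation_config()) {
  stopifnot(n_strides >= 1)
  fs <- cfg$sample_rate_hz
  out <- list()
  got <- 0L
  rec_id <- 0L
  sub_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, 2 * ceiling(n_strides / 4) + 64)
  )
  draw <- withr::with_seed(
    seed + 1L,
    tibble::tibble(
      v = stats::runif(length(sub_seeds), cfg$speed_range_mps[1] + 0.1,
                       cfg$speed_range_mps[2] - 0.1),
      curved = stats::runif(length(sub_seeds)) < cfg$curve_fraction,
      phase = stats::runif(length(sub_seeds), 0, 2 * pi)
    )
  )
  while (got < n_strides) {
    rec_id <- rec_id + 1L
    if (rec_id > length(sub_seeds)) {
      stop("simulation exhausted its seed pool before reaching `n_strides`;",
           " configuration yields too few detectable strides", call. = FALSE)
    }
    v0 <- draw$v[rec_id]
    f0 <- cfg$freq_intercept + cfg$freq_slope * v0
    duration <- 10 / f0 + 1.2 # ~10 stride cycles plus tail for the last window
    n <- as.integer(round(duration * fs))
    horse <- sprintf("h%02d", (rec_id - 1L) %% 10L + 1L)
    if (draw$curved[rec_id]) {
      tt <- (seq_len(n) - 1) / fs
      v_t <- v0 * (1 + cfg$curve_speed_cv *
                     sin(2 * pi * tt / duration + draw$phase[rec_id]))
      v_t <- pmin(pmax(v_t, cfg$speed_range_mps[1]), cfg$speed_range_mps[2])
      sim <- simulate_canter(
        v_t, duration, cfg, seed = sub_seeds[rec_id],
        yaw_rate_dps = v0 / cfg$curve_radius_m * 180 / pi
      )
      distance <- sum(v_t) / fs
      label <- curve_average_speed(distance / (2 * pi), n / fs)
    } else {
      sim <- simulate_canter(v0, duration, cfg, seed = sub_seeds[rec_id])
      label <- v0
    }
    peaks <- detect_stride_peaks(sim$recording, seg_cfg)
    if (length(peaks) == 0 || nrow(sim$truth) == 0) next
    win <- extract_windows(sim$recording, peaks, seg_cfg)
    true_speed <- sim$truth$speed_mps[
      vapply(win$anchor,
             function(a) which.min(abs(sim$truth$peak_index - a)),
             integer(1))
    ]
    ds <- attach_reference_speeds(
      win,
      speeds = if (draw$curved[rec_id]) label else true_speed,
      mode = if (draw$curved[rec_id]) "curved" else "straight",
      horse_id = horse
    )
    ds$speed_true_mps <- true_speed
    ds$recording_id <- rec_id
    out[[length(out) + 1L]] <- ds
    got <- got + nrow(ds)
  }
  dplyr::bind_rows(out)[seq_len(n_strides), ]
}

#' Perturb reference speeds with reference-system measurement error
#'
#' Emulates the uncertainty of the two reference systems: straight-path
#' speeds are multiplied by `1 + e` with
#' `e ~ N(0, cfg$ref_error_rel^2)` (the camera system's relative distance
#' accuracy, default 1.4%); curve speeds are divided by `1 + u` with
#' `u ~ N(0, cfg$chrono_rel_sd^2)` (chronometer timing jitter relative to
#' the transit time) — one draw per curve group, since the whole group
#' shares one timing measurement.
#'
#' @param dataset a stride-dataset tibble.
#' @param cfg a [simulation_config()].
#' @param seed integer seed.
#' @return the dataset with perturbed `speed_mps`.
#' @export
reference_error_injection <- function(dataset, cfg = simulation_config(),
                                      seed = 1) {
  dataset <- check_stride_dataset(dataset)
  withr::with_seed(seed, {
    straight <- dataset$source == "straight"
    e <- stats::rnorm(sum(straight), 0, cfg$ref_error_rel)
    dataset$speed_mps[straight] <- dataset$speed_mps[straight] * (1 + e)
    if (any(!straight)) {
      grp <- if ("recording_id" %in% names(dataset)) {
        dataset$recording_id[!straight]
      } else {
        cumsum(c(TRUE, diff(which(!straight)) > 1))
      }
      u <- stats::rnorm(length(unique(grp)), 0, cfg$chrono_rel_sd)
      names(u) <- as.character(unique(grp))
      dataset$speed_mps[!straight] <-
        dataset$speed_mps[!straight] / (1 + u[as.character(grp)])
    }
  })
  check_speeds(dataset$speed_mps)
  dataset
}

#' Absolute error implied by a relative reference accuracy
#'
#' Converts the reference system's relative accuracy into the absolute
#' error at a given measured distance (e.g. 1.4% of a 2 m distance is
#' 0.028 m).
#'
#' @param distance_m measured distance (m).
#' @param relative relative accuracy (fraction of the measured distance).
#' @return absolute error in metres.
#' @export
reference_absolute_error <- function(distance_m, relative = 0.014) {
  stopifnot(distance_m > 0, relative >= 0)
  distance_m * relative
}
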