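#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter (default fourth order, 10 Hz
#' cut-off) forward and backward so the output is zero-phase: rectified
#' means are not phase-shifted across the window. Coefficients come from
#' [signal::butter()]; each pass runs in direct-form-II-transposed with
#' steady-state initial conditions and odd-reflection end padding, so a
#' constant signal passes through exactly and end transients are
#' suppressed even on short 101-sample windows.
#'
#' @param x numeric vector, or a matrix whose rows are channels.
#' @param sample_rate_hz sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz cut-off frequency in Hz.
#' @param order filter order.
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, sample_rate_hz, cutoff_hz = 10, order = 4) {
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, sample_rate_hz / 2), call. = FALSE)
  }
  bw <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2))
  if (is.matrix(x)) {
    t(apply(x, 1, filtfilt_ss, b = bw$b, a = bw$a))
  } else {
    filtfilt_ss(x, bw$b, bw$a)
  }
}

# One direct-form-II-transposed pass with initial state z.
df2t_pass <- function(b, a, x, z) {
  nf <- length(b)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (k in seq_len(nf - 2)) {
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
    }
    z[nf - 1] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# Forward-backward filtering with steady-state initial conditions and
# odd-reflection padding of 3 * order samples at each end.
filtfilt_ss <- function(x, b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  nfact <- 3L * (nf - 1L)
  if (length(x) <= nfact) {
    stop("signal too short to filter: need more than ", nfact, " samples",
         call. = FALSE)
  }
  A <- diag(nf - 1)
  A[, 1] <- A[, 1] + a[2:nf]
  if (nf > 2) {
    A[1:(nf - 2), 2:(nf - 1)] <- A[1:(nf - 2), 2:(nf - 1)] - diag(nf - 2)
  }
  zi <- solve(A, b[2:nf] - b[1] * a[2:nf])
  n <- length(x)
  xx <- c(2 * x[1] - x[(nfact + 1):2], x,
          2 * x[n] - x[(n - 1):(n - nfact)])
  y <- df2t_pass(b, a, xx, zi * xx[1])
  y <- rev(df2t_pass(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + n)]
}

#' Align the window's acceleration with the gravity axis
#'
#' Estimates the gravity direction as the window-mean acceleration vector
#' and applies the minimal rotation (about the axis normal to the plane
#' spanned by that vector and z) taking it onto +z, to every acceleration
#' sample of the window. Per-sample vector norms are preserved; gyroscope
#' channels pass through untouched.
#'
#' @param window a 6 x 101 stride-window matrix.
#' @return the window with rotated acceleration channels.
#' @export
gravity_align <- function(window) {
  acc <- window[c("ax", "ay", "az"), , drop = FALSE]
  m <- rowMeans(acc)
  nm <- sqrt(sum(m^2))
  if (nm < 0.1) {
    stop(sprintf(
      "mean acceleration magnitude %.3g g is below 0.1 g: gravity direction undefined",
      nm
    ), call. = FALSE)
  }
  window[c("ax", "ay", "az"), ] <- rotation_to_z(m / nm) %*% acc
  window
}

# Minimal rotation matrix taking unit vector u onto (0, 0, 1); Rodrigues
# form about axis u x z. Antipodal u (pointing straight down) flips about x.
rotation_to_z <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(u * z)
  v <- c(u[2], -u[1], 0) # u x z
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  k <- v / s
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Mean overall dynamic body acceleration of a stride window
#'
#' ODBA pipeline, applied per window: low-pass filter each acceleration
#' axis ([lowpass_filter()]), rotate so the window-mean acceleration lies
#' on +z ([gravity_align()]), subtract each axis's mean over the window,
#' rectify, sum the three axes per sample, and average over the window's
#' samples. The result is a non-negative scalar in g that tracks the
#' vigour of trunk motion, and through it the speed. Gyroscope channels
#' are not used.
#'
#' @param window a 6 x 101 stride-window matrix.
#' @param sample_rate_hz sampling rate of the source recording.
#' @param cutoff_hz,order low-pass settings, see [lowpass_filter()].
#' @return mean ODBA in g (>= 0).
#' @export
compute_odba <- function(window, sample_rate_hz = 100, cutoff_hz = 10,
                         order = 4) {
  window[c("ax", "ay", "az"), ] <- lowpass_filter(
    window[c("ax", "ay", "az"), , drop = FALSE],
    sample_rate_hz, cutoff_hz, order
  )
  window <- gravity_align(window)
  acc <- window[c("ax", "ay", "az"), , drop = FALSE]
  dyn <- abs(acc - rowMeans(acc))
  mean(colSums(dyn))
}

#' Add a mean-ODBA column to a stride dataset
#'
#' @param dataset a stride-dataset tibble.
#' @param sample_rate_hz sampling rate the windows were recorded at.
#' @return `dataset` with an `odba` column (g).
#' @export
add_odba <- function(dataset, sample_rate_hz = 100) {
  dataset <- check_stride_dataset(dataset)
  feats <- stride_features(dataset)
  dataset$odba <- vapply(
    seq_len(nrow(feats)),
    function(i) compute_odba(unfeaturize(feats[i, ]), sample_rate_hz),
    numeric(1)
  )
  dataset
}

#' Fit the ODBA-linear speed baseline
#'
#' Ordinary least-squares regression of reference speed on per-stride mean
#' ODBA: `speed = intercept + slope * ODBA`.
#'
#' @param dataset a stride-dataset tibble with >= 2 strides.
#' @param sample_rate_hz sampling rate of the windows.
#' @return an `odba_model` with `intercept` (m/s) and `slope`
#'   (m/s per g of ODBA).
#' @export
fit_odba_model <- function(dataset, sample_rate_hz = 100) {
  dataset <- check_stride_dataset(dataset, min_rows = 2)
  if (!"odba" %in% names(dataset)) {
    dataset <- add_odba(dataset, sample_rate_hz)
  }
  if (stats::var(dataset$odba) == 0) {
    stop("degenerate design: all strides have identical ODBA", call. = FALSE)
  }
  fit <- stats::lm(speed_mps ~ odba, data = dataset)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      fit = fit,
      sample_rate_hz = sample_rate_hz,
      n_train = nrow(dataset)
    ),
    class = "odba_model"
  )
}

#' @export
print.odba_model <- function(x, ...) {
  cat(sprintf(
    "<odba_model> speed = %.4g + %.4g * ODBA  (m/s, ODBA in g; n = %d)\n",
    x$intercept, x$slope, x$n_train
  ))
  invisible(x)
}

#' @param object an `odba_model`.
#' @param newdata a stride-dataset tibble, a window tibble, a single 6 x
#'   101 window matrix, or a numeric vector of precomputed ODBA values.
#' @param ... unused.
#' @rdname fit_odba_model
#' @export
predict.odba_model <- function(object, newdata, ...) {
  odba <- if (is.numeric(newdata) && !is.matrix(newdata)) {
    newdata
  } else if (is.data.frame(newdata) && "odba" %in% names(newdata)) {
    newdata$odba
  } else {
    x <- as_feature_matrix(newdata)
    vapply(seq_len(nrow(x)),
           function(i) compute_odba(unfeaturize(x[i, ]),
                                    object$sample_rate_hz),
           numeric(1))
  }
  object$intercept + object$slope * odba
}

#' @export
tidy.odba_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "odba"),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.odba_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n_train = x$n_train,
    intercept = x$intercept,
    slope = x$slope
  )
}

#' Save / read an ODBA model as JSON
#'
#' The persisted file stores the two coefficients and the filter settings
#' as plain JSON, human-readable and diff-able.
#'
#' @param model an `odba_model`.
#' @param path file path.
#' @export
write_odba_model <- function(model, path) {
  stopifnot(inherits(model, "odba_model"))
  jsonlite::write_json(
    list(
      format = "odba-model/1",
      intercept_mps = model$intercept,
      slope_mps_per_g = model$slope,
      sample_rate_hz = model$sample_rate_hz,
      n_train = model$n_train
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_odba_model
#' @export
read_odba_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "odba-model/1")) {
    stop("not an odba-model/1 file: ", path, call. = FALSE)
  }
  structure(
    list(
      intercept = obj$intercept_mps,
      slope = obj$slope_mps_per_g,
      fit = NULL,
      sample_rate_hz = obj$sample_rate_hz,
      n_train = as.integer(obj$n_train)
    ),
    class = "odba_model"
  )
}
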