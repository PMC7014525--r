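test_that("low-pass filter has unit DC gain, flat passband, strong stopband", {
  expect_lt(max(abs(lowpass_filter(rep(3.2, 101), 100) - 3.2)), 1e-9)

  t <- (0:100) / 100
  s2 <- sin(2 * pi * 2 * t)
  expect_lt(abs(max(abs(lowpass_filter(s2, 100))) - 1), 0.02)

  s40 <- sin(2 * pi * 40 * t)
  expect_lt(max(abs(lowpass_filter(s40, 100))), 0.05)

  expect_error(lowpass_filter(s2, 100, cutoff_hz = 50), "Nyquist")

  # matrix input filters each row
  m <- rbind(rep(1, 101), s2)
  fm <- lowpass_filter(m, 100)
  expect_equal(fm[1, ], lowpass_filter(rep(1, 101), 100))
  expect_equal(fm[2, ], lowpass_filter(s2, 100))
})

const_window <- function(acc) {
  rbind(
    ax = rep(acc[1], 101), ay = rep(acc[2], 101), az = rep(acc[3], 101),
    gx = rep(0, 101), gy = rep(0, 101), gz = rep(0, 101)
  )
}

test_that("gravity alignment maps the window-mean acceleration onto +z", {
  w <- const_window(c(0, 0, 1))
  expect_equal(gravity_align(w), w)

  w2 <- gravity_align(const_window(c(1, 0, 0)))
  expect_equal(unname(w2[c("ax", "ay", "az"), 1]), c(0, 0, 1),
               tolerance = 1e-12)

  # norms preserved per sample on an arbitrary window
  w3 <- random_window(seed = 5)
  r3 <- gravity_align(w3)
  norms <- function(w) sqrt(colSums(w[c("ax", "ay", "az"), ]^2))
  expect_equal(norms(r3), norms(w3), tolerance = 1e-12)
  m <- rowMeans(r3[c("ax", "ay", "az"), ])
  expect_equal(unname(m[1:2]), c(0, 0), tolerance = 1e-12)
  expect_gt(m[3], 0)
  # gyroscope channels untouched
  expect_identical(r3[c("gx", "gy", "gz"), ], w3[c("gx", "gy", "gz"), ])

  expect_error(gravity_align(const_window(c(0.01, 0, 0.02))), "0.1 g")
})

test_that("ODBA of a constant window is zero and of a sine is 2A/pi", {
  expect_equal(compute_odba(const_window(c(0.2, -0.1, 0.95))), 0,
               tolerance = 1e-12)

  t <- (0:100) / 100
  w <- const_window(c(0, 0, 1))
  w["az", ] <- 1 + 0.5 * sin(2 * pi * 2 * t) # two full periods
  expect_equal(compute_odba(w), 2 * 0.5 / pi, tolerance = 0.02)
})

test_that("ODBA sums the three axes' rectified deviations", {
  # slow oscillations pass the 10 Hz filter essentially unchanged, and the
  # window mean stays on +z so alignment is near-identity
  t <- (0:100) / 100
  w <- const_window(c(0, 0, 1))
  w["ax", ] <- 0.3 * sin(2 * pi * 2 * t)
  w["ay", ] <- 0.2 * sin(2 * pi * 3 * t)
  w["az", ] <- 1 + 0.4 * sin(2 * pi * 2 * t)
  per_axis <- function(x) mean(abs(x - mean(x)))
  brute <- per_axis(w["ax", ]) + per_axis(w["ay", ]) + per_axis(w["az", ])
  expect_equal(compute_odba(w), brute, tolerance = 0.02)
  expect_gte(compute_odba(w), 0)
})

test_that("ODBA agrees with an independent literal re-implementation", {
  worst <- 0
  for (s in 1:100) {
    w <- random_window(seed = 1000 + s)
    worst <- max(worst, abs(compute_odba(w) - independent_odba(w)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ODBA is invariant to constant shifts parallel to the window mean", {
  w <- random_window(seed = 77)
  # the gravity estimate is the mean of the *filtered* window, so the
  # invariance holds for shifts parallel to that vector
  m <- rowMeans(lowpass_filter(w[c("ax", "ay", "az"), ], 100))
  shifted <- w
  shifted[c("ax", "ay", "az"), ] <- w[c("ax", "ay", "az"), ] + 0.5 * m
  expect_equal(compute_odba(shifted), compute_odba(w), tolerance = 1e-9)
})

test_that("the ODBA-linear fit recovers exact and noisy relationships", {
  windows <- lapply(1:40, function(s) random_window(seed = 200 + s))
  odba <- vapply(windows, compute_odba, numeric(1))
  ds <- attach_reference_speeds(
    tibble::tibble(anchor = seq_along(windows), t_anchor = 0,
                   window = windows),
    speeds = 2 + 3 * odba
  )
  fit <- fit_odba_model(ds)
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(fit$slope, 3, tolerance = 1e-8)
  expect_equal(unname(predict(fit, ds)), ds$speed_mps, tolerance = 1e-8)

  # parameter recovery under Gaussian noise: estimates within 3 SE of truth
  withr::with_seed(42, {
    x <- runif(500, 0.5, 3)
    y <- 1.5 + 2.2 * x + rnorm(500, sd = 0.1)
  })
  ds2 <- ds[rep(1, 500), ]
  ds2$odba <- x
  ds2$speed_mps <- y
  fit2 <- fit_odba_model(ds2)
  est <- tidy(fit2)
  expect_lt(abs(est$estimate[1] - 1.5) / est$std.error[1], 3)
  expect_lt(abs(est$estimate[2] - 2.2) / est$std.error[2], 3)

  expect_error(fit_odba_model(ds[1, ]), "at least 2")
  ds3 <- ds[1:5, ]
  ds3$odba <- rep(1, 5)
  expect_error(fit_odba_model(ds3), "identical ODBA")
})

test_that("ODBA predictions follow intercept + slope * ODBA", {
  model <- structure(
    list(intercept = 1.25, slope = 2.5, fit = NULL, sample_rate_hz = 100,
         n_train = 10),
    class = "odba_model"
  )
  expect_equal(predict(model, 0), 1.25)
  x <- c(0.3, 1.1, 2.7)
  expect_equal(predict(model, x), 1.25 + 2.5 * x)
})

test_that("ODBA models persist as JSON and reload exactly", {
  ds <- shared_dataset()[1:30, ]
  fit <- fit_odba_model(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_odba_model(fit, path)
  back <- read_odba_model(path)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-15)
  expect_equal(back$slope, fit$slope, tolerance = 1e-15)
  probe <- c(0.5, 1, 2)
  expect_equal(predict(back, probe), predict(fit, probe), tolerance = 1e-15)
})
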