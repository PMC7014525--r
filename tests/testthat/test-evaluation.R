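# brute-force oracles, written as explicit loops
brute_pct_above <- function(m, p, thr) {
  n_above <- 0
  for (i in seq_along(m)) {
    if (abs(m[i] - p[i]) > thr) n_above <- n_above + 1
  }
  100 * n_above / length(m)
}
brute_rmse <- function(m, p) {
  acc <- 0
  for (i in seq_along(m)) acc <- acc + (m[i] - p[i])^2
  sqrt(acc / length(m))
}
brute_ba <- function(m, p) {
  d <- numeric(length(m))
  for (i in seq_along(m)) d[i] <- p[i] - m[i]
  mu <- sum(d) / length(d)
  s <- sqrt(sum((d - mu)^2) / (length(d) - 1))
  c(bias = mu, low = mu - 1.96 * s, high = mu + 1.96 * s,
    width = 2 * 1.96 * s)
}

test_that("metrics match brute-force implementations on random vectors", {
  worst <- c(pct = 0, rmse = 0, ba = 0)
  withr::with_seed(2718, {
    for (rep in 1:1000) {
      n <- sample(2:40, 1)
      m <- runif(n, 3, 9)
      p <- m + rnorm(n, sd = 0.7)
      thr <- runif(1, 0.1, 1)
      worst["pct"] <- max(worst["pct"],
                          abs(percent_error_above(m, p, thr) -
                                brute_pct_above(m, p, thr)))
      worst["rmse"] <- max(worst["rmse"], abs(rmse(m, p) - brute_rmse(m, p)))
      ba <- bland_altman(m, p)
      ref <- brute_ba(m, p)
      worst["ba"] <- max(worst["ba"], abs(ba$mean_bias - ref["bias"]),
                         abs(ba$loa_low - ref["low"]),
                         abs(ba$loa_high - ref["high"]),
                         abs(ba$width - ref["width"]))
    }
  })
  expect_lt(worst["pct"], 1e-9)
  expect_lt(worst["rmse"], 1e-9)
  expect_lt(worst["ba"], 1e-9)
})

test_that("the error-above threshold is a strict inequality", {
  m <- c(5, 5)
  expect_equal(percent_error_above(m, m), 0)
  expect_equal(percent_error_above(m, m + c(0.7, 0.5)), 50)
  # an error of exactly 0.6 m/s does not count
  expect_equal(percent_error_above(5, 5.6), 0)
  expect_equal(percent_error_above(5, 5.6 + 1e-9), 100)
})

test_that("rmse handles identity, constant error and hand-computed cases", {
  expect_equal(rmse(c(4, 5, 6), c(4, 5, 6)), 0)
  expect_equal(rmse(rep(5, 7), rep(5.5, 7)), 0.5)
  expect_equal(rmse(c(1, 1), c(1.3, 1.4)), sqrt(0.125))
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(numeric(), numeric()), "at least 1")
})

test_that("Bland-Altman bias, limits and width follow the sample sd", {
  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ba0$mean_bias, 0)
  expect_equal(ba0$width, 0)

  ba <- bland_altman(c(5, 5), c(4, 6)) # differences -1, +1
  expect_equal(ba$mean_bias, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$width, 3.92 * sqrt(2))
  expect_equal(ba$width, ba$loa_high - ba$loa_low)

  expect_error(bland_altman(5, 5.1), "at least 2")
})

test_that("metric symmetries: swap invariance and bias sign flip", {
  withr::with_seed(99, {
    m <- runif(50, 4, 8)
    p <- m + rnorm(50, sd = 0.5)
  })
  expect_equal(percent_error_above(m, p), percent_error_above(p, m))
  expect_equal(rmse(m, p), rmse(p, m))
  expect_equal(bland_altman(m, p)$mean_bias, -bland_altman(p, m)$mean_bias)

  # adding a constant shifts the bias, not the width
  ba <- bland_altman(m, p)
  ba_c <- bland_altman(m, p + 0.37)
  expect_equal(ba_c$mean_bias, ba$mean_bias + 0.37)
  expect_equal(ba_c$width, ba$width, tolerance = 1e-12)
})

test_that("limits-of-agreement width converges to 3.92 sigma", {
  d <- withr::with_seed(31415, rnorm(1e5, sd = 0.8))
  m <- rep(6, 1e5)
  ba <- bland_altman(m, m + d)
  expect_lt(abs(ba$width - 3.92 * 0.8) / (3.92 * 0.8), 0.02)
})

test_that("repeated holdout partitions cleanly and reports per rep x method", {
  ds <- shared_dataset()[1:150, ]
  ds$stride_uid <- seq_len(nrow(ds))
  seen <- new.env()
  spy <- list(
    spy = list(
      fit = function(train) {
        seen$train_uid <- train$stride_uid
        mean(train$speed_mps)
      },
      predict = function(model, test) {
        seen$test_uid <- test$stride_uid
        rep(model, nrow(test))
      }
    )
  )
  rep1 <- repeated_holdout(ds, spy, n_reps = 3, seed = 5)
  expect_equal(nrow(rep1$rows), 3)
  # disjoint and exhaustive split at the stride level
  expect_length(intersect(seen$train_uid, seen$test_uid), 0)
  expect_setequal(c(seen$train_uid, seen$test_uid), ds$stride_uid)
  expect_length(seen$train_uid, 120)

  both <- repeated_holdout(ds, speed_methods(), n_reps = 4, seed = 5)
  expect_equal(nrow(both$rows), 8)
  expect_setequal(unique(both$rows$method), c("svm", "odba"))

  # same master seed reproduces the whole report
  again <- repeated_holdout(ds, speed_methods(), n_reps = 4, seed = 5)
  expect_identical(both$rows, again$rows)
  differs <- repeated_holdout(ds, spy, n_reps = 3, seed = 6)
  expect_false(identical(rep1$rows$rmse, differs$rows$rmse))

  # summaries are recomputable from the rows
  svm_rows <- both$rows[both$rows$method == "svm", ]
  svm_sum <- both$summary[both$summary$method == "svm", ]
  expect_equal(svm_sum$mean_pct_error, mean(svm_rows$pct_error_above))
  expect_equal(svm_sum$min_pct_error, min(svm_rows$pct_error_above))
  expect_equal(svm_sum$max_pct_error, max(svm_rows$pct_error_above))
  expect_equal(svm_sum$mean_rmse, mean(svm_rows$rmse))
  expect_equal(svm_sum$sd_loa_width, sd(svm_rows$loa_width))

  expect_error(repeated_holdout(ds, list(a = spy$spy, a = spy$spy),
                                n_reps = 1),
               "uniquely named")
})

test_that("horse-level grouping keeps each horse on one side of the split", {
  ds <- shared_dataset()[1:150, ]
  seen <- new.env()
  spy <- list(spy = list(
    fit = function(train) { seen$train_horses <- unique(train$horse_id); 6 },
    predict = function(model, test) {
      seen$test_horses <- unique(test$horse_id)
      rep(model, nrow(test))
    }
  ))
  repeated_holdout(ds, spy, n_reps = 1, seed = 2, group_by_horse = TRUE)
  expect_length(intersect(seen$train_horses, seen$test_horses), 0)
})

test_that("Bland-Altman plots draw the bias and limit lines", {
  withr::with_seed(12, {
    m <- runif(60, 4, 8)
    p <- m + rnorm(60, 0.1, 0.4)
  })
  ba <- bland_altman(m, p)
  gg <- autoplot(ba)
  built <- ggplot2::ggplot_build(gg)
  hlines <- sort(unlist(lapply(built$data[-1], function(d) d$yintercept)))
  expect_equal(hlines, sort(c(ba$mean_bias, ba$loa_low, ba$loa_high)))

  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  b0 <- ggplot2::ggplot_build(autoplot(ba0))
  expect_equal(unique(unlist(lapply(b0$data[-1], function(d) d$yintercept))), 0)

  path <- withr::local_tempfile(fileext = ".png")
  plot_bland_altman(ba, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
})
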