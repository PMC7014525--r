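#' Percentage of stride speed errors above a threshold
#'
#' The headline accuracy criterion for show-jumping use: the share of
#' strides whose absolute speed error exceeds the target value, by default
#' 0.6 m/s. The inequality is strict — an error of exactly the threshold
#' does not count.
#'
#' @param measured reference speeds (m/s).
#' @param predicted model speeds (m/s), same length.
#' @param threshold error threshold in m/s.
#' @return percentage in `[0, 100]`.
#' @export
percent_error_above <- function(measured, predicted, threshold = 0.6) {
  check_paired(measured, predicted, min_n = 1)
  100 * sum(abs(measured - predicted) > threshold) / length(measured)
}

#' Root-mean-square error of predicted speeds
#'
#' @inheritParams percent_error_above
#' @return RMSE in m/s.
#' @export
rmse <- function(measured, predicted) {
  check_paired(measured, predicted, min_n = 1)
  sqrt(mean((measured - predicted)^2))
}

check_paired <- function(measured, predicted, min_n) {
  if (length(measured) != length(predicted)) {
    stop(sprintf("length mismatch: %d measured vs %d predicted speeds",
                 length(measured), length(predicted)), call. = FALSE)
  }
  if (length(measured) < min_n) {
    stop("need at least ", min_n, " paired speeds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bland-Altman agreement between predicted and measured speeds
#'
#' Differences are oriented `predicted - measured`, so a model that
#' underestimates fast strides shows negative differences at high means.
#' The 95% limits of agreement are `bias ± 1.96 * sd` with the sample
#' (n − 1) standard deviation; their span is the width of the limit of
#' agreement.
#'
#' @inheritParams percent_error_above
#' @return a `bland_altman` object with `mean_bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `width`, and a `data` tibble of per-stride `mean` and
#'   `diff` for plotting.
#' @export
bland_altman <- function(measured, predicted) {
  check_paired(measured, predicted, min_n = 2)
  d <- predicted - measured
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      mean_bias = bias,
      sd_diff = s,
      loa_low = bias - 1.96 * s,
      loa_high = bias + 1.96 * s,
      width = 2 * 1.96 * s,
      n = length(d),
      data = tibble::tibble(mean = (measured + predicted) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.3f m/s, 95%% limits of agreement [%.3f, %.3f] (width %.3f) over %d strides\n",
    x$mean_bias, x$loa_low, x$loa_high, x$width, x$n
  ))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_bias = x$mean_bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    width = x$width, n = x$n
  )
}

#' Bland-Altman plot
#'
#' Scatter of per-stride difference (predicted − measured) against the
#' pair mean, with horizontal lines at the bias and the 95% limits of
#' agreement.
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(shape = 1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of measured and predicted speed (m/s)",
      y = "Predicted - measured speed (m/s)",
      title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f] m/s",
                      object$mean_bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Write a Bland-Altman plot to file
#'
#' @param result a [bland_altman()] result.
#' @param path output image path (extension picks the device, e.g. `.png`).
#' @param width,height,dpi passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(result, path, width = 6, height = 4,
                              dpi = 150) {
  stopifnot(inherits(result, "bland_altman"))
  ggplot2::ggsave(path, autoplot(result), width = width, height = height,
                  dpi = dpi)
  invisible(path)
}

#' Built-in trainable speed estimators
#'
#' Returns the method table used by [repeated_holdout()]: each entry has a
#' `fit(train)` function returning a fitted model and a
#' `predict(model, test)` function returning speeds. `"svm"` is the
#' nu-SVR window model, `"odba"` the ODBA-linear baseline.
#'
#' @param names which methods to include.
#' @param svm_cfg an [svm_config()] for the SVR entry.
#' @param sample_rate_hz sampling rate of the windows.
#' @return named list of method definitions.
#' @export
speed_methods <- function(names = c("svm", "odba"),
                          svm_cfg = svm_config(),
                          sample_rate_hz = 100) {
  all <- list(
    svm = list(
      fit = function(train) fit_svm(train, svm_cfg),
      predict = function(model, test) predict(model, test)
    ),
    odba = list(
      fit = function(train) fit_odba_model(train, sample_rate_hz),
      predict = function(model, test) {
        predict(model, add_odba(test, sample_rate_hz))
      }
    )
  )
  missing <- setdiff(names, names(all))
  if (length(missing)) {
    stop("unknown method(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all[names]
}

#' Repeated random-holdout comparison of speed estimators
#'
#' The full comparison protocol: for each of `n_reps` repetitions, the
#' strides are split uniformly at random into disjoint training
#' (`train_fraction`, default 80%) and test parts — the same stride is
#' never in both — each method is fitted on the training part and scored
#' on the test part with the percentage of errors above `threshold`, the
#' RMSE, and the Bland-Altman limits of agreement. A master seed spawns
#' one sub-seed per repetition, so repetitions are independent yet the
#' whole report is reproducible.
#'
#' Splits are at the stride level by default, so strides of one horse can
#' appear in both parts; pass `group_by_horse = TRUE` to split whole
#' horses instead.
#'
#' @param dataset a stride-dataset tibble.
#' @param methods named list of method definitions, see [speed_methods()].
#' @param n_reps number of repetitions.
#' @param train_fraction fraction of strides used for training, in (0, 1).
#' @param threshold error threshold (m/s) for [percent_error_above()].
#' @param seed master seed.
#' @param group_by_horse split at the horse level instead of the stride
#'   level.
#' @return an `evaluation_report`: `rows` (one per repetition x method
#'   with `repetition`, `method`, `pct_error_above`, `rmse`, `loa_width`,
#'   `bias`, `n_test`), `summary` (per-method mean/min/max of the
#'   percentage error, mean and sd of RMSE and of the LoA width) and the
#'   protocol parameters.
#' @export
repeated_holdout <- function(dataset, methods = speed_methods(),
                             n_reps = 50, train_fraction = 0.8,
                             threshold = 0.6, seed = 1,
                             group_by_horse = FALSE) {
  dataset <- check_stride_dataset(dataset, min_rows = 2)
  stopifnot(n_reps >= 1, train_fraction > 0, train_fraction < 1)
  if (is.null(names(methods)) || any(names(methods) == "") ||
      anyDuplicated(names(methods))) {
    stop("`methods` must be a uniquely named list", call. = FALSE)
  }
  n <- nrow(dataset)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    idx_train <- withr::with_seed(
      rep_seeds[r],
      holdout_train_indices(dataset, train_fraction, group_by_horse)
    )
    train <- dataset[idx_train, ]
    test <- dataset[-idx_train, ]
    if (nrow(train) == 0 || nrow(test) == 0) {
      stop("empty train or test partition; dataset too small for the split",
           call. = FALSE)
    }
    purrr::map_dfr(names(methods), function(m) {
      model <- methods[[m]]$fit(train)
      pred <- methods[[m]]$predict(model, test)
      ba <- bland_altman(test$speed_mps, pred)
      tibble::tibble(
        repetition = r, method = m,
        pct_error_above = percent_error_above(test$speed_mps, pred,
                                              threshold),
        rmse = rmse(test$speed_mps, pred),
        loa_width = ba$width,
        bias = ba$mean_bias,
        n_test = nrow(test)
      )
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_pct_error = mean(.data$pct_error_above),
      min_pct_error = min(.data$pct_error_above),
      max_pct_error = max(.data$pct_error_above),
      mean_rmse = mean(.data$rmse),
      sd_rmse = stats::sd(.data$rmse),
      mean_loa_width = mean(.data$loa_width),
      sd_loa_width = stats::sd(.data$loa_width),
      .groups = "drop"
    )
  structure(
    list(
      rows = rows,
      summary = summary,
      params = list(n_reps = n_reps, train_fraction = train_fraction,
                    threshold = threshold, seed = seed,
                    group_by_horse = group_by_horse, n_strides = n)
    ),
    class = "evaluation_report"
  )
}

holdout_train_indices <- function(dataset, train_fraction, group_by_horse) {
  n <- nrow(dataset)
  if (!group_by_horse) {
    return(sample.int(n, size = max(1, round(train_fraction * n))))
  }
  horses <- unique(dataset$horse_id)
  k <- max(1, round(train_fraction * length(horses)))
  if (k >= length(horses)) k <- length(horses) - 1
  if (k < 1) stop("need at least 2 horses for a horse-level split",
                  call. = FALSE)
  train_horses <- sample(horses, k)
  which(dataset$horse_id %in% train_horses)
}

#' @export
print.evaluation_report <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<evaluation_report> %d reps of a %d/%d%% split on %d strides (threshold %.2g m/s, seed %d)\n",
    p$n_reps, round(100 * p$train_fraction),
    round(100 * (1 - p$train_fraction)), p$n_strides, p$threshold, p$seed
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$rows

#' @export
glance.evaluation_report <- function(x, ...) x$summary

#' Per-repetition metric distributions of an evaluation report
#'
#' Boxplots of the three comparison metrics across repetitions, one panel
#' per metric, methods side by side.
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- object$rows |>
    tidyr::pivot_longer(
      c("pct_error_above", "rmse", "loa_width"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = factor(
      .data$metric,
      levels = c("pct_error_above", "rmse", "loa_width"),
      labels = c("% error > threshold", "RMSE (m/s)", "LoA width (m/s)")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d repetitions of the %d%%/%d%% holdout",
                                  object$params$n_reps,
                                  round(100 * object$params$train_fraction),
                                  round(100 * (1 - object$params$train_fraction)))) +
    ggplot2::theme_minimal()
}
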