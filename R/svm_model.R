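#' SVR configuration
#'
#' Hyper-parameters of the nu-support-vector regression speed model. The
#' cost constant defaults to 4 and the support-vector fraction `nu` to
#' 0.75; with nu-regression the epsilon tube is then determined by the
#' optimiser rather than set by hand. The radial-basis kernel width
#' defaults to `gamma = 1/606`, i.e. one over the feature dimension.
#' Per-feature standardisation (zero mean, unit variance, estimated on the
#' training set) is on by default.
#'
#' @param nu support-vector fraction, in (0, 1].
#' @param cost cost constant (> 0).
#' @param kernel kernel name understood by [e1071::svm()].
#' @param gamma kernel width, a positive number or `"auto"` for 1/606.
#' @param scaling standardise features using training-set statistics.
#' @return an `svm_config` list.
#' @export
svm_config <- function(nu = 0.75, cost = 4, kernel = "radial",
                       gamma = "auto", scaling = TRUE) {
  stopifnot(nu > 0, nu <= 1, cost > 0)
  if (identical(gamma, "auto")) gamma <- 1 / 606
  stopifnot(is.numeric(gamma), gamma > 0)
  structure(
    list(nu = nu, cost = cost, kernel = kernel, gamma = gamma,
         scaling = isTRUE(scaling)),
    class = "svm_config"
  )
}

#' Flatten a stride window into its canonical 606-feature vector
#'
#' Channel-major order: the 101 `ax` samples, then `ay`, `az`, `gx`, `gy`,
#' `gz`. The flattening is deterministic and invertible via
#' [unfeaturize()].
#'
#' @param window a 6 x 101 stride-window matrix (rows `ax..gz`).
#' @return named numeric vector of length 606 (`f000..f605`).
#' @export
featurize <- function(window) {
  if (!is.matrix(window) || nrow(window) != 6 || ncol(window) != 101) {
    stop("a stride window must be a 6 x 101 matrix; got ",
         paste(dim(window), collapse = " x "), call. = FALSE)
  }
  stats::setNames(as.vector(t(window)), feature_names())
}

#' @rdname featurize
#' @param features numeric vector of length 606.
#' @export
unfeaturize <- function(features) {
  if (length(features) != 606) {
    stop("expected 606 features, got ", length(features), call. = FALSE)
  }
  w <- t(matrix(as.numeric(features), nrow = 101, ncol = 6))
  rownames(w) <- imu_channels
  w
}

#' Fit a nu-SVR speed model on stride windows
#'
#' Trains support-vector regression mapping the flattened 6 x 101 window
#' (606 features) to the reference speed. Feature columns with zero
#' variance in the training set are excluded from standardisation. The fit
#' is deterministic given identical inputs and configuration.
#'
#' @param dataset a stride-dataset tibble (>= 2 strides).
#' @param cfg an [svm_config()].
#' @return an `svr_speed_model`.
#' @export
fit_svm <- function(dataset, cfg = svm_config()) {
  dataset <- check_stride_dataset(dataset, min_rows = 2)
  x <- stride_features(dataset)
  y <- dataset$speed_mps
  col_var <- apply(x, 2, stats::var)
  if (all(col_var == 0)) {
    stop("degenerate dataset: all strides have identical features",
         call. = FALSE)
  }
  scale_cols <- if (cfg$scaling) col_var > 0 else rep(FALSE, ncol(x))
  fit <- e1071::svm(
    x, y,
    type = "nu-regression", kernel = cfg$kernel,
    nu = cfg$nu, cost = cfg$cost, gamma = cfg$gamma,
    scale = scale_cols, fitted = FALSE
  )
  structure(
    list(
      fit = fit,
      config = cfg,
      n_train = nrow(x),
      speed_range = range(y),
      version = svr_model_version
    ),
    class = "svr_speed_model"
  )
}

svr_model_version <- "svr-speed-model/1"

#' @export
print.svr_speed_model <- function(x, ...) {
  cat(sprintf(
    "<svr_speed_model> nu=%g cost=%g kernel=%s | %d support vectors from %d strides | trained speeds %.2f-%.2f m/s\n",
    x$config$nu, x$config$cost, x$config$kernel,
    x$fit$tot.nSV, x$n_train, x$speed_range[1], x$speed_range[2]
  ))
  invisible(x)
}

#' Predict per-stride speeds
#'
#' @param object a fitted `svr_speed_model`.
#' @param newdata a stride-dataset tibble, a window tibble from
#'   [extract_windows()], a single 6 x 101 window matrix, or a feature
#'   matrix with 606 columns.
#' @param ... unused.
#' @return numeric vector of speeds in m/s.
#' @export
predict.svr_speed_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  as.numeric(stats::predict(object$fit, x))
}

as_feature_matrix <- function(newdata) {
  x <- if (is.matrix(newdata) && ncol(newdata) == 101 && nrow(newdata) == 6) {
    matrix(featurize(newdata), nrow = 1)
  } else if (is.data.frame(newdata) && "window" %in% names(newdata)) {
    do.call(rbind, lapply(newdata$window, featurize))
  } else if (is.data.frame(newdata)) {
    as.matrix(newdata[intersect(feature_names(), names(newdata))])
  } else {
    as.matrix(newdata)
  }
  if (ncol(x) != 606) {
    stop("expected 606 feature columns, got ", ncol(x), call. = FALSE)
  }
  colnames(x) <- feature_names()
  x
}

#' Save / load a fitted SVR speed model
#'
#' The serialised file carries a format version tag; loading a file whose
#' tag does not match the version this package writes is an error naming
#' both versions.
#'
#' @param model an `svr_speed_model`.
#' @param path file path.
#' @return [load_model()] returns the model; [save_model()] returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svr_speed_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(model) || is.null(model$version)) {
    stop("not a serialized speed model: ", path, call. = FALSE)
  }
  if (!identical(model$version, svr_model_version)) {
    stop(sprintf(
      "model format version mismatch: file has '%s', this package reads '%s'",
      model$version, svr_model_version
    ), call. = FALSE)
  }
  model
}

#' @export
glance.svr_speed_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_support_vectors = x$fit$tot.nSV,
    nu = x$config$nu,
    cost = x$config$cost,
    kernel = x$config$kernel,
    gamma = x$config$gamma,
    speed_min = x$speed_range[1],
    speed_max = x$speed_range[2]
  )
}
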