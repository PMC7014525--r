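# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# default-configuration synthetic stride dataset shared by several files
shared_dataset <- function(n = 300, seed = 101) {
  memo(sprintf("ds-%d-%d", n, seed), simulate_dataset(n, seed = seed))
}

# a smooth random stride window: gravity on z plus low-frequency
# oscillations, so gravity alignment is well defined
random_window <- function(seed = 1, fs = 100) {
  withr::with_seed(seed, {
    t <- (0:100) / fs
    osc <- function(amp) {
      f1 <- stats::runif(1, 1, 4)
      amp * sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) +
        0.3 * amp * sin(2 * pi * 2 * f1 * t + stats::runif(1, 0, 2 * pi))
    }
    w <- rbind(
      ax = osc(0.4), ay = osc(0.3), az = 1 + osc(0.8),
      gx = osc(30), gy = osc(40), gz = osc(15)
    )
    w
  })
}

# independent literal re-implementation of the ODBA pipeline: same
# mathematical definition, separate straight-line code path (explicit
# difference-equation filter, explicit Rodrigues rotation)
independent_odba <- function(window, fs = 100, cutoff = 10, order = 4) {
  bw <- signal::butter(order, cutoff / (fs / 2))
  b <- bw$b
  a <- bw$a
  iir <- function(x, zi) {
    # transposed direct-form II written as an explicit recurrence
    nb <- length(b)
    z <- zi
    y <- numeric(length(x))
    for (n in seq_along(x)) {
      acc <- b[1] * x[n] + z[1]
      if (nb > 2) z[1:(nb - 2)] <- b[2:(nb - 1)] * x[n] + z[2:(nb - 1)] -
          a[2:(nb - 1)] * acc
      z[nb - 1] <- b[nb] * x[n] - a[nb] * acc
      y[n] <- acc
    }
    y
  }
  zero_phase <- function(x) {
    m <- length(b) - 1
    pad <- 3 * m
    # steady-state initial conditions (solve the DC fixed point of the state)
    M <- diag(m)
    M[, 1] <- M[, 1] + a[2:(m + 1)]
    if (m > 1) M[1:(m - 1), 2:m] <- M[1:(m - 1), 2:m] - diag(m - 1)
    zi <- solve(M, b[2:(m + 1)] - b[1] * a[2:(m + 1)])
    ext <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
             2 * x[length(x)] - rev(x)[2:(pad + 1)])
    fwd <- iir(ext, zi * ext[1])
    bwd <- rev(iir(rev(fwd), zi * fwd[length(fwd)]))
    bwd[(pad + 1):(pad + length(x))]
  }
  acc <- window[c("ax", "ay", "az"), , drop = FALSE]
  for (r in 1:3) acc[r, ] <- zero_phase(acc[r, ])
  g <- rowMeans(acc)
  g <- g / sqrt(sum(g^2))
  z <- c(0, 0, 1)
  axis <- c(g[2] * z[3] - g[3] * z[2],
            g[3] * z[1] - g[1] * z[3],
            g[1] * z[2] - g[2] * z[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(g * z)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    k <- axis / s
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    diag(3) + s * K + (1 - cth) * K %*% K
  }
  rot <- R %*% acc
  total <- 0
  for (r in 1:3) total <- total + abs(rot[r, ] - mean(rot[r, ]))
  mean(total)
}
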