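#' Uncorrelated white-noise task signal
#'
#' I.i.d. uniform values on `range` (default \[0.1, 0.9\], so targets stay
#' strictly inside the sigmoid readout's range with margin). Used as the
#' input of the memory task, where the target is the input shifted into the
#' past: with no autocorrelation, only memorization can solve it.
#'
#' @param length number of samples (one per reservoir tick).
#' @param seed seed for the draw.
#' @param range amplitude interval.
#' @return numeric vector with attributes `provenance` (generator,
#'   parameters, seed).
#' @export
white_noise <- function(length, seed = NULL, range = c(0.1, 0.9)) {
  stopifnot(length >= 1L)
  u <- with_seed(seed, runif(length, range[1], range[2]))
  attr(u, "provenance") <- list(generator = "white_noise", seed = seed,
                                range = range)
  u
}

#' Mackey-Glass delay-differential time series
#'
#' Integrates the scalar delay differential equation
#' `dx/dt = beta * x(t - tau) / (1 + x(t - tau)^n) - gamma * x(t)` with the
#' standard benchmark constants beta = 0.2, gamma = 0.1, n = 10, by
#' fixed-step fourth-order Runge-Kutta (internal step `dt` = 0.1, linear
#' interpolation of the stored history at off-grid delayed times), sampling
#' every 1.0 time unit from a constant history, and discarding a warm-up.
#' The delay tau tunes regularity: periodic near tau = 5, mildly chaotic at
#' tau = 20, chaotic at tau = 28. The sampled segment is rescaled affinely
#' into `range` (min/max of the generated segment; stored in provenance) so
#' targets are comparable across tau and sigmoid-representable.
#'
#' @param length number of unit-interval samples returned.
#' @param tau delay (>= 1, in time units).
#' @param history constant pre-history value (default 1.2).
#' @param dt internal integration step (0.1).
#' @param warmup number of leading samples discarded (default 1,000).
#' @param rescale rescale into `range`? Set `FALSE` for the raw trajectory.
#' @param range target interval for the rescaled series.
#' @return numeric vector with a `provenance` attribute.
#' @export
mackey_glass <- function(length, tau, history = 1.2, dt = 0.1,
                         warmup = 1000L, rescale = TRUE,
                         range = c(0.1, 0.9)) {
  stopifnot(tau >= 1, length >= 1L)
  beta <- 0.2; gamma <- 0.1; n_exp <- 10
  per_sample <- round(1 / dt)
  n_steps <- (warmup + length) * per_sample
  x <- numeric(n_steps + 1L)
  x[1L] <- history
  lag_steps <- tau / dt
  # delayed value at continuous step position s (can be half-integer)
  lagged <- function(s) {
    j <- s - lag_steps
    if (j <= 0) return(history)
    j0 <- floor(j)
    f <- j - j0
    if (f == 0) x[j0 + 1L]
    else (1 - f) * x[j0 + 1L] + f * x[j0 + 2L]
  }
  deriv <- function(xv, xd) beta * xd / (1 + xd^n_exp) - gamma * xv
  for (s in seq_len(n_steps)) {
    xc <- x[s]
    d0 <- lagged(s - 1)
    dh <- lagged(s - 0.5)
    d1 <- lagged(s)
    k1 <- deriv(xc, d0)
    k2 <- deriv(xc + dt / 2 * k1, dh)
    k3 <- deriv(xc + dt / 2 * k2, dh)
    k4 <- deriv(xc + dt * k3, d1)
    x[s + 1L] <- xc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(x[s + 1L]))
      stop("Mackey-Glass integration diverged", call. = FALSE)
  }
  out <- x[1L + (warmup + seq_len(length)) * per_sample]
  prov <- list(generator = "mackey_glass", tau = tau, beta = beta,
               gamma = gamma, n = n_exp, dt = dt, history = history,
               warmup = warmup)
  if (rescale) {
    lo <- min(out); hi <- max(out)
    out <- if (hi > lo)
      range[1] + (out - lo) * (range[2] - range[1]) / (hi - lo)
    else rep(mean(range), length(out))
    prov$rescale <- list(from = c(lo, hi), to = range)
  }
  attr(out, "provenance") <- prov
  out
}

#' Shifted-target alignment for memory/prediction tasks
#'
#' Builds the aligned (input, target) pairs for the target
#' `T(t) = u(t + delta)`: `delta < 0` is a memory task (recall the input
#' |delta| steps ago), `delta > 0` a prediction task (forecast |delta| steps
#' ahead). Only indices where `t + delta` is in range are kept, so |delta|
#' samples are trimmed.
#'
#' @param series input series u(t).
#' @param delta signed integer shift in ticks.
#' @return list with `input` (u over the valid times), `target`
#'   (u shifted), and `times` (the valid t indices into `series`).
#' @export
make_target <- function(series, delta) {
  L <- length(series)
  delta <- as.integer(delta)
  if (abs(delta) >= L)
    stop("|delta| must be smaller than the series length", call. = FALSE)
  t_valid <- seq.int(max(1L, 1L - delta), min(L, L - delta))
  list(input = as.numeric(series[t_valid]),
       target = as.numeric(series[t_valid + delta]),
       times = t_valid)
}

#' Export a task series as a two-column CSV with a JSON provenance sidecar
#'
#' @param series numeric series carrying a `provenance` attribute.
#' @param file CSV path; provenance goes to `<file>.json`.
#' @return `file`, invisibly.
#' @export
write_series <- function(series, file) {
  write.csv(data.frame(t = seq_along(series), value = as.numeric(series)),
            file, row.names = FALSE)
  prov <- attr(series, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(file)
}

#' Read a task series written by [write_series()]
#' @param file CSV path.
#' @return numeric series with provenance restored when the sidecar exists.
#' @export
read_series <- function(file) {
  d <- read.csv(file)
  s <- d$value
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar))
    attr(s, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  s
}
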