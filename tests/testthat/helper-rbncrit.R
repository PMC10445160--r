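# Shared fixtures and independent oracles used across the test files.

# Hand-built reservoir with fully enumerated wiring, bypassing the random
# generator, for exact-dynamics checks.
toy_reservoir <- function(pre, w, w_in = NULL, input_idx = NULL) {
  K <- nrow(pre); N <- ncol(pre)
  if (is.null(w_in)) w_in <- numeric(N)
  if (is.null(input_idx)) input_idx <- seq_len(N %/% 2L)
  structure(list(
    pre = pre, w = w, w_in = w_in,
    input_idx = input_idx,
    readout_idx = setdiff(seq_len(N), input_idx),
    config = structure(list(n_neurons = N, in_degree = K,
                            sigma_star = NA_real_, seed = NA_integer_),
                       class = "rbn_config")),
    class = "rbn_reservoir")
}

# Independent R-language evaluation of one synchronous update:
# x_i <- theta(w_in_i * u + sum_k w[k,i] * x[pre[k,i]]), theta(0) = 0.
step_oracle <- function(res, state, u = 0) {
  N <- res$config$n_neurons
  out <- integer(N)
  for (i in seq_len(N)) {
    s <- res$w_in[i] * u + sum(res$w[, i] * state[res$pre[, i]])
    out[i] <- if (s > 0) 1L else 0L
  }
  out
}

# Brute-force minimal-period scan, written independently of the package.
period_oracle <- function(a) {
  W <- length(a)
  for (p in seq_len(W %/% 2L)) {
    ok <- TRUE
    for (t in seq_len(W - p)) {
      if (a[t] != a[t + p]) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  NA_integer_
}

# Exact state-space cycle length from a given initial state of a tiny
# network: iterate the full binary state until a state repeats, return the
# cycle period and the activity sequence along the cycle.
state_cycle_oracle <- function(res, x0, max_steps = 5000L) {
  seen <- new.env(hash = TRUE)
  x <- as.integer(x0)
  traj <- list()
  for (t in seq_len(max_steps)) {
    key <- paste(x, collapse = "")
    if (!is.null(seen[[key]]))
      return(list(period = t - seen[[key]],
                  entry = seen[[key]],
                  counts = vapply(traj, sum, 0L)))
    seen[[key]] <- t
    traj[[t]] <- x
    x <- step_oracle(res, x)
  }
  stop("no cycle found within max_steps")
}

# Deterministic small reservoir for repeated use.
small_reservoir <- function(sigma_star = -0.66, n = 200L, seed = 42L) {
  generate_reservoir(n, 16L, sigma_star, seed = seed)
}

# The two sigma* phase scans are shared by several acceptance checks;
# compute each once per test run.
scan_cache <- new.env(parent = emptyenv())

negative_branch_scan <- function() {
  if (is.null(scan_cache$neg))
    scan_cache$neg <- scan_phase(seq(-0.9, -0.5, by = 0.01),
                                 n_reservoirs = 20, n_neurons = 2000,
                                 seed = 1)
  scan_cache$neg
}

positive_branch_scan <- function() {
  if (is.null(scan_cache$pos))
    scan_cache$pos <- scan_phase(seq(3, 5, by = 0.1),
                                 n_reservoirs = 20, n_neurons = 2000,
                                 seed = 1)
  scan_cache$pos
}
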