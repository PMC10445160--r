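#' Canonical weight-distribution parameters for a given sigma*
#'
#' The free dynamics of the network are invariant under positive rescaling of
#' the weight matrix (the Heaviside threshold ignores positive scale), so any
#' Gaussian weight distribution N(mu, sigma) with mu != 0 is equivalent to the
#' canonical form with mean sign(sigma*) = sign(mu) and standard deviation
#' |sigma*| = sigma/|mu|. The perfectly balanced case mu = 0 is equivalent to
#' N(0, 1) and is requested with the token `"balanced"`.
#'
#' @param sigma_star signed nonzero ratio sigma/mu, or the string
#'   `"balanced"` for the zero-mean case.
#' @return named numeric vector `c(mu, sigma)`.
#' @examples
#' canonical_params(-0.66)     # c(mu = -1, sigma = 0.66)
#' canonical_params("balanced")
#' @export
canonical_params <- function(sigma_star) {
  if (identical(sigma_star, "balanced"))
    return(c(mu = 0, sigma = 1))
  if (!is.numeric(sigma_star) || length(sigma_star) != 1L ||
      !is.finite(sigma_star) || sigma_star == 0)
    stop("`sigma_star` must be a nonzero finite number or \"balanced\"",
         call. = FALSE)
  c(mu = sign(sigma_star), sigma = abs(sigma_star))
}

#' Reservoir configuration
#'
#' @param n_neurons number of neurons N (the reference experiments use
#'   N = 10,000; scans here default to smaller N, stated per experiment).
#' @param in_degree number of nonzero incoming recurrent weights per neuron
#'   (K = 16 throughout).
#' @param sigma_star control parameter sigma/mu, or `"balanced"`.
#' @param seed integer seed controlling topology, weights and the
#'   input/readout partition.
#' @return object of class `rbn_config`.
#' @export
rbn_config <- function(n_neurons, in_degree = 16L, sigma_star, seed) {
  n_neurons <- as.integer(n_neurons)
  in_degree <- as.integer(in_degree)
  if (n_neurons < 1L) stop("`n_neurons` must be >= 1", call. = FALSE)
  if (in_degree < 1L || in_degree > n_neurons - 1L)
    stop("`in_degree` must be in [1, n_neurons - 1]", call. = FALSE)
  canonical_params(sigma_star)  # validates sigma_star
  structure(list(n_neurons = n_neurons, in_degree = in_degree,
                 sigma_star = sigma_star, seed = as.integer(seed)),
            class = "rbn_config")
}

#' Generate a random Boolean network reservoir
#'
#' Builds a fixed in-degree recurrent network: every neuron receives exactly
#' K incoming connections from distinct presynaptic partners sampled
#' uniformly (self-connections excluded), with i.i.d. Gaussian weights at the
#' canonical parameters for `sigma_star`. The neurons are split uniformly at
#' random into two equal halves: the input half carries input weights drawn
#' uniformly from [-0.5, 0.5] with half of them zeroed, and the disjoint
#' readout half is what a readout layer observes.
#'
#' @param config an [rbn_config()], or `n_neurons` when using the shorthand
#'   arguments below.
#' @param in_degree,sigma_star,seed shorthand used when `config` is a number.
#' @return object of class `rbn_reservoir` with elements `pre` (K x N
#'   presynaptic index table), `w` (K x N weights), `w_in` (length-N input
#'   weights, zero outside the input half), `input_idx`, `readout_idx`,
#'   `config`.
#' @examples
#' r <- generate_reservoir(rbn_config(100, 16, -0.66, seed = 1))
#' colSums(r$w != 0)  # every neuron has exactly 16 nonzero inputs
#' @export
generate_reservoir <- function(config, in_degree = 16L, sigma_star = NULL,
                               seed = NULL) {
  if (!inherits(config, "rbn_config"))
    config <- rbn_config(config, in_degree, sigma_star, seed)
  N <- config$n_neurons; K <- config$in_degree
  ms <- canonical_params(config$sigma_star)
  with_seed(config$seed, {
    # K distinct presynaptic partners per neuron, self excluded
    pre <- matrix(0L, nrow = K, ncol = N)
    for (i in seq_len(N)) {
      p <- sample.int(N - 1L, K)
      pre[, i] <- ifelse(p >= i, p + 1L, p)
    }
    w <- matrix(rnorm(K * N, mean = ms["mu"], sd = ms["sigma"]),
                nrow = K, ncol = N)
    half <- N %/% 2L
    input_idx <- sort(sample.int(N, half))
    readout_idx <- setdiff(seq_len(N), input_idx)
    w_in <- numeric(N)
    w_in[input_idx] <- draw_input_weights(half)
    structure(list(pre = pre, w = w, w_in = w_in,
                   input_idx = input_idx, readout_idx = readout_idx,
                   config = config),
              class = "rbn_reservoir")
  })
}

# Input weights uniform on [-0.5, 0.5], half set to zero.
draw_input_weights <- function(n) {
  v <- runif(n, -0.5, 0.5)
  v[sample.int(n, n %/% 2L)] <- 0
  v
}

#' Redraw the input weights of a reservoir ("tossing")
#'
#' Task benchmarks run each reservoir several times with an independent
#' random redraw of the input weight values on the same input half; topology,
#' recurrent weights and the input/readout partition are untouched.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param seed seed for the redraw.
#' @return the reservoir with new `w_in`.
#' @export
toss_input_weights <- function(reservoir, seed) {
  stopifnot(inherits(reservoir, "rbn_reservoir"))
  with_seed(seed, {
    w_in <- numeric(reservoir$config$n_neurons)
    w_in[reservoir$input_idx] <-
      draw_input_weights(length(reservoir$input_idx))
    reservoir$w_in <- w_in
    reservoir
  })
}

#' Random binary initial state with a fixed active fraction
#'
#' Exactly `round(active_fraction * n)` neurons (round half up) are set
#' active, chosen uniformly at random.
#'
#' @param n_neurons state length.
#' @param active_fraction fraction of active neurons in \[0, 1\]
#'   (experiments start at 0.2).
#' @param seed seed for the draw.
#' @return integer vector in `{0,1}` of length `n_neurons`.
#' @export
init_state <- function(n_neurons, active_fraction = 0.2, seed = NULL) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("`active_fraction` must be in [0, 1]", call. = FALSE)
  n_on <- as.integer(floor(active_fraction * n_neurons + 0.5))
  with_seed(seed, {
    x <- integer(n_neurons)
    if (n_on > 0L) x[sample.int(n_neurons, n_on)] <- 1L
    x
  })
}

#' One synchronous update step
#'
#' Applies `x_i(t) = theta(w_in_i u + sum_j w_ij x_j(t-1))` once, with the
#' strict Heaviside convention theta(0) = 0.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param state binary state vector of length N.
#' @param input_value scalar drive u(t) (0 for free evolution).
#' @return the next binary state.
#' @export
rbn_step <- function(reservoir, state, input_value = 0) {
  stopifnot(inherits(reservoir, "rbn_reservoir"))
  if (length(state) != reservoir$config$n_neurons)
    stop("state length does not match the reservoir", call. = FALSE)
  out <- .rbn_simulate(reservoir$pre, reservoir$w, reservoir$w_in,
                       as.integer(state), as.numeric(input_value), integer(0))
  out$final
}

#' Free evolution of a reservoir
#'
#' Runs the network with zero input for `n_transient + n_steady` steps and
#' records the population activity A(t) (as exact active-neuron counts) at
#' every step. Statistics downstream are computed on the steady window only.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param initial_state binary state vector (see [init_state()]).
#' @param n_transient discarded burn-in length (reference protocol: 1,000).
#' @param n_steady steady-window length (default matches the transient).
#' @return an `activity_trace` (see [activity_trace()]).
#' @export
run_free <- function(reservoir, initial_state, n_transient = 1000L,
                     n_steady = 1000L) {
  stopifnot(inherits(reservoir, "rbn_reservoir"),
            n_transient >= 1L, n_steady >= 1L)
  total <- n_transient + n_steady
  out <- .rbn_simulate(reservoir$pre, reservoir$w, reservoir$w_in,
                       as.integer(initial_state), numeric(total), integer(0))
  activity_trace(out$counts, reservoir$config$n_neurons, n_transient)
}

#' Input-driven run with readout-half state recording
#'
#' Drives the network with the series `u(t)` through the input weights and
#' records, at every step, the states of the readout half, time-aligned with
#' the input: row t of the history is the state reached after `input[t]` was
#' applied.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param initial_state binary state vector.
#' @param input numeric drive series u(t).
#' @return list with `trace` (an `activity_trace` with no transient marked)
#'   and `history` (length(input) x N/2 binary matrix over the readout half).
#' @export
run_driven <- function(reservoir, initial_state, input) {
  stopifnot(inherits(reservoir, "rbn_reservoir"), length(input) >= 1L)
  out <- .rbn_simulate(reservoir$pre, reservoir$w, reservoir$w_in,
                       as.integer(initial_state), as.numeric(input),
                       reservoir$readout_idx)
  list(trace = activity_trace(out$counts, reservoir$config$n_neurons, 0L),
       history = out$history)
}

#' @export
print.rbn_reservoir <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "RBN reservoir: N = %d, K = %d, sigma* = %s, seed = %d\n",
    cfg$n_neurons, cfg$in_degree, format(cfg$sigma_star), cfg$seed))
  invisible(x)
}
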