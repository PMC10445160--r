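#' Analytic excitatory/inhibitory balance for a given sigma*
#'
#' The balance is the signed fraction b = (S+ - S-)/S of excitatory minus
#' inhibitory synapses. For weights w ~ N(sign(sigma*), |sigma*|) the
#' expected balance is
#'
#'   b = P(w > 0) - P(w < 0) = 2 Phi(1/sigma*) - 1,
#'
#' with Phi the standard normal CDF. b is antisymmetric in sigma*, tends to
#' +/-1 as sigma* -> 0 from either side, and to 0 as |sigma*| -> infinity;
#' the perfectly balanced zero-mean case has b = 0 exactly.
#'
#' @param sigma_star nonzero ratio sigma/mu, or `"balanced"`.
#' @param n_neurons,in_degree optional network dimensions; if given, the
#'   report carries the total synapse count S = K * N.
#' @return object of class `balance_report`: `b`, `excitatory_fraction`,
#'   `inhibitory_fraction`, `total_synapses`.
#' @examples
#' balance_from_sigma_star(-0.66)$b   # about -0.87 (94% inhibitory)
#' balance_from_sigma_star(4.0)$b     # about +0.20 (60% excitatory)
#' @export
balance_from_sigma_star <- function(sigma_star, n_neurons = NULL,
                                    in_degree = NULL) {
  if (identical(sigma_star, "balanced")) {
    p_exc <- 0.5
  } else {
    canonical_params(sigma_star)  # validates
    p_exc <- pnorm(1 / sigma_star)
  }
  S <- if (is.null(n_neurons) || is.null(in_degree)) NA_real_
       else as.numeric(n_neurons) * as.numeric(in_degree)
  new_balance_report(p_exc, S)
}

new_balance_report <- function(excitatory_fraction, total_synapses) {
  structure(list(b = 2 * excitatory_fraction - 1,
                 excitatory_fraction = excitatory_fraction,
                 inhibitory_fraction = 1 - excitatory_fraction,
                 total_synapses = total_synapses),
            class = "balance_report")
}

#' Empirical balance of a generated reservoir
#'
#' Counts the strictly positive and strictly negative recurrent weights of a
#' reservoir (the weight distribution is continuous, so exact zeros do not
#' occur) and reports the observed signed balance b = (S+ - S-)/S over the
#' S = K * N synapses.
#'
#' @param reservoir an `rbn_reservoir`.
#' @return a `balance_report`.
#' @export
empirical_balance <- function(reservoir) {
  stopifnot(inherits(reservoir, "rbn_reservoir"))
  S_plus <- sum(reservoir$w > 0)
  S <- length(reservoir$w)
  new_balance_report(S_plus / S, S)
}

#' Balance-versus-sigma* curve
#'
#' Tabulates the analytic balance over a grid, optionally alongside the
#' empirical balance of one generated reservoir per grid point so the two
#' routes can be audited side by side.
#'
#' @param sigma_grid numeric vector of nonzero sigma* values.
#' @param empirical_n,empirical_k if both non-NULL, also generate a reservoir
#'   (N = `empirical_n`, K = `empirical_k`) per grid point and record its
#'   counted balance.
#' @param seed master seed for the empirical reservoirs.
#' @param file optional path; if given the table is written as CSV.
#' @return data.frame with columns `sigma_star`, `b` (analytic) and, when
#'   requested, `b_empirical`.
#' @export
balance_curve <- function(sigma_grid, empirical_n = NULL, empirical_k = NULL,
                          seed = 1L, file = NULL) {
  out <- data.frame(
    sigma_star = sigma_grid,
    b = vapply(sigma_grid, function(s) balance_from_sigma_star(s)$b, 0))
  if (!is.null(empirical_n) && !is.null(empirical_k)) {
    seeds <- seed_stream(seed, length(sigma_grid))
    out$b_empirical <- vapply(seq_along(sigma_grid), function(i) {
      r <- generate_reservoir(empirical_n, empirical_k, sigma_grid[i],
                              seeds[i])
      empirical_balance(r)$b
    }, 0)
  }
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("balance b = %+.4f (%.1f%% excitatory, %.1f%% inhibitory)\n",
              x$b, 100 * x$excitatory_fraction, 100 * x$inhibitory_fraction))
  invisible(x)
}
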