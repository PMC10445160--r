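#' Free-run ensemble statistics at one value of sigma*
#'
#' Generates `n_reservoirs` independent reservoirs at the same sigma*, runs
#' each once from a random 20%-active initial state, and aggregates the
#' steady-window statistics: the reservoir averages of the time-mean
#' activity and its time variance, the mean BiEntropy of the binarized
#' steady activity, and the across-reservoir variance of that BiEntropy
#' (population convention, divide by n). The BiEntropy variance is the
#' order/disorder susceptibility whose peak locates the critical points.
#'
#' @param sigma_star control parameter (or `"balanced"`).
#' @param n_reservoirs ensemble size (reference protocol: 100).
#' @param n_neurons,in_degree network dimensions.
#' @param n_transient,n_steady run lengths (reference: 1,000 each).
#' @param active_fraction initial active fraction (reference: 0.2).
#' @param seed master seed; per-reservoir seeds come from [seed_stream()].
#' @param seed_offset offset into the master seed stream, used by
#'   [scan_phase()] to give each grid point a disjoint seed block.
#' @return one-row data.frame: `sigma_star`, `n_reservoirs`,
#'   `mean_activity`, `activity_variance`, `mean_bientropy`,
#'   `bientropy_variance`.
#' @export
ensemble_stats <- function(sigma_star, n_reservoirs, n_neurons,
                           in_degree = 16L, n_transient = 1000L,
                           n_steady = 1000L, active_fraction = 0.2,
                           seed = 1L, seed_offset = 0L) {
  stopifnot(n_reservoirs >= 2L)
  seeds <- seed_stream(seed, 2L * n_reservoirs, offset = seed_offset)
  a_bar <- da2 <- hb <- numeric(n_reservoirs)
  for (i in seq_len(n_reservoirs)) {
    r <- generate_reservoir(n_neurons, in_degree, sigma_star,
                            seed = seeds[2L * i - 1L])
    x0 <- init_state(n_neurons, active_fraction, seed = seeds[2L * i])
    tr <- run_free(r, x0, n_transient, n_steady)
    s <- steady_stats(tr)
    a_bar[i] <- s[["mean_activity"]]
    da2[i] <- s[["activity_variance"]]
    hb[i] <- bientropy(binarize_trace(tr))
  }
  sig <- if (identical(sigma_star, "balanced")) NA_real_ else sigma_star
  data.frame(sigma_star = sig,
             n_reservoirs = n_reservoirs,
             mean_activity = mean(a_bar),
             activity_variance = mean(da2),
             mean_bientropy = mean(hb),
             bientropy_variance = mean((hb - mean(hb))^2))
}

#' Locate the critical point and critical region on a sigma* scan
#'
#' The critical point is the grid value maximizing the across-reservoir
#' BiEntropy variance; ties go to the leftmost grid point and are flagged.
#' The critical region is the maximal contiguous grid interval containing
#' the peak on which the variance exceeds `region_threshold` times the peak
#' value (a robust stand-in for "nonzero" under finite sampling).
#'
#' @param stats data.frame as returned by [scan_phase()]/[ensemble_stats()],
#'   with columns `sigma_star` and `bientropy_variance`, sorted or not.
#' @param region_threshold fraction of the peak variance defining the
#'   region (default 0.01).
#' @return object of class `criticality_report`: `critical_point`,
#'   `critical_region` (length-2 vector), `region_width`, `peak_variance`,
#'   `tie` flag, `region_threshold`.
#' @export
locate_critical <- function(stats, region_threshold = 0.01) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 3L)
  stats <- stats[order(stats$sigma_star), ]
  v <- stats$bientropy_variance
  g <- stats$sigma_star
  if (all(v == 0))
    stop(structure(class = c("rbncrit_no_transition", "error", "condition"),
                   list(message = "no transition: BiEntropy variance is zero everywhere",
                        call = sys.call(-1))))
  peak <- max(v)
  idx <- which(v == peak)
  in_region <- v > region_threshold * peak
  # contiguous run containing the (leftmost) peak
  i0 <- i1 <- idx[1L]
  while (i0 > 1L && in_region[i0 - 1L]) i0 <- i0 - 1L
  while (i1 < length(v) && in_region[i1 + 1L]) i1 <- i1 + 1L
  structure(list(critical_point = g[idx[1L]],
                 critical_region = c(g[i0], g[i1]),
                 region_width = g[i1] - g[i0],
                 peak_variance = peak,
                 tie = length(idx) > 1L,
                 region_threshold = region_threshold),
            class = "criticality_report")
}

#' Phase scan over a sigma* grid
#'
#' Runs [ensemble_stats()] at each grid value and locates the critical
#' point/region from the BiEntropy-variance curve. Recommended grid steps:
#' 0.01 around the negative critical point, 0.1 on the (much wider)
#' positive side.
#'
#' @param sigma_grid numeric vector of sigma* values.
#' @param n_reservoirs ensemble size per grid point.
#' @param n_neurons,in_degree,n_transient,n_steady,active_fraction passed to
#'   [ensemble_stats()].
#' @param seed master seed; grid point i uses a disjoint seed block.
#' @param region_threshold passed to [locate_critical()].
#' @param file optional CSV path for the phase table.
#' @return list with `stats` (data.frame, one row per grid value) and
#'   `criticality` (a `criticality_report`).
#' @export
scan_phase <- function(sigma_grid, n_reservoirs = 20L, n_neurons = 2000L,
                       in_degree = 16L, n_transient = 1000L,
                       n_steady = 1000L, active_fraction = 0.2, seed = 1L,
                       region_threshold = 0.01, file = NULL) {
  rows <- lapply(seq_along(sigma_grid), function(i) {
    ensemble_stats(sigma_grid[i], n_reservoirs, n_neurons, in_degree,
                   n_transient, n_steady, active_fraction,
                   seed = seed, seed_offset = (i - 1L) * 2L * n_reservoirs)
  })
  stats <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(stats, file, row.names = FALSE)
  list(stats = stats,
       criticality = locate_critical(stats, region_threshold))
}

#' @export
print.criticality_report <- function(x, ...) {
  cat(sprintf(
    "critical point sigma* = %g (peak BiEntropy variance %.3g)%s\n",
    x$critical_point, x$peak_variance,
    if (x$tie) " [tie at peak, leftmost reported]" else ""))
  cat(sprintf("critical region: [%g, %g], width %g (threshold %g of peak)\n",
              x$critical_region[1], x$critical_region[2], x$region_width,
              x$region_threshold))
  invisible(x)
}
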