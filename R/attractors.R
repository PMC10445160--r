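ATTRACTOR_CATEGORIES <- c("extinguished", "fixed", "cyclic", "irregular")

#' Minimal period of a steady activity sequence
#'
#' Finds the smallest p with 1 <= p <= floor(W/2) such that
#' `A(t) = A(t + p)` for every valid t, using exact integer equality on the
#' active-count representation. Periods longer than half the window are not
#' testable and return `NA` (such traces are classified irregular).
#'
#' @param counts integer activity counts over the steady window (W >= 4).
#' @return minimal period, or `NA_integer_` if none is found.
#' @export
detect_period <- function(counts) {
  counts <- as.integer(counts)
  W <- length(counts)
  stopifnot(W >= 4L)
  for (p in seq_len(W %/% 2L)) {
    if (all(counts[seq_len(W - p)] == counts[(p + 1L):W]))
      return(p)
  }
  NA_integer_
}

#' Classify the steady-state activity into an attractor category
#'
#' Four categories: `extinguished` (steady activity identically zero),
#' `fixed` (constant nonzero activity, including the saturated state
#' A = 1), `cyclic` (minimal period between 2 and half the window), and
#' `irregular` (no period found within the window — either chaotic or a
#' cycle longer than the observation can resolve).
#'
#' @param trace an `activity_trace`.
#' @return object of class `attractor_label`: `category` and `period`
#'   (`NA` unless cyclic).
#' @export
classify_trace <- function(trace) {
  a <- steady_counts(trace)
  if (all(a == 0L))
    return(new_attractor_label("extinguished"))
  p <- detect_period(a)
  if (is.na(p)) return(new_attractor_label("irregular"))
  if (p == 1L) return(new_attractor_label("fixed"))
  new_attractor_label("cyclic", p)
}

new_attractor_label <- function(category, period = NA_integer_) {
  structure(list(category = category, period = as.integer(period)),
            class = "attractor_label")
}

#' Dominant attractor of a reservoir over many initial conditions
#'
#' The modal category over the runs; ties are broken toward the earlier
#' category in the fixed order extinguished < fixed < cyclic < irregular
#' (increasing dynamical complexity) and flagged.
#'
#' @param labels list of `attractor_label`s, or a character vector of
#'   categories.
#' @return object of class `dominant_attractor`: `label` (category),
#'   `dominance` (modal fraction), `counts` (per category), `tie` flag.
#' @export
dominant_attractor <- function(labels) {
  if (is.list(labels))
    labels <- vapply(labels, function(l) l$category, "")
  stopifnot(length(labels) >= 1L, all(labels %in% ATTRACTOR_CATEGORIES))
  counts <- table(factor(labels, levels = ATTRACTOR_CATEGORIES))
  top <- max(counts)
  winners <- names(counts)[counts == top]
  structure(list(label = winners[1L],
                 dominance = top / length(labels),
                 counts = counts,
                 tie = length(winners) > 1L),
            class = "dominant_attractor")
}

#' Pooled attractor distribution of an ensemble at one sigma*
#'
#' Generates `n_reservoirs` reservoirs, runs each from `n_init` random
#' initial states, classifies every steady activity, and pools category
#' fractions over all (reservoir x initial condition) runs.
#'
#' @inheritParams ensemble_stats
#' @param n_init number of random initial conditions per reservoir.
#' @return list with `fractions` (named numeric summing to 1), `runs`
#'   (long data.frame: reservoir_id, init_id, category, period) and
#'   `dominant` (data.frame: reservoir_id, label, dominance, tie).
#' @export
attractor_distribution <- function(sigma_star, n_reservoirs, n_init,
                                   n_neurons, in_degree = 16L,
                                   n_transient = 1000L, n_steady = 1000L,
                                   active_fraction = 0.2, seed = 1L,
                                   seed_offset = 0L) {
  stopifnot(n_reservoirs >= 1L, n_init >= 1L)
  seeds <- seed_stream(seed, n_reservoirs * (n_init + 1L),
                       offset = seed_offset)
  runs <- vector("list", n_reservoirs)
  dom <- vector("list", n_reservoirs)
  k <- 0L
  for (i in seq_len(n_reservoirs)) {
    k <- k + 1L
    r <- generate_reservoir(n_neurons, in_degree, sigma_star,
                            seed = seeds[k])
    labels <- vector("list", n_init)
    for (j in seq_len(n_init)) {
      k <- k + 1L
      x0 <- init_state(n_neurons, active_fraction, seed = seeds[k])
      labels[[j]] <- classify_trace(run_free(r, x0, n_transient, n_steady))
    }
    runs[[i]] <- data.frame(
      reservoir_id = i, init_id = seq_len(n_init),
      category = vapply(labels, function(l) l$category, ""),
      period = vapply(labels, function(l) l$period, 0L))
    d <- dominant_attractor(labels)
    dom[[i]] <- data.frame(reservoir_id = i, label = d$label,
                           dominance = d$dominance, tie = d$tie)
  }
  runs <- do.call(rbind, runs)
  fr <- table(factor(runs$category, levels = ATTRACTOR_CATEGORIES))
  list(fractions = c(fr / sum(fr)),
       runs = runs,
       dominant = do.call(rbind, dom))
}

#' Attractor landscape over a sigma* grid
#'
#' Runs [attractor_distribution()] at each grid value; returns the long
#' classification table, the per-sigma* pooled distribution (one row per
#' grid value with one column per category) and the per-reservoir dominant
#' attractors.
#'
#' @inheritParams scan_phase
#' @param n_init initial conditions per reservoir.
#' @param file optional base path; if given, writes `<file>_runs.csv` and
#'   `<file>_distribution.csv`.
#' @return list with `runs`, `distribution`, `dominant` data.frames.
#' @export
scan_attractors <- function(sigma_grid, n_reservoirs = 20L, n_init = 20L,
                            n_neurons = 2000L, in_degree = 16L,
                            n_transient = 1000L, n_steady = 1000L,
                            active_fraction = 0.2, seed = 1L, file = NULL) {
  block <- n_reservoirs * (n_init + 1L)
  res <- lapply(seq_along(sigma_grid), function(i) {
    attractor_distribution(sigma_grid[i], n_reservoirs, n_init, n_neurons,
                           in_degree, n_transient, n_steady,
                           active_fraction, seed = seed,
                           seed_offset = (i - 1L) * block)
  })
  runs <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(sigma_star = sigma_grid[i], res[[i]]$runs)))
  distribution <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(sigma_star = sigma_grid[i], t(res[[i]]$fractions))))
  dominant <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(sigma_star = sigma_grid[i], res[[i]]$dominant)))
  if (!is.null(file)) {
    write.csv(runs, paste0(file, "_runs.csv"), row.names = FALSE)
    write.csv(distribution, paste0(file, "_distribution.csv"),
              row.names = FALSE)
  }
  list(runs = runs, distribution = distribution, dominant = dominant)
}

#' @export
print.attractor_label <- function(x, ...) {
  cat(x$category,
      if (!is.na(x$period)) sprintf("(period %d)", x$period) else "", "\n")
  invisible(x)
}

#' @export
print.dominant_attractor <- function(x, ...) {
  cat(sprintf("dominant attractor: %s (dominance %.2f)%s\n", x$label,
              x$dominance, if (x$tie) " [tie]" else ""))
  invisible(x)
}
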