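#' Population-activity trace of a reservoir run
#'
#' Stores the activity as exact integer active-neuron counts so that
#' periodicity checks downstream use exact equality; `A(t) = counts/N` is a
#' multiple of 1/N in \[0, 1\]. The first `n_transient` steps are the burn-in;
#' the remainder is the steady window on which all statistics are computed.
#'
#' @param counts integer vector of active-neuron counts per step.
#' @param n_neurons network size N.
#' @param n_transient number of leading steps to exclude from statistics.
#' @return object of class `activity_trace`.
#' @export
activity_trace <- function(counts, n_neurons, n_transient = 0L) {
  counts <- as.integer(counts)
  n_transient <- as.integer(n_transient)
  if (any(counts < 0L | counts > n_neurons))
    stop("activity counts must lie in [0, n_neurons]", call. = FALSE)
  if (n_transient < 0L || n_transient >= length(counts))
    stop("steady window must be nonempty", call. = FALSE)
  structure(list(counts = counts, n_neurons = as.integer(n_neurons),
                 n_transient = n_transient),
            class = "activity_trace")
}

#' Steady-window active counts of a trace
#' @param trace an `activity_trace`.
#' @return integer vector of counts after the transient.
#' @export
steady_counts <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  trace$counts[(trace$n_transient + 1L):length(trace$counts)]
}

#' Activity values A(t) of a trace
#' @param trace an `activity_trace`.
#' @param steady_only drop the transient window?
#' @return numeric vector of activity fractions in \[0, 1\].
#' @export
activity <- function(trace, steady_only = FALSE) {
  stopifnot(inherits(trace, "activity_trace"))
  v <- if (steady_only) steady_counts(trace) else trace$counts
  v / trace$n_neurons
}

#' Time mean and time variance of the steady activity
#'
#' Computes the time average A-bar of the steady-window activity and its
#' time variance mean((A - A-bar)^2) (population convention: divide by the
#' window length).
#'
#' @param trace an `activity_trace`.
#' @return named numeric vector `c(mean_activity, activity_variance)`.
#' @export
steady_stats <- function(trace) {
  a <- activity(trace, steady_only = TRUE)
  m <- mean(a)
  c(mean_activity = m, activity_variance = mean((a - m)^2))
}

#' @export
print.activity_trace <- function(x, ...) {
  s <- steady_stats(x)
  cat(sprintf(
    "activity trace: %d steps (%d transient), steady mean A = %.4f, var = %.3g\n",
    length(x$counts), x$n_transient, s[1], s[2]))
  invisible(x)
}
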