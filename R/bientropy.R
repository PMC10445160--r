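#' BiEntropy of a binary string
#'
#' Croll's order/disorder measure for bit streams: the Shannon entropies of
#' the string and of its successive binary derivatives (pairwise XOR of
#' adjacent bits), combined with weights that emphasise the higher
#' derivatives. It is 0 for fully ordered streams (constant or
#' single-period), near 1 for algorithmically disordered ones.
#'
#' Two weightings are used. The power-weighted form (BiEn),
#' `sum_k H(p_k) 2^k / (2^(n-1) - 1)`, is exact for short strings but its
#' weights overflow doubles beyond a few dozen bits; the logarithmic form
#' (TBiEn), `sum_k H(p_k) log2(k + 2) / sum_k log2(k + 2)`, is the
#' prescription for long streams. `bientropy()` selects BiEn for strings of
#' at most `power_max` bits and TBiEn above, which is the convention used by
#' all ensemble statistics here (steady windows are ~1,000 bits).
#'
#' @param bits integer/logical vector of bits (length >= 2).
#' @param power_max longest string evaluated with the power-weighted form.
#' @return entropy value in \[0, 1\].
#' @examples
#' bientropy(rep(0, 8))                    # 0: fully ordered
#' bientropy(rep(c(0, 1), 4))              # 1/127: only the k = 0 term
#' @export
bientropy <- function(bits, power_max = 32L) {
  bits <- check_bits(bits)
  if (length(bits) <= power_max) bien(bits) else tbien(bits)
}

check_bits <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 2L)
    stop("BiEntropy needs at least 2 bits", call. = FALSE)
  if (any(bits != 0L & bits != 1L))
    stop("input must be binary", call. = FALSE)
  bits
}

# p(1) entropies of the string and its n-2 successive binary derivatives
derivative_entropies <- function(bits) {
  n <- length(bits)
  h <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    h[k] <- shannon_bit(mean(bits))
    bits <- xor(bits[-1L], bits[-length(bits)])
  }
  h
}

shannon_bit <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' @rdname bientropy
#' @export
bien <- function(bits) {
  bits <- check_bits(bits)
  n <- length(bits)
  h <- derivative_entropies(bits)
  sum(h * 2^(seq_len(n - 1L) - 1L)) / (2^(n - 1) - 1)
}

#' @rdname bientropy
#' @export
tbien <- function(bits) {
  bits <- check_bits(bits)
  n <- length(bits)
  w <- log2(seq_len(n - 1L) + 1)  # log2(k + 2), k = 0..n-2
  h <- derivative_entropies(bits)
  sum(h * w) / sum(w)
}

#' Binarize the steady activity of a trace
#'
#' Thresholds the steady-window activity at its own time mean:
#' `s(t) = 1` iff `A(t) > A-bar`. Constant traces (fixed points, saturated
#' or extinguished activity) map to the all-zero string; period-2
#' oscillations map to alternating strings.
#'
#' @param trace an `activity_trace`.
#' @return integer bit vector, one bit per steady-window step.
#' @export
binarize_trace <- function(trace) {
  a <- steady_counts(trace)
  as.integer(a > mean(a))
}
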