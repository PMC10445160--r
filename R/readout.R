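#' Train the sigmoid linear readout by full-batch ADAM
#'
#' The readout is a single unit `y(t) = f(W x(t) + c)` with the logistic
#' `f(z) = 1/(1 + exp(-z))`, reading the binary states of the readout half.
#' Training minimizes the mean squared error against targets in (0, 1) by
#' full-batch gradient descent with ADAM (moment constants 0.9/0.999,
#' epsilon 1e-8), starting from zero weights and bias, so the result is
#' deterministic given the inputs. Defaults follow the reference protocol:
#' learning rate 0.001, 4,000 epochs, no early stopping.
#'
#' @param states L x M binary state matrix (rows = time, columns = readout
#'   neurons).
#' @param targets length-L target vector, values in (0, 1).
#' @param alpha learning rate.
#' @param epochs number of full-batch epochs.
#' @param record_loss keep the per-epoch loss curve?
#' @return object of class `readout_model`: `weights` (length M), `bias`,
#'   `hyperparams`, and `loss` when recorded.
#' @export
train_readout <- function(states, targets, alpha = 0.001, epochs = 4000L,
                          record_loss = FALSE) {
  states <- as.matrix(states)
  L <- nrow(states)
  stopifnot(L == length(targets), alpha > 0, epochs >= 1L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  M <- ncol(states)
  w <- numeric(M); c0 <- 0
  mw <- vw <- numeric(M); mc <- vc <- 0
  loss <- if (record_loss) numeric(epochs) else NULL
  for (e in seq_len(epochs)) {
    z <- drop(states %*% w) + c0
    y <- 1 / (1 + exp(-z))
    err <- y - targets
    if (record_loss) loss[e] <- mean(err^2)
    if (!all(is.finite(err)))
      stop("readout training diverged (non-finite loss); lower alpha",
           call. = FALSE)
    dz <- (2 / L) * err * y * (1 - y)
    gw <- drop(crossprod(states, dz))
    gc <- sum(dz)
    mw <- b1 * mw + (1 - b1) * gw;  vw <- b2 * vw + (1 - b2) * gw^2
    mc <- b1 * mc + (1 - b1) * gc;  vc <- b2 * vc + (1 - b2) * gc^2
    corr1 <- 1 - b1^e; corr2 <- 1 - b2^e
    w <- w - alpha * (mw / corr1) / (sqrt(vw / corr2) + eps)
    c0 <- c0 - alpha * (mc / corr1) / (sqrt(vc / corr2) + eps)
  }
  structure(list(weights = w, bias = c0,
                 hyperparams = list(alpha = alpha, epochs = epochs,
                                    optimizer = "adam"),
                 loss = loss),
            class = "readout_model")
}

#' Closed-form ridge readout on the logit scale (test oracle)
#'
#' A non-iterative alternative trainer used as an independent cross-check
#' of the gradient trainer: since `f` is invertible on (0, 1), fitting
#' `W x + c` to `logit(T)` by ridge-regularized least squares gives a
#' readout whose sigmoid output approximates the targets directly.
#'
#' @param states L x M binary state matrix.
#' @param targets length-L target vector in (0, 1).
#' @param lambda ridge penalty (the intercept is unpenalized).
#' @return a `readout_model`.
#' @export
ridge_readout <- function(states, targets, lambda = 1e-6) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(targets),
            all(targets > 0 & targets < 1))
  z <- log(targets / (1 - targets))
  X <- cbind(1, states)
  M <- ncol(states)
  A <- crossprod(X) + diag(c(0, rep(lambda, M)))
  beta <- solve(A, crossprod(X, z))
  structure(list(weights = drop(beta[-1L]), bias = beta[1L],
                 hyperparams = list(lambda = lambda, optimizer = "ridge")),
            class = "readout_model")
}

#' Readout output for a state history
#' @param object a `readout_model`.
#' @param states L x M state matrix.
#' @param ... unused.
#' @return length-L output y(t) in (0, 1).
#' @export
predict.readout_model <- function(object, states, ...) {
  z <- drop(as.matrix(states) %*% object$weights) + object$bias
  1 / (1 + exp(-z))
}

#' Performance score Corr(y, T)
#'
#' Pearson correlation between the readout output and the target: 1 for a
#' perfect (up to increasing affine transform) match, ~0 for an unrelated
#' output. If either side has zero variance the correlation is defined
#' as 0.
#'
#' @param y readout output.
#' @param target target series.
#' @return correlation in \[-1, 1\].
#' @export
eval_corr <- function(y, target) {
  stopifnot(length(y) == length(target))
  if (sd(y) == 0 || sd(target) == 0) return(0)
  cor(y, target)
}

#' Task specification for memory/prediction benchmarks
#'
#' @param kind `"memory"` (white-noise input, delta < 0) or `"prediction"`
#'   (Mackey-Glass input, delta > 0).
#' @param delta signed target shift in ticks.
#' @param tau Mackey-Glass delay (prediction only).
#' @param washout leading aligned samples excluded from training/scoring.
#' @param train,test training and held-out segment lengths.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(kind = c("memory", "prediction"), delta, tau = NULL,
                      washout = 1000L, train = 4000L, test = 1000L) {
  kind <- match.arg(kind)
  delta <- as.integer(delta)
  if (kind == "memory" && delta >= 0L)
    stop("memory tasks need delta < 0", call. = FALSE)
  if (kind == "prediction") {
    if (delta <= 0L) stop("prediction tasks need delta > 0", call. = FALSE)
    if (is.null(tau)) stop("prediction tasks need `tau`", call. = FALSE)
  }
  structure(list(kind = kind, delta = delta, tau = tau,
                 washout = as.integer(washout), train = as.integer(train),
                 test = as.integer(test)),
            class = "task_spec")
}

task_input <- function(task, seed) {
  L <- task$washout + task$train + task$test + abs(task$delta)
  if (task$kind == "memory") white_noise(L, seed = seed)
  else mackey_glass(L, tau = task$tau)
}

#' Run one reservoir on one task, averaged over input-weight tossings
#'
#' Protocol: the task input series is fixed per task seed; the reservoir is
#' run `n_tossings` times, each with an independent redraw of the input
#' weights (and a fresh 20%-active initial state), the readout is trained on
#' the training segment of the aligned (state, target) pairs (after a
#' washout) and scored by Corr(y, T) on the held-out test segment. The
#' record carries the mean and spread over tossings.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param task a [task_spec()].
#' @param n_tossings input-weight redraws (reference protocol: 5).
#' @param seed master seed (input series, tossings, initial states).
#' @param alpha,epochs readout training hyperparameters.
#' @param trainer `"adam"` (reference) or `"ridge"` (fast closed form).
#' @param score_on score on the held-out `"test"` segment (default) or on
#'   the `"train"` segment.
#' @return object of class `performance_record`: a one-row data.frame with
#'   reservoir metadata, task parameters, `corr_mean`, `corr_sd`,
#'   `n_tossings`, plus the per-tossing scores in `attr(, "corrs")`.
#' @export
run_task <- function(reservoir, task, n_tossings = 5L, seed = 1L,
                     alpha = 0.001, epochs = 4000L,
                     trainer = c("adam", "ridge"),
                     score_on = c("test", "train")) {
  stopifnot(inherits(reservoir, "rbn_reservoir"),
            inherits(task, "task_spec"))
  trainer <- match.arg(trainer)
  score_on <- match.arg(score_on)
  seeds <- seed_stream(seed, 2L * n_tossings + 1L)
  u <- task_input(task, seed = seeds[1L])
  al <- make_target(u, task$delta)
  n_tr <- task$washout + task$train
  idx_train <- (task$washout + 1L):n_tr
  idx_test <- (n_tr + 1L):(n_tr + task$test)
  if (score_on == "train") idx_test <- idx_train
  N <- reservoir$config$n_neurons
  corrs <- numeric(n_tossings)
  for (k in seq_len(n_tossings)) {
    r <- toss_input_weights(reservoir, seed = seeds[2L * k])
    x0 <- init_state(N, 0.2, seed = seeds[2L * k + 1L])
    hist <- run_driven(r, x0, u)$history
    X <- hist[al$times, , drop = FALSE]
    model <- if (trainer == "adam")
      train_readout(X[idx_train, , drop = FALSE], al$target[idx_train],
                    alpha = alpha, epochs = epochs)
    else
      ridge_readout(X[idx_train, , drop = FALSE], al$target[idx_train])
    y <- predict(model, X[idx_test, , drop = FALSE])
    corrs[k] <- eval_corr(y, al$target[idx_test])
  }
  rec <- data.frame(sigma_star = if (identical(reservoir$config$sigma_star,
                                               "balanced")) NA_real_
                                 else reservoir$config$sigma_star,
                    n_neurons = N,
                    kind = task$kind, delta = task$delta,
                    tau = if (is.null(task$tau)) NA_real_ else task$tau,
                    corr_mean = mean(corrs), corr_sd = sd(corrs),
                    n_tossings = n_tossings)
  attr(rec, "corrs") <- corrs
  class(rec) <- c("performance_record", class(rec))
  rec
}
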