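#' Task sweep over reservoir ensembles
#'
#' For each sigma* value, generates an ensemble of reservoirs, labels each
#' with its dominant free-run attractor (over `n_init` random initial
#' conditions), then runs every task on every reservoir with
#' [run_task()] (averaging over input-weight tossings). Away from the
#' positive critical region the across-reservoir spread of the scores is
#' expected to be near zero on the negative branch and large on the
#' positive branch.
#'
#' @param sigma_values numeric vector of sigma* values.
#' @param tasks list of [task_spec()]s.
#' @param n_reservoirs reservoirs per sigma*.
#' @param n_init free-run initial conditions for the dominant-attractor
#'   label.
#' @param n_neurons,in_degree network dimensions.
#' @param n_tossings input-weight redraws per (reservoir, task).
#' @param seed master seed.
#' @param trainer,alpha,epochs readout training settings (see [run_task()]).
#' @param file optional CSV path for the long performance table.
#' @return data.frame, one row per (sigma*, reservoir, task):
#'   `sigma_star`, `reservoir_id`, `dominant_attractor`, `dominance`,
#'   `kind`, `delta`, `tau`, `corr_mean`, `corr_sd`, `n_tossings`.
#' @export
run_task_sweep <- function(sigma_values, tasks, n_reservoirs = 10L,
                           n_init = 10L, n_neurons = 500L, in_degree = 16L,
                           n_tossings = 5L, seed = 1L,
                           trainer = "adam", alpha = 0.001, epochs = 4000L,
                           file = NULL) {
  stopifnot(length(tasks) >= 1L)
  block <- n_reservoirs * (n_init + 2L)
  rows <- list()
  for (si in seq_along(sigma_values)) {
    sig <- sigma_values[si]
    seeds <- seed_stream(seed, block, offset = (si - 1L) * block)
    k <- 0L
    for (ri in seq_len(n_reservoirs)) {
      k <- k + 1L
      r <- generate_reservoir(n_neurons, in_degree, sig, seed = seeds[k])
      labels <- vector("list", n_init)
      for (j in seq_len(n_init)) {
        k <- k + 1L
        x0 <- init_state(n_neurons, 0.2, seed = seeds[k])
        labels[[j]] <- classify_trace(run_free(r, x0))
      }
      dom <- dominant_attractor(labels)
      k <- k + 1L
      for (ti in seq_along(tasks)) {
        rec <- run_task(r, tasks[[ti]], n_tossings = n_tossings,
                        seed = seed_stream(seeds[k], 1L, offset = ti),
                        trainer = trainer, alpha = alpha, epochs = epochs)
        rec <- cbind(data.frame(reservoir_id = ri,
                                dominant_attractor = dom$label,
                                dominance = dom$dominance),
                     as.data.frame(rec))
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("sigma_star", "reservoir_id", "dominant_attractor",
                 "dominance", "kind", "delta", "tau", "corr_mean",
                 "corr_sd", "n_tossings")]
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Cross-task performance pairing
#'
#' Runs a memory task and a prediction task on the same reservoirs at
#' matched difficulty and pairs the scores per reservoir, to ask whether
#' reservoirs good at one task are good at the other. Default difficulty
#' pairs follow the reference levels: simple (tau = 5, delta = -2), average
#' (tau = 20, delta = -6), difficult (tau = 28, delta = -10), with the
#' prediction shift fixed at +10.
#'
#' @param sigma_values sigma* values for the shared reservoir ensembles.
#' @param pairs data.frame with columns `tau` and `delta_memory` (one row
#'   per difficulty level); `delta_prediction` is fixed at +10.
#' @param ... passed to [run_task_sweep()] (`n_reservoirs`, `n_neurons`,
#'   `trainer`, ...).
#' @param washout,train,test task segment lengths.
#' @param file optional CSV path.
#' @return data.frame, one row per (sigma*, reservoir, difficulty pair):
#'   memory and prediction scores side by side with the dominant attractor.
#' @export
cross_task <- function(sigma_values,
                       pairs = data.frame(tau = c(5, 20, 28),
                                          delta_memory = c(-2L, -6L, -10L)),
                       washout = 1000L, train = 4000L, test = 1000L,
                       ..., file = NULL) {
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    tasks <- list(
      task_spec("memory", delta = pairs$delta_memory[p],
                washout = washout, train = train, test = test),
      task_spec("prediction", delta = 10L, tau = pairs$tau[p],
                washout = washout, train = train, test = test))
    sweep <- run_task_sweep(sigma_values, tasks, ...)
    mem <- sweep[sweep$kind == "memory", ]
    prd <- sweep[sweep$kind == "prediction", ]
    key <- c("sigma_star", "reservoir_id")
    merged <- merge(
      mem[, c(key, "dominant_attractor", "dominance", "corr_mean")],
      prd[, c(key, "corr_mean")],
      by = key, suffixes = c("_memory", "_prediction"))
    merged$tau <- pairs$tau[p]
    merged$delta_memory <- pairs$delta_memory[p]
    out[[p]] <- merged
  }
  out <- do.call(rbind, out)
  names(out)[names(out) == "corr_mean_memory"] <- "corr_memory"
  names(out)[names(out) == "corr_mean_prediction"] <- "corr_prediction"
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Write a reservoir to a directory of plain-text files
#'
#' Stores the synapse table, input weights and partition as CSV plus a JSON
#' sidecar with the configuration and seed; [read_reservoir()] validates the
#' invariants (fixed in-degree, equal disjoint halves, input-weight range)
#' on load.
#'
#' @param reservoir an `rbn_reservoir`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reservoir <- function(reservoir, dir) {
  stopifnot(inherits(reservoir, "rbn_reservoir"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- reservoir$config$in_degree
  N <- reservoir$config$n_neurons
  syn <- data.frame(post = rep(seq_len(N), each = K),
                    pre = as.integer(reservoir$pre),
                    weight = as.numeric(reservoir$w))
  write.csv(syn, file.path(dir, "synapses.csv"), row.names = FALSE)
  neurons <- data.frame(
    neuron = seq_len(N),
    role = ifelse(seq_len(N) %in% reservoir$input_idx, "input", "readout"),
    w_in = reservoir$w_in)
  write.csv(neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(reservoir$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reservoir written by [write_reservoir()]
#' @param dir directory containing `synapses.csv`, `neurons.csv`,
#'   `config.json`.
#' @return an `rbn_reservoir`.
#' @export
read_reservoir <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  syn <- read.csv(file.path(dir, "synapses.csv"))
  neurons <- read.csv(file.path(dir, "neurons.csv"))
  N <- as.integer(cfg$n_neurons); K <- as.integer(cfg$in_degree)
  if (nrow(syn) != N * K || !all(table(syn$post) == K))
    stop("corrupt reservoir: in-degree is not uniform", call. = FALSE)
  input_idx <- neurons$neuron[neurons$role == "input"]
  readout_idx <- neurons$neuron[neurons$role == "readout"]
  if (length(input_idx) != N %/% 2L ||
      length(intersect(input_idx, readout_idx)) > 0L)
    stop("corrupt reservoir: input/readout halves are not a partition",
         call. = FALSE)
  if (any(abs(neurons$w_in) > 0.5))
    stop("corrupt reservoir: input weights outside [-0.5, 0.5]",
         call. = FALSE)
  ord <- order(syn$post)
  syn <- syn[ord, ]
  structure(list(
    pre = matrix(as.integer(syn$pre), nrow = K),
    w = matrix(syn$weight, nrow = K),
    w_in = neurons$w_in[order(neurons$neuron)],
    input_idx = sort(input_idx), readout_idx = sort(readout_idx),
    config = rbn_config(N, K, cfg$sigma_star, cfg$seed)),
    class = "rbn_reservoir")
}
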