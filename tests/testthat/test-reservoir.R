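test_that("canonical parameters decompose sigma* into sign and magnitude", {
  expect_equal(canonical_params(-0.66), c(mu = -1, sigma = 0.66))
  expect_equal(canonical_params(4.0), c(mu = 1, sigma = 4.0))
  expect_equal(canonical_params("balanced"), c(mu = 0, sigma = 1))
  expect_error(canonical_params(0), "nonzero")
  expect_error(canonical_params(NaN), "nonzero")
  expect_error(canonical_params(Inf), "nonzero")
})

test_that("generated reservoirs satisfy the structural invariants", {
  r <- generate_reservoir(100, 16, -0.66, seed = 1)
  expect_equal(unname(colSums(r$w != 0)), rep(16, 100))
  # distinct presynaptic partners, no self-connections
  for (i in seq_len(100)) {
    expect_equal(anyDuplicated(r$pre[, i]), 0L)
    expect_false(i %in% r$pre[, i])
  }
  # equal disjoint halves
  expect_length(r$input_idx, 50)
  expect_length(r$readout_idx, 50)
  expect_length(intersect(r$input_idx, r$readout_idx), 0)
  # input weights: bounded, nonzero only on the input half, half zeroed
  expect_true(all(abs(r$w_in) <= 0.5))
  expect_true(all(r$w_in[r$readout_idx] == 0))
  expect_equal(sum(r$w_in[r$input_idx] == 0), 25)
})

test_that("reservoir generation is deterministic given the seed", {
  a <- generate_reservoir(80, 10, 2.5, seed = 7)
  b <- generate_reservoir(80, 10, 2.5, seed = 7)
  expect_identical(a, b)
  c <- generate_reservoir(80, 10, 2.5, seed = 8)
  expect_false(identical(a$w, c$w))
})

test_that("weight signs follow the Gaussian law for the canonical params", {
  # P(w > 0) = Phi(1/sigma*) for the canonical N(sign, |sigma*|) weights
  r <- generate_reservoir(2000, 16, 4.0, seed = 11)
  p_hat <- mean(r$w > 0)
  p <- pnorm(1 / 4.0)
  se <- sqrt(p * (1 - p) / length(r$w))
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("initial states contain exactly the requested active count", {
  expect_equal(sum(init_state(10, 0.2, seed = 1)), 2)
  expect_equal(sum(init_state(10, 0, seed = 1)), 0)
  expect_equal(sum(init_state(10, 1, seed = 1)), 10)
  expect_equal(sum(init_state(10, 0.25, seed = 1)), 3)  # round half up
  expect_error(init_state(10, 1.2), "active_fraction")
  expect_identical(init_state(50, 0.2, seed = 3), init_state(50, 0.2, seed = 3))
})

test_that("one update step matches a per-neuron hand evaluation", {
  # 3-neuron toy with enumerated weights
  pre <- matrix(c(2L, 3L,  1L, 3L,  1L, 2L), nrow = 2)
  w <- matrix(c(0.5, -1,  2, 0,  -0.3, 0.4), nrow = 2)
  res <- toy_reservoir(pre, w)
  x <- c(1L, 0L, 1L)
  # neuron 1: 0.5*x2 - 1*x3 = -1 -> 0; neuron 2: 2*x1 + 0*x3 = 2 -> 1
  # neuron 3: -0.3*x1 + 0.4*x2 = -0.3 -> 0
  expect_equal(rbn_step(res, x), c(0L, 1L, 0L))
  expect_equal(rbn_step(res, x), step_oracle(res, x))
  # theta(0) = 0: zero state with zero input stays zero
  expect_equal(rbn_step(res, c(0L, 0L, 0L)), c(0L, 0L, 0L))
  # strictly negative weights kill any state
  res_neg <- toy_reservoir(pre, -abs(w) - 0.1)
  expect_equal(rbn_step(res_neg, c(1L, 1L, 1L)), c(0L, 0L, 0L))
  expect_error(rbn_step(res, c(1L, 0L)), "state length")
})

test_that("compiled dynamics agree with the R oracle over a trajectory", {
  res <- small_reservoir(n = 60L, seed = 5L)
  x <- init_state(60, 0.3, seed = 9)
  for (t in 1:25) {
    nxt <- rbn_step(res, x)
    expect_identical(nxt, step_oracle(res, x))
    x <- nxt
  }
})

test_that("free dynamics are invariant under positive weight rescaling", {
  res <- small_reservoir(n = 80L, seed = 13L)
  scaled <- res
  scaled$w <- res$w * 37.5
  x0 <- init_state(80, 0.2, seed = 1)
  t1 <- run_free(res, x0, 50, 50)
  t2 <- run_free(scaled, x0, 50, 50)
  expect_identical(t1$counts, t2$counts)
  # driven case: scaling recurrent AND input weights preserves trajectories
  scaled$w_in <- res$w_in * 37.5
  u <- white_noise(60, seed = 2)
  d1 <- run_driven(res, x0, u)
  d2 <- run_driven(scaled, x0, u)
  expect_identical(d1$history, d2$history)
})

test_that("absorbing states behave as the threshold rule dictates", {
  res <- small_reservoir(n = 50L, seed = 21L)
  zero <- integer(50)
  expect_equal(rbn_step(res, zero), zero)  # all-off absorbs under no input
  # all-on absorbs when every neuron's total incoming weight is positive
  pos <- res
  pos$w <- abs(pos$w)
  expect_equal(rbn_step(pos, rep(1L, 50)), rep(1L, 50))
})

test_that("free runs record bounded 1/N-quantized activity and saturate or die", {
  r_up <- generate_reservoir(400, 16, 0.1, seed = 2)
  tr_up <- run_free(r_up, init_state(400, 0.2, seed = 3), 200, 200)
  expect_length(tr_up$counts, 400)
  a <- activity(tr_up)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(abs(a * 400 - round(a * 400)) < 1e-12))
  expect_true(all(activity(tr_up, steady_only = TRUE) == 1))  # saturated
  r_dn <- generate_reservoir(400, 16, -0.1, seed = 2)
  tr_dn <- run_free(r_dn, init_state(400, 0.2, seed = 3), 200, 200)
  expect_true(all(steady_counts(tr_dn) == 0))  # extinguished
})

test_that("driven runs align with the input and reduce to free runs at zero drive", {
  res <- small_reservoir(n = 100L, seed = 31L)
  x0 <- init_state(100, 0.2, seed = 4)
  free <- run_free(res, x0, 1, 79)
  driven <- run_driven(res, x0, numeric(80))
  expect_identical(driven$trace$counts, free$counts)
  u <- white_noise(37, seed = 5)
  d <- run_driven(res, x0, u)
  expect_equal(dim(d$history), c(37, 50))
  expect_true(all(d$history %in% 0:1))
})

test_that("input-weight tossing changes only the input weights", {
  res <- small_reservoir(n = 100L, seed = 41L)
  tossed <- toss_input_weights(res, seed = 99)
  expect_identical(tossed$w, res$w)
  expect_identical(tossed$pre, res$pre)
  expect_identical(tossed$input_idx, res$input_idx)
  expect_false(identical(tossed$w_in, res$w_in))
  expect_true(all(tossed$w_in[res$readout_idx] == 0))
  expect_true(all(abs(tossed$w_in) <= 0.5))
})

test_that("reservoir serialization round-trips and the loader validates", {
  res <- small_reservoir(n = 40L, seed = 51L)
  dir <- withr::local_tempdir()
  write_reservoir(res, dir)
  back <- read_reservoir(dir)
  expect_equal(back$pre, res$pre)
  expect_equal(back$w, res$w)
  expect_equal(back$w_in, res$w_in)
  expect_equal(back$input_idx, res$input_idx)
  # dynamics agree exactly after the round trip
  x0 <- init_state(40, 0.2, seed = 6)
  expect_identical(run_free(res, x0, 20, 20)$counts,
                   run_free(back, x0, 20, 20)$counts)
  # tampered input weight is rejected
  n <- read.csv(file.path(dir, "neurons.csv"))
  n$w_in[1] <- 2.0
  write.csv(n, file.path(dir, "neurons.csv"), row.names = FALSE)
  expect_error(read_reservoir(dir), "input weights")
})

test_that("config validation rejects impossible parameters", {
  expect_error(rbn_config(100, 100, 1, 1), "in_degree")
  expect_error(rbn_config(100, 0, 1, 1), "in_degree")
  expect_error(rbn_config(0, 16, 1, 1), "n_neurons")
  expect_error(rbn_config(100, 16, 0, 1), "nonzero")
})
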