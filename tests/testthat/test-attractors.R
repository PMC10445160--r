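test_that("minimal periods are found by exact integer matching", {
  expect_equal(detect_period(rep(c(3L, 5L), 3)), 2)
  expect_equal(detect_period(rep(7L, 8)), 1)
  expect_equal(detect_period(rep(c(1L, 2L, 3L), 4)), 3)
  # period 4 sequence is not reported as its sub-multiples
  expect_equal(detect_period(rep(c(1L, 2L, 1L, 3L), 3)), 4)
  expect_true(is.na(detect_period(c(1L, 5L, 2L, 8L, 3L, 9L, 4L))))
})

test_that("period detection agrees with an independent brute-force scan", {
  set.seed(11)
  for (i in 1:30) {
    base <- sample(0:6, sample(2:6, 1), replace = TRUE)
    a <- rep(base, length.out = sample(10:40, 1))
    if (i %% 3 == 0) a <- sample(0:50, sample(8:30, 1), replace = TRUE)
    expect_identical(detect_period(a), period_oracle(a))
  }
})

test_that("traces map onto the four attractor categories", {
  z <- activity_trace(c(5L, rep(0L, 8)), 10, 1)
  expect_equal(classify_trace(z)$category, "extinguished")
  sat <- activity_trace(c(2L, rep(10L, 8)), 10, 1)
  expect_equal(classify_trace(sat)$category, "fixed")  # saturated is fixed
  fix <- activity_trace(rep(4L, 9), 10, 1)
  expect_equal(classify_trace(fix)$category, "fixed")
  cyc <- activity_trace(c(2L, rep(c(30L, 32L), 5)), 100, 1)
  lab <- classify_trace(cyc)
  expect_equal(lab$category, "cyclic")
  expect_equal(lab$period, 2)
  irr <- activity_trace(c(1L, 5L, 2L, 8L, 3L, 9L, 4L, 7L, 6L), 10, 1)
  expect_equal(classify_trace(irr)$category, "irregular")
})

test_that("the dominant attractor is the modal category with the stated ties", {
  labs <- c(rep("cyclic", 60), rep("irregular", 40))
  d <- dominant_attractor(labs)
  expect_equal(d$label, "cyclic")
  expect_equal(d$dominance, 0.6)
  expect_false(d$tie)
  d1 <- dominant_attractor(rep("fixed", 100))
  expect_equal(d1$label, "fixed")
  expect_equal(d1$dominance, 1)
  # 50/50 tie resolves to the earlier category in the fixed order and flags
  d2 <- dominant_attractor(c(rep("fixed", 50), rep("cyclic", 50)))
  expect_equal(d2$label, "fixed")
  expect_true(d2$tie)
})

test_that("activity-level classification is consistent with exhaustive state cycles", {
  # tiny networks: find the true state-space cycle from each initial state
  # and check the activity classifier never reports a period incompatible
  # with it (the activity period must divide the state period)
  for (seed in c(1, 2, 3, 4)) {
    res <- generate_reservoir(10, 3, -0.66, seed = seed)
    for (s0 in 1:5) {
      x0 <- init_state(10, 0.3, seed = 100 * seed + s0)
      oracle <- state_cycle_oracle(res, x0)
      tr <- run_free(res, x0, n_transient = max(oracle$entry, 1),
                     n_steady = 200)
      lab <- classify_trace(tr)
      if (lab$category == "cyclic") {
        expect_equal(oracle$period %% lab$period, 0)
      } else if (lab$category %in% c("extinguished", "fixed")) {
        # constant activity on the cycle: all cycle states share one count
        cyc_counts <- oracle$counts[oracle$entry:length(oracle$counts)]
        expect_lte(length(unique(cyc_counts)), oracle$period)
      }
      # a state cycle that fits the window can never be labelled irregular
      if (oracle$period <= 100) expect_false(lab$category == "irregular")
    }
  }
})

test_that("irregular labels vanish once the window exceeds the true cycle", {
  res <- generate_reservoir(12, 4, "balanced", seed = 6)
  x0 <- init_state(12, 0.25, seed = 7)
  oracle <- state_cycle_oracle(res, x0)
  tr <- run_free(res, x0, n_transient = max(oracle$entry, 1),
                 n_steady = max(4L, 2L * oracle$period + 2L))
  expect_false(classify_trace(tr)$category == "irregular")
})

test_that("pooled attractor distributions behave across the phases", {
  # deep frozen phase: everything extinguishes
  frozen <- attractor_distribution(-0.2, n_reservoirs = 4, n_init = 5,
                                   n_neurons = 400, n_transient = 300,
                                   n_steady = 300, seed = 8)
  expect_equal(unname(frozen$fractions["extinguished"]), 1)
  expect_equal(sum(frozen$fractions), 1)
  expect_true(all(frozen$dominant$label == "extinguished"))
  expect_true(all(frozen$dominant$dominance == 1))
  # far disordered positive phase: irregular dominates (N large enough
  # that finite-size short cycles have vanished)
  dis <- attractor_distribution(6, n_reservoirs = 4, n_init = 5,
                                n_neurons = 1000, n_transient = 300,
                                n_steady = 300, seed = 9)
  expect_gte(unname(dis$fractions["irregular"]), 0.9)
  expect_equal(nrow(dis$runs), 20)
})

test_that("the attractor landscape table has the documented shape", {
  out <- scan_attractors(c(-0.3, -0.66), n_reservoirs = 3, n_init = 4,
                         n_neurons = 300, n_transient = 200,
                         n_steady = 200, seed = 10)
  expect_equal(nrow(out$runs), 2 * 3 * 4)
  expect_named(out$runs, c("sigma_star", "reservoir_id", "init_id",
                           "category", "period"))
  expect_equal(nrow(out$distribution), 2)
  expect_equal(unname(rowSums(out$distribution[, -1])), c(1, 1))
  expect_equal(nrow(out$dominant), 6)
})
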