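test_that("null cohort simulation is deterministic given the seed", {
  sp <- null_model_spec(n_agents = 5, seed = 99)
  expect_identical(simulate_null_cohort(sp), simulate_null_cohort(sp))
  sp2 <- null_model_spec(n_agents = 5, seed = 100)
  expect_false(identical(simulate_null_cohort(sp), simulate_null_cohort(sp2)))
})

test_that("uniform kernel visits every arm at its expected frequency", {
  sp <- null_model_spec(n_agents = 1300, n_trials_per_agent = 10, seed = 4)
  m <- simulate_null_cohort(sp)  # > 1e5 draws
  freq <- tabulate(as.vector(m) + 1L, 9) / length(m)
  se <- sqrt((1 / 9) * (8 / 9) / length(m))
  expect_true(all(abs(freq - 1 / 9) < 3.5 * se))
})

test_that("no-immediate-repeat kernel never produces offset-zero transitions", {
  sp <- null_model_spec(n_agents = 50, kernel = "no_repeat", seed = 7)
  m <- simulate_null_cohort(sp)
  expect_true(all(m[, -1] != m[, -ncol(m)]))
})

test_that("offset kernel draws follow the supplied weights", {
  w <- c(0, 0, 1, 0, 0, 0, 1, 0, 0)  # only +/-2 moves
  sp <- null_model_spec(n_agents = 30, kernel = "offset", weights = w, seed = 8)
  m <- simulate_null_cohort(sp)
  off <- ((m[, -1] - m[, -ncol(m)] + 4) %% 9) - 4
  expect_true(all(off %in% c(-2, 2)))
  expect_error(null_model_spec(n_agents = 2, kernel = "offset",
                               weights = rep(-1, 9)), "non-negative")
})

test_that("exact pooled length distribution has mode 2 and simulation agrees", {
  ex <- null_length_distribution()
  expect_equal(attr(ex, "mode"), 2L)
  sp <- null_model_spec(n_agents = 500, n_trials_per_agent = 16, seed = 21)
  h <- null_length_histogram(simulate_null_cohort(sp))
  p <- as.numeric(ex) / sum(ex)
  keep <- p > 5e-4  # fold negligible cells out of the chi-squared
  chi <- suppressWarnings(stats::chisq.test(
    c(as.numeric(h)[keep], sum(h[!keep])), p = c(p[keep], sum(p[!keep]))))
  expect_gt(chi$p.value, 0.001)
})

test_that("first-segment pmf is exact: closed form, simulation and edge cases", {
  pmf <- analytic_first_segment_pmf(9)
  expect_equal(sum(pmf), 1)
  expect_equal(unname(pmf[1]), 1 / 9)
  expect_equal(unname(which.max(pmf)), 3)  # first-segment mode differs from pooled
  # closed form matches an independent direct product evaluation
  direct <- vapply(1:8, function(k) prod((9 - seq_len(k) + 1) / 9) * k / 9,
                   numeric(1))
  expect_equal(unname(pmf[1:8]), direct)
  # two arms: lengths 1 or 2 only, each probability 1/2
  expect_equal(unname(analytic_first_segment_pmf(2)), c(0.5, 0.5))
  # simulated first segments match the pmf (chi-squared)
  sp <- null_model_spec(n_agents = 2000, n_trials_per_agent = 10, seed = 31)
  m <- simulate_null_cohort(sp)
  fs <- apply(m, 1, function(a) decompose_unique_sequences(a)$lengths[1])
  chi <- suppressWarnings(stats::chisq.test(tabulate(fs, 9), p = pmf))
  expect_gt(chi$p.value, 0.01)
})

test_that("pooled histogram is invariant to how trials are split across agents", {
  h1 <- null_length_histogram(simulate_null_cohort(
    null_model_spec(n_agents = 58, n_trials_per_agent = 16, seed = 12)))
  h2 <- null_length_histogram(simulate_null_cohort(
    null_model_spec(n_agents = 4, n_trials_per_agent = 232, seed = 12)))
  expect_equal(sum(h1), sum(h2))
  tab <- rbind(as.numeric(h1)[1:7], as.numeric(h2)[1:7])  # drop sparse tail
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
})

test_that("two-arm uniform kernel matches its analytic segment distribution", {
  sp <- null_model_spec(n_agents = 300, n_trials_per_agent = 10, n_arms = 2,
                        max_entries = 2, seed = 14)
  m <- simulate_null_cohort(sp)
  fs <- apply(m, 1, function(a) decompose_unique_sequences(a, 2)$lengths[1])
  p1 <- mean(fs == 1)
  se <- sqrt(0.25 / length(fs))
  expect_lt(abs(p1 - 0.5), 4 * se)
})

test_that("histogram mode ties are reported and broken toward the smaller length", {
  h <- null_length_histogram(list(c(0, 0), c(0, 1)), n_arms = 9)
  # lengths: [1,1] and [2] -> counts c(2, 1, ...): mode 1
  expect_equal(attr(h, "mode"), 1L)
  h2 <- null_length_histogram(list(c(0, 0, 1, 2)), n_arms = 9)
  # lengths [1, 3]: tie between 1 and 3 -> smaller reported first
  expect_equal(attr(h2, "mode"), 1L)
  expect_equal(attr(h2, "modes"), c(1L, 3L))
})
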