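test_that("decision time is mean over days of trial time per arm entry plus one", {
  b <- block_from_entries(list(0:8), t_trial = 600)
  expect_equal(decision_time(b), 60)
  # zero arm visits still yields a finite decision time
  b0 <- block_from_entries(list(integer(0)), t_trial = 600)
  expect_equal(decision_time(b0), 600)
  # two days average: 600/10 and 300/10
  b2 <- block_from_entries(list(0:8, 0:8), t_trial = c(600, 300))
  expect_equal(decision_time(b2), 45)
  expect_error(session_block(list()), "at least one trial")
})

test_that("errors count returns to already-visited arms", {
  expect_equal(count_errors(c(0, 1, 2, 3)), 0)
  expect_equal(count_errors(c(0, 1, 2, 1, 0)), 2)
  expect_equal(count_errors(integer(0)), 0)
  b <- block_from_entries(list(c(0, 1, 1), c(0, 1, 2)))
  expect_equal(mean_errors(b), 0.5)
})

test_that("unique-sequence decomposition parses greedily and partitions entries", {
  expect_equal(decompose_unique_sequences(0:8)$lengths, 9L)
  expect_equal(decompose_unique_sequences(c(0, 1, 2, 1, 3))$lengths, c(3L, 2L))
  expect_equal(decompose_unique_sequences(c(0, 0, 0))$lengths, c(1L, 1L, 1L))
  # partition property and error relation on random sequences: every segment
  # boundary is a within-segment repeat (hence an error), while returns to
  # arms from earlier segments add errors without closing a segment
  set.seed(71)
  for (i in 1:200) {
    a <- sample(0:8, sample(0:12, 1), replace = TRUE)
    d <- decompose_unique_sequences(a)
    expect_equal(sum(d$lengths), length(a))
    expect_equal(sum(d$counts), length(d$lengths))
    if (length(a)) expect_lte(length(d$lengths) - 1L, count_errors(a))
    expect_true(all(d$lengths >= 1 & d$lengths <= 9))
    # each boundary entry repeats an arm of the segment it closes
    pos <- cumsum(d$lengths)
    for (k in seq_len(max(length(d$lengths) - 1L, 0L))) {
      seg <- a[(pos[k] - d$lengths[k] + 1):pos[k]]
      expect_true(a[pos[k] + 1L] %in% seg)
    }
  }
})

test_that("unique-sequence score weights squared per-length counts", {
  # lengths [9] -> 9; [4,5] -> 9; [2,2,3] -> 11
  expect_equal(unique_sequence_score(block_from_entries(list(0:8))), 9)
  expect_equal(unique_sequence_score(
    block_from_entries(list(c(0, 1, 2, 3, 3, 4, 5, 6, 7)))), 9)
  expect_equal(unique_sequence_score(
    block_from_entries(list(c(0, 1, 1, 2, 2, 3, 4)))), 11)
  # block score is the mean of per-trial scores
  b <- block_from_entries(list(0:8, c(0, 1, 1, 2, 2, 3, 4)))
  expect_equal(unique_sequence_score(b), 10)
})

test_that("perfect performance is a fixed point of errors, USS and decomposition", {
  b <- block_from_entries(list(0:8, 0:8, 0:8))
  expect_equal(mean_errors(b), 0)
  expect_equal(unique_sequence_score(b), 9)
  expect_equal(decompose_unique_sequences(b$trials[[1]])$lengths, 9L)
})

test_that("learning rate is the sign-flipped slope of daily errors", {
  # errors 5,4,3,... decrease by 1/day -> +1
  days <- lapply(1:5, function(d) c(0:3, rep(0L, 6 - d)))  # 6-d repeats of arm 0
  b <- block_from_entries(days)
  errs <- vapply(b$trials, count_errors, numeric(1))
  expect_equal(diff(errs), rep(-1, 4))
  expect_equal(learning_rate(b), 1)
  # constant errors -> 0
  expect_equal(learning_rate(block_from_entries(list(c(0, 0), c(1, 1)))), 0)
  # errors rising 0.5/day -> -0.5 (0 errors on day 1, 1 error on day 3)
  b2 <- session_block(list(trial("m01", 4, 1, arms = c(0, 1), t_trial = 600),
                           trial("m01", 4, 3, arms = c(0, 1, 0), t_trial = 600)))
  expect_equal(learning_rate(b2), -0.5)
  expect_error(learning_rate(block_from_entries(list(0:2))), ">= 2 distinct days")
})

test_that("exploration ratio counts non-centre regions out of 27", {
  lay <- arena_layout()
  all_r <- lay$maze_regions
  b <- block_from_entries(list(0:8), regions = all_r)
  expect_equal(exploration_ratio(b), 1)
  b0 <- block_from_entries(list(integer(0)), regions = lay$inner_centre)
  expect_equal(exploration_ratio(b0), 0)
  b18 <- block_from_entries(list(0:8), regions = c(lay$arms, lay$bridges))
  expect_equal(exploration_ratio(b18), 18 / 27)
})

test_that("cumulative arm time and velocity average per-day values", {
  tr <- trial("m1", 4, 1, arms = 0:2, t_trial = 600, dwell = c(10, 20, 30))
  expect_equal(cumulative_arm_time(session_block(list(tr))), 60)
  expect_equal(cumulative_arm_time(block_from_entries(list(integer(0)))), 0)
  b <- block_from_entries(list(0:8, 0:8), t_trial = c(600, 600),
                          dwell_each = NULL)
  b$trials[[1]]$dwell <- rep(60 / 9, 9); b$trials[[2]]$dwell <- rep(120 / 9, 9)
  expect_equal(cumulative_arm_time(b), 90)
  sb <- block_from_entries(list(0:8), t_trial = 600, distance_cm = 600)
  expect_equal(mean_speed(sb), 1)
  sb2 <- block_from_entries(list(0:8, 0:8), t_trial = c(100, 100),
                            distance_cm = c(200, 400))
  expect_equal(mean_speed(sb2), 3)
  expect_equal(mean_speed(block_from_entries(list(0:8), distance_cm = 0)), 0)
})

test_that("adjacent-arm offsets use circular arithmetic over -4..4", {
  b <- block_from_entries(list(c(1, 3)))
  h <- adjacent_offset_distribution(b)
  expect_equal(unname(h[["2"]]), 1)
  # wrap-around: 8 -> 1 is +2
  expect_equal(unname(adjacent_offset_distribution(
    block_from_entries(list(c(8, 1))))[["2"]]), 1)
  expect_equal(unname(adjacent_offset_distribution(
    block_from_entries(list(c(4, 4))))[["0"]]), 1)
  # normalised frequencies lie in [0, 1]; a single trial peaks at exactly 1
  set.seed(5)
  bb <- block_from_entries(lapply(1:6, function(i) sample(0:8, 9, TRUE)))
  hn <- adjacent_offset_distribution(bb, normalise = "max")
  expect_true(all(hn >= 0 & hn <= 1))
  h1 <- adjacent_offset_distribution(block_from_entries(list(c(0, 2, 4, 6))),
                                     normalise = "max")
  expect_equal(max(h1), 1)
})

test_that("metric and daily tables carry the registered maze metrics", {
  set.seed(9)
  blocks <- list(block_from_entries(lapply(1:3, function(i) sample(0:8, 9, TRUE)),
                                    dwell_each = 5, distance_cm = 400),
                 block_from_entries(lapply(1:3, function(i) sample(0:8, 9, TRUE)),
                                    dwell_each = 5, distance_cm = 400,
                                    mouse = "m02"))
  tab <- metric_table(blocks)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("dmt", "errors", "uss", "learning_rate",
                    "exploration_ratio", "arm_time", "velocity") %in% names(tab)))
  d <- daily_metrics(blocks)
  expect_equal(nrow(d), 6)
  expect_equal(mean(d$uss[d$mouse_id == "m01"]), tab$uss[tab$mouse_id == "m01"])
})
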