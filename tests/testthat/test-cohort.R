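test_that("cohort generation is deterministic and seed-sensitive", {
  a <- generate_cohort(small_spec(seed = 101))
  b <- generate_cohort(small_spec(seed = 101))
  expect_identical(cohort_metric_tables(a), cohort_metric_tables(b))
  expect_identical(a$weights, b$weights)
  c2 <- generate_cohort(small_spec(seed = 102))
  expect_false(identical(cohort_metric_tables(a), cohort_metric_tables(c2)))
})

test_that("adding a mouse leaves existing mice untouched", {
  a <- generate_cohort(cohort_spec(n_mice = 5, ages = c(4, 18), seed = 55))
  b <- generate_cohort(cohort_spec(n_mice = 6, ages = c(4, 18), seed = 55))
  ta <- cohort_metric_tables(a)[["4"]]
  tb <- cohort_metric_tables(b)[["4"]]
  shared <- ta$mouse_id
  expect_equal(ta, tb[tb$mouse_id %in% shared, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("full stability with zero noise duplicates metrics across ages", {
  sp <- cohort_spec(n_mice = 5, ages = c(4, 18),
                    rho = c(maze = 1, speed = 1, object = 1),
                    noise_sd = 0, seed = 77)
  tabs <- cohort_metric_tables(generate_cohort(sp))
  cols <- setdiff(names(tabs[["4"]]), "age_months")
  expect_equal(tabs[["4"]][cols], tabs[["18"]][cols], ignore_attr = TRUE)
})

test_that("weight series increase strictly under a positive slope", {
  co <- generate_cohort(cohort_spec(seed = 78))
  for (w in split(co$weights$weight_g, co$weights$mouse_id))
    expect_true(all(diff(w) > 0))
})

test_that("generated sequences prefer the second adjacent arm", {
  co <- generate_cohort(cohort_spec(n_mice = 12, ages = 4, seed = 79))
  h <- Reduce(`+`, lapply(co$blocks, adjacent_offset_distribution))
  # the two most frequent moves are the second adjacent arms, either way round
  expect_setequal(names(sort(h, decreasing = TRUE))[1:2], c("-2", "2"))
  expect_lt(h[["0"]], h[["2"]])   # same-arm re-entry is the rarest move
  expect_lt(h[["1"]], h[["2"]])   # first adjacent less preferred than second
})

test_that("truth table reports the planted parameters", {
  sp <- cohort_spec(seed = 80, decliner = list(mouse = 3, onset_age = 8))
  co <- generate_cohort(sp)
  tr <- truth_table(co)
  expect_equal(tr$decliner, "m03")
  expect_equal(tr$rho[["maze"]], 0.7)
  expect_equal(length(tr$ability), 22)
  # drifting ability trajectory only for the decliner
  expect_true(all(tr$ability_by_age[1, ] == tr$ability[1]))
  expect_true(all(diff(tr$ability_by_age[3, 2:4]) < 0))
  # no decliner planted -> empty decliner list
  expect_length(truth_table(generate_cohort(small_spec(seed = 81)))$decliner, 0)
})

test_that("the attrition schedule keeps completers only at later ages", {
  sp <- cohort_spec(n_mice = 58, seed = 82, attrition = TRUE)
  co <- generate_cohort(sp)
  n_at <- table(vapply(co$blocks, `[[`, numeric(1), "age_months"))
  expect_equal(unname(n_at[as.character(c(4, 8, 12, 18))]), c(58, 46, 31, 22),
               ignore_attr = TRUE)
  expect_error(cohort_spec(n_mice = 22, seed = 1, attrition = TRUE), "58")
})

test_that("pipeline closure: generated files reload into identical metrics", {
  dir <- withr::local_tempdir()
  sp <- cohort_spec(n_mice = 4, ages = c(4, 18), seed = 83)
  co <- generate_cohort(sp, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("events.csv", "trials.csv", "weights.csv", "bouts.csv",
      "occupancy.csv", "truth.csv")))))
  ev <- read_event_log(file.path(dir, "events.csv"))
  ti <- read_trial_table(file.path(dir, "trials.csv"))
  blocks <- sessions_from_logs(ev, ti)
  got <- metric_table(blocks, bouts = read_bout_table(file.path(dir, "bouts.csv")))
  want <- metric_table(co$blocks, bouts = co$bouts)
  expect_equal(got[order(got$age_months, got$mouse_id), ],
               want[order(want$age_months, want$mouse_id), ],
               ignore_attr = TRUE, tolerance = 1e-12)
  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  generate_cohort(sp, dir = dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
})

test_that("invalid specs fail before any work is done", {
  expect_error(cohort_spec(seed = 1, rho = c(maze = 1.5, speed = 0, object = 0)),
               "rho")
  expect_error(cohort_spec(seed = 1, decliner = list(mouse = 99, onset_age = 8)),
               "out of range")
  expect_error(cohort_spec(seed = 1, decliner = list(mouse = 2, onset_age = 5)),
               "age point")
  expect_error(cohort_spec(n_mice = 22), "seed")
})
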