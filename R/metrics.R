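# Nine-arm radial-maze performance metrics.
#
# All session-level metrics are means over the observed trial days of a
# per-day quantity; a full session has 16 days but missing days simply
# reduce the divisor.

#' Registered performance metrics
#'
#' The eleven metrics entering standardisation and the combination search:
#' seven radial-maze measures and the four object-preference ratios. Maze
#' velocity is included; open-field measures (arena speed, zone occupancy)
#' are computed by the package but deliberately excluded from the cognitive
#' metric universe, as the open field assays anxiety rather than cognition.
#'
#' @return character vector of metric names.
#' @export
metric_universe <- function() {
  c("dmt", "errors", "uss", "learning_rate", "exploration_ratio",
    "arm_time", "velocity", "or1", "or15", "ol1", "ol15")
}

# the five maze metrics entering decliner detection, with their adverse
# trend direction (+1: an increase with age is adverse)
decliner_metrics <- function() {
  c(uss = -1, errors = +1, dmt = +1, arm_time = -1, exploration_ratio = -1)
}

as_block <- function(block) {
  if (inherits(block, "maze_trial")) block <- session_block(list(block))
  if (!inherits(block, "session_block")) stopf("expected a session_block")
  block
}

#' Mean decision-making time (DMT)
#'
#' Per trial, the trial duration divided by the number of arm entries plus
#' one; the session value is the mean over observed days. The `+ 1`
#' guarantees a finite value for a day with zero arm visits (a full-length
#' trial with no entries scores its whole duration).
#'
#' @param block a [session_block()] (a single [trial()] is promoted).
#' @return mean decision-making time in seconds.
#' @examples
#' tr <- trial("m1", 4, 1, arms = 0:8, t_trial = 600)
#' decision_time(tr)  # 600 / (9 + 1) = 60
#' @export
decision_time <- function(block) {
  block <- as_block(block)
  mean(vapply(block$trials, function(tr) tr$t_trial / (length(tr$arms) + 1),
              numeric(1)))
}

#' Working-memory errors in a trial
#'
#' An error is a return to an arm already visited in the same session:
#' the number of arm entries minus the number of distinct arms entered.
#'
#' @param x a [trial()] or an integer vector of arm indices in entry order.
#' @return error count (non-negative integer).
#' @export
count_errors <- function(x) {
  arms <- if (inherits(x, "maze_trial")) x$arms else as.integer(x)
  length(arms) - length(unique(arms))
}

#' Mean daily errors over a session
#'
#' @param block a [session_block()].
#' @return mean errors per observed day.
#' @export
mean_errors <- function(block) {
  block <- as_block(block)
  mean(vapply(block$trials, count_errors, numeric(1)))
}

#' Decompose an arm-entry sequence into unique sequences
#'
#' Greedy left-to-right parse: a segment grows while each new entry is not
#' already in the current segment; a within-segment repeat closes the
#' segment and the repeated entry opens the next one, so segments partition
#' the entry list and every boundary coincides with an error. The trailing
#' segment is kept even when no error closes it (error-free full trials
#' contribute a single segment of length `n_arms`).
#'
#' @param arms integer vector of arm indices in entry order (or a [trial()]).
#' @param n_arms number of maze arms, used to size the count vector.
#' @return a list of class `uss_decomposition` with `lengths` (segment
#'   lengths in parse order) and `counts` (frequency `f_i` of each length
#'   `i = 1..n_arms`).
#' @examples
#' decompose_unique_sequences(c(0, 1, 2, 1, 3))$lengths  # 3 2
#' @export
decompose_unique_sequences <- function(arms, n_arms = 9L) {
  if (inherits(arms, "maze_trial")) { n_arms <- arms$n_arms; arms <- arms$arms }
  arms <- as.integer(arms)
  lengths <- integer(0)
  cur <- integer(0)
  for (a in arms) {
    if (a %in% cur) {
      lengths <- c(lengths, length(cur))
      cur <- a
    } else cur <- c(cur, a)
  }
  if (length(cur)) lengths <- c(lengths, length(cur))
  structure(list(lengths = lengths, counts = tabulate(lengths, n_arms)),
            class = "uss_decomposition")
}

#' @export
print.uss_decomposition <- function(x, ...) {
  cat("Unique-sequence decomposition: lengths [",
      paste(x$lengths, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# per-trial weighted score: sum over lengths i of i * f_i^2
uss_trial <- function(tr) {
  f <- decompose_unique_sequences(tr)$counts
  sum(seq_along(f) * f^2)
}

#' Unique-sequence score (USS)
#'
#' Length-weighted sum of squared per-length segment counts,
#' `sum_i i * f_i^2`, evaluated per trial and averaged over the observed
#' days. The per-length frequencies `f_i` are counted within each trial.
#'
#' @param block a [session_block()].
#' @return the session USS.
#' @export
unique_sequence_score <- function(block) {
  block <- as_block(block)
  mean(vapply(block$trials, uss_trial, numeric(1)))
}

#' Learning rate over a session
#'
#' Ordinary least-squares slope of daily error counts against day number,
#' sign-flipped so that error counts that fall across the session give a
#' positive learning rate.
#'
#' @param block a [session_block()] with at least two distinct days.
#' @return learning rate in errors/day (sign-flipped slope).
#' @export
learning_rate <- function(block) {
  block <- as_block(block)
  days <- vapply(block$trials, `[[`, integer(1), "day")
  if (length(unique(days)) < 2L)
    stopf("learning_rate needs >= 2 distinct days")
  err <- vapply(block$trials, count_errors, numeric(1))
  dx <- days - mean(days)
  -sum(dx * (err - mean(err))) / sum(dx^2)
}

#' Exploration ratio
#'
#' Fraction of the maze's explorable regions (all regions except the
#' inner-centre, 27 for a nine-arm maze) entered per day, averaged over the
#' observed days.
#'
#' @param block a [session_block()].
#' @param layout an [arena_layout()].
#' @return mean daily exploration ratio in `[0, 1]`.
#' @export
exploration_ratio <- function(block, layout = arena_layout()) {
  block <- as_block(block)
  explorable <- setdiff(layout$maze_regions, layout$inner_centre)
  mean(vapply(block$trials, function(tr)
    length(intersect(tr$regions, explorable)) / length(explorable), numeric(1)))
}

#' Cumulative arm time
#'
#' Mean over days of the summed dwell time on the arm regions.
#'
#' @param block a [session_block()].
#' @return seconds per day spent on arms.
#' @export
cumulative_arm_time <- function(block) {
  block <- as_block(block)
  mean(vapply(block$trials, function(tr) sum(tr$dwell), numeric(1)))
}

#' Mean maze velocity
#'
#' Mean over days of total path length divided by trial duration.
#'
#' @param block a [session_block()] whose trials carry `distance_cm`.
#' @return cm/s.
#' @export
mean_speed <- function(block) {
  block <- as_block(block)
  mean(vapply(block$trials, function(tr) {
    if (tr$t_trial <= 0) stopf("mean_speed: trial with zero duration (mouse %s day %d)",
                               tr$mouse_id, tr$day)
    tr$distance_cm / tr$t_trial
  }, numeric(1)))
}

#' Adjacent-arm offset distribution
#'
#' For every pair of consecutive arm entries a -> b the circular offset is
#' `((b - a + 4) mod 9) - 4`, i.e. -4..+4 steps clockwise/anti-clockwise
#' with re-entry into the same arm scored 0. Counts are pooled over the
#' block's trials; with `normalise = "max"` each trial's histogram is scaled
#' to its own maximum before averaging across trials, mirroring how
#' normalised frequencies are usually reported for this task.
#'
#' @param block a [session_block()] with at least one trial of >= 2 entries.
#' @param normalise `"none"` (pooled counts) or `"max"` (per-trial
#'   max-normalised frequencies averaged over trials).
#' @return named numeric vector over offsets `-4..4`.
#' @export
adjacent_offset_distribution <- function(block, normalise = c("none", "max")) {
  normalise <- match.arg(normalise)
  block <- as_block(block)
  n_arms <- block$trials[[1]]$n_arms
  half <- n_arms %/% 2L
  offs <- (-half):half
  per_trial <- lapply(block$trials, function(tr) {
    a <- tr$arms
    if (length(a) < 2L) return(NULL)
    o <- arm_offset(a[-length(a)], a[-1], n_arms)
    tabulate(match(o, offs), length(offs))
  })
  per_trial <- per_trial[!vapply(per_trial, is.null, logical(1))]
  if (!length(per_trial)) stopf("no trial has >= 2 arm entries")
  out <- if (normalise == "none") {
    Reduce(`+`, per_trial)
  } else {
    rowMeans(vapply(per_trial, function(h) h / max(h), numeric(length(offs))))
  }
  stats::setNames(out, offs)
}

#' Per-session metric table
#'
#' Computes the seven maze metrics for each session block and, when a bout
#' table is supplied, merges the four object-preference ratios, yielding one
#' row per (mouse, age) over the eleven registered metrics.
#'
#' @param blocks list of [session_block()]s (e.g. from
#'   [sessions_from_logs()] or [generate_cohort()]).
#' @param bouts optional exploration-bout data.frame (columns `mouse_id`,
#'   `age_months`, `task`, `phase`, `object`, `duration`).
#' @param layout an [arena_layout()].
#' @return data.frame with `mouse_id`, `age_months` and one column per
#'   available metric.
#' @export
metric_table <- function(blocks, bouts = NULL, layout = arena_layout()) {
  if (inherits(blocks, "session_block")) blocks <- list(blocks)
  rows <- lapply(blocks, function(b) {
    data.frame(mouse_id = b$mouse_id, age_months = b$age_months,
               dmt = decision_time(b), errors = mean_errors(b),
               uss = unique_sequence_score(b),
               learning_rate = learning_rate(b),
               exploration_ratio = exploration_ratio(b, layout),
               arm_time = cumulative_arm_time(b),
               velocity = mean_speed(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bouts)) {
    pref <- preference_table(bouts)
    out <- merge(out, pref, by = c("mouse_id", "age_months"),
                 all.x = TRUE, sort = FALSE)
  }
  out[order(out$age_months, out$mouse_id), , drop = FALSE]
}

#' Per-day metric values for trend analysis
#'
#' Daily values of the five maze metrics used for per-mouse lifespan
#' regressions: with four age points and 16 days each, a mouse contributes
#' up to 64 observations per metric.
#'
#' @param blocks list of [session_block()]s across ages.
#' @param layout an [arena_layout()].
#' @return long-by-day data.frame with columns `mouse_id`, `age_months`,
#'   `day`, `uss`, `errors`, `dmt`, `arm_time`, `exploration_ratio`.
#' @export
daily_metrics <- function(blocks, layout = arena_layout()) {
  if (inherits(blocks, "session_block")) blocks <- list(blocks)
  explorable <- setdiff(layout$maze_regions, layout$inner_centre)
  rows <- lapply(blocks, function(b) {
    do.call(rbind, lapply(b$trials, function(tr) {
      data.frame(mouse_id = tr$mouse_id, age_months = tr$age_months,
                 day = tr$day,
                 uss = uss_trial(tr), errors = count_errors(tr),
                 dmt = tr$t_trial / (length(tr$arms) + 1),
                 arm_time = sum(tr$dwell),
                 exploration_ratio =
                   length(intersect(tr$regions, explorable)) / length(explorable),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
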