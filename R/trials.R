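#' A single radial-maze trial
#'
#' One maze session for one mouse on one day: the ordered arm entries with
#' their entry times and dwell times, the trial duration, the total path
#' length and the set of maze regions visited. Under the default termination
#' rule a trial ends after `max_duration` seconds or after nine arm entries
#' (revisits included), whichever comes first.
#'
#' @param mouse_id mouse identifier (coerced to character).
#' @param age_months age point in months.
#' @param day test day within the session, 1-16.
#' @param arms integer vector of arm indices (0-based) in entry order.
#' @param t_trial trial duration in seconds (<= `max_duration`).
#' @param entry_t optional entry times (seconds from trial start), one per
#'   arm entry, non-decreasing.
#' @param dwell optional per-entry dwell times on the arm, seconds.
#' @param distance_cm total path length in cm (optional, `NA` if untracked).
#' @param regions optional character vector of visited region ids; when
#'   omitted it is derived as the entered arms, their bridges and the
#'   inner-centre region.
#' @param layout an [arena_layout()].
#' @param max_duration trial cap in seconds (default 600).
#' @return an object of class `maze_trial`.
#' @export
trial <- function(mouse_id, age_months, day, arms, t_trial,
                  entry_t = NULL, dwell = NULL, distance_cm = NA_real_,
                  regions = NULL, layout = arena_layout(),
                  max_duration = 600) {
  arms <- as.integer(arms)
  day <- as.integer(day)
  if (is.na(day) || day < 1L || day > 16L) stopf("day must be in 1..16, got %s", day)
  if (length(arms) && (anyNA(arms) || any(arms < 0L | arms >= layout$n_arms)))
    stopf("arm indices must be in 0..%d", layout$n_arms - 1L)
  if (!is.finite(t_trial) || t_trial < 0 || t_trial > max_duration)
    stopf("t_trial must be in [0, %g] s, got %g", max_duration, t_trial)
  if (is.null(dwell)) dwell <- rep(0, length(arms))
  if (length(dwell) != length(arms)) stopf("dwell must have one value per arm entry")
  if (any(dwell < 0)) stopf("dwell times must be >= 0")
  if (!is.null(entry_t)) {
    if (length(entry_t) != length(arms)) stopf("entry_t must have one value per arm entry")
    if (is.unsorted(entry_t)) stopf("entry times must be non-decreasing")
    if (length(entry_t) && (entry_t[1] < 0 || entry_t[length(entry_t)] > t_trial))
      stopf("entry times must lie within [0, t_trial]")
  }
  if (is.null(regions)) {
    regions <- c(layout$inner_centre,
                 layout$arms[unique(arms) + 1L],
                 layout$bridges[unique(arms) + 1L])
  } else {
    assert_known_regions(regions, layout, "trial regions")
    regions <- unique(as.character(regions))
  }
  structure(list(mouse_id = as.character(mouse_id),
                 age_months = as.numeric(age_months),
                 day = day, arms = arms, entry_t = entry_t, dwell = dwell,
                 t_trial = as.numeric(t_trial),
                 distance_cm = as.numeric(distance_cm),
                 regions = regions, n_arms = layout$n_arms),
            class = "maze_trial")
}

#' A 16-day session block
#'
#' The ordered trials of one mouse at one age point. Days must be unique and
#' in 1..16; missing days are tolerated, and all "mean over the session"
#' metrics divide by the number of observed days.
#'
#' @param trials list of [trial()] objects for one mouse and one age.
#' @return an object of class `session_block`.
#' @export
session_block <- function(trials) {
  if (!length(trials)) stopf("a session block needs at least one trial")
  if (!all(vapply(trials, inherits, logical(1), "maze_trial")))
    stopf("all elements must be maze_trial objects")
  ids <- unique(vapply(trials, `[[`, character(1), "mouse_id"))
  ages <- unique(vapply(trials, `[[`, numeric(1), "age_months"))
  if (length(ids) != 1L || length(ages) != 1L)
    stopf("all trials in a block must share one mouse and one age")
  days <- vapply(trials, `[[`, integer(1), "day")
  if (anyDuplicated(days)) stopf("duplicate test day(s) in block: %s",
                                 paste(days[duplicated(days)], collapse = ", "))
  trials <- trials[order(days)]
  structure(list(mouse_id = ids, age_months = ages, trials = trials),
            class = "session_block")
}

#' @export
print.session_block <- function(x, ...) {
  cat(sprintf("Session block: mouse %s at %g months, %d trial day(s)\n",
              x$mouse_id, x$age_months, length(x$trials)))
  invisible(x)
}

#' @export
length.session_block <- function(x) length(x$trials)

#' Rebuild trials and session blocks from event logs
#'
#' Reconstructs [trial()] objects from a long-format region entry/exit event
#' table plus a companion trial table carrying each day's duration and path
#' length, then groups them into per-(mouse, age) [session_block()]s. This is
#' the bridge between the on-disk CSV dialect and the metric functions.
#'
#' @param events event data.frame as returned by [read_event_log()]: columns
#'   `mouse_id`, `age_months`, `day`, `t`, `region`, `kind`.
#' @param trial_info data.frame with columns `mouse_id`, `age_months`, `day`,
#'   `t_trial`, `distance_cm`.
#' @param layout an [arena_layout()].
#' @return a list of `session_block` objects, one per (mouse, age).
#' @export
sessions_from_logs <- function(events, trial_info, layout = arena_layout()) {
  assert_known_regions(events$region, layout)
  ev_key <- interaction(events$mouse_id, events$age_months, events$day, drop = TRUE)
  info_key <- paste(trial_info$mouse_id, trial_info$age_months, trial_info$day)
  trials <- lapply(split(events, ev_key), function(e) {
    e <- e[order(e$t), , drop = FALSE]
    k <- match(paste(e$mouse_id[1], e$age_months[1], e$day[1]), info_key)
    if (is.na(k))
      stopf("no trial-info row for mouse %s age %g day %d",
            e$mouse_id[1], e$age_months[1], e$day[1])
    is_arm_entry <- e$kind == "entry" & e$region %in% layout$arms
    arm_rows <- which(is_arm_entry)
    arms <- arm_index(e$region[arm_rows], layout)
    # dwell: time to the matching exit of the same region
    dwell <- vapply(arm_rows, function(i) {
      ex <- which(e$region == e$region[i] & e$kind == "exit" & e$t >= e$t[i])
      if (length(ex)) e$t[ex[1]] - e$t[i] else 0
    }, numeric(1))
    trial(mouse_id = e$mouse_id[1], age_months = e$age_months[1],
          day = e$day[1], arms = arms, entry_t = e$t[arm_rows], dwell = dwell,
          t_trial = trial_info$t_trial[k],
          distance_cm = trial_info$distance_cm[k],
          regions = unique(e$region[e$kind == "entry"]), layout = layout)
  })
  by_block <- split(trials, vapply(trials, function(tr)
    paste(tr$mouse_id, tr$age_months), character(1)))
  blocks <- lapply(by_block, session_block)
  ord <- order(vapply(blocks, `[[`, character(1), "mouse_id"),
               vapply(blocks, `[[`, numeric(1), "age_months"))
  unname(blocks[ord])
}
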