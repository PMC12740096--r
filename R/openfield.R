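# Open-field occupancy and novel-object preference measures.

#' Novel-object preference ratio
#'
#' `T_novel / (T_novel + T_familiar)` for one (mouse, task, phase); 0.5 is
#' chance. When the animal explored neither object the ratio is undefined
#' and returned as `NA` with a warning rather than 0, so near-zero-exploration
#' animals are flagged instead of being scored as maximally biased.
#'
#' @param t_novel seconds spent with the novel (or displaced) object.
#' @param t_familiar seconds spent with the familiar object.
#' @return ratio in `[0, 1]`, or `NA` when total exploration is zero.
#' @examples
#' preference_ratio(45, 15)  # 0.75
#' @export
preference_ratio <- function(t_novel, t_familiar) {
  if (any(c(t_novel, t_familiar) < 0)) stopf("bout durations must be >= 0")
  tot <- t_novel + t_familiar
  out <- ifelse(tot > 0, t_novel / tot, NA_real_)
  if (anyNA(out))
    warning("undefined preference ratio: zero exploration of both objects",
            call. = FALSE)
  out
}

#' Preference ratios from an exploration-bout table
#'
#' Aggregates bout durations per (mouse, age, task) for the choice phase and
#' returns one column per task (`or1`, `or15`, `ol1`, `ol15`). Sample-phase
#' ratios, which should sit at chance, are available via `phase = "sample"`.
#'
#' @param bouts data.frame with columns `mouse_id`, `age_months`, `task`
#'   (OR1/OR15/OL1/OL15), `phase` (sample/choice), `object`
#'   (novel/familiar), `duration` (s).
#' @param phase which phase to score (default `"choice"`).
#' @return wide data.frame, one row per (mouse, age).
#' @export
preference_table <- function(bouts, phase = c("choice", "sample")) {
  phase <- match.arg(phase)
  need <- c("mouse_id", "age_months", "task", "phase", "object", "duration")
  miss <- setdiff(need, names(bouts))
  if (length(miss)) stopf("bout table lacks column(s): %s", paste(miss, collapse = ", "))
  b <- bouts[bouts$phase == phase, , drop = FALSE]
  agg <- stats::aggregate(duration ~ mouse_id + age_months + task + object,
                          data = b, FUN = sum)
  keys <- unique(agg[c("mouse_id", "age_months", "task")])
  keys$ratio <- suppressWarnings(vapply(seq_len(nrow(keys)), function(i) {
    sel <- agg$mouse_id == keys$mouse_id[i] &
      agg$age_months == keys$age_months[i] & agg$task == keys$task[i]
    tn <- sum(agg$duration[sel & agg$object == "novel"])
    tf <- sum(agg$duration[sel & agg$object == "familiar"])
    preference_ratio(tn, tf)
  }, numeric(1)))
  if (anyNA(keys$ratio))
    warning("undefined preference ratio(s) flagged as NA and excluded from Z-tables",
            call. = FALSE)
  out <- stats::reshape(keys, idvar = c("mouse_id", "age_months"),
                        timevar = "task", direction = "wide")
  names(out) <- sub("^ratio\\.", "", names(out))
  names(out) <- ifelse(names(out) %in% c("OR1", "OR15", "OL1", "OL15"),
                       tolower(names(out)), names(out))
  rownames(out) <- NULL
  out
}

#' Open-field zone occupancy fractions
#'
#' @param centre,inner,outer zone durations in seconds (vectors recycle).
#' @return data.frame of three fractions summing to 1 per row.
#' @export
zone_fractions <- function(centre, inner, outer) {
  tot <- centre + inner + outer
  if (any(tot <= 0)) stopf("zone durations sum to zero: fractions undefined")
  data.frame(centre = centre / tot, inner = inner / tot, outer = outer / tot)
}

#' Open-field arena speed
#'
#' @param path_cm total path length (cm).
#' @param total_s total exploration time (s), > 0.
#' @return speed in cm/s.
#' @export
arena_speed <- function(path_cm, total_s) {
  if (any(total_s <= 0)) stopf("total time must be > 0")
  path_cm / total_s
}

#' Open-field summary per (mouse, age)
#'
#' Computes outer-zone occupancy fraction (thigmotaxis) and arena speed from
#' an occupancy table. These are reported alongside the cognitive metrics
#' but are not part of the cognitive metric universe.
#'
#' @param occupancy data.frame with columns `mouse_id`, `age_months`,
#'   `centre_s`, `inner_s`, `outer_s`, `total_s`, `path_cm`.
#' @return data.frame with `outer_fraction` and `arena_speed` columns.
#' @export
field_metrics <- function(occupancy) {
  fr <- zone_fractions(occupancy$centre_s, occupancy$inner_s, occupancy$outer_s)
  data.frame(mouse_id = occupancy$mouse_id,
             age_months = occupancy$age_months,
             outer_fraction = fr$outer,
             arena_speed = arena_speed(occupancy$path_cm, occupancy$total_s),
             stringsAsFactors = FALSE)
}
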