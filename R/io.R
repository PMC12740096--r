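# Readers and writers for the on-disk dialects.
#
# Event logs, trial tables, weights and bouts travel as plain CSV; metric,
# Z- and stability tables as TSV. Every table written by the package opens
# with '#'-prefixed header lines recording the package version, the RNG
# seed and a configuration fingerprint, so any run can be reproduced
# bit for bit from its outputs.

pkg_version <- function() as.character(utils::packageVersion("mazetraits"))

write_header <- function(con, seed = NA, config = NULL) {
  writeLines(c(sprintf("# mazetraits %s", pkg_version()),
               sprintf("# seed: %s", seed),
               sprintf("# config: %s",
                       if (is.null(config)) "none" else config_fingerprint(config))),
             con)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- lines[startsWith(lines, "#")]
  seed <- sub("^# seed: ", "", grep("^# seed: ", meta, value = TRUE))
  list(n_skip = length(meta),
       seed = if (length(seed)) suppressWarnings(as.integer(seed)) else NA_integer_)
}

# full-precision number formatting so write -> read is the identity on doubles
fmt_num <- function(x) {
  if (is.double(x)) vapply(x, function(v)
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE), character(1))
  else as.character(x)
}

write_table_impl <- function(df, path, sep, seed = NA, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  write_header(con, seed = seed, config = config)
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_table_impl <- function(path, sep) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- read_header_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, skip = meta$n_skip,
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "seed") <- meta$seed
  df
}

#' Read a region entry/exit event log
#'
#' Long-format CSV with columns `mouse_id`, `age_months`, `day`, `t`
#' (seconds from trial start), `region`, `kind` (entry/exit). Rows are
#' validated (known region ids, timestamps monotone within each trial,
#' entries and exits alternating per region) and returned grouped and
#' time-sorted per (mouse, age, day).
#'
#' @param path CSV file path.
#' @param layout an [arena_layout()] used to resolve region ids.
#' @return data.frame of events; attribute `seed` carries the generating
#'   seed when the file records one.
#' @export
read_event_log <- function(path, layout = arena_layout()) {
  df <- read_table_impl(path, sep = ",")
  need <- c("mouse_id", "age_months", "day", "t", "region", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("event log %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  n_skip <- read_header_meta(path)$n_skip
  bad <- which(!df$kind %in% c("entry", "exit") | is.na(df$t) | df$t < 0)
  if (length(bad))
    stopf("malformed event row at line %d of %s", bad[1] + n_skip + 1L, path)
  assert_known_regions(df$region, layout, sprintf("event log %s", path))
  key <- interaction(df$mouse_id, df$age_months, df$day, drop = TRUE)
  parts <- split(seq_len(nrow(df)), key)
  for (idx in parts) {
    tt <- df$t[idx]
    if (is.unsorted(tt))
      stopf("non-monotone timestamps within trial (mouse %s, age %s, day %s) in %s",
            df$mouse_id[idx[1]], df$age_months[idx[1]], df$day[idx[1]], path)
    sub <- df[idx, , drop = FALSE]
    for (r in unique(sub$region)) {
      kinds <- sub$kind[sub$region == r]
      if (any(kinds != rep(c("entry", "exit"), length.out = length(kinds))))
        stopf("entries and exits do not alternate for region %s (mouse %s, day %s) in %s",
              r, sub$mouse_id[1], sub$day[1], path)
    }
  }
  ord <- order(df$mouse_id, df$age_months, df$day, df$t,
               df$region, df$kind == "exit")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a region entry/exit event log
#'
#' @param events event data.frame (see [read_event_log()] for columns).
#' @param path output CSV path.
#' @param seed generating seed recorded in the header.
#' @param config optional configuration object fingerprinted in the header.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, seed = NA, config = NULL) {
  if (!nrow(events)) stopf("refusing to write an empty event log")
  write_table_impl(events, path, sep = ",", seed = seed, config = config)
  invisible(path)
}

#' Read or write the companion per-trial table
#'
#' Columns `mouse_id`, `age_months`, `day`, `t_trial` (s), `distance_cm`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_trial_table <- function(path) read_table_impl(path, sep = ",")

#' @rdname read_trial_table
#' @param trials trial data.frame.
#' @param seed,config header metadata (see [write_event_log()]).
#' @export
write_trial_table <- function(trials, path, seed = NA, config = NULL) {
  write_table_impl(trials, path, sep = ",", seed = seed, config = config)
  invisible(path)
}

#' Read or write weight and bout tables
#'
#' Weights: `mouse_id`, `age_months`, `weight_g`. Bouts: `mouse_id`,
#' `age_months`, `task`, `phase`, `object`, `duration`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_weight_table <- function(path) read_table_impl(path, sep = ",")

#' @rdname read_weight_table
#' @param df table to write.
#' @param seed,config header metadata.
#' @export
write_weight_table <- function(df, path, seed = NA, config = NULL) {
  write_table_impl(df, path, sep = ",", seed = seed, config = config)
  invisible(path)
}

#' @rdname read_weight_table
#' @export
read_bout_table <- function(path) read_table_impl(path, sep = ",")

#' @rdname read_weight_table
#' @export
write_bout_table <- function(df, path, seed = NA, config = NULL) {
  write_table_impl(df, path, sep = ",", seed = seed, config = config)
  invisible(path)
}

#' Write a metric or Z table
#'
#' Tab-separated, one row per mouse, one column per metric; the header
#' lines carry the package version, seed and config fingerprint.
#'
#' @param table data.frame from [metric_table()] or [zscore_table()].
#' @param path output TSV path.
#' @param seed,config header metadata.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path, seed = NA, config = NULL) {
  if (!nrow(table)) stopf("refusing to write an empty metric table")
  write_table_impl(as.data.frame(table), path, sep = "\t", seed = seed,
                   config = config)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) read_table_impl(path, sep = "\t")

#' Run configuration
#'
#' Bundles the knobs of a pipeline run — arena layout size, metric list,
#' slope penalty, resampling counts, seed and output directory — and
#' travels as JSON. The seed and the fingerprint of the whole object are
#' stamped into every output file header.
#'
#' @param n_arms maze arms.
#' @param metrics metric list to compute.
#' @param lambda slope penalty (>= 0).
#' @param resample_draws resampled datasets per subset size.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_arms = 9L, metrics = metric_universe(), lambda = 0,
                       resample_draws = NULL, seed = 1L, out_dir = ".") {
  if (lambda < 0) stopf("lambda must be >= 0")
  structure(list(n_arms = as.integer(n_arms), metrics = metrics,
                 lambda = lambda, resample_draws = resample_draws,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(n_arms = x$n_arms %||% 9L, metrics = x$metrics %||% metric_universe(),
             lambda = x$lambda %||% 0, resample_draws = x$resample_draws,
             seed = x$seed %||% 1L, out_dir = x$out_dir %||% ".")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a cohort to disk
#'
#' Serialises every table of a synthetic cohort into the package's CSV
#' dialects; called by [generate_cohort()] when `dir` is given.
#'
#' @param cohort a `maze_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "maze_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- cohort$spec$seed
  logs <- cohort_event_log(cohort)
  write_event_log(logs$events, file.path(dir, "events.csv"), seed, cohort$spec)
  write_trial_table(logs$trials, file.path(dir, "trials.csv"), seed, cohort$spec)
  write_weight_table(cohort$weights, file.path(dir, "weights.csv"), seed, cohort$spec)
  write_bout_table(cohort$bouts, file.path(dir, "bouts.csv"), seed, cohort$spec)
  write_weight_table(cohort$occupancy, file.path(dir, "occupancy.csv"), seed,
                     cohort$spec)
  tr <- data.frame(mouse_id = cohort$truth$mouse_id,
                   ability = cohort$truth$ability,
                   decliner = cohort$truth$mouse_id %in% cohort$truth$decliner)
  write_weight_table(tr, file.path(dir, "truth.csv"), seed, cohort$spec)
  invisible(dir)
}
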