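# Shared fixture builders: every fixture is constructed in code.

# a session block from a list of arm-entry vectors (one per day)
block_from_entries <- function(entries, t_trial = 600, dwell_each = NULL,
                               distance_cm = NA_real_, mouse = "m01", age = 4,
                               regions = NULL) {
  trials <- lapply(seq_along(entries), function(d) {
    a <- entries[[d]]
    trial(mouse_id = mouse, age_months = age, day = d, arms = a,
          t_trial = if (length(t_trial) > 1) t_trial[d] else t_trial,
          dwell = if (is.null(dwell_each)) NULL else rep(dwell_each, length(a)),
          distance_cm = if (length(distance_cm) > 1) distance_cm[d] else distance_cm,
          regions = regions)
  })
  session_block(trials)
}

# a metric/Z table with given metric columns filled from a matrix
table_from_matrix <- function(m, age = 4, metrics = colnames(m)) {
  df <- data.frame(mouse_id = sprintf("m%02d", seq_len(nrow(m))),
                   age_months = age, stringsAsFactors = FALSE)
  for (j in seq_along(metrics)) df[[metrics[j]]] <- m[, j]
  df
}

# small cohort spec used across tests (two ages keeps runtime down)
small_spec <- function(seed, ...) {
  cohort_spec(n_mice = 8L, ages = c(4, 18), seed = seed, ...)
}

fisher_interval <- function(rho, n, level = 0.95) {
  zc <- stats::qnorm(1 - (1 - level) / 2)
  tanh(atanh(rho) + c(-1, 1) * zc / sqrt(n - 3))
}
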