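# Synthetic longitudinal cohort generator.
#
# Emulates the study design: female mice tested at 4/8/12/18 months with a
# 16-day radial-maze session, object recognition/location tests and open
# field at each age, plus weight records. Each mouse carries a
# time-invariant cognitive ability; day-to-day sampling noise is calibrated
# so that 16-day session means of the maze metrics correlate at the planted
# rho between any two ages (a test-retest-reliability reading of trait
# stability, which also matches the finding the generator is built to
# embody: the trait itself is stable). Speed and object preference carry
# their own latents with age-level wobble giving inter-age correlations of
# rho_speed and rho_object. Ability acts on the per-step probability of
# re-entering an already-visited arm, never on speed, so maze metrics are
# predictive across ages while speed and object preference are not.

# generation constants; the between-mouse couplings and day-level noise
# scales are calibrated jointly so the planted maze rho is realised in the
# 16-day session means (primarily the unique-sequence score; see vignette)
.gen <- list(
  w_off = c(0.60, 0.80, 1.00, 0.55, 0.12, 0.55, 1.00, 0.80, 0.60),
  eta0 = -0.75,       # baseline log-penalty for re-entering a visited arm
  eta1 = 0.95,       # ability coupling of the revisit penalty
  s_seq_day = 0.90,  # day-level (attention) noise on the revisit penalty
  int_base = 65,     # median inter-entry interval, s
  sdl_int = 0.40,    # lognormal sdlog of intervals
  c_dmt = 0.10,      # decision-tempo coupling (low latent = slow decisions)
  s_dmt_day = 0.175,  # day-level lognormal sd of decision speed
  dwell_base = 11.5, # median arm dwell per entry, s
  sdl_dwell = 0.50,
  c_arm = 0.28,      # dwell-latent coupling of arm time
  s_arm_day = 0.62,
  er_logit = 3.50,   # baseline logit of outer-centre visit probability
  c_er = 0.70,       # ability coupling of outer-centre exploration
  s_er_day = 3.50,
  p_bridge_extra = 0.9,  # bridge-only visits to otherwise unvisited arms
  v_base = 8,        # maze velocity, cm/s
  v_sp = 0.165, v_day = 0.08,
  of_speed0 = 12.71, of_sp = 0.10, of_noise = 0.06,
  outer0 = 0.7288, of_out_mouse = 0.45, of_out_noise = 0.25,
  pref_gain = 0.08, pref_sd = 0.10,
  weight0 = 22, weight_between = 1.2, weight_incr_sd = 0.15
)

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 22 mice followed at 4, 8, 12
#' and 18 months with 16 maze trials per age; maze-metric session means
#' correlate at 0.7 between ages, speed at 0.3, object preference at 0;
#' weight rises ~0.35 g/month, open-field speed falls ~0.26 cm/s/month from
#' 12.71 cm/s, and outer-zone occupancy rises ~0.0067/month from 0.729.
#'
#' @param n_mice cohort size (default 22).
#' @param ages age points in months.
#' @param trials_per_age maze trial days per age (default 16).
#' @param n_arms maze arms (default 9).
#' @param ability_sd s.d. of the latent cognitive ability (default 1).
#' @param rho named inter-age correlations per metric class:
#'   `maze`, `speed`, `object`.
#' @param weight_slope weight gain, g/month.
#' @param speed_slope open-field speed change, cm/s/month (negative).
#' @param outer_slope outer-zone occupancy change, fraction/month.
#' @param decliner `NULL`, or a list with `mouse` (index), `onset_age`
#'   (months) and `drift` (latent s.d. lost per age point from onset;
#'   default 1 emulates a frank decliner).
#' @param noise_sd multiplier on all day-level noise scales (1 preserves
#'   the planted correlations; other values shift them).
#' @param attrition if `TRUE`, apply the 58/46/31/22 schedule across the
#'   four ages (requires `n_mice = 58`); mice with the lowest indices are
#'   retained so paired analyses use the 22 completers.
#' @param seed integer master seed (mandatory); all randomness flows from
#'   it through named substreams per mouse/age/stage, so adding a mouse
#'   leaves every other mouse's data unchanged.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 22L, ages = c(4, 8, 12, 18),
                        trials_per_age = 16L, n_arms = 9L, ability_sd = 1,
                        rho = c(maze = 0.7, speed = 0.3, object = 0),
                        weight_slope = 0.35, speed_slope = -0.26,
                        outer_slope = 0.0067, decliner = NULL, noise_sd = 1,
                        attrition = FALSE, seed) {
  if (missing(seed)) stopf("cohort_spec: a seed is mandatory")
  if (any(abs(rho) > 1)) stopf("|rho| must be <= 1")
  if (!all(c("maze", "speed", "object") %in% names(rho)))
    stopf("rho must name maze, speed and object classes")
  if (n_mice < 2L) stopf("n_mice must be >= 2")
  if (noise_sd < 0 || ability_sd < 0) stopf("noise and ability s.d. must be >= 0")
  if (attrition && n_mice != 58L)
    stopf("the attrition schedule is defined for n_mice = 58")
  if (!is.null(decliner)) {
    need <- c("mouse", "onset_age")
    if (!all(need %in% names(decliner)))
      stopf("decliner needs fields: mouse, onset_age (and optionally drift)")
    decliner$drift <- decliner$drift %||% 1.0
    if (decliner$mouse < 1 || decliner$mouse > n_mice)
      stopf("decliner mouse index out of range")
    if (!decliner$onset_age %in% ages) stopf("decliner onset_age must be an age point")
  }
  structure(list(n_mice = as.integer(n_mice), ages = as.numeric(ages),
                 trials_per_age = as.integer(trials_per_age),
                 n_arms = as.integer(n_arms), ability_sd = ability_sd,
                 rho = rho, weight_slope = weight_slope,
                 speed_slope = speed_slope, outer_slope = outer_slope,
                 decliner = decliner, noise_sd = noise_sd,
                 attrition = attrition, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d mice at ages %s months, %d trials/age, seed %d\n",
              x$n_mice, paste(x$ages, collapse = "/"), x$trials_per_age, x$seed))
  if (!is.null(x$decliner))
    cat(sprintf("  decliner: mouse %d from %g months, drift %g s.d./age\n",
                x$decliner$mouse, x$decliner$onset_age, x$decliner$drift))
  invisible(x)
}

# substream key for age-varying draws; with noise_sd = 0 the same stream is
# replayed at every age, so a fully stable spec (rho = 1) reproduces each
# mouse's data identically across ages
age_key <- function(spec, age) if (spec$noise_sd == 0) "frozen" else age

mice_at_age <- function(spec, age) {
  if (!spec$attrition) return(seq_len(spec$n_mice))
  keep <- c(`4` = 58L, `8` = 46L, `12` = 31L, `18` = 22L)[as.character(age)]
  seq_len(min(spec$n_mice, if (is.na(keep)) spec$n_mice else keep))
}

# latent states for every mouse; deterministic given the spec seed
#
# Each maze-metric family gets its own time-invariant latent (revisit
# avoidance / decision tempo / arm dwell) so their session means can each
# be calibrated to the planted inter-age correlation independently; a
# planted decliner drifts down on all of them from the onset age.
cohort_latents <- function(spec) {
  n <- spec$n_mice
  draw1 <- function(name, sd = 1) vapply(seq_len(n), function(m)
    with_seed(stream_seed(spec$seed, name, m), stats::rnorm(1, 0, sd)), numeric(1))
  g <- draw1("latent", spec$ability_sd)
  g_dec <- draw1("latent-dec")
  g_dwell <- draw1("latent-dwell")
  h_speed <- draw1("latent-speed")
  w_out <- draw1("latent-outer")
  per_age <- function(v) {
    m <- outer(v, rep(1, length(spec$ages)))
    colnames(m) <- as.character(spec$ages)
    m
  }
  g_eff <- per_age(g); dec_eff <- per_age(g_dec); dwell_eff <- per_age(g_dwell)
  if (!is.null(spec$decliner)) {
    k0 <- match(spec$decliner$onset_age, spec$ages)
    drop_ <- spec$decliner$drift * pmax(0, seq_along(spec$ages) - k0 + 1L)
    i <- spec$decliner$mouse
    g_eff[i, ] <- g_eff[i, ] - drop_
    dec_eff[i, ] <- dec_eff[i, ] - drop_
    dwell_eff[i, ] <- dwell_eff[i, ] - drop_
  }
  # age-level speed latent: compound-symmetric with inter-age corr rho_speed
  rs <- spec$rho[["speed"]]
  sp <- vapply(seq_along(spec$ages), function(k)
    vapply(seq_len(n), function(m)
      with_seed(stream_seed(spec$seed, "speed-wobble", m, spec$ages[k]),
                sqrt(max(rs, 0)) * h_speed[m] + sqrt(max(1 - rs, 0)) * stats::rnorm(1)),
      numeric(1)),
    numeric(n))
  colnames(sp) <- as.character(spec$ages)
  list(g = g, g_eff = g_eff, dec_eff = dec_eff, dwell_eff = dwell_eff,
       h_speed = h_speed, sp = sp, w_out = w_out)
}

# one 16-day maze session for one mouse at one age; vectorised across trials
simulate_session <- function(spec, mouse, age, g_eff, dec_eff, dwell_eff,
                             sp_age, layout) {
  K <- .gen
  nt <- spec$trials_per_age
  na <- spec$n_arms
  half <- na %/% 2L
  ns <- spec$noise_sd
  with_seed(stream_seed(spec$seed, "maze", mouse, age_key(spec, age)), {
    # per-day multipliers
    dn_dmt <- stats::rnorm(nt, 0, K$s_dmt_day * ns)
    dn_arm <- stats::rnorm(nt, 0, K$s_arm_day * ns)
    dn_er <- stats::rnorm(nt, 0, K$s_er_day * ns)
    dn_seq <- stats::rnorm(nt, 0, K$s_seq_day * ns)
    # inter-entry intervals and entry times
    ml_int <- log(K$int_base) + K$c_dmt * (-dec_eff) + dn_dmt - K$sdl_int^2 / 2
    ints <- matrix(stats::rlnorm(nt * na, meanlog = rep(ml_int, na),
                                 sdlog = K$sdl_int), nrow = nt)
    tt <- t(apply(ints, 1, cumsum))
    # arm sequences: offset-biased kernel with ability-dependent revisit penalty
    logw_off <- log(K$w_off)
    pen <- K$eta0 + K$eta1 * g_eff + dn_seq
    arms <- matrix(0L, nt, na)
    arms[, 1] <- sample.int(na, nt, replace = TRUE) - 1L
    visited <- matrix(FALSE, nt, na)
    visited[cbind(seq_len(nt), arms[, 1] + 1L)] <- TRUE
    for (j in 2:na) {
      off <- outer(arms[, j - 1L], 0:(na - 1L),
                   function(a, b) ((b - a + half) %% na) - half)
      lw <- matrix(logw_off[off + half + 1L], nt, na) - visited * pen
      gmb <- -log(-log(matrix(stats::runif(nt * na), nt, na)))
      arms[, j] <- max.col(lw + gmb, ties.method = "first") - 1L
      visited[cbind(seq_len(nt), arms[, j] + 1L)] <- TRUE
    }
    # dwell times
    ml_dw <- log(K$dwell_base) + K$c_arm * dwell_eff + dn_arm - K$sdl_dwell^2 / 2
    dw <- matrix(stats::rlnorm(nt * na, meanlog = rep(ml_dw, na),
                               sdlog = K$sdl_dwell), nrow = nt)
    # outer-centre and extra bridge visits
    p_out <- stats::plogis(K$er_logit + K$c_er * g_eff + dn_er)
    n_out <- stats::rbinom(nt, na, p_out)
    out_regions <- lapply(seq_len(nt), function(d)
      sample(layout$outer_centre, n_out[d]))
    # maze velocity (speed latent, not ability)
    v_day <- K$v_base * exp(K$v_sp * sp_age + stats::rnorm(nt, 0, K$v_day * ns))
    extra_draw <- matrix(stats::runif(nt * na), nt, na)
    trials <- lapply(seq_len(nt), function(d) {
      keep <- which(tt[d, ] <= 600)
      a <- arms[d, keep]
      et <- tt[d, keep]
      # a completed trial ends once the mouse leaves the ninth arm entered
      # (it is allowed back to the centre before removal)
      full <- length(keep) == na
      gap <- c(diff(et), 600 - if (length(et)) et[length(et)] else 0)
      dwell <- pmin(dw[d, keep], 0.85 * gap)
      t_trial <- if (full) min(600, et[na] + dwell[na] + 1) else 600
      unvisited <- setdiff(0:(na - 1L), a)
      extra_b <- unvisited[extra_draw[d, unvisited + 1L] < K$p_bridge_extra]
      regions <- unique(c(layout$inner_centre,
                          layout$arms[a + 1L], layout$bridges[a + 1L],
                          layout$bridges[extra_b + 1L], out_regions[[d]]))
      trial(mouse_id = sprintf("m%02d", mouse), age_months = age, day = d,
            arms = a, entry_t = et, dwell = dwell, t_trial = t_trial,
            distance_cm = v_day[d] * t_trial, regions = regions,
            layout = layout)
    })
    session_block(trials)
  })
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces the full dataset of one study: 16-day maze sessions per age
#' (arm sequences, entry/dwell times, path lengths, regions visited),
#' object-exploration bouts for OR1/OR15/OL1/OL15, open-field occupancy and
#' weight records, together with the generating truth for recovery tests.
#' Identical spec and seed give an identical cohort; with `dir` set, the
#' CSV files written are byte-identical across runs.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory; when given, `events.csv`, `trials.csv`,
#'   `weights.csv`, `bouts.csv`, `occupancy.csv` and `truth.csv` are
#'   written there in the dialects read by the `read_*` functions.
#' @return an object of class `maze_cohort`: `spec`, `blocks` (list of
#'   [session_block()]s), `weights`, `bouts`, `occupancy`, `truth`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- arena_layout(spec$n_arms)
  lat <- cohort_latents(spec)
  K <- .gen
  blocks <- list()
  for (k in seq_along(spec$ages)) {
    age <- spec$ages[k]
    for (m in mice_at_age(spec, age)) {
      blocks[[length(blocks) + 1L]] <-
        simulate_session(spec, m, age, lat$g_eff[m, k], lat$dec_eff[m, k],
                         lat$dwell_eff[m, k], lat$sp[m, k], layout)
    }
  }
  weights <- do.call(rbind, lapply(seq_len(spec$n_mice), function(m)
    with_seed(stream_seed(spec$seed, "weight", m), {
      ages_m <- spec$ages[vapply(spec$ages, function(a) m %in% mice_at_age(spec, a),
                                 logical(1))]
      base <- stats::rnorm(1, K$weight0, K$weight_between)
      incr <- diff(ages_m) * spec$weight_slope *
        exp(stats::rnorm(length(ages_m) - 1L, 0, K$weight_incr_sd))
      data.frame(mouse_id = sprintf("m%02d", m), age_months = ages_m,
                 weight_g = base + c(0, cumsum(incr)), stringsAsFactors = FALSE)
    })))
  bouts <- do.call(rbind, lapply(seq_len(spec$n_mice), function(m) {
    do.call(rbind, lapply(spec$ages, function(age) {
      if (!m %in% mice_at_age(spec, age)) return(NULL)
      with_seed(stream_seed(spec$seed, "bouts", m, age_key(spec, age)), {
        do.call(rbind, lapply(c("OR1", "OR15", "OL1", "OL15"), function(task) {
          ro <- spec$rho[["object"]]
          o_m <- with_seed(stream_seed(spec$seed, "latent-object", m, task),
                           stats::rnorm(1))
          u <- sqrt(max(ro, 0)) * o_m + sqrt(max(1 - ro, 0)) * stats::rnorm(1)
          p <- min(max(0.5 + K$pref_gain + K$pref_sd * u, 0.02), 0.98)
          tot <- stats::rlnorm(1, log(35), 0.35)
          samp <- stats::rlnorm(2, log(15), 0.4)
          data.frame(mouse_id = sprintf("m%02d", m), age_months = age,
                     task = task,
                     phase = c("sample", "sample", "choice", "choice"),
                     object = c("novel", "familiar", "novel", "familiar"),
                     duration = c(samp, p * tot, (1 - p) * tot),
                     stringsAsFactors = FALSE)
        }))
      })
    }))
  }))
  occupancy <- do.call(rbind, lapply(seq_len(spec$n_mice), function(m) {
    do.call(rbind, lapply(seq_along(spec$ages), function(k) {
      age <- spec$ages[k]
      if (!m %in% mice_at_age(spec, age)) return(NULL)
      with_seed(stream_seed(spec$seed, "field", m, age), {
        base_out <- min(max(K$outer0 + spec$outer_slope * (age - spec$ages[1]),
                            0.05), 0.95)
        f_out <- stats::plogis(stats::qlogis(base_out) +
                                 K$of_out_mouse * lat$w_out[m] +
                                 K$of_out_noise * stats::rnorm(1))
        centre_share <- stats::rbeta(1, 2, 3)
        total_s <- 1800
        speed <- (K$of_speed0 + spec$speed_slope * (age - spec$ages[1])) *
          exp(K$of_sp * lat$sp[m, k] + stats::rnorm(1, 0, K$of_noise))
        data.frame(mouse_id = sprintf("m%02d", m), age_months = age,
                   centre_s = (1 - f_out) * centre_share * total_s,
                   inner_s = (1 - f_out) * (1 - centre_share) * total_s,
                   outer_s = f_out * total_s, total_s = total_s,
                   path_cm = speed * total_s, stringsAsFactors = FALSE)
      })
    }))
  }))
  rownames(weights) <- rownames(bouts) <- rownames(occupancy) <- NULL
  truth <- list(mouse_id = sprintf("m%02d", seq_len(spec$n_mice)),
                ability = lat$g, ability_by_age = lat$g_eff,
                speed_latent = lat$sp, rho = spec$rho,
                decliner = if (is.null(spec$decliner)) character(0) else
                  sprintf("m%02d", spec$decliner$mouse))
  cohort <- structure(list(spec = spec, blocks = blocks, weights = weights,
                           bouts = bouts, occupancy = occupancy, truth = truth),
                      class = "maze_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.maze_cohort <- function(x, ...) {
  cat(sprintf("Synthetic maze cohort: %d mice, ages %s months, %d session blocks\n",
              x$spec$n_mice, paste(x$spec$ages, collapse = "/"), length(x$blocks)))
  if (length(x$truth$decliner))
    cat(sprintf("  planted decliner: %s\n", paste(x$truth$decliner, collapse = ", ")))
  invisible(x)
}

#' Planted generating parameters of a cohort
#'
#' The oracle table for recovery tests: each mouse's latent ability (and
#' its per-age trajectory, which differs from the scalar only for a planted
#' decliner), the planted inter-age correlations, and the decliner
#' identity.
#'
#' @param x a `maze_cohort` or a [cohort_spec()] (regenerated if a spec).
#' @return list with `mouse_id`, `ability`, `ability_by_age`, `rho`,
#'   `decliner`.
#' @export
truth_table <- function(x) {
  if (inherits(x, "cohort_spec")) x <- generate_cohort(x)
  stopifnot(inherits(x, "maze_cohort"))
  x$truth
}

#' Event-log and trial tables of a cohort
#'
#' Serialises the cohort's maze sessions into the long-format region
#' entry/exit event table plus the companion per-trial table (duration and
#' path length) — the same dialect [read_event_log()] ingests and
#' [sessions_from_logs()] reconstructs from. Non-arm region visits are
#' placed at deterministic times within the trial, so the serialisation is
#' reproducible bit for bit.
#'
#' @param cohort a `maze_cohort`.
#' @return list of data.frames `events` and `trials`.
#' @export
cohort_event_log <- function(cohort) {
  stopifnot(inherits(cohort, "maze_cohort"))
  layout <- arena_layout(cohort$spec$n_arms)
  ev <- list(); ti <- list()
  for (b in cohort$blocks) for (tr in b$trials) {
    rows <- data.frame(t = c(0, min(0.5, tr$t_trial)),
                       region = layout$inner_centre,
                       kind = c("entry", "exit"), stringsAsFactors = FALSE)
    if (length(tr$arms)) {
      et <- tr$entry_t
      arm_r <- layout$arms[tr$arms + 1L]
      bridge_r <- layout$bridges[tr$arms + 1L]
      # bridge crossing starts within the gap since the previous entry so
      # repeated crossings of one bridge never overlap
      gap_before <- diff(c(0, et))
      rows <- rbind(rows,
        data.frame(t = pmax(et - pmin(1.5, 0.4 * gap_before), 0),
                   region = bridge_r, kind = "entry"),
        data.frame(t = et, region = bridge_r, kind = "exit"),
        data.frame(t = et, region = arm_r, kind = "entry"),
        data.frame(t = et + tr$dwell, region = arm_r, kind = "exit"))
    }
    # other visited regions (outer-centre, bridge-only) at evenly spaced times
    extra <- setdiff(tr$regions,
                     c(layout$inner_centre,
                       if (length(tr$arms)) layout$arms[tr$arms + 1L],
                       if (length(tr$arms)) layout$bridges[tr$arms + 1L]))
    if (length(extra)) {
      tau <- tr$t_trial * seq_along(extra) / (length(extra) + 1)
      rows <- rbind(rows,
        data.frame(t = tau, region = extra, kind = "entry"),
        data.frame(t = pmin(tau + 1, tr$t_trial), region = extra, kind = "exit"))
    }
    rows <- rows[order(rows$t, rows$region, rows$kind == "exit"), , drop = FALSE]
    rows <- cbind(data.frame(mouse_id = tr$mouse_id, age_months = tr$age_months,
                             day = tr$day, stringsAsFactors = FALSE), rows)
    ev[[length(ev) + 1L]] <- rows
    ti[[length(ti) + 1L]] <- data.frame(mouse_id = tr$mouse_id,
                                        age_months = tr$age_months, day = tr$day,
                                        t_trial = tr$t_trial,
                                        distance_cm = tr$distance_cm,
                                        stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev); trials <- do.call(rbind, ti)
  rownames(events) <- rownames(trials) <- NULL
  list(events = events, trials = trials)
}

#' Metric and Z-tables straight from a cohort
#'
#' Convenience wrapper running the metric stage over a cohort's session
#' blocks and bout table: one [metric_table()] per age, optionally
#' standardised.
#'
#' @param cohort a `maze_cohort`.
#' @param standardise return `ztable`s instead of raw metric tables.
#' @return named list of per-age tables (names are the ages).
#' @export
cohort_metric_tables <- function(cohort, standardise = FALSE) {
  stopifnot(inherits(cohort, "maze_cohort"))
  layout <- arena_layout(cohort$spec$n_arms)
  tab <- metric_table(cohort$blocks, bouts = cohort$bouts, layout = layout)
  out <- lapply(split(tab, tab$age_months), function(x) {
    rownames(x) <- NULL
    if (standardise) zscore_table(x) else x
  })
  out[order(as.numeric(names(out)))]
}
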