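# Stochastic null model of arm choice.
#
# The null agent starts from a uniformly chosen arm and draws subsequent
# arms from one of three kernels; applying the same unique-sequence
# decomposition as for real animals gives the chance-level length
# distribution against which mouse behaviour is compared.

#' Specification of the stochastic null model
#'
#' @param n_agents number of simulated agents.
#' @param n_trials_per_agent trials per agent (default 16, one session).
#' @param n_arms number of maze arms (default 9).
#' @param kernel arm-choice rule: `"uniform"` (iid uniform over all arms,
#'   same-arm re-entry allowed), `"no_repeat"` (uniform over the other
#'   arms), or `"offset"` (offsets -4..+4 drawn with weights `weights`).
#' @param weights offset weights over -4..+4 for the `"offset"` kernel;
#'   non-negative, not all zero (normalised internally).
#' @param max_entries arm entries per trial before termination (default 9).
#' @param seed integer seed.
#' @return an object of class `null_model_spec`.
#' @export
null_model_spec <- function(n_agents, n_trials_per_agent = 16L, n_arms = 9L,
                            kernel = c("uniform", "no_repeat", "offset"),
                            weights = NULL, max_entries = 9L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (n_agents < 1L || n_trials_per_agent < 1L || max_entries < 1L)
    stopf("agent, trial and entry counts must be >= 1")
  if (n_arms < 2L) stopf("n_arms must be >= 2")
  half <- n_arms %/% 2L
  if (kernel == "offset") {
    if (is.null(weights) || length(weights) != 2L * half + 1L)
      stopf("offset kernel needs %d weights (offsets %d..%d)",
            2L * half + 1L, -half, half)
    if (any(weights < 0) || sum(weights) <= 0)
      stopf("offset weights must be non-negative and not all zero")
    weights <- weights / sum(weights)
  }
  structure(list(n_agents = as.integer(n_agents),
                 n_trials_per_agent = as.integer(n_trials_per_agent),
                 n_arms = as.integer(n_arms), kernel = kernel,
                 weights = weights, max_entries = as.integer(max_entries),
                 seed = as.integer(seed)),
            class = "null_model_spec")
}

#' Simulate a null cohort of arm-entry sequences
#'
#' Every trial starts from a uniformly chosen arm; subsequent entries are
#' drawn from the spec's kernel until `max_entries` entries. Reproducible
#' given the spec seed.
#'
#' @param spec a [null_model_spec()].
#' @return integer matrix of arm indices, one row per trial
#'   (`n_agents * n_trials_per_agent` rows, `max_entries` columns).
#' @export
simulate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "null_model_spec"))
  n <- spec$n_agents * spec$n_trials_per_agent
  k <- spec$n_arms
  half <- k %/% 2L
  with_seed(spec$seed, {
    m <- matrix(0L, nrow = n, ncol = spec$max_entries)
    m[, 1L] <- sample.int(k, n, replace = TRUE) - 1L
    if (spec$max_entries > 1L) for (j in 2:spec$max_entries) {
      m[, j] <- switch(spec$kernel,
        uniform = sample.int(k, n, replace = TRUE) - 1L,
        no_repeat = {
          step <- sample.int(k - 1L, n, replace = TRUE)  # 1..k-1, never 0
          (m[, j - 1L] + step) %% k
        },
        offset = {
          off <- sample((-half):half, n, replace = TRUE, prob = spec$weights)
          (m[, j - 1L] + off) %% k
        })
    }
    m
  })
}

#' Pooled unique-sequence length histogram of simulated trials
#'
#' Applies the same [decompose_unique_sequences()] parse used for animal
#' data to every simulated trial, pools the segment lengths, and reports the
#' histogram and its modal length. Ties are broken toward the smaller
#' length and reported in the `modes` attribute.
#'
#' @param sequences integer matrix from [simulate_null_cohort()] (or a list
#'   of integer vectors).
#' @param n_arms number of arms (lengths run 1..`n_arms`).
#' @return named integer vector of counts over lengths `1..n_arms`, with
#'   attributes `mode` (smallest modal length) and `modes` (all tied modes).
#' @export
null_length_histogram <- function(sequences, n_arms = 9L) {
  if (is.matrix(sequences)) sequences <- asplit(sequences, 1)
  if (!length(sequences)) stopf("no sequences supplied")
  lens <- unlist(lapply(sequences, function(s)
    decompose_unique_sequences(s, n_arms)$lengths), use.names = FALSE)
  h <- tabulate(lens, n_arms)
  modes <- which(h == max(h))
  structure(stats::setNames(h, seq_len(n_arms)),
            mode = modes[1L], modes = modes)
}

#' Exact pooled segment-length distribution under iid uniform choice
#'
#' Expected per-trial counts of unique-sequence lengths for the iid uniform
#' kernel, by dynamic programming over the parse state (size of the growing
#' segment): after each entry a segment of size `s` closes with probability
#' `s / n_arms` and the next segment starts at size 1; the trailing segment
#' is counted at termination. This is the analytic companion to
#' [null_length_histogram()] and pins down the model's modal length without
#' sampling error.
#'
#' @param n_arms number of arms.
#' @param n_entries entries per trial.
#' @return named numeric vector of expected counts per trial over lengths
#'   `1..n_arms`, with attribute `mode`.
#' @export
null_length_distribution <- function(n_arms = 9L, n_entries = 9L) {
  counts <- numeric(n_arms)
  state <- numeric(n_arms)  # probability the growing segment has size s
  state[1L] <- 1
  if (n_entries > 1L) for (k in 2:n_entries) {
    nxt <- numeric(n_arms)
    for (s in which(state > 0)) {
      p_close <- s / n_arms
      counts[s] <- counts[s] + state[s] * p_close
      nxt[1L] <- nxt[1L] + state[s] * p_close
      if (s < n_arms) nxt[s + 1L] <- nxt[s + 1L] + state[s] * (1 - p_close)
    }
    state <- nxt
  }
  counts <- counts + state
  structure(stats::setNames(counts, seq_len(n_arms)),
            mode = which.max(counts))
}

#' Exact first-segment length distribution under iid uniform choice
#'
#' Closed form for the length of the first parsed unique sequence:
#' `P(L = k) = (n-1)/n * (n-2)/n * ... * (n-k+1)/n * k/n` for `k < n`, with
#' the error-free event folded into `k = n`. Distinguishes first-segment
#' from pooled-segment statistics (their modes differ: 3 vs 2 for nine
#' arms and nine entries).
#'
#' @param n_arms number of arms (>= 2).
#' @return numeric probability vector over lengths `1..n_arms` (sums to 1).
#' @export
analytic_first_segment_pmf <- function(n_arms = 9L) {
  if (n_arms < 2L) stopf("n_arms must be >= 2")
  p <- numeric(n_arms)
  q <- 1  # P(first k entries all distinct)
  for (k in seq_len(n_arms - 1L)) {
    p[k] <- q * k / n_arms
    q <- q * (n_arms - k) / n_arms
  }
  p[n_arms] <- q
  stats::setNames(p, seq_len(n_arms))
}
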