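# Per-mouse lifespan trends, cross-age prediction, exhaustive metric-subset
# search, subsample resampling and decliner detection.

#' Per-mouse lifespan trend of one metric
#'
#' Regresses a mouse's metric values on age in months. For the maze metrics
#' the natural input is the per-day values from [daily_metrics()] (up to 64
#' observations across four ages); for once-per-age measures such as weight
#' the four block values are used. Needs data at three or more distinct
#' ages; otherwise `NA` is returned (a missing trend, not an error, so
#' cohort-level summaries simply skip the mouse).
#'
#' @param values numeric metric values.
#' @param ages ages in months, parallel to `values`.
#' @param lambda slope penalty passed to [stability_fit()].
#' @return a [stability_fit()] object, or `NA` when fewer than three
#'   distinct ages carry data.
#' @export
lifespan_trend <- function(values, ages, lambda = 0) {
  ok <- stats::complete.cases(values, ages)
  if (length(unique(ages[ok])) < 3L) return(NA)
  stability_fit.default(ages[ok], values[ok], lambda = lambda)
}

#' Cross-age predictive correlation of a metric combination
#'
#' Stouffer-combines the given metric subset within each age's Z-table,
#' aligns mice present at both ages, and fits the late composite on the
#' early composite, reporting slope, intercept, Pearson r, R^2 and p.
#'
#' @param z_early,z_late `ztable`s for the two ages (e.g. 4 and 18 months).
#' @param metrics non-empty metric subset to combine.
#' @param lambda slope penalty.
#' @return a [stability_fit()] with extra fields `metrics` and `ages`.
#' @export
predictive_correlation <- function(z_early, z_late, metrics, lambda = 0) {
  a <- stouffer_combine(z_early, metrics)
  b <- stouffer_combine(z_late, metrics)
  m <- merge(a[c("mouse_id", "z")], b[c("mouse_id", "z")],
             by = "mouse_id", suffixes = c("_early", "_late"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stopf("fewer than 3 mice present at both ages")
  fit <- stability_fit.default(m$z_early, m$z_late, lambda = lambda)
  fit$metrics <- metrics
  fit$ages <- c(unique(z_early$age_months), unique(z_late$age_months))
  fit$xname <- sprintf("combined Z at %g months", fit$ages[1])
  fit$yname <- sprintf("combined Z at %g months", fit$ages[2])
  fit
}

#' Exhaustive metric-combination search
#'
#' Evaluates every non-empty subset of the metric universe (2047 subsets
#' for the full eleven metrics) by the mean coefficient of determination of
#' its Stouffer composite across the configured age comparisons, and
#' returns the subsets ranked by that mean R^2 (ties broken
#' lexicographically on the subset label, so the ranking is deterministic).
#'
#' @param ztables named list of `ztable`s keyed by age (names coercible to
#'   numeric, e.g. `"4"`, `"8"`, `"12"`, `"18"`).
#' @param metrics metric universe to search over (default: the registered
#'   metrics present in every table).
#' @param comparisons list of age pairs to average over; default compares
#'   the earliest age with each later age (4 vs 8, 4 vs 12, 4 vs 18 for the
#'   full design, since the study frames prediction from the first age
#'   point).
#' @param lambda slope penalty for the underlying fits.
#' @return data.frame with one row per subset: `subset` (label
#'   `"a+b+c"`), `size`, `mean_r2`, `rank`, ordered best first.
#' @export
combination_search <- function(ztables, metrics = NULL, comparisons = NULL,
                               lambda = 0) {
  ages <- as.numeric(names(ztables))
  if (anyNA(ages)) stopf("ztables must be a list named by age")
  ord <- order(ages)
  ztables <- ztables[ord]; ages <- ages[ord]
  metrics <- metrics %||% Reduce(intersect, c(list(metric_universe()),
                                              lapply(ztables, names)))
  metrics <- sort(metrics)
  p <- length(metrics)
  if (!p) stopf("no common metric columns across the Z-tables")
  comparisons <- comparisons %||%
    lapply(ages[-1], function(a) c(ages[1], a))
  # precompute per-age Z matrices with mouse ids as rownames
  zmats <- lapply(ztables, function(z) {
    m <- as.matrix(as.data.frame(z)[, metrics, drop = FALSE])
    rownames(m) <- z$mouse_id
    m
  })
  names(zmats) <- as.character(ages)
  n_sub <- 2^p - 1L
  labels <- character(n_sub); sizes <- integer(n_sub); score <- numeric(n_sub)
  bits <- 2^(seq_len(p) - 1L)
  for (s in seq_len(n_sub)) {
    sel <- bitwAnd(s, bits) > 0L
    labels[s] <- paste(metrics[sel], collapse = "+")
    sizes[s] <- sum(sel)
    r2 <- vapply(comparisons, function(cp) {
      za <- zmats[[as.character(cp[1])]]; zb <- zmats[[as.character(cp[2])]]
      ca <- stouffer_rows(za[, sel, drop = FALSE])
      cb <- stouffer_rows(zb[, sel, drop = FALSE])
      common <- intersect(names(ca)[!is.na(ca)], names(cb)[!is.na(cb)])
      if (length(common) < 3L) return(NA_real_)
      pearson_r(ca[common], cb[common])^2
    }, numeric(1))
    score[s] <- mean(r2, na.rm = TRUE)
  }
  out <- data.frame(subset = labels, size = sizes, mean_r2 = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_r2, out$subset), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# row-wise Stouffer composite of a Z matrix, preserving names
stouffer_rows <- function(zm) {
  k <- rowSums(!is.na(zm))
  z <- ifelse(k > 0, rowSums(zm, na.rm = TRUE) / sqrt(k), NA_real_)
  stats::setNames(z, rownames(zm))
}

#' Subsample-resampling robustness curve
#'
#' Draws random mouse subsets of every size from `min_size` up to the full
#' cohort (`draws` datasets per size; the defaults give `n * n` resampled
#' datasets, 441 for a cohort of 21), refits the early-vs-late regression
#' on each, and summarises the variance of the Pearson coefficient as a
#' function of the fit's degrees of freedom (`size - 2`). Draws of fewer
#' than three mice cannot support a fit and carry `NA`; they are excluded
#' from the variance curve. A stable trait shows low, flat variance at high
#' degrees of freedom and blows up only below roughly ten.
#'
#' @param x,y paired per-mouse values at the two ages (e.g. combined Z at 4
#'   and 18 months).
#' @param draws resampled datasets per size (default `length(x)`).
#' @param min_size smallest subset size drawn (default 1).
#' @param lambda slope penalty.
#' @param seed integer seed for the subset draws.
#' @return list of class `resampling_curve`: `fits` (data.frame with
#'   `size`, `dof`, `r`), `variance` (data.frame `dof`, `var_r`),
#'   `n_fits` (total datasets drawn).
#' @export
resampling_variance_curve <- function(x, y, draws = NULL, min_size = 1L,
                                      lambda = 0, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("need at least 4 paired mice")
  draws <- as.integer(draws %||% n)
  sizes <- seq.int(as.integer(min_size), n)
  fits <- with_seed(seed, {
    do.call(rbind, lapply(sizes, function(s) {
      r <- vapply(seq_len(draws), function(i) {
        idx <- sample.int(n, s)
        if (s < 3L) return(NA_real_)
        f <- stability_fit.default(x[idx], y[idx], lambda = lambda)
        if (is.na(f$r)) NA_real_ else f$r
      }, numeric(1))
      data.frame(size = s, dof = s - 2L, r = r)
    }))
  })
  usable <- fits[!is.na(fits$r), , drop = FALSE]
  variance <- stats::aggregate(r ~ dof, data = usable,
                               FUN = function(v) stats::var(v) * (length(v) - 1) / length(v))
  names(variance)[2] <- "var_r"
  structure(list(fits = fits, variance = variance, n_fits = nrow(fits)),
            class = "resampling_curve")
}

#' @export
print.resampling_curve <- function(x, ...) {
  cat(sprintf("Resampling robustness curve: %d resampled datasets, dof %d..%d\n",
              x$n_fits, min(x$variance$dof), max(x$variance$dof)))
  invisible(x)
}

#' Detect cognitive decliners
#'
#' A mouse is flagged as a decliner when at least `m` of the five maze
#' metrics (USS, errors, decision-making time, cumulative arm time,
#' exploration ratio) show a statistically significant trend across ages in
#' the adverse direction for that metric (falling USS/arm time/exploration
#' ratio, rising errors/decision time). Trends are fitted on per-day values
#' via [lifespan_trend()]; p-values are used raw by default (the m-of-5
#' consensus is the guard against isolated false positives), with a
#' Bonferroni option for familywise control across the five metrics.
#'
#' @param daily per-day metric data.frame from [daily_metrics()].
#' @param m minimum number of concordant adverse metrics to flag (default 3).
#' @param alpha per-metric significance level (default 0.05).
#' @param adjust `"none"` (raw p, default) or `"bonferroni"` (alpha / 5).
#' @param lambda slope penalty for the trend fits.
#' @return data.frame with one row per mouse: `mouse_id`,
#'   `n_adverse` (significant adverse trends among the five), `flagged`;
#'   attribute `"details"` holds the per-(mouse, metric) slopes and
#'   p-values.
#' @export
detect_decliners <- function(daily, m = 3L, alpha = 0.05,
                             adjust = c("none", "bonferroni"), lambda = 0) {
  adjust <- match.arg(adjust)
  adverse <- decliner_metrics()
  miss <- setdiff(names(adverse), names(daily))
  if (length(miss)) stopf("daily metric column(s) absent: %s",
                          paste(miss, collapse = ", "))
  thr <- if (adjust == "bonferroni") alpha / length(adverse) else alpha
  det <- do.call(rbind, lapply(split(daily, daily$mouse_id), function(d) {
    do.call(rbind, lapply(names(adverse), function(mt) {
      f <- lifespan_trend(d[[mt]], d$age_months, lambda = lambda)
      if (!inherits(f, "stability_fit"))
        return(data.frame(mouse_id = d$mouse_id[1], metric = mt,
                          slope = NA_real_, p = NA_real_, adverse = FALSE))
      sl <- f$coefficients[["slope"]]
      data.frame(mouse_id = d$mouse_id[1], metric = mt, slope = sl,
                 p = f$p.value,
                 adverse = !is.na(f$p.value) && f$p.value < thr &&
                   sign(sl) == adverse[[mt]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(det) <- NULL
  agg <- stats::aggregate(adverse ~ mouse_id, data = det, FUN = sum)
  out <- data.frame(mouse_id = agg$mouse_id, n_adverse = agg$adverse,
                    flagged = agg$adverse >= m, stringsAsFactors = FALSE)
  attr(out, "details") <- det
  out
}
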