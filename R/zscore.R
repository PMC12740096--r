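# Per-age standardisation and Stouffer combination.

#' Standardise a metric table into Z-scores
#'
#' Each metric column is standardised within each age group as
#' `(x - mu) / sigma` with the population mean and, by default, the
#' population standard deviation (divisor `n`; a sample-sd switch is
#' provided and recorded, since the choice rescales every Z by a constant
#' factor). Columns for which a lower raw value means better performance
#' (decision-making time and errors by convention) are sign-inverted after
#' standardisation so that a higher Z is always better; the inversion is
#' recorded in the `inverted` attribute. Re-applying the function to a
#' Z-table standardises without re-inverting, making the operation
#' idempotent on complete columns.
#'
#' @param tbl data.frame with `mouse_id`, `age_months` and metric columns
#'   (e.g. from [metric_table()]), or an existing `ztable`.
#' @param metrics metric columns to standardise (default: every registered
#'   metric present in `tbl`).
#' @param invert metrics to sign-invert after standardisation.
#' @param sd_type `"population"` (divisor n) or `"sample"` (divisor n-1).
#' @return a data.frame of class `ztable` with the same shape; attributes
#'   `inverted`, `sd_type` and `scaling` (per-age mu/sigma used).
#' @export
zscore_table <- function(tbl, metrics = NULL, invert = c("dmt", "errors"),
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (inherits(tbl, "ztable")) invert <- character(0)  # already applied
  metrics <- metrics %||% intersect(metric_universe(), names(tbl))
  if (!length(metrics)) stopf("no registered metric columns found")
  miss <- setdiff(metrics, names(tbl))
  if (length(miss)) stopf("metric column(s) absent: %s", paste(miss, collapse = ", "))
  out <- tbl
  scaling <- list()
  for (age in unique(tbl$age_months)) {
    sel <- tbl$age_months == age
    for (m in metrics) {
      x <- tbl[[m]][sel]
      ok <- !is.na(x)
      if (sum(ok) < 2L)
        stopf("metric '%s' at %g months has < 2 non-missing values", m, age)
      mu <- mean(x[ok])
      sigma <- stats::sd(x[ok])
      if (sd_type == "population") sigma <- sigma * sqrt((sum(ok) - 1) / sum(ok))
      if (!is.finite(sigma) || sigma == 0)
        stopf("metric '%s' at %g months is constant: Z-score undefined", m, age)
      z <- (x - mu) / sigma
      if (m %in% invert) z <- -z
      out[[m]][sel] <- z
      scaling[[paste(age, m, sep = ":")]] <- c(mu = mu, sigma = sigma)
    }
  }
  structure(out, inverted = intersect(invert, metrics), sd_type = sd_type,
            scaling = scaling, class = c("ztable", class(tbl)))
}

#' Stouffer combination of Z-scores
#'
#' Combines the selected metric Z-scores of each mouse into one composite,
#' `Z = sum_i Z_i / sqrt(k)`, where `k` counts the metrics actually
#' available for that mouse (missing entries are excluded and `k` reduced
#' accordingly); a mouse with no available metric gets `NA`.
#'
#' @param ztbl a `ztable` from [zscore_table()].
#' @param metrics non-empty character vector of metric columns to combine.
#' @return data.frame with `mouse_id`, `age_months`, `z` (composite) and
#'   `k` (metrics used per mouse).
#' @examples
#' # four metrics each at Z = 1 combine to 4 / sqrt(4) = 2
#' @export
stouffer_combine <- function(ztbl, metrics) {
  if (!length(metrics)) stopf("metric subset must be non-empty")
  miss <- setdiff(metrics, names(ztbl))
  if (length(miss)) stopf("metric column(s) absent: %s", paste(miss, collapse = ", "))
  zm <- as.matrix(as.data.frame(ztbl)[, metrics, drop = FALSE])
  k <- rowSums(!is.na(zm))
  z <- ifelse(k > 0, rowSums(zm, na.rm = TRUE) / sqrt(k), NA_real_)
  data.frame(mouse_id = ztbl$mouse_id, age_months = ztbl$age_months,
             z = z, k = k, stringsAsFactors = FALSE)
}
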