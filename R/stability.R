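# Slope-regularised linear trait-stability fit and Pearson correlation.
#
# The fit minimises sum((y - (a + b x))^2) + lambda * b^2. With lambda = 0
# this is exactly ordinary least squares; a positive lambda shrinks the
# slope toward zero to guard against over-fitting short longitudinal
# series. Significance is always reported from the F test of the
# unpenalised fit, which is how fit significance is conventionally quoted
# for these regressions.

#' Pearson's product-moment correlation
#'
#' Direct evaluation of
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' on complete pairs. A constant input leaves `r` undefined; `NA` is
#' returned with a warning rather than an error so that degenerate
#' per-mouse series propagate as flagged missing values.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("pearson_r needs >= 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(dx * dy) / den
}

#' Trait-stability linear fit
#'
#' Fits `y = intercept + slope * x` by least squares with an optional L2
#' penalty `lambda` on the slope (`slope = Sxy / (Sxx + lambda)`); with the
#' default `lambda = 0` the estimates equal ordinary least squares to
#' machine precision. The report carries Pearson's r between x and y, `R^2
#' = r^2`, and the p-value of the unpenalised fit's F test, which is the
#' trio quoted for each metric or metric combination when comparing two
#' ages or a mouse's lifespan.
#'
#' @param x predictor (e.g. combined Z at 4 months, or age in months), or a
#'   formula `y ~ x`.
#' @param y response (e.g. combined Z at 18 months).
#' @param lambda ridge penalty on the slope, >= 0 (default 0).
#' @param data data.frame in which a formula is evaluated.
#' @param ... unused.
#' @return an object of class `stability_fit` with components
#'   `coefficients` (intercept, slope), `r`, `r.squared`, `p.value`, `n`,
#'   `lambda`, `fitted.values`, `residuals`, `x`, `y`.
#' @examples
#' f <- stability_fit(1:10, 2 * (1:10) + 1)
#' coef(f)          # intercept 1, slope 2
#' summary(f)
#' @export
stability_fit <- function(x, ...) UseMethod("stability_fit")

#' @rdname stability_fit
#' @export
stability_fit.formula <- function(x, data = parent.frame(), lambda = 0, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 2L) stopf("formula must be of the form y ~ x")
  fit <- stability_fit.default(mf[[2L]], mf[[1L]], lambda = lambda)
  fit$call <- match.call()
  fit$xname <- names(mf)[2L]; fit$yname <- names(mf)[1L]
  fit
}

#' @rdname stability_fit
#' @export
stability_fit.default <- function(x, y, lambda = 0, ...) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stopf("stability fit needs >= 3 complete observations")
  if (!is.finite(lambda) || lambda < 0) stopf("lambda must be >= 0")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("predictor is constant: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / (sxx + lambda)
  intercept <- mean(y) - slope * mean(x)
  r <- if (sum((y - mean(y))^2) == 0) {
    NA_real_  # constant response: correlation undefined, slope is 0
  } else sxy / sqrt(sxx * sum((y - mean(y))^2))
  r2 <- r^2
  p <- if (is.na(r) || n < 4 && abs(r) >= 1) NA_real_ else {
    fstat <- r2 * (n - 2) / max(1 - r2, .Machine$double.eps)
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  }
  fitted <- intercept + slope * x
  structure(list(coefficients = c(intercept = intercept, slope = slope),
                 r = r, r.squared = r2, p.value = p, n = n, lambda = lambda,
                 fitted.values = fitted, residuals = y - fitted,
                 x = x, y = y, xname = "x", yname = "y",
                 call = match.call()),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, digits = 4, ...) {
  cat("Trait-stability linear fit")
  if (x$lambda > 0) cat(sprintf(" (slope penalty lambda = %g)", x$lambda))
  cat("\n")
  cat(sprintf("  n = %d, intercept = %.*g, slope = %.*g\n",
              x$n, digits, x$coefficients[["intercept"]],
              digits, x$coefficients[["slope"]]))
  cat(sprintf("  Pearson r = %.*g, R^2 = %.*g, p = %.*g\n",
              digits, x$r, digits, x$r.squared, digits, x$p.value))
  invisible(x)
}

#' @export
summary.stability_fit <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(sum(object$residuals^2) / max(object$n - 2, 1))),
            class = "summary.stability_fit")
}

#' @export
print.summary.stability_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.4g on %d degrees of freedom\n",
              x$sigma, x$fit$n - 2))
  invisible(x)
}

#' @export
coef.stability_fit <- function(object, ...) object$coefficients

#' @export
residuals.stability_fit <- function(object, ...) object$residuals

#' @export
fitted.stability_fit <- function(object, ...) object$fitted.values

#' @export
predict.stability_fit <- function(object, newx = NULL, ...) {
  if (is.null(newx)) return(object$fitted.values)
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * newx
}

#' @export
plot.stability_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
                 main = sprintf("r = %.3f, p = %.3g", x$r, x$p.value), ...)
  graphics::abline(x$coefficients[["intercept"]], x$coefficients[["slope"]])
  invisible(x)
}
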