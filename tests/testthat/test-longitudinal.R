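test_that("lifespan trend needs three ages and flags constant series", {
  expect_true(is.na(suppressWarnings(lifespan_trend(c(1, 2), c(4, 8)))))
  f <- suppressWarnings(lifespan_trend(rep(5, 4), c(4, 8, 12, 18)))
  expect_equal(coef(f)[["slope"]], 0)
  expect_true(is.na(f$r))
  # strictly increasing weight-like series
  w <- c(22, 24.5, 27.4, 31.2)
  fw <- lifespan_trend(w, c(4, 8, 12, 18))
  expect_gt(fw$r, 0.99)
  expect_lt(fw$p.value, 0.05)
})

test_that("a planted negative drift is recovered with its confidence interval", {
  set.seed(31)
  ages <- rep(c(4, 8, 12, 18), each = 16)
  slopes <- replicate(50, {
    y <- -0.5 * (ages - 4) / 4 + rnorm(length(ages))  # -0.5 sd per age step
    f <- lifespan_trend(y, ages)
    c(coef(f)[["slope"]] * 4, f$p.value)  # per age-step units
  })
  expect_lt(abs(mean(slopes[1, ]) + 0.5), 0.1)
  expect_gt(mean(slopes[2, ] < 0.05), 0.9)  # drift is detected
})

test_that("predictive correlation is 1 for identical tables and ~0 for noise", {
  set.seed(32)
  m <- cbind(uss = rnorm(20), errors = rnorm(20))
  za <- table_from_matrix(m, age = 4); zb <- table_from_matrix(m, age = 18)
  f <- predictive_correlation(za, zb, c("uss", "errors"))
  expect_equal(f$r, 1, tolerance = 1e-12)
  big <- 2000
  za2 <- table_from_matrix(cbind(uss = rnorm(big)), age = 4)
  zb2 <- table_from_matrix(cbind(uss = rnorm(big)), age = 18)
  expect_lt(abs(predictive_correlation(za2, zb2, "uss")$r), 4 / sqrt(big))
  expect_error(predictive_correlation(za, zb, character(0)), "non-empty")
})

test_that("combination search is exhaustive with deterministic ranking", {
  set.seed(33)
  m4 <- matrix(rnorm(10 * 3), ncol = 3, dimnames = list(NULL, c("uss", "dmt", "or1")))
  zt <- list(`4` = table_from_matrix(m4, age = 4),
             `18` = table_from_matrix(m4 + rnorm(30, 0, 0.4), age = 18))
  res <- combination_search(zt)
  expect_equal(nrow(res), 7)  # 2^3 - 1
  expect_equal(anyDuplicated(res$subset), 0)
  expect_equal(res$rank, 1:7)
  expect_true(all(diff(res$mean_r2) <= 1e-12))
  # every subset of the universe appears exactly once
  expect_setequal(res$subset,
                  c("dmt", "or1", "uss", "dmt+or1", "dmt+uss", "or1+uss",
                    "dmt+or1+uss"))
})

test_that("combination search recovers a planted three-metric signal", {
  set.seed(34)
  n <- 40
  g <- rnorm(n)
  signal <- c("arm_time", "uss", "velocity")
  noise <- c("dmt", "errors", "or1")
  mk <- function() {
    m <- cbind(sapply(signal, function(i) g + rnorm(n, 0, 0.3)),
               sapply(noise, function(i) rnorm(n)))
    colnames(m) <- c(signal, noise)
    m
  }
  zt <- list(`4` = table_from_matrix(mk(), age = 4),
             `18` = table_from_matrix(mk(), age = 18))
  res <- combination_search(zt)
  expect_equal(nrow(res), 63)
  expect_equal(res$subset[1], paste(sort(signal), collapse = "+"))
})

test_that("resampling curve draws n x n datasets with zero variance at full size", {
  set.seed(35)
  n <- 21
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, 0, 0.7)
  rc <- resampling_variance_curve(x, y, seed = 5)
  expect_equal(rc$n_fits, 441)
  expect_equal(rc$variance$var_r[rc$variance$dof == n - 2], 0, tolerance = 1e-15)
  # draws smaller than three mice cannot be fitted
  expect_true(all(is.na(rc$fits$r[rc$fits$size < 3])))
  expect_false(anyNA(rc$fits$r[rc$fits$size >= 3]))
  # correlation variance is low and stable at high degrees of freedom
  v <- rc$variance
  expect_lt(mean(v$var_r[v$dof > 10]), mean(v$var_r[v$dof < 5]))
  # reproducible under the seed
  rc2 <- resampling_variance_curve(x, y, seed = 5)
  expect_identical(rc$fits, rc2$fits)
})

test_that("decliner flags need m concordant adverse significant trends", {
  set.seed(36)
  ages <- rep(c(4, 8, 12, 18), each = 16)
  mk_daily <- function(mouse, shift = c(uss = 0, errors = 0, dmt = 0,
                                        arm_time = 0, exploration_ratio = 0)) {
    step <- (ages - 4) / 4
    data.frame(mouse_id = mouse, age_months = ages, day = rep(1:16, 4),
               uss = 10 + shift[["uss"]] * step + rnorm(64),
               errors = 3 + shift[["errors"]] * step + rnorm(64),
               dmt = 60 + shift[["dmt"]] * step + rnorm(64),
               arm_time = 90 + shift[["arm_time"]] * step + rnorm(64),
               exploration_ratio = 0.8 + shift[["exploration_ratio"]] * step +
                 rnorm(64, 0, 0.05))
  }
  # frank decliner: adverse drift in all five; one-metric mouse; stable mouse
  d <- rbind(mk_daily("decl", c(uss = -2, errors = 2, dmt = 2, arm_time = -2,
                                exploration_ratio = -0.15)),
             mk_daily("onemetric", c(uss = -2, errors = 0, dmt = 0,
                                     arm_time = 0, exploration_ratio = 0)),
             mk_daily("stable"))
  res <- detect_decliners(d)
  expect_equal(res$mouse_id[res$flagged], "decl")
  expect_false(res$flagged[res$mouse_id == "onemetric"])
  det <- attr(res, "details")
  expect_true(all(c("slope", "p") %in% names(det)))
  # raising m to 6 can never flag
  expect_false(any(detect_decliners(d, m = 6)$flagged))
})
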