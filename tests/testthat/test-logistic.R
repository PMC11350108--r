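test_that("Newton fit recovers the closed-form 2x2 log odds ratio", {
  # binary covariate with counts (8 events / 2 non) vs (4 / 6):
  # log OR = log((8/2) / (4/6)) = log 6
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  fit <- fit_logistic_newton(matrix(x, ncol = 1), y)
  expect_equal(unname(fit$coef[2]), log(6), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("Newton fit matches glm (independent IRLS implementation) to 1e-6", {
  set.seed(12)
  X <- matrix(rnorm(40), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rbinom(20, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_logistic_newton(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
  llr_ref <- ref$null.deviance - ref$deviance
  expect_equal(fit$llr_stat, llr_ref, tolerance = 1e-6)
})

test_that("complete separation is detected strictly and capped in lenient mode", {
  x <- c(rnorm(10, -3), rnorm(10, 3))
  y <- rep(c(0, 1), each = 10)
  expect_error(fit_logistic_newton(matrix(x, ncol = 1,
                                          dimnames = list(NULL, "sep")), y),
               "separation")
  f <- fit_logistic_newton(matrix(x, ncol = 1), y, strict = FALSE)
  expect_true(f$separated)
  expect_true(all(is.finite(f$coef)))
})

test_that("LLR p-value is calibrated under the null (type I error 5% +/- 2%)", {
  set.seed(99)
  n_sim <- 500
  rejections <- vapply(seq_len(n_sim), function(i) {
    X <- matrix(rnorm(37), ncol = 1)
    y <- c(rep(1, 17), rep(0, 20))  # label-independent covariate
    fit_logistic_newton(X, y)$llr_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("risk-model odds ratios back-transform to per-unit scale", {
  set.seed(20)
  tab <- data.frame(
    group = c(rep("HCM_VF", 17), rep("HCM", 20)),
    m = c(rnorm(17, 64, 7), rnorm(20, 58, 8)))
  fit <- fit_risk_model(tab, "m")
  # refit on hand-scaled data and undo the scaling by hand
  z <- (tab$m - mean(tab$m)) / sd(tab$m)
  ref <- glm(I(tab$group == "HCM_VF") ~ z, family = binomial())
  expect_equal(fit$or$odds_ratio, exp(unname(coef(ref)[2]) / sd(tab$m)),
               tolerance = 1e-6)
  expect_true(fit$or$ci_lo < fit$or$odds_ratio,
              fit$or$ci_hi > fit$or$odds_ratio)
})

test_that("univariate screening keeps separated measures and obeys alpha", {
  set.seed(7)
  tab <- data.frame(
    group = c(rep("HCM_VF", 15), rep("HCM", 15)),
    strong = c(rnorm(15, 3), rnorm(15, 0)),   # ~3 pooled SDs apart
    null_m = rnorm(30))
  expect_identical(screen_univariate(tab, c("strong", "null_m")), "strong")
  expect_setequal(screen_univariate(tab, c("strong", "null_m"), alpha = 1),
                  c("strong", "null_m"))
  # power check: a 3-SD shift qualifies in essentially every cohort
  hits <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    t2 <- data.frame(group = tab$group,
                     s = c(rnorm(15, 3), rnorm(15, 0)))
    length(screen_univariate(t2, "s")) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("collinearity rejection drops the peak-phase twin and logs it", {
  set.seed(8)
  base <- rnorm(40, 60, 8)
  tab <- data.frame(
    recovery_mean_at = base + rnorm(40, 0, 3),
    peak_mean_at = base + rnorm(40, 0, 3),
    other = rnorm(40))
  r <- cor(tab$recovery_mean_at, tab$peak_mean_at)
  expect_gt(r, 0.85)
  kept <- drop_collinear(tab, names(tab), r_threshold = r - 0.01)
  expect_true("recovery_mean_at" %in% kept)
  expect_false("peak_mean_at" %in% kept)
  log <- attr(kept, "dropped")
  expect_equal(log$dropped, "peak_mean_at")
  expect_equal(log$r, r, tolerance = 1e-12)
  # orthogonal measures are untouched
  kept2 <- drop_collinear(tab[, c("recovery_mean_at", "other")],
                          c("recovery_mean_at", "other"))
  expect_length(kept2, 2)
})

test_that("backward stepwise keeps significant models and rejects noise first", {
  set.seed(30)
  tab <- data.frame(
    group = c(rep("HCM_VF", 30), rep("HCM", 30)),
    inf1 = c(rnorm(30, 2), rnorm(30, 0)),
    inf2 = c(rnorm(30, 1.5), rnorm(30, 0)))
  st <- backward_stepwise(tab, c("inf1", "inf2"))
  expect_setequal(st$retained, c("inf1", "inf2"))
  expect_length(st$removal_order, 0)
  # a pure-noise covariate is removed before any informative one
  first_out <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    t2 <- data.frame(
      group = c(rep("HCM_VF", 25), rep("HCM", 25)),
      inf1 = c(rnorm(25, 1.5), rnorm(25, 0)),
      noise = rnorm(50))
    st2 <- backward_stepwise(t2, c("inf1", "noise"))
    if (length(st2$removal_order)) st2$removal_order[1] else "none"
  }, character(1))
  removed <- first_out[first_out != "none"]
  expect_gte(mean(removed == "noise"), 0.9)
})
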