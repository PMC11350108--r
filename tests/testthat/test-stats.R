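test_that("rank-sum test takes the exact path for small untied samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  # enumeration oracle: all C(6,3) = 20 assignments of ranks to group a;
  # the observed allocation is the most extreme on each side -> two-sided 2/20
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(1:2, 1:5), "at least 3")
})

test_that("rank-sum p matches full enumeration on a random small fixture", {
  set.seed(14)
  a <- round(rnorm(4, 0, 5), 2); b <- round(rnorm(5, 1, 5), 2)
  got <- wilcoxon_rank_sum(a, b)
  pool <- c(a, b); n <- length(pool)
  combs <- utils::combn(n, length(a))
  w_obs <- sum(rank(pool)[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ws <- apply(combs, 2, function(idx)
    sum(rank(pool)[idx]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu))
  expect_equal(got$p, p_exact, tolerance = 1e-9)
})

test_that("rank-sum power grows toward 1 for well-separated groups", {
  set.seed(3)
  hits <- mean(replicate(60, {
    wilcoxon_rank_sum(rnorm(25), rnorm(25, 2))$p < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("Kruskal-Wallis matches a hand-rank oracle and enforces its contract", {
  g <- list(c(1, 5, 9), c(2, 6, 10), c(3, 7, 11))
  got <- kruskal_wallis(g)
  # oracle: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 (no ties here)
  pool <- unlist(g); N <- length(pool); rk <- rank(pool)
  grp <- rep(1:3, lengths(g))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  expect_equal(got$statistic, H, tolerance = 1e-10)
  expect_equal(got$df, 2)
  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0, tolerance = 1e-10)
  expect_equal(ident$p, 1, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "rank_sum")
})

test_that("Cohen's h reproduces the published worked example and its bounds", {
  # exact formula value is 0.2271; the published 0.22 reflects truncation
  expect_lt(abs(cohens_h(4 / 20, 2 / 17) - 0.22), 0.01)
  expect_equal(cohens_h(0.37, 0.37), 0)
  expect_equal(cohens_h(0, 1), pi)
  expect_error(cohens_h(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the arcsine proportion test is symmetric and reports Cohen's h", {
  r <- proportion_test(4, 20, 2, 17)
  expect_equal(r$h, cohens_h(0.2, 2 / 17))
  expect_gt(r$p, 0.05)  # the published comparison was non-significant
  r2 <- proportion_test(2, 17, 4, 20)
  expect_equal(r2$p, r$p)
})

test_that("correlations match brute-force formulas and rank invariance", {
  set.seed(10)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.8)
  got <- correlations(x, y, "pearson")
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$estimate, oracle, tolerance = 1e-12)
  expect_equal(correlations(x, x)$estimate, 1)
  # monotone transform: spearman unchanged at 1, pearson below 1
  z <- exp(x)
  expect_equal(correlations(x, z, "spearman")$estimate, 1)
  expect_lt(correlations(x, z, "pearson")$estimate, 1)
  sp <- correlations(x, y, "spearman")
  expect_equal(sp$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(correlations(x, rep(1, 30)), "constant")
  expect_error(correlations(1:3, 2:4), "n >= 4")
})

test_that("group comparison reports are rank-based and label-invariant", {
  set.seed(4)
  tab <- data.frame(group = rep(c("A", "B"), each = 12),
                    m1 = c(rnorm(12), rnorm(12, 3)),
                    m2 = rnorm(24))
  cmp <- compare_groups(tab, "A", "B", c("m1", "m2"))
  expect_lt(cmp$p[cmp$measure == "m1"], 0.01)
  expect_gt(cmp$p[cmp$measure == "m2"], 0.05)
  # monotone transform of the data leaves the rank test untouched
  tab2 <- tab; tab2$m1 <- exp(tab$m1)
  cmp2 <- compare_groups(tab2, "A", "B", "m1")
  expect_equal(cmp2$p, cmp$p[cmp$measure == "m1"], tolerance = 1e-12)
})
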