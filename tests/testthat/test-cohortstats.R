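test_that("2-SD exclusion keeps degenerate and symmetric inputs intact, catches a gross outlier", {
  expect_equal(exclude_outliers(rep(1.5, 5))$n_removed, 0L)
  expect_equal(exclude_outliers(c(-1, 0, 1))$n_removed, 0L)

  set.seed(8)
  hits <- 0; extra <- 0
  for (i in 1:40) {
    x <- c(rnorm(100), 10)
    res <- exclude_outliers(x)
    if (!res$keep[101]) hits <- hits + 1
    extra <- extra + (res$n_removed - 1)
  }
  expect_gte(hits, 38)        # injected point caught in >= 95% of seeds
  expect_lte(extra / 40, 1)   # genuine 2-SD tail hits stay rare
  expect_error(exclude_outliers(c(1, 2)), "3 values")
})

test_that("exclusion never removes more than half the sample", {
  set.seed(9)
  for (i in 1:50) {
    x <- rcauchy(sample(5:40, 1))   # heavy tails stress the bound
    expect_lte(exclude_outliers(x)$n_removed, floor(length(x) / 2))
  }
})

test_that("BH adjustment matches the hand-computed step-up and handles edge cases", {
  r <- fdr_bh(c(0.01, 0.04, 0.03, 0.005))
  expect_equal(r$p_adj, c(0.02, 0.04, 0.04, 0.02))
  expect_equal(fdr_bh(0.037)$p_adj, 0.037)
  r1 <- fdr_bh(rep(1, 6))
  expect_true(all(r1$p_adj == 1) && !any(r1$reject))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH never rejects a p-value larger than the largest rejected one", {
  set.seed(10)
  for (i in 1:30) {
    p <- runif(15)^2
    r <- fdr_bh(p)
    if (any(r$reject)) expect_lte(max(p[r$reject]), min(p[!r$reject], Inf))
  }
})

test_that("rank tests agree with exact enumeration on tiny samples", {
  # all-positive paired differences, n = 6: W = 21, p = 2 / 2^6
  r <- rank_tests(c(1.2, 0.5, 2, 0.1, 0.8, 1.5), "wilcoxon_signed_rank")
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, 2 / 64)

  # identical groups: H = 0
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(rank_tests(g, "kruskal_wallis")$statistic, 0)

  # fully separated groups of 4: U in {0, 16}, p = 2 / choose(8, 4)
  r2 <- rank_tests(list(c(1, 2, 3, 4), c(10, 11, 12, 13)), "mann_whitney")
  expect_true(r2$statistic %in% c(0, 16))
  expect_equal(r2$p_value, 2 / choose(8, 4))
})

test_that("rank tests reject degenerate designs", {
  expect_error(rank_tests(rep(0, 8), "wilcoxon_signed_rank"), "zero")
  expect_error(rank_tests(c(0, 0, 0, 0, 1, 2, 3, -2), "wilcoxon_signed_rank"),
               "5 nonzero")
  expect_error(rank_tests(list(1:2, 1:5), "mann_whitney"), "3 observations")
})

test_that("Spearman correlation: monotone limits, midrank example, monotone-transform invariance", {
  x <- c(3, 7, 1, 9, 4, 6)
  expect_equal(spearman_cor(sort(x), 1:6)$rho, 1)
  expect_equal(spearman_cor(sort(x), 6:1)$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)

  set.seed(12)
  a <- rnorm(20); b <- rnorm(20) + a
  r0 <- spearman_cor(a, b)
  r1 <- spearman_cor(exp(a), b)        # strictly monotone transform
  expect_equal(r1$rho, r0$rho)
  expect_equal(r1$p_value, r0$p_value)
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
})
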