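# Cohort statistics: Spearman, Kaplan-Meier, log-rank/Gehan, Mann-Whitney,
# sample size.

test_that("spearman detects perfect monotone association", {
  expect_equal(spearman_test(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_test(1:3, c(3, 2, 1))$rho, -1)
  expect_error(spearman_test(c(1, 1, 1), 1:3), "constant")
})

test_that("small-sample spearman p equals full permutation enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 5)           # one tie pair
  res <- spearman_test(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)))
  # independent oracle: loop over all 720 permutations with cor()
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(y), function(p) cor(rank(x), rank(p)), numeric(1L))
  p_oracle <- mean(abs(rhos) >= abs(res$rho) - 1e-9)
  expect_equal(res$p, p_oracle)
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(25); y <- x + rnorm(25)
    r0 <- spearman_test(x, y)$rho
    expect_equal(spearman_test(exp(x), y)$rho, r0)
    expect_equal(spearman_test(x, y^3)$rho, r0)
  }
})

test_that("spearman t-approximation tracks cor.test for larger n", {
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40, sd = 2)
  res <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("product-limit estimate matches hand computation and first-crossing
           median", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_surv_at(km, 2), 0.5)          # (3/4)(2/3)
  expect_equal(km$median, 2)
  expect_equal(km$surv, c(3 / 4, 1 / 2, 1 / 4, 0))
})

test_that("an all-censored cohort keeps S at 1 with undefined median", {
  km <- km_estimate(c(5, 8, 9), c(0, 0, 0))
  expect_equal(km_surv_at(km, c(1, 6, 10)), c(1, 1, 1))
  expect_true(is.na(km$median))
  expect_equal(km$censor_times, c(5, 8, 9))
})

test_that("without censoring the curve is the empirical survival function", {
  set.seed(12)
  t <- round(rexp(40, 1 / 500)) + 1
  km <- km_estimate(t, rep(1L, 40L))
  grid <- seq(0, max(t), length.out = 25L)
  expect_equal(km_surv_at(km, grid),
               vapply(grid, function(g) mean(t > g), numeric(1L)))
})

test_that("log-rank matches the hand-computed hypergeometric sum", {
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  # t=1: E1=1/2 V=1/4; t=2: E1=1/3 V=2/9; O1-E1 = 2 - 5/6 = 7/6
  expect_equal(lr$statistic, (7 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))
})

test_that("identical groups give zero statistics and p = 1", {
  t <- c(3, 5, 8, 13); e <- c(1, 0, 1, 1)
  expect_equal(logrank_test(t, e, t, e)$statistic, 0)
  expect_equal(logrank_test(t, e, t, e)$p, 1)
  expect_equal(gehan_test(t, e, t, e)$statistic, 0)
  expect_error(logrank_test(numeric(0), integer(0), t, e), "non-empty")
  expect_error(logrank_test(t, c(0, 0, 0, 0), t, c(0, 0, 0, 0)), "event")
})

test_that("log-rank agrees with the survival package on random cohorts", {
  set.seed(19)
  for (i in 1:5) {
    ta <- rexp(30, 1 / 300); tb <- rexp(30, 1 / 400)
    ea <- rbinom(30, 1, 0.9); eb <- rbinom(30, 1, 0.9)
    mine <- logrank_test(ta, ea, tb, eb)
    df <- data.frame(time = c(ta, tb), ev = c(ea, eb),
                     grp = rep(1:2, each = 30L))
    sd_ <- survival::survdiff(survival::Surv(time, ev) ~ grp, data = df)
    expect_equal(mine$statistic, sd_$chisq, tolerance = 1e-8)
  }
})

test_that("both survival tests are invariant to common time rescaling", {
  set.seed(23)
  ta <- rexp(25, 1 / 300); tb <- rexp(25, 1 / 500)
  ea <- rbinom(25, 1, 0.8); eb <- rbinom(25, 1, 0.8)
  for (f in list(logrank_test, gehan_test)) {
    a <- f(ta, ea, tb, eb)
    b <- f(ta * 7.3, ea, tb * 7.3, eb)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  }
})

test_that("gehan weighting emphasises early hazard separation", {
  # early separation: group A dies fast initially, hazards converge later
  ta <- c(1, 2, 3, 4, 5, 30, 40, 50, 60, 70)
  tb <- c(10, 20, 25, 28, 29, 31, 41, 51, 61, 71)
  e <- rep(1L, 10L)
  ge <- gehan_test(ta, e, tb, e)
  lr <- logrank_test(ta, e, tb, e)
  expect_gt(ge$statistic, lr$statistic)
  # and with no censoring, the ordering decision agrees with Mann-Whitney
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  ge2 <- gehan_test(c(1, 2, 3), rep(1L, 3L), c(4, 5, 6), rep(1L, 3L))
  expect_true(ge2$observed_minus_expected > 0)  # group A dies earlier
  expect_true(mw$U < 4.5)                       # same direction of shift
})

test_that("mann-whitney exact enumeration reproduces the 20-arrangement case", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                       # 2 of choose(6,3) = 20
  same <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$U, 16 / 2)
  expect_equal(same$p, 1)
})

test_that("mann-whitney agrees with wilcox.test where both are exact", {
  set.seed(29)
  a <- rnorm(7); b <- rnorm(8) + 0.5           # continuous: no ties
  mine <- mann_whitney_u(a, b)
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$U, unname(wt$statistic))
  expect_equal(mine$p, wt$p.value, tolerance = 1e-12)
})

test_that("sample-size search reproduces the canonical 64 per group", {
  expect_equal(power_sample_size(0.5, 0.05, 0.8), 64L)
  expect_equal(power_sample_size(10, 0.05, 0.8), 2L)
  expect_error(power_sample_size(-1), "> 0")
  # consistency with the closed-form power solver
  expect_equal(power_sample_size(0.5, 0.05, 0.8),
               as.integer(ceiling(power.t.test(delta = 0.5, sd = 1,
                                               power = 0.8)$n)))
})

test_that("required n falls with effect size and rises with target power", {
  d <- c(0.2, 0.35, 0.5, 0.8, 1.2)
  ns <- vapply(d, power_sample_size, integer(1L))
  expect_true(all(diff(ns) < 0))
  pw <- c(0.5, 0.7, 0.8, 0.9, 0.95)
  np <- vapply(pw, function(p) power_sample_size(0.5, 0.05, p), integer(1L))
  expect_true(all(diff(np) > 0))
})
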