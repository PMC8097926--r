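test_that("Mann-Whitney exact p-values match enumeration for small samples", {
  r1 <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 0.1) # 2 of the C(6,3) = 20 labelings are as extreme
  expect_equal(r1$method, "exact")

  r2 <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1 / 3) # 2 of 6 labelings
})

test_that("Mann-Whitney handles identical samples, ties and U bounds", {
  r <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  expect_equal(r$method, "normal-approximation") # ties force approximation

  # U_x + U_y = n1 * n2, and both lie in [0, n1 * n2]
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1))
    y <- rnorm(sample(3:15, 1))
    ux <- mann_whitney_test(x, y)$statistic
    uy <- mann_whitney_test(y, x)$statistic
    expect_equal(ux + uy, length(x) * length(y))
    expect_gte(ux, 0)
    expect_lte(ux, length(x) * length(y))
  }
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p is invariant under monotone transforms", {
  set.seed(5)
  x <- runif(4)
  y <- runif(5)
  p0 <- mann_whitney_test(x, y)$p_value
  expect_equal(mann_whitney_test(exp(x), exp(y))$p_value, p0)
  expect_equal(mann_whitney_test(x^3 + 10, y^3 + 10)$p_value, p0)
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman_correlation(1:3, c(2, 4, 6))$r, 1)
  expect_equal(spearman_correlation(1:3, c(3, 2, 1))$r, -1)
  # r = 1 - 6 * 2 / (4 * 15) = 0.8
  r <- spearman_correlation(1:4, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_true(r$ci_low <= r$r && r$r <= r$ci_high)
  # Fisher-z CI with var 1.06 / (n - 3)
  se <- sqrt(1.06 / (4 - 3))
  expect_equal(r$ci_low, tanh(atanh(0.8) - qnorm(0.975) * se))
  expect_equal(r$ci_high, tanh(atanh(0.8) + qnorm(0.975) * se))
})

test_that("Spearman r is invariant under strictly increasing transforms", {
  set.seed(8)
  x <- rnorm(20)
  y <- rnorm(20)
  r0 <- spearman_correlation(x, y)$r
  expect_equal(spearman_correlation(exp(x), y)$r, r0)
  expect_equal(spearman_correlation(x, y^3)$r, r0)
  expect_warning(res <- spearman_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(res$r))
})

test_that("Kaplan-Meier product-limit estimate matches hand computation", {
  km <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$steps$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$medians$median, 2)

  # censoring shrinks the risk set without a drop
  km2 <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1)))
  s <- km2$steps
  expect_equal(s$surv[s$time == 1], 2 / 3)
  expect_equal(s$surv[s$time == 3], 0)
  expect_equal(km2$medians$median, 3)

  # all censored: survival stays 1, median undefined
  km3 <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(km3$steps$surv == 1))
  expect_true(is.na(km3$medians$median))

  expect_error(kaplan_meier(tibble::tibble(time = c(0, 1), event = c(1, 1))),
               "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  t <- sort(round(rexp(30, 0.1), 3))
  km <- kaplan_meier(tibble::tibble(time = t, event = 1))
  emp <- vapply(km$steps$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$steps$surv, emp)
})

test_that("log-rank statistic matches the hand-computed Mantel-Cox value", {
  rec <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                        g = c("a", "a", "b", "b"))
  lr <- logrank_test(rec, "g")
  # E_a = 1/2 + 1/3, V = 1/4 + 2/9, chisq = (2 - 5/6)^2 / (17/36) = 49/17
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-6)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  # identical groups: no signal
  rec2 <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                         g = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(rec2, "g")
  expect_equal(lr2$chisq, 0, tolerance = 1e-9)
  expect_equal(lr2$p_value, 1, tolerance = 1e-6)

  # zero events: undefined, flagged
  rec3 <- tibble::tibble(time = 1:4, event = 0, g = c("a", "a", "b", "b"))
  expect_warning(lr3 <- logrank_test(rec3, "g"), "no events")
  expect_true(is.na(lr3$chisq))
})

test_that("log-rank equals the squared standardized observed-minus-expected sum", {
  set.seed(21)
  rec <- tibble::tibble(
    time = rexp(40, 0.1), event = rbinom(40, 1, 0.8),
    g = rep(c("a", "b"), 20)
  )
  lr <- logrank_test(rec, "g")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = rec)
  z2 <- (sd_fit$obs[1] - sd_fit$exp[1])^2 / sd_fit$var[1, 1]
  expect_equal(lr$chisq, z2, tolerance = 1e-9)
  # relabeling leaves the statistic unchanged
  rec$g <- ifelse(rec$g == "a", "b", "a")
  expect_equal(logrank_test(rec, "g")$chisq, lr$chisq, tolerance = 1e-12)
})

test_that("Cox hazard ratio: null data, label swap and separation", {
  # identical survival in both groups -> HR 1
  base <- tibble::tibble(time = rep(c(2, 4, 6, 8), 2), event = 1,
                         g = rep(c("lo", "hi"), each = 4))
  cox <- cox_hazard_ratio(base, "g", level = "hi")
  expect_equal(cox$hr, 1, tolerance = 1e-6)

  # swapping labels inverts the HR exactly
  set.seed(31)
  rec <- tibble::tibble(
    time = rexp(60, 0.1) * rep(c(1, 2), 30), event = rbinom(60, 1, 0.85),
    g = rep(c("x", "y"), 30)
  )
  c1 <- cox_hazard_ratio(rec, "g", level = "y")
  c2 <- cox_hazard_ratio(rec, "g", level = "x")
  expect_equal(c1$log_hr, -c2$log_hr, tolerance = 1e-8)
  expect_equal(c1$hr, 1 / c2$hr, tolerance = 1e-8)

  # complete separation is flagged with an unbounded CI
  sep <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                        event = c(1, 1, 1, 1, 1, 1),
                        g = rep(c("bad", "good"), each = 3))
  expect_warning(cs <- cox_hazard_ratio(sep, "g", level = "good"),
                 "separation")
  expect_true(cs$separation)
  expect_equal(cs$ci_high, Inf)
})

test_that("Cox score test at beta = 0 matches the log-rank statistic", {
  set.seed(77)
  n <- 240
  rec <- tibble::tibble(
    time = rexp(n, 0.05), event = rbinom(n, 1, 0.85),
    g = rep(c("a", "b"), n / 2)
  )
  lr <- logrank_test(rec, "g")
  fit <- survival::coxph(survival::Surv(time, event) ~ g, data = rec)
  score <- summary(fit)$sctest[["test"]]
  expect_lt(abs(score - lr$chisq) / lr$chisq, 0.05)
})
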