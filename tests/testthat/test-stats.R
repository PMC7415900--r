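test_that("epsilon is one for two levels and under compound symmetry", {
  set.seed(21)
  expect_equal(gg_epsilon(matrix(rnorm(20), 10, 2)), 1)

  # data whose sample covariance is exactly compound symmetric
  n <- 12; k <- 5
  Z <- qr.Q(qr(scale(matrix(rnorm(n * k), n, k), scale = FALSE))) * sqrt(n - 1)
  CS <- matrix(0.4, k, k); diag(CS) <- 1
  X <- Z %*% chol(CS)
  expect_equal(gg_epsilon(X), 1, tolerance = 1e-10)
})

test_that("epsilon matches the eigenvalue oracle and stays in range", {
  set.seed(22)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    M <- matrix(rnorm(40 * k), 40, k) %*% matrix(rnorm(k * k), k)
    e <- gg_epsilon(M)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
    C <- qr.Q(qr(stats::contr.helmert(k)))
    lam <- eigen(crossprod(C, cov(M) %*% C), symmetric = TRUE)$values
    expect_equal(e, sum(lam)^2 / ((k - 1) * sum(lam^2)), tolerance = 1e-10)
  }
})

test_that("repeated-measures ANOVA matches the aov error-stratum oracle", {
  set.seed(23)
  d <- rm_table(3, 3, function(a, e, w) sample(1:9, 1))
  mine <- rm_anova_week(d)
  fit <- summary(stats::aov(
    value ~ factor(week) * factor(eye) +
      Error(factor(animal_id) / (factor(week) * factor(eye))), data = d))
  f_or <- c(
    fit[["Error: factor(animal_id):factor(week)"]][[1]]$`F value`[1],
    fit[["Error: factor(animal_id):factor(eye)"]][[1]]$`F value`[1],
    fit[["Error: factor(animal_id):factor(week):factor(eye)"]][[1]]$`F value`[1]
  )
  p_or <- c(
    fit[["Error: factor(animal_id):factor(week)"]][[1]]$`Pr(>F)`[1],
    fit[["Error: factor(animal_id):factor(eye)"]][[1]]$`Pr(>F)`[1],
    fit[["Error: factor(animal_id):factor(week):factor(eye)"]][[1]]$`Pr(>F)`[1]
  )
  expect_equal(mine$statistic, f_or, tolerance = 1e-10)
  expect_equal(mine$p_uncorrected, p_or, tolerance = 1e-10)
})

test_that("ANOVA is location invariant and handles degenerate data", {
  set.seed(24)
  d <- rm_table(4, 4)
  a1 <- rm_anova_week(d)
  d2 <- d; d2$value <- d$value + 100
  a2 <- rm_anova_week(d2)
  expect_equal(a1$statistic, a2$statistic)
  expect_equal(a1$epsilon_gg, a2$epsilon_gg)
  expect_equal(a1$p_gg, a2$p_gg)

  flat <- d; flat$value <- 3
  ws <- capture_warnings(aflat <- rm_anova_week(flat))
  expect_length(ws, 3)  # all three effects are degenerate
  expect_match(ws, "Degenerate", all = TRUE)
  expect_equal(aflat$statistic[1], 0)
  expect_equal(aflat$p_gg[1], 1)

  # in the rejection-relevant region (F >= 1) the GG correction can only
  # increase the p-value; for F < 1 shrinking both df can lower it, so the
  # monotonicity claim is restricted accordingly
  seen <- 0
  for (i in 1:40) {
    a <- rm_anova_week(rm_table(5, 4, function(a, e, w) rnorm(1, 0.2 * w)))
    wk <- a[a$effect == "week", ]
    crit <- stats::qf(0.95, wk$df1, wk$df2)
    # the corrected critical value is always larger
    expect_gt(stats::qf(0.95, wk$epsilon_gg * wk$df1, wk$epsilon_gg * wk$df2),
              crit - 1e-12)
    if (wk$statistic >= crit && wk$epsilon_gg < 1) {
      seen <- seen + 1
      expect_gte(wk$p_gg, wk$p_uncorrected - 1e-12)
    }
  }
  expect_gte(seen, 3)
})

test_that("incomplete animals are dropped with a warning", {
  set.seed(25)
  d <- rm_table(4, 3)
  d <- d[!(d$animal_id == "a4" & d$week == 9), ]
  expect_warning(a <- rm_anova_week(d), "a4")
  expect_equal(attr(a, "n_animals"), 3)
})

test_that("consecutive contrasts are paired t-tests with Bonferroni family k-1", {
  set.seed(26)
  d <- rm_table(6, 6, function(a, e, w) rnorm(1, mean = -0.1 * w))
  cc <- consecutive_contrasts(d)
  expect_equal(nrow(cc), 5)
  expect_true(all(cc$family_size == 5))
  expect_equal(cc$p_bonferroni, pmin(1, 5 * cc$p_raw))

  # oracle: explicit paired t on eye-averaged animal means
  ea <- d |>
    dplyr::group_by(animal_id, week) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  w <- sort(unique(ea$week))
  diffs <- ea$value[ea$week == w[2]][order(ea$animal_id[ea$week == w[2]])] -
    ea$value[ea$week == w[1]][order(ea$animal_id[ea$week == w[1]])]
  tor <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
  expect_equal(cc$statistic[1], tor, tolerance = 1e-10)
  expect_equal(cc$p_raw[1], t.test(diffs)$p.value, tolerance = 1e-10)

  same <- d
  same$value <- 1
  cc0 <- consecutive_contrasts(same)
  expect_true(all(cc0$statistic == 0))
  expect_true(all(cc0$p_raw == 1))
})

test_that("linear trend uses integer orthogonal coefficients", {
  expect_equal(linear_contrast_coefficients(6), c(-5L, -3L, -1L, 1L, 3L, 5L))
  expect_equal(linear_contrast_coefficients(3), c(-1L, 0L, 1L))
  expect_equal(sum(linear_contrast_coefficients(5)), 0L)

  flat <- rm_table(4, 6, function(a, e, w) 2)
  tr <- linear_trend_contrast(flat)
  expect_equal(tr$statistic, 0)

  set.seed(27)
  d <- rm_table(6, 6, function(a, e, w) -w + rnorm(1, sd = 0.5))
  tr <- linear_trend_contrast(d)
  expect_lt(tr$estimate, 0)
  # oracle: one-sample t on per-animal contrast scores
  ea <- d |>
    dplyr::group_by(animal_id, week) |>
    dplyr::summarise(value = mean(value), .groups = "drop") |>
    dplyr::arrange(animal_id, week)
  L <- tapply(ea$value * rep(c(-5, -3, -1, 1, 3, 5), times = 6), ea$animal_id, sum)
  expect_equal(tr$statistic, unname(t.test(L)$statistic), tolerance = 1e-10)
  expect_equal(tr$p_raw, t.test(L)$p.value, tolerance = 1e-10)

  uneq <- d[d$week != 9, ]
  expect_error(linear_trend_contrast(uneq), "equally spaced")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 3),
                      value = c(1, 2, 3, 4, 5, 6, 8, 9, 10))
  res <- oneway_anova(d)
  gm <- mean(d$value)
  ssb <- 3 * sum((tapply(d$value, d$group, mean) - gm)^2)
  ssw <- sum((d$value - rep(tapply(d$value, d$group, mean), each = 3))^2)
  expect_equal(res$anova$statistic, (ssb / 2) / (ssw / 6))
  expect_equal(res$anova$p_value,
               stats::oneway.test(value ~ group, d, var.equal = TRUE)$p.value)
  expect_equal(nrow(res$contrasts), 3)
  expect_true(all(res$contrasts$family_size == 3))

  dg <- tibble::tibble(group = rep(c("a", "b"), each = 3), value = rep(1:2, each = 3))
  expect_warning(r0 <- oneway_anova(dg), "Zero within-group")
  expect_equal(r0$anova$statistic, Inf)
  expect_equal(r0$anova$p_value, 0)

  small <- tibble::tibble(group = c("a", "a", "b"), value = 1:3)
  expect_warning(expect_error(oneway_anova(small), "At least 2 groups"), "fewer than 2")
})

test_that("one-way type-I error is near nominal under the null", {
  set.seed(28)
  rej <- 0
  for (i in 1:2000) {
    d <- tibble::tibble(group = rep(c("g1", "g2"), each = 20), value = rnorm(40))
    if (oneway_anova(d)$anova$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 2000, 0.04)
  expect_lte(rej / 2000, 0.06)
})

test_that("tests are scale invariant", {
  set.seed(29)
  d <- rm_table(5, 4)
  d2 <- d; d2$value <- d$value * 3.7
  expect_equal(rm_anova_week(d)$statistic, rm_anova_week(d2)$statistic)
  expect_equal(consecutive_contrasts(d)$statistic,
               consecutive_contrasts(d2)$statistic)
  expect_equal(linear_trend_contrast(d)$statistic,
               linear_trend_contrast(d2)$statistic)
})

test_that("tidy and glance methods expose the fitted summaries", {
  set.seed(30)
  a <- rm_anova_week(rm_table(4, 3))
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$effect, c("week", "eye", "week:eye"))
  gl <- glance(a)
  expect_equal(gl$n_animals, 4)
  expect_equal(gl$n_weeks, 3)
})
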