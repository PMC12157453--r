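test_that("Welch test matches the from-scratch formula oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_t(a, b, tails = "one", direction = "greater")
  orc <- oracle_welch(a, b, "greater")
  expect_equal(res$statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$df, orc$df, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)

  set.seed(14)
  a2 <- rnorm(8, 1, 2); b2 <- rnorm(5, 0, 0.5)
  for (dir in c("greater", "less")) {
    expect_equal(welch_t(a2, b2, "one", dir)$p_value,
                 oracle_welch(a2, b2, dir)$p, tolerance = 1e-12)
  }
  # two-tailed p = 2 * min(one-tailed, 1 - one-tailed)
  p1 <- welch_t(a2, b2, "one", "greater")$p_value
  expect_equal(welch_t(a2, b2, "two")$p_value, 2 * min(p1, 1 - p1),
               tolerance = 1e-12)

  # identical groups: t = 0, one-tailed p = 0.5
  res0 <- welch_t(c(1, 2, 3), c(1, 2, 3), "one", "greater")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 0.5)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Dunnett with one treatment reduces to the pooled t-test", {
  set.seed(15)
  ctrl <- rnorm(6); trt <- rnorm(6, 1)
  d2 <- dunnett(ctrl, list(t = trt), tails = "two")
  tt <- t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(d2$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(d2$statistic, unname(tt$statistic), tolerance = 1e-12)
  d1 <- dunnett(ctrl, list(t = trt), tails = "one", direction = "greater")
  tt1 <- t.test(trt, ctrl, var.equal = TRUE, alternative = "greater")
  expect_equal(d1$p_value, tt1$p.value, tolerance = 1e-6)
})

test_that("Dunnett adjusted p-values match a Monte Carlo max-t oracle", {
  set.seed(16)
  n <- 6
  groups <- list(g1 = rnorm(n, 0.8), g2 = rnorm(n, 0.2), g3 = rnorm(n, 1.5))
  ctrl <- rnorm(n)
  res1 <- dunnett(ctrl, groups, tails = "one", direction = "greater")
  res2 <- dunnett(ctrl, groups, tails = "two")

  # oracle: draws from the many-to-one multivariate t under the null
  # (balanced: correlation 1/2), >= 1e6 draws
  df <- 4 * n - 4
  B <- 1e6
  set.seed(99)
  u0 <- rnorm(B)
  w <- sqrt(rchisq(B, df) / df)
  tmax <- rep(-Inf, B); tmaxabs <- rep(0, B)
  for (j in 1:3) {
    tj <- (sqrt(0.5) * u0 + sqrt(0.5) * rnorm(B)) / w
    tmax <- pmax(tmax, tj)
    tmaxabs <- pmax(tmaxabs, abs(tj))
  }
  for (i in 1:3) {
    expect_lt(abs(res1$p_value[i] - mean(tmax >= res1$statistic[i])), 0.003)
    expect_lt(abs(res2$p_value[i] - mean(tmaxabs >= abs(res2$statistic[i]))),
              0.003)
  }
})

test_that("Dunnett respects multiplicity and group-order invariance", {
  set.seed(17)
  ctrl <- rnorm(5)
  groups <- list(a = rnorm(5, 0.5), b = rnorm(4, -0.3), c = rnorm(6, 1))
  res <- dunnett(ctrl, groups, tails = "one", direction = "greater")
  # adjusted >= unadjusted per-comparison pooled-t p
  pooled <- c(ctrl, unlist(groups))
  for (i in seq_along(groups)) {
    unadj <- pt(res$statistic[i], res$df[i], lower.tail = FALSE)
    expect_gte(res$p_value[i] + 1e-12, unadj)
  }
  perm <- dunnett(ctrl, groups[c(3, 1, 2)], tails = "one",
                  direction = "greater")
  expect_equal(sort(res$p_value), sort(perm$p_value), tolerance = 1e-9)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("Dunnett agrees with an established multiple-comparison routine", {
  skip_if_not_installed("multcomp")
  set.seed(18)
  dat <- data.frame(
    y = c(rnorm(6), rnorm(6, 0.7), rnorm(5, -0.2), rnorm(7, 1.1)),
    g = factor(rep(c("ctrl", "a", "b", "c"), c(6, 6, 5, 7)),
               levels = c("ctrl", "a", "b", "c")))
  fit <- multcomp::glht(stats::aov(y ~ g, dat),
                        linfct = multcomp::mcp(g = "Dunnett"),
                        alternative = "greater")
  ref <- summary(fit, test = multcomp::adjusted("single-step"))
  ours <- dunnett(dat$y[dat$g == "ctrl"],
                  list(a = dat$y[dat$g == "a"], b = dat$y[dat$g == "b"],
                       c = dat$y[dat$g == "c"]),
                  tails = "one", direction = "greater")
  expect_equal(ours$p_value, unname(as.numeric(ref$test$pvalues)),
               tolerance = 2e-3)
})

test_that("Tukey two-group limit satisfies q = t * sqrt(2)", {
  set.seed(19)
  g1 <- rnorm(7); g2 <- rnorm(7, 1)
  res <- tukey_test(list(g1 = g1, g2 = g2))
  t_pooled <- unname(t.test(g1, g2, var.equal = TRUE)$statistic)
  expect_equal(res$statistic, abs(t_pooled) * sqrt(2), tolerance = 1e-12)
})

test_that("Tukey p-values match a Monte Carlo studentized-range oracle", {
  set.seed(20)
  n <- 6
  groups <- list(a = rnorm(n, 0), b = rnorm(n, 0.9), c = rnorm(n, 0.4))
  res <- tukey_test(groups)
  df <- 3 * n - 3
  B <- 1e6
  set.seed(199)
  z <- matrix(rnorm(3 * B), B, 3)
  q_null <- (apply(z, 1, max) - apply(z, 1, min)) / sqrt(rchisq(B, df) / df)
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$p_value[i] - mean(q_null >= res$statistic[i])), 0.003)
  }
})

test_that("Tukey agrees with TukeyHSD and is order-invariant", {
  set.seed(21)
  dat <- data.frame(y = c(rnorm(5), rnorm(6, 1), rnorm(7, 0.3)),
                    g = factor(rep(c("a", "b", "c"), c(5, 6, 7))))
  ours <- tukey_test(split(dat$y, dat$g))
  ref <- TukeyHSD(aov(y ~ g, dat))$g
  expect_equal(sort(ours$p_value), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
  perm <- tukey_test(split(dat$y, dat$g)[c(2, 3, 1)])
  expect_equal(sort(ours$p_value), sort(perm$p_value), tolerance = 1e-12)

  same <- tukey_test(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$p_value > 0.999))
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson_cor(x, 2 * x + 1)$statistic, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$statistic, -1, tolerance = 1e-12)

  y <- c(2.2, 1.5, 3.9, 5.1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$statistic, r_oracle, tolerance = 1e-12)
  t_r <- r_oracle * sqrt(2 / (1 - r_oracle^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_r), 2), tolerance = 1e-12)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})
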