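test_that("BH step-up handles the boundary cases", {
  expect_length(bh_adjust(numeric(0))$reject, 0)
  # m = 1: reject iff p <= q
  expect_true(bh_adjust(0.05, 0.05)$reject)
  expect_false(bh_adjust(0.051, 0.05)$reject)
  expect_true(all(bh_adjust(rep(0, 5))$reject))
  # the classic step-up example: p(4) = 0.05 <= 4 * 0.05 / 4 rescues all four
  bh <- bh_adjust(c(0.01, 0.02, 0.04, 0.05), 0.05)
  expect_true(all(bh$reject))
  # adjusted p-values are monotone in rank
  p <- c(0.3, 0.01, 0.2, 0.04)
  adj <- bh_adjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejection flags equal the brute-force step-up on random vectors", {
  set.seed(55)
  mismatches <- 0L
  for (i in 1:10000) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    if (!identical(bh_adjust(p, q)$reject, oracle_bh_reject(p, q)))
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("group comparison reproduces the 2x2 mortality contrast with formatted percentages", {
  # 22 high-ICP subjects with 13 ICU deaths vs 154 low-ICP with 26
  d <- data.frame(
    icp_group = factor(rep(c("high", "low"), c(22, 154)), c("low", "high")),
    icu_death = c(rep(1, 13), rep(0, 9), rep(1, 26), rep(0, 128)))
  tab <- compare_groups(d, "icp_group")
  row <- tab[tab$variable == "icu_death", ]
  expect_equal(row$group_high, "13 (59.1%)")
  expect_equal(row$group_low, "26 (16.9%)")
  expect_lt(row$p_value, 0.001)
  expect_true(row$fdr_significant)
  # the 22-subject high group puts one expected cell below 5 (22*39/176 = 4.875),
  # so the spec'd small-cell rule switches to Fisher's exact test
  expect_equal(row$test, "fisher")
})

test_that("identical group distributions give p = 1 and constants are flagged", {
  base <- data.frame(x = rnorm(40), k = rbinom(40, 1, 0.5), c = 5)
  d <- rbind(cbind(base, g = "a"), cbind(base, g = "b"))
  tab <- compare_groups(d, "g")
  expect_equal(tab$p_value[tab$variable == "x"], 1, tolerance = 1e-9)
  expect_equal(tab$p_value[tab$variable == "k"], 1, tolerance = 1e-9)
  expect_equal(tab$p_value[tab$variable == "c"], 1)
  expect_equal(tab$type[tab$variable == "c"], "constant")
})

test_that("test selection switches with normality and expected cell counts", {
  set.seed(66)
  d <- data.frame(
    g = rep(c("a", "b"), each = 60),
    normalish = rnorm(120, 10, 2),
    skewed = rexp(120, 0.2),
    rare = c(rep(1, 3), rep(0, 57), rep(1, 1), rep(0, 59)))
  tab <- compare_groups(d, "g")
  expect_equal(tab$test[tab$variable == "normalish"], "t-test")
  expect_equal(tab$test[tab$variable == "skewed"], "wilcoxon")
  expect_equal(tab$test[tab$variable == "rare"], "fisher")  # expected cells < 5

  d3 <- data.frame(g = rep(c("a", "b", "c"), each = 40),
                   x = rnorm(120), y = rexp(120))
  tab3 <- compare_groups(d3, "g")
  expect_equal(tab3$test[tab3$variable == "x"], "anova")
  expect_equal(tab3$test[tab3$variable == "y"], "kruskal-wallis")
})

test_that("chi-square on a 2x2 equals the squared two-proportion z-statistic", {
  tab <- matrix(c(13, 26, 9, 128), 2)  # deaths / survivors by group
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
  pp <- sum(tab[, 1]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(unname(chi), z^2, tolerance = 1e-10)
  # Fisher's exact on the same table is consistent with the printed bound
  expect_lt(fisher.test(tab)$p.value, 0.001)
})

test_that("multivariable logistic model recovers a planted log odds ratio", {
  set.seed(71)
  n <- 2000
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 1.0 * d$x + 0.5 * d$z))
  fit <- multivariate_logistic(d, "y", c("x", "z"))
  row <- fit[fit$variable == "x", ]
  expect_true(row$ci_low <= exp(1) && exp(1) <= row$ci_high)
  # duplicating the data leaves the point estimate unchanged
  fit2 <- multivariate_logistic(rbind(d, d), "y", c("x", "z"))
  expect_equal(fit$or, fit2$or, tolerance = 1e-8)
})

test_that("logistic Wald intervals achieve near-nominal coverage for a null covariate", {
  set.seed(72)
  cover <- vapply(1:100, function(r) {
    n <- 2000
    d <- data.frame(x = rnorm(n), z = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-1 + 0.5 * d$z))
    fit <- multivariate_logistic(d, "y", c("x", "z"), always_keep = "x")
    row <- fit[fit$variable == "x", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("univariable screen gates entry and always_keep overrides it", {
  set.seed(73)
  n <- 800
  d <- data.frame(strong = rnorm(n), noise = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 1.2 * d$strong))
  fit <- multivariate_logistic(d, "y", c("strong", "noise"),
                               always_keep = "noise")
  expect_setequal(attr(fit, "entered"), c("strong", "noise"))
  fit2 <- multivariate_logistic(d, "y", c("strong", "noise"))
  expect_true("strong" %in% attr(fit2, "entered"))
})

test_that("stratified correlation returns exact values and affine invariance", {
  x <- c(1, 2, 3, 4, 5, 6)
  s <- rep("a", 6)
  res <- fluid_icp_correlation(2 * x, x, s)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  set.seed(81)
  u <- rnorm(50); v <- 0.5 * u + rnorm(50, 0, 0.5)
  r1 <- fluid_icp_correlation(u, v, rep("a", 50))$r
  r2 <- fluid_icp_correlation(3 * u + 7, 0.1 * v - 2, rep("a", 50))$r
  expect_equal(r1, r2, tolerance = 1e-12)
  # degenerate strata are reported, not errors
  res2 <- fluid_icp_correlation(c(1, 1, 1), c(1, 2, 3), rep("a", 3))
  expect_true(is.na(res2$r))
  res3 <- fluid_icp_correlation(c(1, 2), c(1, 2), rep("a", 2))
  expect_match(res3$note, "fewer than 3")
})

test_that("correlation p-values are well calibrated under independence", {
  set.seed(82)
  # a single independent draw at n = 500 has |r| well under 0.15
  one <- fluid_icp_correlation(rnorm(500), rnorm(500), rep("a", 500))
  expect_lt(abs(one$r), 0.15)
  # and across replicates the p-values are uniform
  ps <- vapply(1:200, function(r)
    fluid_icp_correlation(rnorm(500), rnorm(500), rep("a", 500))$p_value,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
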