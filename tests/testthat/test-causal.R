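test_that("confounder screen keeps planted confounders and mostly drops noise", {
  # strong common cause of treatment and outcome must be selected
  d <- simulate_confounded(2000, true_or = 2, beta_conf = 1.0, seed = 3)
  scr <- screen_confounders(d, "treated", "outcome", c("z1", "z2"))
  expect_true(scr$selected[scr$covariate == "z1"])

  # a covariate independent of both is excluded in most replicates
  set.seed(5)
  excl <- vapply(1:60, function(r) {
    d <- simulate_confounded(2000, true_or = 2, seed = 500 + r)
    d$noise <- rnorm(nrow(d))
    scr <- screen_confounders(d, "treated", "outcome", "noise")
    !scr$selected[1]
  }, logical(1))
  expect_gte(mean(excl), 0.85)
})

test_that("constant covariates are skipped with a warning", {
  d <- simulate_confounded(200, seed = 8)
  d$flat <- 1
  expect_warning(scr <- screen_confounders(d, "treated", "outcome", "flat"),
                 "constant")
  expect_false(scr$selected[1])
})

test_that("propensity fitting handles the empty, linear and smooth cases", {
  d <- simulate_confounded(2000, seed = 12)
  # no covariates -> marginal prevalence everywhere
  ps0 <- fit_propensity(d, "treated", character(0))
  expect_equal(unique(as.numeric(ps0)), mean(d$treated), tolerance = 1e-12)

  # linear truth: smooth and linear fits agree closely; both track the truth
  ps_lin <- fit_propensity(d, "treated", c("z1", "z2"), smooth = FALSE)
  ps_gam <- fit_propensity(d, "treated", c("z1", "z2"), smooth = TRUE)
  expect_lt(sqrt(mean((ps_lin - ps_gam)^2)), 0.05)
  expect_gt(cor(as.numeric(ps_gam), d$ps_true), 0.95)
})

test_that("separation triggers the ridge fallback with a warning", {
  d <- data.frame(x = c(rnorm(50, -3), rnorm(50, 3)),
                  treated = rep(c(0L, 1L), each = 50))
  expect_warning(ps <- fit_propensity(d, "treated", "x", smooth = FALSE),
                 "separation")
  expect_true(all(ps >= 0.01 & ps <= 0.99))
})

test_that("stabilized weight formulas follow the estimand definitions", {
  ps <- c(0.25, 0.5, 0.8)
  t <- c(1, 0, 1)
  pt <- mean(t)
  w_ate <- stabilized_weights(ps, t, "ATE")
  expect_equal(w_ate, c(pt / 0.25, (1 - pt) / 0.5, pt / 0.8))
  # treated subject at ps 0.25 with prevalence 0.5 gets ATE weight 2
  expect_equal(stabilized_weights(c(0.25, 0.6), c(1, 0), "ATE")[1], 0.5 / 0.25)
  w_att <- stabilized_weights(ps, t, "ATT")
  expect_equal(w_att, c(1, 0.5 / 0.5, 1))
  w_atu <- stabilized_weights(ps, t, "ATU")
  expect_equal(w_atu, c(0.75 / 0.25, 1, 0.2 / 0.8))
  # propensity equal to prevalence makes every ATE weight 1
  expect_equal(stabilized_weights(rep(pt, 3), t, "ATE"), rep(1, 3))
  expect_error(stabilized_weights(c(0, 0.5), c(1, 0), "ATE"), "strictly")
})

test_that("stabilized ATE weights sum to about n under a correct model", {
  d <- simulate_confounded(2000, true_or = 2, seed = 19)
  ps <- fit_propensity(d, "treated", c("z1", "z2"), smooth = FALSE)
  w <- stabilized_weights(ps, d$treated, "ATE")
  expect_lt(abs(sum(w) - nrow(d)) / nrow(d), 0.10)
})

test_that("weighting with the true propensity balances the confounders", {
  d <- simulate_confounded(2000, true_or = 2, beta_conf = 0.8, seed = 27)
  w <- stabilized_weights(pmin(pmax(d$ps_true, 0.01), 0.99), d$treated, "ATE")
  bal <- balance_smd(d, c("z1", "z2"), d$treated, w)
  expect_true(all(abs(bal$smd) < 0.1))
  raw <- balance_smd(d, c("z1", "z2"), d$treated)
  expect_gt(max(abs(raw$smd)), 0.3)  # confounding is real before weighting
})

test_that("unit-weight effect estimate reproduces the 2x2 odds ratio", {
  # 22 treated with 13 deaths vs 154 controls with 26 deaths
  y <- c(rep(1, 13), rep(0, 9), rep(1, 26), rep(0, 128))
  t <- c(rep(1, 22), rep(0, 154))
  est <- estimate_effect(y, t, rep(1, 176), estimand = "ATE", n_boot = 200,
                         seed = 1)
  expect_equal(est$estimate, (13 * 128) / (9 * 26), tolerance = 1e-10)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
})

test_that("ATT, ATU and ATE coincide exactly under an intercept-only propensity model", {
  d <- simulate_confounded(500, true_or = 2, seed = 33)
  ps <- fit_propensity(d, "treated", character(0))
  ors <- vapply(c("ATT", "ATU", "ATE"), function(es) {
    w <- stabilized_weights(ps, d$treated, es)
    if (es == "ATT") expect_true(all(w[d$treated == 1] == 1))
    estimate_effect(d$outcome, d$treated, w, estimand = es, n_boot = 50,
                    seed = 2)$estimate
  }, numeric(1))
  expect_equal(unname(ors[1]), unname(ors[2]), tolerance = 1e-12)
  expect_equal(unname(ors[1]), unname(ors[3]), tolerance = 1e-12)
})

test_that("zero events in an arm yields a continuity-corrected estimate with warning", {
  y <- c(rep(0, 30), rep(1, 5), rep(0, 25))
  t <- rep(c(1, 0), each = 30)
  expect_warning(est <- estimate_effect(y, t, rep(1, 60), n_boot = 50, seed = 3),
                 "continuity")
  expect_gt(est$estimate, 0)
})

test_that("IPTW recovers a planted conditional odds ratio of 3 with modest bias", {
  d <- simulate_confounded(2000, true_or = 3, seed = 5)
  te <- treatment_effect(d, "treated", "outcome", c("z1", "z2"),
                         estimands = "ATE", screen = FALSE, smooth = FALSE,
                         n_boot = 300, seed = 5)
  e <- te$effects$ATE
  expect_lt(abs(e$estimate - 3) / 3, 0.15)
  expect_true(e$ci_low <= 3 && 3 <= e$ci_high)
  # confounded naive estimate is materially worse
  naive <- exp(coef(glm(outcome ~ treated, d, family = binomial()))[2])
  expect_gt(abs(naive - 3), abs(e$estimate - 3))
})
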