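#' Screen candidate confounders
#'
#' A candidate covariate is retained when either (a) its univariable
#' association with the outcome reaches p < \code{p_threshold} (likelihood
#' ratio test from a univariable logistic model), or (b) adding it to the
#' outcome-on-treatment logistic model changes the treatment coefficient by
#' more than \code{beta_change} in relative terms. Both quantities are logged
#' for every candidate. Constant covariates are skipped with a warning.
#'
#' @param data data.frame holding the columns named below.
#' @param treatment name of the binary treatment column.
#' @param outcome name of the binary outcome column.
#' @param candidates character vector of candidate covariate names.
#' @param p_threshold outcome-association threshold, default 0.1.
#' @param beta_change relative treatment-coefficient change threshold,
#'   default 0.1 (10 percent).
#' @return data.frame with one row per candidate: \code{covariate},
#'   \code{p_outcome}, \code{beta_change}, \code{selected}, \code{note}.
#' @export
screen_confounders <- function(data, treatment, outcome, candidates,
                               p_threshold = 0.1, beta_change = 0.1) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  y <- data[[outcome]]
  base <- glm(stats::reformulate(treatment, outcome), data = data,
              family = binomial())
  b0 <- coef(base)[2]
  out <- lapply(candidates, function(v) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("constant covariate skipped: ", v)
      return(data.frame(covariate = v, p_outcome = NA_real_,
                        beta_change = NA_real_, selected = FALSE,
                        note = "constant"))
    }
    m1 <- glm(stats::reformulate(v, outcome), data = data, family = binomial())
    m0 <- glm(stats::reformulate("1", outcome), data = data, family = binomial())
    p_out <- stats::anova(m0, m1, test = "LRT")$`Pr(>Chi)`[2]
    madj <- glm(stats::reformulate(c(treatment, v), outcome), data = data,
                family = binomial())
    b1 <- coef(madj)[2]
    rel <- if (abs(b0) > 1e-8) abs(b1 - b0) / abs(b0) else abs(b1 - b0)
    data.frame(covariate = v, p_outcome = p_out, beta_change = rel,
               selected = (p_out < p_threshold) || (rel > beta_change),
               note = "")
  })
  do.call(rbind, out)
}

#' Fit a propensity-score model
#'
#' Probability of treatment given covariates from a logistic model. With
#' \code{smooth = TRUE}, continuous covariates (at least 10 distinct values)
#' enter as penalized thin-plate spline terms in a \code{mgcv::gam}; otherwise
#' a plain logistic regression is used. Fitted probabilities are clipped to
#' \code{clip}. With an empty covariate set the model is intercept-only and
#' every subject's score equals the marginal treatment prevalence. If the fit
#' shows signs of separation (fitted probabilities at the boundary or
#' non-convergence), a ridge-penalized linear logistic fit is substituted with
#' a warning.
#'
#' @param data data.frame.
#' @param treatment name of the binary treatment column.
#' @param covariates character vector of covariate names (possibly empty).
#' @param smooth use penalized smooth terms for continuous covariates.
#' @param clip length-2 clipping bounds for the fitted scores.
#' @return numeric vector of propensity scores in (0, 1), with the fitted
#'   model as attribute \code{model}.
#' @export
fit_propensity <- function(data, treatment, covariates, smooth = TRUE,
                           clip = c(0.01, 0.99)) {
  t <- as.integer(data[[treatment]])
  if (length(unique(t)) != 2)
    stop("input error: need at least one treated and one control subject",
         call. = FALSE)
  if (length(covariates) == 0) {
    ps <- rep(mean(t), length(t))
    return(structure(pmin(pmax(ps, clip[1]), clip[2]), model = NULL))
  }
  is_cont <- vapply(covariates, function(v)
    is.numeric(data[[v]]) && length(unique(data[[v]])) >= 10, logical(1))
  fit <- NULL
  if (smooth && any(is_cont)) {
    terms <- ifelse(is_cont, paste0("s(", covariates, ")"), covariates)
    fml <- stats::as.formula(paste(treatment, "~", paste(terms, collapse = " + ")))
    fit <- tryCatch(mgcv::gam(fml, data = data, family = binomial()),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    fit <- suppressWarnings(glm(stats::reformulate(covariates, treatment),
                                data = data, family = binomial()))
  }
  ps <- as.numeric(predict(fit, type = "response"))
  if (!separable_ok(fit, ps)) {
    warning("possible separation in propensity model; using ridge-penalized logistic fit")
    X <- model.matrix(stats::reformulate(covariates), data = data)
    ps <- ridge_logit(X, t)$fitted
    fit <- NULL
  }
  structure(pmin(pmax(ps, clip[1]), clip[2]), model = fit)
}

separable_ok <- function(fit, ps) {
  conv <- if (!is.null(fit$converged)) fit$converged else TRUE
  conv && !any(ps > 1 - 1e-8) && !any(ps < 1e-8)
}

# ridge-penalized logistic regression by IRLS (intercept unpenalized);
# fallback for separation only
ridge_logit <- function(X, y, lambda = 1e-2, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / pmax(w, 1e-10)
    new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  list(coef = drop(beta), fitted = plogis(drop(X %*% beta)))
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' ATE weights are the stabilized form (marginal treatment prevalence in the
#' numerator): treated \eqn{P(T=1)/ps}, controls \eqn{P(T=0)/(1-ps)}. ATT
#' weights: treated 1, controls \eqn{ps/(1-ps)}. ATU weights: treated
#' \eqn{(1-ps)/ps}, controls 1.
#'
#' @param ps propensity scores in (0, 1).
#' @param treatment binary treatment indicator.
#' @param estimand \code{"ATE"}, \code{"ATT"} or \code{"ATU"}.
#' @return positive finite weights, one per subject.
#' @export
stabilized_weights <- function(ps, treatment, estimand = c("ATE", "ATT", "ATU")) {
  estimand <- match.arg(estimand)
  if (any(ps <= 0) || any(ps >= 1))
    stop("input error: propensity scores must lie strictly in (0, 1)", call. = FALSE)
  t <- as.integer(treatment)
  pt <- mean(t)
  w <- switch(estimand,
              ATE = ifelse(t == 1, pt / ps, (1 - pt) / (1 - ps)),
              ATT = ifelse(t == 1, 1, ps / (1 - ps)),
              ATU = ifelse(t == 1, (1 - ps) / ps, 1))
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}

weighted_or <- function(y, t, w, correct = FALSE) {
  a <- sum(w[t == 1 & y == 1])
  b <- sum(w[t == 0 & y == 1])
  cc <- sum(w[t == 1 & y == 0])
  d <- sum(w[t == 0 & y == 0])
  if (correct || any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  (a * d) / (b * cc)
}

#' Weighted standardized mean differences
#'
#' Balance diagnostic: per covariate, the difference of (weighted) treated and
#' control means divided by the pooled unweighted standard deviation. Factor
#' covariates are expanded to indicator columns.
#'
#' @param data data.frame of covariates.
#' @param covariates covariate names.
#' @param treatment binary treatment vector.
#' @param weights case weights (NULL = unweighted).
#' @return data.frame with \code{covariate} and \code{smd}.
#' @export
balance_smd <- function(data, covariates, treatment, weights = NULL) {
  t <- as.integer(treatment)
  if (is.null(weights)) weights <- rep(1, length(t))
  X <- model.matrix(stats::reformulate(covariates), data = data)[, -1, drop = FALSE]
  smd <- vapply(colnames(X), function(cn) {
    x <- X[, cn]
    m1 <- sum(weights[t == 1] * x[t == 1]) / sum(weights[t == 1])
    m0 <- sum(weights[t == 0] * x[t == 0]) / sum(weights[t == 0])
    s <- sqrt((var(x[t == 1]) + var(x[t == 0])) / 2)
    if (s == 0) 0 else (m1 - m0) / s
  }, numeric(1))
  data.frame(covariate = colnames(X), smd = unname(smd))
}

#' Estimate a weighted treatment effect with bootstrap confidence intervals
#'
#' Point estimate is the odds ratio from a weighted logistic regression of the
#' outcome on treatment (for this saturated model, identical to the weighted
#' 2x2 odds ratio). Confidence limits are percentile bootstrap over
#' \code{n_boot} nonparametric resamples; when \code{weight_fn} is supplied it
#' is called with the resample indices so the propensity model and weights are
#' refit inside every resample. The p-value is a normal approximation from the
#' bootstrap spread of the log odds ratio. If an arm has zero (weighted)
#' events, a continuity-corrected odds ratio is reported with a warning.
#'
#' @param outcome binary outcome vector.
#' @param treatment binary treatment vector.
#' @param weights per-subject weights (used as-is for the point estimate).
#' @param estimand label recorded in the result (\code{"ATE"}, \code{"ATT"},
#'   \code{"ATU"}).
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed integer seed for the bootstrap.
#' @param weight_fn optional \code{function(idx)} returning refitted weights
#'   for the subjects in \code{idx}; defaults to reusing \code{weights[idx]}.
#' @param balance_data,balance_covariates optional covariate data for a
#'   before/after weighting balance table.
#' @return object of class \code{effect_estimate}.
#' @export
estimate_effect <- function(outcome, treatment, weights,
                            estimand = "ATE", n_boot = 1000, seed = NULL,
                            weight_fn = NULL, balance_data = NULL,
                            balance_covariates = NULL) {
  y <- as.integer(outcome)
  t <- as.integer(treatment)
  if (sum(weights[t == 1]) <= 0 || sum(weights[t == 0]) <= 0)
    stop("input error: both arms need positive total weight", call. = FALSE)
  cells0 <- c(sum(weights[t == 1 & y == 1]), sum(weights[t == 0 & y == 1]),
              sum(weights[t == 1 & y == 0]), sum(weights[t == 0 & y == 0]))
  if (any(cells0 == 0)) {
    warning("zero (weighted) events in an arm; continuity-corrected odds ratio")
    est <- weighted_or(y, t, weights, correct = TRUE)
  } else {
    fit <- suppressWarnings(glm(y ~ t, family = quasibinomial(), weights = weights))
    est <- exp(coef(fit)[["t"]])
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  boot_lor <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    wb <- if (is.null(weight_fn)) weights[idx] else weight_fn(idx)
    if (length(unique(t[idx])) < 2) return(NA_real_)
    log(weighted_or(y[idx], t[idx], wb,
                    correct = any(tapply(y[idx], t[idx], function(v) sum(v) == 0 ||
                                           sum(1 - v) == 0))))
  }, numeric(1))
  boot_lor <- boot_lor[is.finite(boot_lor)]
  ci <- exp(quantile(boot_lor, c(0.025, 0.975), names = FALSE))
  se <- sd(boot_lor)
  p <- if (se > 0) 2 * pnorm(-abs(log(est)) / se) else NA_real_
  bal <- NULL
  if (!is.null(balance_data) && length(balance_covariates)) {
    before <- balance_smd(balance_data, balance_covariates, t)
    after <- balance_smd(balance_data, balance_covariates, t, weights)
    bal <- data.frame(covariate = before$covariate,
                      smd_unweighted = before$smd,
                      smd_weighted = after$smd)
  }
  structure(list(estimand = estimand, estimate = unname(est),
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 weights = weights, n_boot = length(boot_lor),
                 balance_table = bal),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s odds ratio: %.2f (95%% CI %.2f-%.2f), p = %.3g [%d bootstrap resamples]\n",
              x$estimand, x$estimate, x$ci_low, x$ci_high, x$p_value, x$n_boot))
  if (!is.null(x$balance_table)) {
    cat("  max |SMD| after weighting:",
        sprintf("%.3f", max(abs(x$balance_table$smd_weighted))), "\n")
  }
  invisible(x)
}

#' Confounder screening, propensity weighting and effect estimation in one call
#'
#' Runs \code{\link{screen_confounders}} (optional),
#' \code{\link{fit_propensity}}, \code{\link{stabilized_weights}} and
#' \code{\link{estimate_effect}} for each requested estimand, refitting the
#' propensity model inside every bootstrap resample.
#'
#' @param data data.frame with treatment, outcome and covariates.
#' @param treatment,outcome column names.
#' @param candidates candidate covariate names.
#' @param estimands subset of \code{c("ATT", "ATU", "ATE")}.
#' @param screen apply confounder screening (default TRUE; FALSE uses all
#'   candidates).
#' @param smooth smooth propensity terms, see \code{\link{fit_propensity}}.
#' @param n_boot,seed bootstrap controls.
#' @param clip propensity clipping bounds.
#' @return list with \code{effects} (named list of
#'   \code{\link{estimate_effect}} results), \code{screening} (data.frame),
#'   \code{selected} (covariate names), \code{ps} (propensity scores).
#' @export
treatment_effect <- function(data, treatment, outcome, candidates,
                             estimands = c("ATT", "ATU", "ATE"),
                             screen = TRUE, smooth = TRUE,
                             n_boot = 500, seed = 1L, clip = c(0.01, 0.99)) {
  screening <- NULL
  selected <- candidates
  if (screen && length(candidates)) {
    screening <- screen_confounders(data, treatment, outcome, candidates)
    selected <- screening$covariate[screening$selected]
  }
  ps <- fit_propensity(data, treatment, selected, smooth = smooth, clip = clip)
  t <- as.integer(data[[treatment]])
  y <- as.integer(data[[outcome]])
  # linear-logistic refit on a precomputed model matrix keeps the
  # per-resample propensity refit cheap inside the bootstrap
  X <- if (length(selected))
    model.matrix(stats::reformulate(selected), data = data) else NULL
  effects <- lapply(estimands, function(es) {
    w <- stabilized_weights(ps, t, es)
    wfn <- function(idx) {
      fit <- suppressWarnings(glm.fit(X[idx, , drop = FALSE], t[idx],
                                      family = binomial()))
      ps_b <- pmin(pmax(fit$fitted.values, clip[1]), clip[2])
      stabilized_weights(ps_b, t[idx], es)
    }
    estimate_effect(y, t, w, estimand = es, n_boot = n_boot, seed = seed,
                    weight_fn = if (length(selected)) wfn else NULL,
                    balance_data = data, balance_covariates = selected)
  })
  names(effects) <- estimands
  list(effects = effects, screening = screening, selected = selected, ps = ps)
}
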