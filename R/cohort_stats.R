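#' Benjamini-Hochberg step-up FDR control
#'
#' Classical step-up: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, reject hypotheses 1..k* where \eqn{k^* = \max\{k : p_{(k)} \le
#' kq/m\}}. Adjusted p-values come from \code{stats::p.adjust("BH")} and are
#' monotone non-decreasing in rank.
#'
#' @param p p-values in [0, 1].
#' @param q target false discovery rate, default 0.05.
#' @return list with \code{reject} (logical, in input order) and
#'   \code{adjusted} (BH-adjusted p-values); both empty for empty input.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (!length(p)) return(list(reject = logical(0), adjusted = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("input error: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  list(reject = reject, adjusted = p.adjust(p, method = "BH"))
}

fmt_pct <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)

is_categorical <- function(x) is.factor(x) || is.character(x) || is.logical(x) ||
  (is.numeric(x) && length(unique(x[!is.na(x)])) <= 2)

#' Baseline group comparisons with normality gating and FDR control
#'
#' Builds a Table-1-style comparison across groups. Continuous variables are
#' tested for normality per group (Lilliefors-corrected Kolmogorov-Smirnov);
#' when every group looks normal a t-test (2 groups) or one-way ANOVA is used,
#' otherwise Wilcoxon rank-sum or Kruskal-Wallis. Categorical variables use
#' the chi-square test without continuity correction, switching to Fisher's
#' exact test when any expected cell count is below 5. Benjamini-Hochberg
#' correction is applied across all rows; summaries are mean +/- sd or
#' n (percent to one decimal).
#'
#' @param data data.frame.
#' @param group name of the grouping column (>= 2 non-empty groups).
#' @param vars variables to compare (default: all other columns).
#' @param q FDR level for the BH flags, default 0.05.
#' @param normality_alpha per-group normality-test level, default 0.05.
#' @return data.frame of class \code{comparison_table}: one row per variable
#'   with per-group summary strings, \code{test}, \code{p_value},
#'   \code{p_adjusted}, \code{fdr_significant}.
#' @export
compare_groups <- function(data, group, vars = setdiff(names(data), group),
                           q = 0.05, normality_alpha = 0.05) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2 || any(table(g) == 0))
    stop("input error: need at least 2 non-empty groups", call. = FALSE)
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    row <- data.frame(variable = v, type = "", test = "", p_value = NA_real_,
                      note = "")
    for (l in lv) row[[paste0("group_", l)]] <- ""
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      row$type <- "constant"
      row$p_value <- 1
      row$note <- "constant variable"
      for (l in lv) row[[paste0("group_", l)]] <- as.character(x[ok][1])
      return(row)
    }
    if (is_categorical(x)) {
      x <- factor(x)
      tab <- table(g[ok], x[ok])
      pos <- if (nlevels(x) == 2) nlevels(x) else NULL
      for (l in lv) {
        n_l <- sum(g[ok] == l)
        row[[paste0("group_", l)]] <- if (!is.null(pos))
          fmt_pct(tab[l, pos], n_l)
        else paste(vapply(colnames(tab), function(cl)
          fmt_pct(tab[l, cl], n_l), character(1)), collapse = " / ")
      }
      expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
      if (any(expected < 5)) {
        row$test <- "fisher"
        row$p_value <- fisher.test(tab)$p.value
      } else {
        row$test <- "chi-square"
        row$p_value <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      }
      row$type <- "categorical"
    } else {
      for (l in lv) {
        xs <- x[ok & g == l]
        row[[paste0("group_", l)]] <- sprintf("%.1f ± %.1f", mean(xs), sd(xs))
      }
      normal <- all(vapply(lv, function(l) {
        xs <- x[ok & g == l]
        if (length(xs) < 5 || sd(xs) == 0) return(FALSE)
        tryCatch(nortest::lillie.test(xs)$p.value > normality_alpha,
                 error = function(e) FALSE)
      }, logical(1)))
      if (normal) {
        if (nlevels(g) == 2) {
          row$test <- "t-test"
          row$p_value <- t.test(x[ok] ~ g[ok])$p.value
        } else {
          row$test <- "anova"
          row$p_value <- summary(aov(x[ok] ~ g[ok]))[[1]][["Pr(>F)"]][1]
        }
      } else {
        if (nlevels(g) == 2) {
          row$test <- "wilcoxon"
          row$p_value <- suppressWarnings(wilcox.test(x[ok] ~ g[ok], exact = FALSE)$p.value)
        } else {
          row$test <- "kruskal-wallis"
          row$p_value <- kruskal.test(x[ok] ~ g[ok])$p.value
        }
      }
      row$type <- "continuous"
    }
    row
  })
  out <- do.call(rbind, rows)
  bh <- bh_adjust(out$p_value, q)
  out$p_adjusted <- bh$adjusted
  out$fdr_significant <- bh$reject
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df[, setdiff(names(df), "note")], row.names = FALSE)
  invisible(x)
}

#' Multivariable logistic regression for ICU mortality
#'
#' Candidates passing a univariable screen (likelihood-ratio p <
#' \code{screen_p}) plus any \code{always_keep} variables enter a joint
#' maximum-likelihood logistic model; odds ratios with Wald confidence
#' intervals are reported. On signs of separation the model is refit with a
#' ridge penalty and a warning (point estimates only).
#'
#' @param data data.frame.
#' @param outcome name of the binary outcome column.
#' @param candidates candidate covariate names.
#' @param screen_p univariable entry threshold, default 0.1.
#' @param always_keep covariates kept regardless of the screen.
#' @return data.frame with \code{variable}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}; attribute \code{screen} holds the
#'   univariable p-values, attribute \code{entered} the final covariate set.
#' @export
multivariate_logistic <- function(data, outcome, candidates, screen_p = 0.1,
                                  always_keep = NULL) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) != 2)
    stop("input error: outcome must be binary", call. = FALSE)
  m0 <- glm(stats::reformulate("1", outcome), data = data, family = binomial())
  univ <- vapply(candidates, function(v) {
    m1 <- tryCatch(glm(stats::reformulate(v, outcome), data = data,
                       family = binomial()), error = function(e) NULL)
    if (is.null(m1)) return(NA_real_)
    stats::anova(m0, m1, test = "LRT")$`Pr(>Chi)`[2]
  }, numeric(1))
  entered <- union(candidates[!is.na(univ) & univ < screen_p], always_keep)
  if (!length(entered))
    stop("input error: no covariate passed the univariable screen", call. = FALSE)
  if (nrow(data) <= 10 * length(entered))
    warning("fewer than 10 events-per-variable-style observations per covariate")
  fit <- suppressWarnings(glm(stats::reformulate(entered, outcome), data = data,
                              family = binomial()))
  cf <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  if (!fit$converged || any(abs(cf) > 15) || any(se > 10)) {
    warning("possible separation; ridge-penalized estimates reported without CIs")
    X <- model.matrix(stats::reformulate(entered), data = data)
    rf <- ridge_logit(X, as.integer(y))
    cf <- rf$coef[-1]
    names(cf) <- colnames(X)[-1]
    out <- data.frame(variable = names(cf), or = exp(cf),
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_)
  } else {
    z <- cf / se
    out <- data.frame(variable = names(cf), or = exp(cf),
                      ci_low = exp(cf - qnorm(0.975) * se),
                      ci_high = exp(cf + qnorm(0.975) * se),
                      p_value = 2 * pnorm(-abs(z)))
  }
  rownames(out) <- NULL
  attr(out, "screen") <- data.frame(variable = candidates, p_univariable = univ)
  attr(out, "entered") <- entered
  out
}

#' Fluid balance vs daily mean ICP correlation by outcome stratum
#'
#' Pearson correlation of first-day fluid balance with the daily ICP mean,
#' computed separately within each outcome stratum (e.g. ICU deaths vs
#' survivors), with \eqn{R^2 = r^2} and the two-sided correlation test
#' p-value.
#'
#' @param fluid_balance numeric, mL.
#' @param icp_mean numeric, mmHg.
#' @param strata stratum labels (e.g. ICU-death indicator).
#' @return data.frame with \code{stratum}, \code{n}, \code{r},
#'   \code{r_squared}, \code{p_value}; strata with fewer than 3 subjects or a
#'   degenerate variable yield NA with a note.
#' @export
fluid_icp_correlation <- function(fluid_balance, icp_mean, strata) {
  s <- factor(strata)
  out <- lapply(levels(s), function(l) {
    i <- s == l & !is.na(fluid_balance) & !is.na(icp_mean)
    n <- sum(i)
    if (n < 3)
      return(data.frame(stratum = l, n = n, r = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, note = "fewer than 3 subjects"))
    if (sd(fluid_balance[i]) == 0 || sd(icp_mean[i]) == 0)
      return(data.frame(stratum = l, n = n, r = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, note = "zero variance"))
    ct <- cor.test(fluid_balance[i], icp_mean[i], method = "pearson")
    data.frame(stratum = l, n = n, r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
               note = "")
  })
  do.call(rbind, out)
}
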