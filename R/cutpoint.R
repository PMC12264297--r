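#' Kaplan-Meier estimate of ICU survival
#'
#' Product-limit estimator of the survival function, right-continuous with
#' S(0) = 1 and drops only at observed event times.
#'
#' @param time follow-up in hours (positive).
#' @param event 1 = ICU death, 0 = censored at ICU discharge.
#' @return a \code{survival::survfit} object.
#' @export
km_estimate <- function(time, event) {
  if (any(time <= 0)) stop("input error: times must be positive", call. = FALSE)
  survival::survfit(survival::Surv(time, event) ~ 1)
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' @param fit a \code{survfit} object.
#' @param t times at which to read the right-continuous step function.
#' @return survival probabilities, 1 before the first event.
#' @export
km_survival <- function(fit, t) {
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  sf(t)
}

#' Two-group log-rank test
#'
#' Classical log-rank statistic: at each distinct event time the observed
#' number of group-1 events is compared with its expectation under the
#' hypergeometric null given the risk sets, and the standardized sum is
#' referred to a chi-square distribution with 1 df. Implemented directly
#' (vectorized over distinct event times) so it can be evaluated cheaply
#' across many candidate dichotomizations.
#'
#' @param time follow-up, hours.
#' @param event 1 = death, 0 = censored.
#' @param group two-level grouping (logical, 0/1, or factor with 2 levels);
#'   both groups must be non-empty.
#' @return list with \code{chi_square}, \code{p_value}, \code{observed} and
#'   \code{expected} events in group 1, and \code{variance}.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2)
    stop("input error: log-rank needs two non-empty groups", call. = FALSE)
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1]))
  if (!length(ut))
    return(list(chi_square = 0, p_value = 1, observed = 0, expected = 0,
                variance = 0))
  st <- sort(time)
  st1 <- sort(time[g == 1])
  n <- length(time)
  # at-risk counts: subjects with time >= t
  N <- n - findInterval(ut, st, left.open = TRUE)
  N1 <- length(st1) - findInterval(ut, st1, left.open = TRUE)
  et <- time[event == 1]
  d <- as.numeric(table(factor(et, levels = ut)))
  d1 <- as.numeric(table(factor(et[g[event == 1] == 1], levels = ut)))
  E1 <- d * N1 / N
  V <- ifelse(N > 1, d * (N1 / N) * (1 - N1 / N) * (N - d) / (N - 1), 0)
  O <- sum(d1)
  E <- sum(E1)
  Vs <- sum(V)
  chi <- if (Vs > 0) (O - E)^2 / Vs else 0
  list(chi_square = chi,
       p_value = if (Vs > 0) pchisq(chi, df = 1, lower.tail = FALSE) else 1,
       observed = O, expected = E, variance = Vs)
}

#' Scan candidate cut-points of a marker for the minimum log-rank p-value
#'
#' X-tile-style optimal dichotomization: candidates are the distinct rounded
#' marker values; for each admissible candidate c (both groups
#' \code{marker <= c} / \code{marker > c} holding at least
#' \code{min_group_frac} of subjects) the two-group log-rank test is computed,
#' and the candidate with the smallest p-value wins (ties broken toward the
#' larger chi-square, then the smaller cut). Because the minimum p over many
#' candidate cuts is anti-conservative, a Sidak-style minimum-p correction
#' \code{1 - (1 - p_min)^m} over the m candidates is reported alongside the
#' raw p; the raw minimum still drives cut selection, mirroring the original
#' procedure.
#'
#' @param marker continuous marker (daily ICP mean in mmHg or variance in
#'   mmHg^2).
#' @param time,event survival data as in \code{\link{logrank_test}}.
#' @param min_group_frac minimum fraction of subjects on each side of an
#'   admissible cut (default 0.05).
#' @param rounding digits for candidate rounding (default 0: integer
#'   candidates).
#' @return object of class \code{cutpoint_result}: \code{best_cut},
#'   \code{chi_square}, \code{p_value}, \code{corrected_p},
#'   \code{group_sizes} (n_low, n_high), and \code{scan_table} (one row per
#'   admissible candidate). When no candidate is admissible, \code{best_cut}
#'   is NA with \code{reason = "no admissible cutpoint"}.
#' @export
scan_cutpoints <- function(marker, time, event, min_group_frac = 0.05,
                           rounding = 0) {
  if (anyNA(marker)) stop("input error: missing marker values", call. = FALSE)
  n <- length(marker)
  cands <- sort(unique(round(marker, rounding)))
  min_n <- ceiling(min_group_frac * n)
  rows <- lapply(cands, function(cc) {
    n_low <- sum(marker <= cc)
    n_high <- n - n_low
    if (n_low < max(1, min_n) || n_high < max(1, min_n)) return(NULL)
    lr <- logrank_test(time, event, marker > cc)
    data.frame(cut = cc, chi_square = lr$chi_square, p_value = lr$p_value,
               n_low = n_low, n_high = n_high)
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0) {
    return(structure(list(best_cut = NA_real_, chi_square = NA_real_,
                          p_value = NA_real_, corrected_p = NA_real_,
                          group_sizes = c(n_low = NA_integer_, n_high = NA_integer_),
                          scan_table = data.frame(),
                          reason = "no admissible cutpoint"),
                     class = "cutpoint_result"))
  }
  ord <- order(scan$p_value, -scan$chi_square, scan$cut)
  best <- scan[ord[1], ]
  m <- nrow(scan)
  # -expm1(m * log1p(-p)) stays accurate for p near 0, where 1-(1-p)^m underflows
  structure(list(best_cut = best$cut, chi_square = best$chi_square,
                 p_value = best$p_value,
                 corrected_p = min(1, max(best$p_value,
                                          -expm1(m * log1p(-best$p_value)))),
                 group_sizes = c(n_low = best$n_low, n_high = best$n_high),
                 scan_table = scan, reason = NULL),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  if (is.na(x$best_cut)) {
    cat("Cut-point scan:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Optimal cut-point: %g (chi-square %.2f, raw p %.3g, corrected p %.3g)\n",
              x$best_cut, x$chi_square, x$p_value, x$corrected_p))
  cat(sprintf("  groups: n_low = %d (marker <= cut), n_high = %d; %d candidates scanned\n",
              x$group_sizes["n_low"], x$group_sizes["n_high"], nrow(x$scan_table)))
  invisible(x)
}

#' Dichotomize a marker at a cut-point
#'
#' Low group is \code{marker <= cut}, high group \code{marker > cut} (a value
#' exactly at the cut is low).
#'
#' @param marker numeric marker values.
#' @param cut threshold.
#' @return factor with levels \code{low}, \code{high}; attribute
#'   \code{degenerate} is TRUE (with a warning) when all subjects fall on one
#'   side.
#' @export
dichotomize <- function(marker, cut) {
  f <- factor(ifelse(marker > cut, "high", "low"), levels = c("low", "high"))
  deg <- length(unique(f[!is.na(f)])) < 2
  if (deg) warning("degenerate dichotomization: all subjects in one group")
  attr(f, "degenerate") <- deg
  f
}
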