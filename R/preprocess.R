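#' Round chart events to the nearest hour slot
#'
#' Assigns each measurement within a subject's first ICU day to its nearest
#' hour (ties at half past round up), averages multiple measurements landing
#' on the same slot, and flags slots without any measurement as missing.
#' Events rounding to hour 24 (i.e. at or after 23:30) are clamped to slot 24
#' (index 23).
#'
#' @param times POSIXct timestamps, or numeric hours since \code{day_start}.
#' @param values ICP measurements, mmHg.
#' @param day_start POSIXct anchor of the 24-h window (ignored for numeric
#'   \code{times}).
#' @return list with \code{values} (length 24, NA where missing) and
#'   \code{mask} (length-24 logical, TRUE = observed).
#' @export
round_to_hour <- function(times, values, day_start = NULL) {
  if (length(times) != length(values))
    stop("input error: times and values differ in length", call. = FALSE)
  if (inherits(times, "POSIXt")) {
    if (is.null(day_start))
      stop("input error: day_start required for POSIXct times", call. = FALSE)
    hrs <- as.numeric(difftime(times, day_start, units = "hours"))
  } else {
    hrs <- as.numeric(times)
  }
  if (length(hrs) && (any(hrs < 0) || any(hrs >= 24)))
    stop("input error: events outside the [day_start, day_start + 24 h) window",
         call. = FALSE)
  vals <- rep(NA_real_, 24)
  if (length(hrs)) {
    idx <- pmin(floor(hrs + 0.5), 23) + 1  # nearest hour, :30 rounds up, clamp 24 -> 23
    agg <- tapply(values, idx, mean)
    vals[as.integer(names(agg))] <- as.numeric(agg)
  }
  list(values = vals, mask = !is.na(vals))
}

#' First-day exclusion rule from the hourly missingness mask
#'
#' A subject is excluded when no first-day ICP monitoring is available at all,
#' or when the longest run of consecutive missing hour slots (runs touching
#' the start or end of the day included) exceeds 6 hours. A gap of exactly
#' 6 hours is retained.
#'
#' @param mask length-24 logical, TRUE = observed.
#' @return logical scalar, TRUE = excluded.
#' @export
gap_exclude <- function(mask) {
  if (length(mask) != 24)
    stop("input error: mask must have length 24", call. = FALSE)
  if (!any(mask)) return(TRUE)
  r <- rle(!mask)
  longest <- max(c(0, r$lengths[r$values]))
  longest > 6
}

#' Impute missing hourly values by interpolation
#'
#' Interior missing slots are filled by linear interpolation between the
#' nearest observed neighbours; leading and trailing missing slots carry the
#' nearest observed value (flat extrapolation). Observed slots are returned
#' unchanged.
#'
#' @param values length-24 numeric with NA at missing slots.
#' @param mask optional length-24 logical; derived from \code{is.na(values)}
#'   when omitted.
#' @return completed length-24 numeric vector.
#' @export
impute_series <- function(values, mask = !is.na(values)) {
  if (length(values) != 24)
    stop("input error: values must have length 24", call. = FALSE)
  if (!any(mask))
    stop("precondition violation: fully-missing series cannot be imputed",
         call. = FALSE)
  if (all(mask)) return(as.numeric(values))
  if (sum(mask) == 1) return(rep(as.numeric(values[mask]), 24))
  approx(x = which(mask), y = values[mask], xout = 1:24, rule = 2)$y
}

#' Daily mean and variance of a completed hourly series
#'
#' @param values completed length-24 numeric vector (mmHg).
#' @return named numeric: \code{icp_mean} (mmHg) and \code{icp_variance}
#'   (mmHg^2, sample variance with denominator 23).
#' @export
summarize_series <- function(values) {
  if (length(values) != 24 || anyNA(values))
    stop("input error: summarize_series needs a completed 24-point series",
         call. = FALSE)
  c(icp_mean = mean(values), icp_variance = var(values))
}

#' Build first-day hourly ICP series for a cohort
#'
#' Applies \code{\link{round_to_hour}}, \code{\link{gap_exclude}},
#' \code{\link{impute_series}} and \code{\link{summarize_series}} per subject.
#' Subjects listed in \code{admissions} but absent from \code{events} get a
#' fully-missing series and are excluded with reason \code{"no monitoring"}.
#'
#' @param events data.frame with \code{subject_id}, \code{charttime},
#'   \code{icp_mmHg}; events outside a subject's first 24 h are dropped.
#' @param admissions data.frame with \code{subject_id} and \code{icu_intime}
#'   (POSIXct) anchoring each subject's day window.
#' @return object of class \code{icp_series}: list with \code{summary}
#'   (data.frame: subject_id, n_events, n_observed, excluded, reason,
#'   icp_mean, icp_variance), \code{series} (n x 24 completed matrix, NA rows
#'   for excluded subjects) and \code{mask} (n x 24 logical).
#' @export
first_day_series <- function(events, admissions) {
  need <- c("subject_id", "charttime", "icp_mmHg")
  if (!all(need %in% names(events)))
    stop("input error: events must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- admissions$subject_id
  n <- length(ids)
  series <- matrix(NA_real_, n, 24, dimnames = list(ids, paste0("h", 1:24)))
  mask <- matrix(FALSE, n, 24, dimnames = dimnames(series))
  summ <- data.frame(subject_id = ids, n_events = 0L, n_observed = 0L,
                     excluded = FALSE, reason = "",
                     icp_mean = NA_real_, icp_variance = NA_real_)
  ev_by_id <- split(events, events$subject_id)
  for (i in seq_len(n)) {
    sub <- ev_by_id[[as.character(ids[i])]]
    start <- admissions$icu_intime[i]
    if (!is.null(sub)) {
      hrs <- as.numeric(difftime(sub$charttime, start, units = "hours"))
      keep <- hrs >= 0 & hrs < 24
      sub <- sub[keep, ]
    }
    if (is.null(sub) || nrow(sub) == 0) {
      summ$excluded[i] <- TRUE
      summ$reason[i] <- "no monitoring"
      next
    }
    rt <- round_to_hour(sub$charttime, sub$icp_mmHg, day_start = start)
    summ$n_events[i] <- nrow(sub)
    summ$n_observed[i] <- sum(rt$mask)
    mask[i, ] <- rt$mask
    if (gap_exclude(rt$mask)) {
      summ$excluded[i] <- TRUE
      summ$reason[i] <- "monitoring gap over 6 h"
      series[i, ] <- rt$values
      next
    }
    series[i, ] <- impute_series(rt$values, rt$mask)
    s <- summarize_series(series[i, ])
    summ$icp_mean[i] <- s["icp_mean"]
    summ$icp_variance[i] <- s["icp_variance"]
  }
  structure(list(summary = summ, series = series, mask = mask),
            class = "icp_series")
}

#' @export
print.icp_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf("First-day ICP series: %d subjects, %d excluded (%s)\n",
              nrow(s), sum(s$excluded),
              paste(unique(s$reason[s$excluded]), collapse = "; ")))
  ok <- !s$excluded
  if (any(ok))
    cat(sprintf("  ICP_mean %.1f +/- %.1f mmHg, ICP_variance median %.1f mmHg^2\n",
                mean(s$icp_mean[ok]), sd(s$icp_mean[ok]),
                median(s$icp_variance[ok])))
  invisible(x)
}

#' Normalize a cohort series matrix
#'
#' Per-timepoint (column-wise) normalization across the cohort: z-score
#' (default) centers each column and scales it to unit sample variance;
#' min-max maps each column to [0, 1]. Degenerate columns (zero variance or
#' zero range) map to all-zeros. Column centers/scales are stored as
#' attributes so the transform is invertible via
#' \code{\link{denormalize_matrix}}.
#'
#' @param x numeric matrix, subjects in rows (n >= 2), time points in columns.
#' @param method \code{"zscore"} or \code{"minmax"}.
#' @return normalized matrix with attributes \code{norm_center},
#'   \code{norm_scale}, \code{norm_method}.
#' @export
normalize_matrix <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("input error: normalization needs at least 2 series", call. = FALSE)
  if (method == "zscore") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
  } else {
    ctr <- apply(x, 2, min)
    scl <- apply(x, 2, max) - ctr
  }
  scl_safe <- ifelse(scl > 0, scl, 1)
  out <- sweep(sweep(x, 2, ctr), 2, scl_safe, "/")
  out[, scl == 0] <- 0
  attr(out, "norm_center") <- ctr
  attr(out, "norm_scale") <- scl
  attr(out, "norm_method") <- method
  out
}

#' Invert \code{\link{normalize_matrix}}
#'
#' @param x matrix produced by \code{\link{normalize_matrix}} (degenerate
#'   columns are restored to their constant value).
#' @return matrix on the original scale.
#' @export
denormalize_matrix <- function(x) {
  ctr <- attr(x, "norm_center")
  scl <- attr(x, "norm_scale")
  if (is.null(ctr) || is.null(scl))
    stop("input error: not a normalized matrix (missing attributes)", call. = FALSE)
  out <- sweep(sweep(unclass(x), 2, ifelse(scl > 0, scl, 1), "*"), 2, ctr, "+")
  attributes(out)[c("norm_center", "norm_scale", "norm_method")] <- NULL
  out
}

#' Aggregate first-day covariate measurements
#'
#' Reduces multi-measured first-day variables the way bedside data are
#' summarized clinically: mean for vitals, min and/or max for labs, min for
#' GCS, and fluid balance as total input minus urine output.
#'
#' @param measurements long data.frame with columns \code{subject_id},
#'   \code{variable}, \code{value}.
#' @param rules named list mapping variable names to aggregation functions
#'   (any of \code{"mean"}, \code{"min"}, \code{"max"}, \code{"sum"}).
#'   Variables absent from \code{rules} are aggregated by mean. If variables
#'   \code{"fluid_input"} and \code{"urine_output"} are present, a
#'   \code{fluid_balance} column (sum(input) - sum(urine)) is added.
#' @return wide data.frame, one row per subject, columns
#'   \code{<variable>_<stat>} (or the bare variable name for single-stat
#'   rules); missing variables yield NA, never an error.
#' @export
aggregate_first_day <- function(measurements,
                                rules = list(gcs = "min",
                                             heart_rate = "mean",
                                             sbp = "mean",
                                             resp_rate = "mean",
                                             temperature = "mean")) {
  need <- c("subject_id", "variable", "value")
  if (!all(need %in% names(measurements)))
    stop("input error: measurements must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ids <- sort(unique(measurements$subject_id))
  out <- data.frame(subject_id = ids)
  vars <- setdiff(unique(measurements$variable), c("fluid_input", "urine_output"))
  for (v in vars) {
    stats_wanted <- rules[[v]]
    if (is.null(stats_wanted)) stats_wanted <- "mean"
    sub <- measurements[measurements$variable == v, ]
    for (st in stats_wanted) {
      f <- match.fun(st)
      agg <- tapply(sub$value, sub$subject_id, f)
      col <- if (length(stats_wanted) == 1) paste0(v, "_", st) else paste0(v, "_", st)
      out[[col]] <- as.numeric(agg[as.character(ids)])
    }
  }
  if (all(c("fluid_input", "urine_output") %in% measurements$variable)) {
    inp <- measurements[measurements$variable == "fluid_input", ]
    urn <- measurements[measurements$variable == "urine_output", ]
    tot_in <- tapply(inp$value, inp$subject_id, sum)
    tot_out <- tapply(urn$value, urn$subject_id, sum)
    out$fluid_balance <- as.numeric(tot_in[as.character(ids)]) -
      as.numeric(tot_out[as.character(ids)])
  }
  out
}
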