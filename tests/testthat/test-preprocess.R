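day0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

test_that("nearest-hour rounding assigns, averages duplicates, and passes exact hours through", {
  # 00:29 rounds down to slot 1, 00:41 rounds up to slot 2
  rt <- round_to_hour(day0 + c(29, 41) * 60, c(12, 14), day0)
  expect_equal(rt$values[1:2], c(12, 14))
  expect_identical(rt$mask[1:2], c(TRUE, TRUE))
  expect_true(all(is.na(rt$values[3:24])))

  # 00:50 and 01:10 both land on hour 1 and are averaged
  rt <- round_to_hour(day0 + c(50, 70) * 60, c(14, 10), day0)
  expect_equal(rt$values[2], 12)

  # exact hourly grid is the identity
  rt <- round_to_hour(day0 + (0:23) * 3600, 1:24, day0)
  expect_true(all(rt$mask))
  expect_equal(rt$values, as.numeric(1:24))

  # ties at :30 round up; measurements at/after 23:30 clamp to the last slot
  rt <- round_to_hour(day0 + c(0.5, 23.7) * 3600, c(5, 9), day0)
  expect_equal(rt$values[2], 5)
  expect_equal(rt$values[24], 9)

  expect_error(round_to_hour(day0 + 25 * 3600, 1, day0), "window")
})

test_that("every event contributes to exactly one slot (count conservation)", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(1:60, 1)
    hrs <- runif(n, 0, 24)
    rt <- round_to_hour(hrs, rnorm(n, 10))
    slot <- pmin(floor(hrs + 0.5), 23) + 1
    expect_equal(sum(rt$mask), length(unique(slot)))
    expect_equal(sum(tabulate(slot, 24) > 0), sum(rt$mask))
  }
})

test_that("gap exclusion follows the strict over-6-hour rule", {
  m <- rep(TRUE, 24)
  expect_false(gap_exclude(m))                      # fully observed
  m7 <- m; m7[5:11] <- FALSE
  expect_true(gap_exclude(m7))                      # 7-hour gap excluded
  m6 <- m; m6[5:10] <- FALSE
  expect_false(gap_exclude(m6))                     # exactly 6 retained
  expect_true(gap_exclude(rep(FALSE, 24)))          # no monitoring at all
  edge <- m; edge[1:7] <- FALSE
  expect_true(gap_exclude(edge))                    # run touching the day edge counts
})

test_that("gap exclusion equals a brute-force longest-run scan on random masks", {
  set.seed(7)
  got <- want <- logical(10000)
  for (i in 1:10000) {
    mask <- runif(24) > runif(1, 0.05, 0.6)
    got[i] <- gap_exclude(mask)
    want[i] <- !any(mask) || oracle_longest_gap(mask) > 6L
  }
  expect_identical(got, want)
})

test_that("interpolation fills interior gaps linearly and edges flat, never touching observed values", {
  v <- rep(NA_real_, 24)
  v[5] <- 10; v[7] <- 14
  out <- impute_series(v)
  expect_equal(out[6], 12)
  expect_equal(out[1:4], rep(10, 4))    # leading flat carry
  expect_equal(out[8:24], rep(14, 17))  # trailing flat carry

  v2 <- rep(NA_real_, 24); v2[3] <- 9
  expect_equal(impute_series(v2)[1:2], c(9, 9))

  full <- rnorm(24)
  expect_equal(impute_series(full), full)            # identity when complete
  expect_equal(impute_series(out), out)              # idempotent
  expect_error(impute_series(rep(NA_real_, 24)), "fully-missing")
})

test_that("imputation preserves observed entries on random patterns", {
  set.seed(15)
  for (i in 1:200) {
    v <- rnorm(24, 12, 3)
    miss <- sample(24, sample(1:20, 1))
    vm <- v; vm[miss] <- NA
    if (all(is.na(vm))) next
    out <- impute_series(vm)
    obs <- setdiff(1:24, miss)
    expect_equal(out[obs], v[obs])
    expect_false(anyNA(out))
  }
})

test_that("series summary gives the 24-point mean and sample variance", {
  expect_equal(summarize_series(rep(10, 24)),
               c(icp_mean = 10, icp_variance = 0))
  alt <- rep(c(8, 12), 12)
  s <- summarize_series(alt)
  expect_equal(unname(s["icp_mean"]), 10)
  expect_equal(unname(s["icp_variance"]), 24 * 4 / 23)  # = 4.1739...
})

test_that("z-score normalization is column-wise with the degenerate-column rule", {
  x <- rbind(c(9, 5), c(11, 5))
  z <- normalize_matrix(x)
  expect_equal(z[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(z[, 2], c(0, 0))                       # constant column -> zeros
  set.seed(3)
  big <- matrix(rnorm(50 * 24, 10, 4), 50)
  zb <- normalize_matrix(big)
  expect_equal(unname(colMeans(zb)), rep(0, 24), tolerance = 1e-12)
  expect_equal(unname(apply(zb, 2, sd)), rep(1, 24), tolerance = 1e-12)
  expect_error(normalize_matrix(big[1, , drop = FALSE]), "at least 2")
})

test_that("normalization round-trips through its stored affine parameters", {
  set.seed(8)
  x <- matrix(rnorm(40 * 24, 12, 5), 40)
  x[, 7] <- 3  # degenerate column must round-trip too
  for (m in c("zscore", "minmax")) {
    z <- normalize_matrix(x, method = m)
    expect_lt(max(abs(denormalize_matrix(z) - x)), 1e-10)
    if (m == "minmax") {
      expect_gte(min(z), 0)
      expect_lte(max(z), 1)
    }
  }
})

test_that("first-day aggregation uses min for GCS, mean for vitals, and input minus urine for fluid balance", {
  meas <- data.frame(
    subject_id = 1,
    variable = c("gcs", "gcs", "gcs", "heart_rate", "heart_rate",
                 "fluid_input", "urine_output"),
    value = c(14, 7, 10, 60, 100, 3000, 1800))
  agg <- aggregate_first_day(meas)
  expect_equal(agg$gcs_min, 7)
  expect_equal(agg$heart_rate_mean, 80)
  expect_equal(agg$fluid_balance, 1200)
})

test_that("cohort series builder flags no-monitoring and long-gap subjects", {
  adm <- data.frame(subject_id = 1:3, icu_intime = day0)
  ev <- rbind(
    data.frame(subject_id = 1, charttime = day0 + (0:23) * 3600,
               icp_mmHg = rnorm(24, 10)),
    data.frame(subject_id = 2, charttime = day0 + c(0:7, 16:23) * 3600,
               icp_mmHg = rnorm(16, 10)))  # 8-hour hole
  ser <- first_day_series(ev, adm)
  expect_identical(ser$summary$excluded, c(FALSE, TRUE, TRUE))
  expect_identical(ser$summary$reason, c("", "monitoring gap over 6 h",
                                         "no monitoring"))
  expect_false(anyNA(ser$series[1, ]))
  expect_equal(unname(ser$summary$icp_mean[1]), mean(ser$series[1, ]))
})
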