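#' Validate input CSV schemas
#'
#' Checks the chart-event and cohort tables for required columns, parseable
#' ISO-8601 timestamps, finite ICP values and duplicate subjects, returning a
#' machine-readable violation list instead of failing on first error.
#'
#' @param chartevents path to a chart-events CSV (\code{subject_id},
#'   \code{charttime}, \code{icp_mmHg}).
#' @param cohort path to a cohort CSV (\code{subject_id}, \code{icu_intime},
#'   \code{icu_death}, \code{time_hours}, covariates).
#' @return data.frame with columns \code{file}, \code{check}, \code{detail};
#'   zero rows when both files are well-formed.
#' @export
validate_inputs <- function(chartevents, cohort) {
  viol <- list()
  add <- function(file, check, detail)
    viol[[length(viol) + 1]] <<- data.frame(file = file, check = check,
                                            detail = detail)
  ce <- tryCatch(read.csv(chartevents, stringsAsFactors = FALSE),
                 error = function(e) {
                   add(chartevents, "readable", conditionMessage(e))
                   NULL
                 })
  if (!is.null(ce)) {
    for (col in c("subject_id", "charttime", "icp_mmHg"))
      if (!col %in% names(ce))
        add(chartevents, "column", paste("missing column", col))
    if ("charttime" %in% names(ce)) {
      parsed <- parse_iso(ce$charttime)
      bad <- which(is.na(parsed))
      if (length(bad))
        add(chartevents, "timestamp",
            paste("non-ISO timestamp at rows:",
                  paste(head(bad, 10), collapse = ", ")))
    }
    if ("icp_mmHg" %in% names(ce)) {
      vals <- suppressWarnings(as.numeric(ce$icp_mmHg))
      if (any(!is.finite(vals)))
        add(chartevents, "value",
            paste("non-finite icp_mmHg at rows:",
                  paste(head(which(!is.finite(vals)), 10), collapse = ", ")))
    }
  }
  co <- tryCatch(read.csv(cohort, stringsAsFactors = FALSE),
                 error = function(e) {
                   add(cohort, "readable", conditionMessage(e))
                   NULL
                 })
  if (!is.null(co)) {
    for (col in c("subject_id", "icu_intime", "icu_death", "time_hours"))
      if (!col %in% names(co))
        add(cohort, "column", paste("missing column", col))
    if ("subject_id" %in% names(co) && anyDuplicated(co$subject_id))
      add(cohort, "duplicates",
          paste("duplicated subject_id:",
                paste(head(unique(co$subject_id[duplicated(co$subject_id)]), 10),
                      collapse = ", ")))
    if ("icu_intime" %in% names(co)) {
      parsed <- parse_iso(co$icu_intime)
      if (any(is.na(parsed)))
        add(cohort, "timestamp",
            paste("non-ISO icu_intime at rows:",
                  paste(head(which(is.na(parsed)), 10), collapse = ", ")))
    }
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(file = character(0), check = character(0),
                  detail = character(0))
}

# per-element ISO parse that returns NA for bad entries
parse_iso <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

default_run_config <- function() {
  list(mode = "simulate",
       sim = list(),
       chartevents = NULL, cohort = NULL,
       normalization = "zscore",
       k_range = 2:7,
       cutpoint = list(min_group_frac = 0.05, rounding = 0),
       causal = list(estimands = c("ATT", "ATU", "ATE"), n_boot = 500,
                     screen = TRUE, smooth = TRUE),
       fdr_q = 0.05,
       seed = 1L,
       out_dir = NULL)
}

#' Run the full first-day ICP analysis pipeline
#'
#' Executes simulate/ingest, preprocessing, clustering, cut-point search,
#' stabilized-IPTW effect estimation and cohort statistics in order, writing
#' per-stage CSVs plus a \code{manifest.json} that records the configuration
#' hash, the seed and subject counts in/out of every stage. Re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param config named list (or path to a YAML file) overriding the defaults:
#'   \code{mode} ("simulate" or "ingest"), \code{sim} (arguments to
#'   \code{\link{sim_config}}), \code{chartevents}/\code{cohort} (CSV paths,
#'   ingest mode), \code{normalization} ("zscore" or "minmax"),
#'   \code{k_range}, \code{cutpoint} (min_group_frac, rounding),
#'   \code{causal} (estimands, n_boot, screen, smooth), \code{fdr_q},
#'   \code{seed}, \code{out_dir} (NULL = no files written).
#' @return (invisibly) a list with all stage results and the \code{manifest}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  seed <- as.integer(cfg$seed)

  ## stage 1: data
  if (identical(cfg$mode, "simulate")) {
    sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = seed), cfg$sim))
    dat <- simulate_cohort(sim_cfg)
    chartevents <- dat$chartevents
    cohort <- dat$cohort
    truth <- dat$truth
  } else if (identical(cfg$mode, "ingest")) {
    viol <- validate_inputs(cfg$chartevents, cfg$cohort)
    if (nrow(viol))
      stop("stage ingest: schema violations:\n",
           paste(viol$file, viol$check, viol$detail, sep = " | ", collapse = "\n"),
           call. = FALSE)
    chartevents <- read.csv(cfg$chartevents, stringsAsFactors = FALSE)
    chartevents$charttime <- parse_iso(chartevents$charttime)
    cohort <- read.csv(cfg$cohort, stringsAsFactors = FALSE)
    cohort$icu_intime <- parse_iso(cohort$icu_intime)
    truth <- NULL
  } else stop("stage config: unknown mode ", cfg$mode, call. = FALSE)

  ## stage 2: hourly series
  admissions <- cohort[, c("subject_id", "icu_intime")]
  ser <- first_day_series(chartevents, admissions)
  included <- ser$summary$subject_id[!ser$summary$excluded]
  if (length(included) == 0)
    stop("stage series: empty post-exclusion cohort", call. = FALSE)
  keep <- match(included, ser$summary$subject_id)
  series_mat <- ser$series[keep, , drop = FALSE]
  summ <- ser$summary[keep, ]
  cohort_in <- cohort[match(included, cohort$subject_id), ]
  cohort_in$icp_mean <- summ$icp_mean
  cohort_in$icp_variance <- summ$icp_variance

  ## stage 3: clustering
  norm <- normalize_matrix(series_mat, method = cfg$normalization)
  sol <- select_k(norm, k_range = cfg$k_range, seed = seed)
  cohort_in$cluster <- relabel_by_size(sol$labels)

  ## stage 4: cut-points
  scans <- lapply(c(icp_mean = "icp_mean", icp_variance = "icp_variance"),
                  function(mk)
                    scan_cutpoints(cohort_in[[mk]], cohort_in$time_hours,
                                   cohort_in$icu_death,
                                   min_group_frac = cfg$cutpoint$min_group_frac,
                                   rounding = cfg$cutpoint$rounding))
  if (is.na(scans$icp_mean$best_cut))
    stop("stage cutpoint: no admissible cut-point for icp_mean", call. = FALSE)
  cohort_in$icp_group <- dichotomize(cohort_in$icp_mean, scans$icp_mean$best_cut)

  ## KM per dichotomized group
  grid <- seq(0, max(cohort_in$time_hours), length.out = 100)
  km_groups <- do.call(rbind, lapply(levels(cohort_in$icp_group), function(l) {
    i <- cohort_in$icp_group == l
    fit <- km_estimate(cohort_in$time_hours[i], cohort_in$icu_death[i])
    data.frame(group = l, time_hours = grid, survival = km_survival(fit, grid))
  }))

  ## stage 5: causal weighting
  candidates <- intersect(c("age", "gender", "gcs_min", "apsiii", "oasis", "sofa"),
                          names(cohort_in))
  cohort_in$treated <- as.integer(cohort_in$icp_group == "high")
  causal <- treatment_effect(cohort_in, "treated", "icu_death", candidates,
                             estimands = cfg$causal$estimands,
                             screen = cfg$causal$screen,
                             smooth = cfg$causal$smooth,
                             n_boot = cfg$causal$n_boot,
                             seed = seed + 1L)
  effects <- do.call(rbind, lapply(causal$effects, function(e)
    data.frame(estimand = e$estimand, estimate = e$estimate,
               ci_low = e$ci_low, ci_high = e$ci_high, p_value = e$p_value)))

  ## stage 6: cohort statistics
  t1_vars <- intersect(c("gender", "age", "icu_death", "apsiii", "oasis", "sofa",
                         "gcs_min", "fluid_balance"), names(cohort_in))
  table1 <- compare_groups(cohort_in[, c("icp_group", t1_vars)], "icp_group",
                           q = cfg$fdr_q)
  logit_cands <- intersect(c("age", "gender", "gcs_min", "apsiii", "oasis",
                             "sofa", "treated"), names(cohort_in))
  logistic <- multivariate_logistic(cohort_in, "icu_death", logit_cands,
                                    always_keep = intersect(c("age", "treated"),
                                                            logit_cands))
  correlation <- if ("fluid_balance" %in% names(cohort_in))
    fluid_icp_correlation(cohort_in$fluid_balance, cohort_in$icp_mean,
                          ifelse(cohort_in$icu_death == 1, "icu_death", "survived"))
  else NULL

  ## manifest
  cfg_hash <- config_hash(cfg)
  manifest <- list(
    config_hash = cfg_hash,
    seed = seed,
    stages = list(
      input = list(n_subjects = nrow(cohort), n_events = nrow(chartevents)),
      series = list(n_in = nrow(cohort), n_excluded = sum(ser$summary$excluded),
                    n_out = length(included),
                    exclusion_reasons = as.list(table(
                      ser$summary$reason[ser$summary$excluded]))),
      cluster = list(selected_k = sol$k,
                     db_by_k = as.list(round(sol$per_k_db, 6)),
                     cluster_sizes = as.list(table(cohort_in$cluster))),
      cutpoint = list(icp_mean_cut = scans$icp_mean$best_cut,
                      icp_variance_cut = scans$icp_variance$best_cut),
      causal = list(selected_covariates = as.list(causal$selected)),
      stats = list(n_table1_rows = nrow(table1))
    )
  )

  result <- list(config = cfg, chartevents = chartevents, cohort = cohort_in,
                 truth = truth, series = ser, clusters = sol, scans = scans,
                 km_groups = km_groups, causal = causal, effects = effects,
                 table1 = table1, logistic = logistic,
                 correlation = correlation, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_outputs(result, cfg$out_dir)
  invisible(result)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  # drop non-portable fields so the hash depends only on analysis settings
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

write_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  s <- result$series$summary
  series_df <- cbind(s, as.data.frame(result$series$series),
                     setNames(as.data.frame(result$series$mask),
                              paste0("obs", 1:24)))
  w(series_df, "series.csv")
  w(data.frame(subject_id = result$cohort$subject_id,
               cluster = as.character(result$cohort$cluster)), "clusters.csv")
  w(data.frame(k = as.integer(names(result$clusters$per_k_db)),
               db_index = as.numeric(result$clusters$per_k_db)), "db_by_k.csv")
  scan_df <- rbind(cbind(marker = "icp_mean", result$scans$icp_mean$scan_table),
                   cbind(marker = "icp_variance",
                         result$scans$icp_variance$scan_table))
  w(scan_df, "cutpoint_scan.csv")
  w(result$km_groups, "km_groups.csv")
  w(result$effects, "effects.csv")
  w(data.frame(subject_id = result$cohort$subject_id,
               ps = as.numeric(result$causal$ps),
               weight_ate = stabilized_weights(result$causal$ps,
                                               result$cohort$treated, "ATE")),
    "weights.csv")
  bal <- result$causal$effects[[1]]$balance_table
  if (!is.null(bal)) w(bal, "balance.csv")
  w(as.data.frame(result$table1), "table1.csv")
  w(result$logistic, "logistic.csv")
  if (!is.null(result$correlation)) w(result$correlation, "correlation.csv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write simulated cohort tables to CSV
#'
#' Writes \code{chartevents.csv}, \code{cohort.csv} and \code{truth.csv} with
#' documented headers, for use as pipeline ingest inputs.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the output directory.
#' @export
write_simulation <- function(config, out_dir) {
  dat <- simulate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ce <- dat$chartevents
  ce$charttime <- format(ce$charttime, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(ce, file.path(out_dir, "chartevents.csv"), row.names = FALSE)
  co <- dat$cohort
  co$icu_intime <- format(co$icu_intime, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(co, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(dat$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(out_dir)
}
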