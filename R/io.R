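#' Read a fluorescence trace and its event log from CSV
#'
#' The trace file needs columns `time_s,fluorescence_afu`; the events file
#' `time_s,kind,aliquot_volume_ul,aliquot_concentration_mM` (UTF-8, comma
#' separated, header row, '.' decimal). Malformed rows are reported with
#' their line numbers.
#'
#' @param trace_path Path to the trace CSV.
#' @param events_path Path to the events CSV.
#' @param initial_volume_ml Cuvette volume before additions (mL).
#' @param id Trace identifier; defaults to the file name.
#' @return A [fluorescence_trace()].
#' @export
read_trace <- function(trace_path, events_path, initial_volume_ml = 2,
                       id = NULL) {
  tr <- read_checked_csv(trace_path, c("time_s", "fluorescence_afu"))
  ev <- read_events(events_path)
  fluorescence_trace(tr$time_s, tr$fluorescence_afu, ev, initial_volume_ml,
                     id = if (is.null(id)) basename(trace_path) else id)
}

#' @rdname read_trace
#' @export
read_events <- function(events_path) {
  ev <- read_checked_csv(events_path,
                         c("time_s", "kind", "aliquot_volume_ul",
                           "aliquot_concentration_mM"),
                         numeric_cols = c("time_s", "aliquot_volume_ul",
                                          "aliquot_concentration_mM"))
  validate_events(ev)
}

#' Read a donor/patient cohort table from CSV
#'
#' Requires at least `donor_id`, `em_nc_mV`, `em_cap_mV`; further columns
#' (e.g. `group`, IVF outcomes) are carried through.
#'
#' @param path Path to the cohort CSV.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  read_checked_csv(path, c("donor_id", "em_nc_mV", "em_cap_mV"),
                   numeric_cols = c("em_nc_mV", "em_cap_mV"))
}

read_checked_csv <- function(path, required, numeric_cols = required) {
  if (!file.exists(path))
    .stop_empredict(paste("file not found:", path), "empredict_load_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stop_empredict(sprintf("%s: missing column(s) %s", path,
                            paste(miss, collapse = ", ")),
                    "empredict_load_error")
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      .stop_empredict(sprintf("%s: unparseable number in column '%s', line %s",
                              path, col, paste(bad + 1L, collapse = ", ")),
                      "empredict_load_error")
    df[[col]] <- v
  }
  df
}

#' Write a trace (and optionally its events) to CSV
#'
#' @param trace A [fluorescence_trace()].
#' @param trace_path Output path for the time/fluorescence table.
#' @param events_path Optional output path for the event log.
#' @return Invisibly, `trace_path`.
#' @export
write_trace <- function(trace, trace_path, events_path = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              fluorescence_afu = trace$fluorescence),
                   trace_path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(trace$events, events_path, row.names = FALSE)
  invisible(trace_path)
}

#' Default pipeline configuration
#'
#' Collects every tunable of the analysis in one list: ionic context,
#' plateau windows, calibration mode, the 5 mV behaviour threshold, the
#' hyperactivation criteria triple, the 0.60 IVF success threshold, cohort
#' and IVF-link parameters, and the master seed. The list round-trips
#' losslessly through YAML or JSON.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    k_out_initial_mM = 5.0, k_in_mM = 120, temperature_K = 310.15,
    window_s = 20, settle_delay_s = 10, min_samples = 5,
    include_valinomycin_point = TRUE, calibration_method = "ols",
    behavior_threshold_mV = 5,
    ha_vcl_min = 150, ha_lin_max = 50, ha_alh_min = 5,
    ivf_success_threshold = 0.60,
    n_donors = 49, cohort_group = "normospermic",
    em_nc_mean_mV = -37.7, em_nc_sd_mV = 9.9,
    em_cap_mean_mV = -57.8, em_cap_sd_mV = 12.9,
    behavior_mixture = c(0.536, 0.328, 0.136),
    measurement_noise_sd_mV = 2,
    ivf_intercept = -1.344, ivf_slope = -0.036,
    seed = 1, simulate_traces = FALSE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    .stop_empredict(paste("unknown config key(s):", paste(bad, collapse = ", ")),
                    "empredict_config_error")
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return For `read_config`, a `pipeline_config`; unknown keys error.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    .stop_empredict(paste("config file not found:", path), "empredict_config_error")
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config` list.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Chains the stages end to end: cohort generation (or a supplied cohort
#' table), optional per-donor trace simulation and re-calibration of Em
#' from the traces, behaviour classification, paired NC-vs-CAP comparison,
#' IVF outcome simulation (or supplied outcomes), Em_CAP-fertilization
#' correlation, and ROC analysis of Em_CAP as a predictor of IVF success.
#' Deterministic for a fixed config (which includes the seed).
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional cohort data frame (columns as [read_cohort()]);
#'   when `NULL` a synthetic cohort is generated from the config.
#' @param ivf Optional IVF outcome data frame with `oocytes` and
#'   `fertilized_2pn` aligned with the cohort rows; when `NULL`, outcomes
#'   are simulated from the config's logistic link.
#' @return List of class `pipeline_report` with elements `config_digest`,
#'   `seed`, `cohort` (with appended `behavior` column), `ivf`,
#'   `group_stats`, `paired_test`, `correlation`, `roc`, and `versions`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL, ivf = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ctx <- ionic_context(config$k_out_initial_mM, config$k_in_mM,
                       config$temperature_K)
  seed <- as.integer(config$seed)

  if (is.null(cohort)) {
    spec <- cohort_spec(
      n_donors = config$n_donors, group = config$cohort_group,
      em_nc_mean_mV = config$em_nc_mean_mV, em_nc_sd_mV = config$em_nc_sd_mV,
      em_cap_mean_mV = config$em_cap_mean_mV, em_cap_sd_mV = config$em_cap_sd_mV,
      behavior_mixture = config$behavior_mixture,
      measurement_noise_sd_mV = config$measurement_noise_sd_mV,
      threshold_mV = config$behavior_threshold_mV)
    cohort <- simulate_cohort(spec, seed = seed)
    if (isTRUE(config$simulate_traces)) {
      # measure each donor's NC and CAP Em through the full fluorimetric
      # calibration instead of taking the generator's noisy readout
      proto <- default_protocol(context = ctx)
      cal_cfg <- list(window = config$window_s, settle_delay = config$settle_delay_s,
                      min_samples = config$min_samples,
                      include_valinomycin_point = config$include_valinomycin_point,
                      method = config$calibration_method)
      dye_noise <- 0.02 * abs(dye_model()$slope_afu_per_mV) * 90
      measure <- function(true_em, sub_seed, cond) {
        dye <- dye_model(noise_sd_afu = dye_noise)
        tr <- simulate_trace(true_em, dye, proto, seed = sub_seed)
        process_trace(tr, ctx, cal_cfg, condition = cond)$em_mV
      }
      for (i in seq_len(nrow(cohort))) {
        cohort$em_nc_mV[i] <- measure(cohort$em_nc_true_mV[i],
                                      seed + 2L * i, "NC_t")
        cohort$em_cap_mV[i] <- measure(cohort$em_cap_true_mV[i],
                                       seed + 2L * i + 1L, "CAP_t")
      }
    }
  }
  if (nrow(cohort) == 0)
    .stop_empredict("empty cohort: nothing to analyse", "empredict_no_data")

  cohort$behavior <- classify_behavior(cohort$em_nc_mV, cohort$em_cap_mV,
                                       config$behavior_threshold_mV)

  if (is.null(ivf)) {
    link <- ivf_link_spec(intercept = config$ivf_intercept,
                          slope = config$ivf_slope,
                          success_threshold = config$ivf_success_threshold)
    ivf <- simulate_ivf_cohort(link, cohort$em_cap_mV, seed = seed + 10000L)
  } else {
    ivf$fertilization_rate <- ivf$fertilized_2pn / ivf$oocytes
    ivf$successful <- ivf_success(ivf$fertilized_2pn, ivf$oocytes,
                                  config$ivf_success_threshold)
    ivf$em_cap_mV <- cohort$em_cap_mV
  }

  group_stats <- list(
    n = nrow(cohort),
    em_nc_mean_mV = mean(cohort$em_nc_mV), em_nc_sd_mV = stats::sd(cohort$em_nc_mV),
    em_cap_mean_mV = mean(cohort$em_cap_mV), em_cap_sd_mV = stats::sd(cohort$em_cap_mV),
    behavior_percent = as.list(100 * prop.table(table(cohort$behavior))))

  roc <- tryCatch(
    roc_analysis(ivf$em_cap_mV, ivf$successful, orientation = "lower"),
    empredict_error = function(e) NULL)

  report <- list(
    seed = seed,
    config_digest = config_digest(config),
    cohort = cohort, ivf = ivf, group_stats = group_stats,
    paired_test = paired_t(cohort$em_nc_mV, cohort$em_cap_mV),
    correlation = pearson(ivf$em_cap_mV, 100 * ivf$fertilization_rate),
    roc = roc,
    versions = list(empredict = as.character(utils::packageVersion("empredict")),
                    r = paste(R.version$major, R.version$minor, sep = ".")))
  class(report) <- "pipeline_report"
  report
}

# stable content digest of a config (no external digest dependency)
config_digest <- function(config) {
  s <- paste(deparse(unclass(config)[order(names(unclass(config)))]),
             collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' @export
print.pipeline_report <- function(x, ...) {
  gs <- x$group_stats
  cat(sprintf("<pipeline_report: n = %d, seed = %d, config %s>\n",
              gs$n, x$seed, x$config_digest))
  cat(sprintf("  Em NC  %.1f +/- %.1f mV; Em CAP %.1f +/- %.1f mV (paired p = %.3g)\n",
              gs$em_nc_mean_mV, gs$em_nc_sd_mV, gs$em_cap_mean_mV,
              gs$em_cap_sd_mV, x$paired_test$p_value))
  bp <- gs$behavior_percent
  cat(sprintf("  behaviour: %.1f%% hyperpolarizing, %.1f%% depolarizing, %.1f%% unchanged\n",
              bp$hyperpolarizing, bp$depolarizing, bp$unchanged))
  cat(sprintf("  Em_CAP vs IVF rate: r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p_value))
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  x <- unclass(report)
  x$cohort$behavior <- as.character(x$cohort$behavior)
  if (!is.null(x$roc)) x$roc <- unclass(x$roc)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
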