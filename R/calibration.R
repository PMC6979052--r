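#' Nernst equilibrium potential for potassium
#'
#' With the membrane rendered K+-selective by valinomycin, the membrane
#' potential is clamped to the potassium equilibrium potential
#' E_K = (RT/F) ln([K+]o / [K+]i). This supplies the theoretical potential
#' for each step of the internal calibration.
#'
#' @param k_out_mM External K+ concentration (mM); may be a vector.
#' @param k_in_mM Intracellular K+ concentration (mM).
#' @param temperature_K Absolute temperature (kelvin).
#' @return Potential(s) in mV. Zero when `k_out_mM == k_in_mM`, strictly
#'   increasing in `k_out_mM`.
#' @export
#' @examples
#' nernst_potential(5, 120, 310.15)   # approx -84.9 mV
nernst_potential <- function(k_out_mM, k_in_mM, temperature_K) {
  if (any(!is.finite(k_out_mM)) || any(k_out_mM <= 0) ||
      !is.finite(k_in_mM) || k_in_mM <= 0 ||
      !is.finite(temperature_K) || temperature_K <= 0)
    .stop_empredict("concentrations and temperature must be finite and > 0",
                    "empredict_invalid_input")
  1000 * (.GAS_CONSTANT * temperature_K / .FARADAY) * log(k_out_mM / k_in_mM)
}

#' External potassium after sequential additions
#'
#' Tracks the cuvette's external K+ concentration and total volume through
#' the event log, applying exact dilution mass balance at each KCl aliquot:
#' K_new = (K V + C_aliquot V_aliquot) / (V + V_aliquot). The valinomycin
#' addition (negligible volume of ionophore solution) leaves K+ unchanged.
#'
#' @param context An [ionic_context()].
#' @param events Event data frame (see [fluorescence_trace()]).
#' @param initial_volume_ml Cuvette volume before any addition (mL).
#' @return Data frame with one row per event: `time_s`, `kind`,
#'   `k_out_mM` (after the addition), `volume_ml` (after the addition).
#' @export
cumulative_potassium <- function(context, events, initial_volume_ml) {
  events <- validate_events(events)
  if (initial_volume_ml <= 0)
    .stop_empredict("initial volume must be > 0", "empredict_invalid_input")
  k <- context$k_out_initial_mM
  v <- initial_volume_ml
  out <- events[c("time_s", "kind")]
  out$k_out_mM <- NA_real_
  out$volume_ml <- NA_real_
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "KCl") {
      v_al <- events$aliquot_volume_ul[i] / 1000  # uL -> mL
      c_al <- events$aliquot_concentration_mM[i]
      k <- (k * v + c_al * v_al) / (v + v_al)
      v <- v + v_al
    }
    out$k_out_mM[i] <- k
    out$volume_ml[i] <- v
  }
  out
}

#' Extract plateau fluorescence around each calibration event
#'
#' The slow dye response settles to a new steady level after each addition;
#' the plateau is summarised as the mean fluorescence over
#' `[t_event + settle_delay, t_event + settle_delay + window]`. An extra
#' "initial" plateau — the resting fluorescence that encodes the sample's
#' own Em — is taken from the `window` seconds immediately preceding the
#' valinomycin addition (recordings start at steady state).
#'
#' @param trace A [fluorescence_trace()].
#' @param window Averaging window length (s).
#' @param settle_delay Dead time after each addition before averaging (s),
#'   allowing dye re-equilibration.
#' @param min_samples Minimum number of samples required in every window.
#' @return Data frame with columns `event` (`"initial"`, `"valinomycin"`,
#'   `"KCl"`), `time_s` (event time; start of recording window for the
#'   initial plateau), `plateau_afu`, `plateau_sd_afu`, `n_samples`.
#' @export
detect_plateaus <- function(trace, window = 20, settle_delay = 10,
                            min_samples = 5L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (window <= 0 || settle_delay < 0)
    .stop_empredict("window must be > 0 and settle_delay >= 0",
                    "empredict_invalid_input")
  events <- trace$events
  val_t <- events$time_s[events$kind == "valinomycin"]

  take <- function(lo, hi, label, right_open = FALSE) {
    sel <- trace$time >= lo & (if (right_open) trace$time < hi else trace$time <= hi)
    if (sum(sel) < min_samples)
      .stop_empredict(
        sprintf("window [%.1f, %.1f] s for event '%s' has %d samples (< %d): window too short",
                lo, hi, label, sum(sel), min_samples),
        "empredict_window_too_short")
    f <- trace$fluorescence[sel]
    c(mean = mean(f), sd = stats::sd(f), n = sum(sel))
  }

  # strictly pre-valinomycin: the addition instant belongs to the response
  init <- take(val_t - window, val_t, "initial", right_open = TRUE)
  rows <- list(data.frame(event = "initial", time_s = val_t - window,
                          plateau_afu = init[["mean"]],
                          plateau_sd_afu = init[["sd"]], n_samples = init[["n"]]))
  for (i in seq_len(nrow(events))) {
    lo <- events$time_s[i] + settle_delay
    hi <- lo + window
    nxt <- if (i < nrow(events)) events$time_s[i + 1] else max(trace$time)
    if (hi > nxt + 1e-9)
      .stop_empredict(
        sprintf("event '%s' at %.1f s is followed by less than settle_delay + window of recording",
                events$kind[i], events$time_s[i]),
        "empredict_window_too_short")
    p <- take(lo, hi, events$kind[i])
    rows[[i + 1]] <- data.frame(event = events$kind[i], time_s = events$time_s[i],
                                plateau_afu = p[["mean"]],
                                plateau_sd_afu = p[["sd"]], n_samples = p[["n"]])
  }
  do.call(rbind, rows)
}

#' Build an internal calibration curve
#'
#' Pairs each post-valinomycin plateau with its theoretical Nernst potential
#' at the prevailing external K+ and fits an ordinary least-squares line of
#' fluorescence on potential. The valinomycin plateau itself anchors the
#' curve at the Nernst potential of the unmodified medium (valinomycin
#' clamps Em to E_K); set `include_valinomycin_point = FALSE` to calibrate
#' from KCl steps only.
#'
#' @param plateaus Plateau table from [detect_plateaus()].
#' @param context An [ionic_context()].
#' @param events Event data frame of the trace.
#' @param initial_volume_ml Cuvette volume before additions (mL).
#' @param include_valinomycin_point Use the valinomycin plateau as a
#'   calibration point at E_K of the initial medium (default TRUE).
#' @return An object of class `calibration_curve`: list with `points`
#'   (data frame `theoretical_em_mV`, `plateau_afu`), `slope` (AFU/mV),
#'   `intercept` (AFU), `r_squared`.
#' @export
build_calibration <- function(plateaus, context, events, initial_volume_ml,
                              include_valinomycin_point = TRUE) {
  events <- validate_events(events)
  ktab <- cumulative_potassium(context, events, initial_volume_ml)
  keep <- if (include_valinomycin_point) ktab$kind %in% c("valinomycin", "KCl")
          else ktab$kind == "KCl"
  ktab <- ktab[keep, , drop = FALSE]
  pl <- plateaus[plateaus$event != "initial", , drop = FALSE]
  pl <- pl[keep, , drop = FALSE]
  if (nrow(ktab) < 2L)
    .stop_empredict("at least 2 calibration points are required",
                    "empredict_insufficient_calibration")
  em <- nernst_potential(ktab$k_out_mM, context$k_in_mM, context$temperature_K)
  if (stats::sd(em) == 0)
    .stop_empredict("theoretical potentials have zero variance: degenerate fit",
                    "empredict_degenerate_fit")
  fit <- stats::lm(pl$plateau_afu ~ em)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pl$plateau_afu - mean(pl$plateau_afu))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(points = data.frame(theoretical_em_mV = em, plateau_afu = pl$plateau_afu),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve: %d points, F = %.3f %+.4f * Em, r^2 = %.4f>\n",
              nrow(x$points), x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Estimate absolute Em from initial fluorescence
#'
#' Inverts the calibration to map the resting (pre-valinomycin) fluorescence
#' to a membrane potential. With `method = "ols"` (default) the fitted line
#' is inverted globally: Em = (F - intercept) / slope. With
#' `method = "piecewise"` the initial fluorescence is linearly interpolated
#' between the bracketing calibration points (extended linearly beyond the
#' extremes). Estimates outside the span of calibration plateau
#' fluorescences are flagged as extrapolated, never rejected.
#'
#' @param initial_fluorescence Resting fluorescence (AFU).
#' @param curve A [build_calibration()] result.
#' @param method `"ols"` or `"piecewise"`.
#' @param condition Condition label (e.g. `"NC0"`, `"NC_t"`, `"CAP_t"`).
#' @return An object of class `em_measurement`: list with `em_mV`,
#'   `condition`, `initial_fluorescence_afu`, `extrapolated`,
#'   `curve_r_squared`, `method`.
#' @export
estimate_em <- function(initial_fluorescence, curve,
                        method = c("ols", "piecewise"), condition = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  method <- match.arg(method)
  if (!is.finite(initial_fluorescence))
    .stop_empredict("initial fluorescence must be finite", "empredict_invalid_input")
  if (method == "ols") {
    if (curve$slope == 0)
      .stop_empredict("calibration slope is zero: fluorescence carries no Em information",
                      "empredict_flat_calibration")
    em <- (initial_fluorescence - curve$intercept) / curve$slope
  } else {
    pts <- curve$points[order(curve$points$plateau_afu), ]
    if (anyDuplicated(pts$plateau_afu))
      .stop_empredict("duplicated plateau fluorescences: piecewise inversion undefined",
                      "empredict_flat_calibration")
    # linear interpolation with linear extension beyond the calibrated span
    em <- stats::approx(pts$plateau_afu, pts$theoretical_em_mV,
                        xout = initial_fluorescence, rule = 1)$y
    if (is.na(em)) {
      n <- nrow(pts)
      if (initial_fluorescence < pts$plateau_afu[1]) lo <- 1:2 else lo <- (n - 1):n
      sl <- diff(pts$theoretical_em_mV[lo]) / diff(pts$plateau_afu[lo])
      em <- pts$theoretical_em_mV[lo[1]] +
        sl * (initial_fluorescence - pts$plateau_afu[lo[1]])
    }
  }
  span <- range(curve$points$plateau_afu)
  structure(
    list(em_mV = em, condition = condition,
         initial_fluorescence_afu = initial_fluorescence,
         extrapolated = initial_fluorescence < span[1] | initial_fluorescence > span[2],
         curve_r_squared = curve$r_squared, method = method),
    class = "em_measurement"
  )
}

#' @export
print.em_measurement <- function(x, ...) {
  cat(sprintf("<em_measurement: %.2f mV (%s)%s, calibration r^2 = %.4f>\n",
              x$em_mV, ifelse(is.na(x$condition), "unlabelled", x$condition),
              if (isTRUE(x$extrapolated)) " [extrapolated]" else "",
              x$curve_r_squared))
  invisible(x)
}

#' Process a fluorescence trace into an Em measurement
#'
#' Deterministic composition of the calibration stages: dilution bookkeeping
#' ([cumulative_potassium()]), plateau extraction ([detect_plateaus()]),
#' calibration fit ([build_calibration()]) and inversion ([estimate_em()]).
#' The returned measurement carries a quality record (fit r-squared,
#' extrapolation flag, per-plateau SDs).
#'
#' @param trace A [fluorescence_trace()].
#' @param context An [ionic_context()].
#' @param config Optional list overriding `window`, `settle_delay`,
#'   `min_samples`, `include_valinomycin_point`, `method` (see the
#'   component functions).
#' @param condition Condition label attached to the measurement.
#' @return An `em_measurement` with extra elements `plateaus` (plateau
#'   table), `curve` (the calibration), and `trace_id`.
#' @export
process_trace <- function(trace, context = ionic_context(), config = list(),
                          condition = NA_character_) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  cfg <- utils::modifyList(
    list(window = 20, settle_delay = 10, min_samples = 5L,
         include_valinomycin_point = TRUE, method = "ols"),
    config)
  pl <- withCallingHandlers(
    detect_plateaus(trace, window = cfg$window, settle_delay = cfg$settle_delay,
                    min_samples = cfg$min_samples),
    error = function(e) {
      if (inherits(e, "empredict_error"))
        .stop_empredict(sprintf("trace '%s': %s", trace$id, conditionMessage(e)),
                        class(e)[1])
    })
  curve <- build_calibration(pl, context, trace$events, trace$initial_volume_ml,
                             include_valinomycin_point = cfg$include_valinomycin_point)
  m <- estimate_em(pl$plateau_afu[pl$event == "initial"], curve,
                   method = cfg$method, condition = condition)
  m$plateaus <- pl
  m$curve <- curve
  m$trace_id <- trace$id
  m
}

#' Process a list of traces
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param context An [ionic_context()].
#' @param config Configuration list as in [process_trace()].
#' @param conditions Optional character vector of condition labels.
#' @return Data frame with one row per trace: `trace_id`, `condition`,
#'   `em_mV`, `r_squared`, `extrapolated`.
#' @export
process_traces <- function(traces, context = ionic_context(), config = list(),
                           conditions = NULL) {
  if (is.null(conditions)) conditions <- rep(NA_character_, length(traces))
  res <- mapply(function(tr, cond) {
    m <- process_trace(tr, context, config, condition = cond)
    data.frame(trace_id = m$trace_id, condition = cond, em_mV = m$em_mV,
               r_squared = m$curve_r_squared, extrapolated = m$extrapolated,
               stringsAsFactors = FALSE)
  }, traces, conditions, SIMPLIFY = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
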