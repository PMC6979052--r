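#' Construct a fluorescence trace
#'
#' A `fluorescence_trace` bundles a time-stamped fluorescence series
#' (arbitrary fluorescence units, AFU) with the event log of reagent
#' additions needed for internal calibration: one valinomycin addition
#' followed by sequential KCl aliquots.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing, starting at recording onset.
#' @param fluorescence Numeric vector of fluorescence values (AFU), same
#'   length as `time`, finite and strictly positive.
#' @param events Data frame with columns `time_s`, `kind`
#'   (`"valinomycin"` or `"KCl"`), `aliquot_volume_ul`,
#'   `aliquot_concentration_mM`. Exactly one valinomycin event, preceding
#'   all KCl events; event times must lie within the trace time span.
#' @param initial_volume_ml Cuvette volume (mL) before any addition.
#' @param id Optional trace identifier used in messages and reports.
#'
#' @return An object of class `fluorescence_trace`: a list with elements
#'   `time`, `fluorescence`, `events`, `initial_volume_ml`, `id`.
#' @export
#' @examples
#' tr <- fluorescence_trace(
#'   time = 0:299, fluorescence = rep(200, 300),
#'   events = data.frame(
#'     time_s = c(60, 120, 180), kind = c("valinomycin", "KCl", "KCl"),
#'     aliquot_volume_ul = c(0, 10, 20),
#'     aliquot_concentration_mM = c(0, 1000, 1000)
#'   ),
#'   initial_volume_ml = 2
#' )
fluorescence_trace <- function(time, fluorescence, events, initial_volume_ml = 2,
                               id = "trace") {
  time <- as.numeric(time)
  fluorescence <- as.numeric(fluorescence)
  if (length(time) != length(fluorescence))
    .stop_empredict("time and fluorescence must have equal length", "empredict_invalid_trace")
  if (length(time) < 2L)
    .stop_empredict("a trace needs at least two samples", "empredict_invalid_trace")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    .stop_empredict("trace times must be finite and strictly increasing", "empredict_invalid_trace")
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0))
    .stop_empredict("fluorescence values must be finite and > 0", "empredict_invalid_trace")
  events <- validate_events(events)
  if (any(events$time_s < min(time)) || any(events$time_s > max(time)))
    .stop_empredict("event times must lie within the trace time span", "empredict_invalid_trace")
  if (!is.numeric(initial_volume_ml) || initial_volume_ml <= 0)
    .stop_empredict("initial_volume_ml must be > 0", "empredict_invalid_trace")
  structure(
    list(time = time, fluorescence = fluorescence, events = events,
         initial_volume_ml = as.numeric(initial_volume_ml), id = as.character(id)),
    class = "fluorescence_trace"
  )
}

validate_events <- function(events) {
  req <- c("time_s", "kind", "aliquot_volume_ul", "aliquot_concentration_mM")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    .stop_empredict(
      paste("events must be a data frame with columns", paste(req, collapse = ", ")),
      "empredict_invalid_events")
  events <- as.data.frame(events)[req]
  events$kind <- as.character(events$kind)
  if (!all(events$kind %in% c("valinomycin", "KCl")))
    .stop_empredict("event kind must be 'valinomycin' or 'KCl'", "empredict_invalid_events")
  if (is.unsorted(events$time_s, strictly = TRUE))
    .stop_empredict("event times must be strictly increasing", "empredict_invalid_events")
  if (sum(events$kind == "valinomycin") != 1L)
    .stop_empredict("exactly one valinomycin event is required", "empredict_invalid_events")
  val_t <- events$time_s[events$kind == "valinomycin"]
  if (any(events$time_s[events$kind == "KCl"] < val_t))
    .stop_empredict("the valinomycin event must precede all KCl events", "empredict_invalid_events")
  if (any(events$aliquot_volume_ul < 0) || any(events$aliquot_concentration_mM < 0))
    .stop_empredict("aliquot volumes and concentrations must be >= 0", "empredict_invalid_events")
  events
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace '%s': %d samples, %.1f-%.1f s, %d events, %.3f mL>\n",
              x$id, length(x$time), min(x$time), max(x$time),
              nrow(x$events), x$initial_volume_ml))
  invisible(x)
}

#' Ionic context of a membrane-potential assay
#'
#' Holds the potassium concentrations and temperature that fix the Nernst
#' potentials used for internal calibration. The default external K+ of
#' 5.0 mM corresponds to a human tubal fluid (HTF)-type medium
#' (4.7 mM KCl + 0.3 mM KH2PO4); intracellular K+ defaults to 120 mM, a
#' standard literature value for human sperm; temperature defaults to 37 C.
#'
#' @param k_out_initial_mM External K+ concentration of the medium (mM).
#' @param k_in_mM Assumed intracellular K+ concentration (mM).
#' @param temperature_K Absolute temperature (kelvin).
#' @return An object of class `ionic_context`.
#' @export
ionic_context <- function(k_out_initial_mM = 5.0, k_in_mM = 120,
                          temperature_K = 310.15) {
  if (!is.numeric(k_out_initial_mM) || k_out_initial_mM <= 0 ||
      !is.numeric(k_in_mM) || k_in_mM <= 0 ||
      !is.numeric(temperature_K) || temperature_K <= 0)
    .stop_empredict("ionic context values must be strictly positive",
                    "empredict_invalid_context")
  if (k_out_initial_mM >= k_in_mM)
    .stop_empredict("k_out_initial_mM must be below k_in_mM at assay start",
                    "empredict_invalid_context")
  structure(
    list(k_out_initial_mM = k_out_initial_mM, k_in_mM = k_in_mM,
         temperature_K = temperature_K),
    class = "ionic_context"
  )
}

#' @export
print.ionic_context <- function(x, ...) {
  cat(sprintf("<ionic_context: [K+]o %.2f mM, [K+]i %.0f mM, %.2f K>\n",
              x$k_out_initial_mM, x$k_in_mM, x$temperature_K))
  invisible(x)
}
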