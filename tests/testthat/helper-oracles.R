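# Independent oracles and small fixture builders shared across tests.

# All-pairs Mann-Whitney concordance with half credit for ties; the
# brute-force reference for trapezoidal ROC AUC. `positive_low = TRUE`
# means smaller scores indicate the positive class.
brute_force_auc <- function(scores, labels, positive_low = TRUE) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p == q) 0.5 else if (positive_low) (p < q) else (p > q)
  }
  tot / (length(pos) * length(neg))
}

# Piecewise-constant step trace: fluorescence holds `levels[i]` from the
# i-th breakpoint (breaks[1] = 0 = recording start) to the next.
step_trace <- function(levels, event_times, event_kinds,
                       aliquot_volume_ul = 10, aliquot_concentration_mM = 1000,
                       duration = max(event_times) + 60, dt = 0.5,
                       initial_volume_ml = 2, noise_sd = 0, seed = NULL) {
  time <- seq(0, duration, by = dt)
  f <- rep(levels[1], length(time))
  for (i in seq_along(event_times)) f[time >= event_times[i]] <- levels[i + 1]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(time), 0, noise_sd)
  }
  ev <- data.frame(
    time_s = event_times, kind = event_kinds,
    aliquot_volume_ul = ifelse(event_kinds == "KCl", aliquot_volume_ul, 0),
    aliquot_concentration_mM = ifelse(event_kinds == "KCl",
                                      aliquot_concentration_mM, 0))
  fluorescence_trace(time, f, ev, initial_volume_ml)
}

# Protocol with a short tau-friendly layout used where speed matters.
fast_protocol <- function(...) {
  default_protocol(interval_s = 40, tail_s = 40, valinomycin_time_s = 30,
                   sample_rate_hz = 5, ...)
}
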