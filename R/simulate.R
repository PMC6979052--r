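#' Dye response model for trace simulation
#'
#' Working model behind the arbitrary-fluorescence-unit traces: an affine
#' steady-state response F = baseline + slope * Em (fluorescence rises as
#' the membrane depolarizes, the behaviour of a quench-mode carbocyanine
#' dye in cell suspension) with first-order equilibration kinetics, additive
#' Gaussian noise and optional linear drift.
#'
#' @param baseline_afu Fluorescence at Em = 0 mV (AFU).
#' @param slope_afu_per_mV Steady-state sensitivity (AFU/mV), nonzero;
#'   positive under the stated sign convention.
#' @param equilibration_tau_s First-order time constant of the dye
#'   response (s), > 0. The default of 2 s reflects the fast
#'   re-equilibration seen in a small stirred cuvette; plateau windows in
#'   the analysis assume responses have settled within the 10 s delay.
#' @param noise_sd_afu SD of additive Gaussian measurement noise (AFU).
#' @param drift_afu_per_s Linear baseline drift (AFU/s).
#' @return An object of class `dye_model`.
#' @export
dye_model <- function(baseline_afu = 500, slope_afu_per_mV = 4,
                      equilibration_tau_s = 2, noise_sd_afu = 0,
                      drift_afu_per_s = 0) {
  if (slope_afu_per_mV == 0)
    .stop_empredict("dye slope must be nonzero", "empredict_invalid_input")
  if (equilibration_tau_s <= 0 || noise_sd_afu < 0)
    .stop_empredict("tau must be > 0 and noise_sd >= 0", "empredict_invalid_input")
  structure(list(baseline_afu = baseline_afu,
                 slope_afu_per_mV = slope_afu_per_mV,
                 equilibration_tau_s = equilibration_tau_s,
                 noise_sd_afu = noise_sd_afu,
                 drift_afu_per_s = drift_afu_per_s),
            class = "dye_model")
}

#' Default calibration protocol
#'
#' A 2.0 mL cuvette of medium with 5.0 mM external K+, valinomycin at 60 s,
#' then four aliquots of 1 M KCl timed 60 s apart and sized (with exact
#' dilution correction) to step external K+ through approximately 10, 20,
#' 40 and 80 mM. Sampling at 5 Hz.
#'
#' @param context An [ionic_context()].
#' @param initial_volume_ml Cuvette volume (mL).
#' @param k_targets_mM Cumulative external K+ targets after each aliquot (mM).
#' @param kcl_stock_mM KCl stock concentration (mM).
#' @param valinomycin_time_s Time of the valinomycin addition (s).
#' @param interval_s Time between additions (s).
#' @param tail_s Recording time after the last addition (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @return List with `events` (event data frame), `context`,
#'   `initial_volume_ml`, `duration_s`, `sample_rate_hz`.
#' @export
default_protocol <- function(context = ionic_context(), initial_volume_ml = 2,
                             k_targets_mM = c(10, 20, 40, 80),
                             kcl_stock_mM = 1000, valinomycin_time_s = 60,
                             interval_s = 60, tail_s = 60, sample_rate_hz = 5) {
  if (any(diff(c(context$k_out_initial_mM, k_targets_mM)) <= 0))
    .stop_empredict("K+ targets must increase from the initial concentration",
                    "empredict_invalid_input")
  if (any(k_targets_mM >= kcl_stock_mM))
    .stop_empredict("K+ targets must stay below the KCl stock concentration",
                    "empredict_invalid_input")
  k <- context$k_out_initial_mM
  v <- initial_volume_ml * 1000  # uL
  vols <- numeric(length(k_targets_mM))
  for (i in seq_along(k_targets_mM)) {
    vols[i] <- v * (k_targets_mM[i] - k) / (kcl_stock_mM - k_targets_mM[i])
    v <- v + vols[i]
    k <- k_targets_mM[i]
  }
  events <- data.frame(
    time_s = valinomycin_time_s + interval_s * (0:length(k_targets_mM)),
    kind = c("valinomycin", rep("KCl", length(k_targets_mM))),
    aliquot_volume_ul = c(0, vols),
    aliquot_concentration_mM = c(0, rep(kcl_stock_mM, length(k_targets_mM)))
  )
  list(events = events, context = context, initial_volume_ml = initial_volume_ml,
       duration_s = max(events$time_s) + tail_s, sample_rate_hz = sample_rate_hz)
}

#' Simulate a DiSC3(5)-style fluorescence trace
#'
#' Forward model of the population assay: the pre-valinomycin segment sits
#' at the steady-state fluorescence of the sample's true Em; at valinomycin
#' the signal relaxes (first order, time constant `tau`) toward the
#' fluorescence of E_K at the current external K+, and each KCl addition
#' relaxes it toward the new E_K. Gaussian noise and linear drift are added
#' on top. Fully reproducible under a fixed seed.
#'
#' @param true_em_mV The sample's membrane potential before valinomycin (mV).
#' @param dye A [dye_model()].
#' @param protocol A protocol list as returned by [default_protocol()].
#' @param seed Integer seed for the noise; `NULL` leaves the RNG state alone.
#' @param id Trace identifier.
#' @return A [fluorescence_trace()]. If any inter-event gap is shorter than
#'   3 tau the trace carries attribute `settled = FALSE` and a warning is
#'   emitted (plateaus may not have settled).
#' @export
simulate_trace <- function(true_em_mV, dye = dye_model(),
                           protocol = default_protocol(), seed = NULL,
                           id = "sim") {
  if (!is.finite(true_em_mV))
    .stop_empredict("true_em_mV must be finite", "empredict_invalid_input")
  events <- validate_events(protocol$events)
  ctx <- protocol$context
  dt <- 1 / protocol$sample_rate_hz
  time <- seq(0, protocol$duration_s, by = dt)

  ktab <- cumulative_potassium(ctx, events, protocol$initial_volume_ml)
  em_targets <- nernst_potential(ktab$k_out_mM, ctx$k_in_mM, ctx$temperature_K)
  f_of <- function(em) dye$baseline_afu + dye$slope_afu_per_mV * em

  gaps <- diff(c(events$time_s, protocol$duration_s))
  settled <- all(gaps >= 3 * dye$equilibration_tau_s)
  if (!settled)
    warning("inter-event spacing below 3 * tau: plateaus may not be settled",
            call. = FALSE)

  f <- rep(f_of(true_em_mV), length(time))
  f_start <- f_of(true_em_mV)
  for (i in seq_len(nrow(events))) {
    t0 <- events$time_s[i]
    target <- f_of(em_targets[i])
    # value reached at the *next* event becomes the next segment's start
    seg <- time >= t0
    f[seg] <- target + (f_start - target) *
      exp(-(time[seg] - t0) / dye$equilibration_tau_s)
    t_next <- if (i < nrow(events)) events$time_s[i + 1] else NULL
    if (!is.null(t_next))
      f_start <- target + (f_start - target) *
        exp(-(t_next - t0) / dye$equilibration_tau_s)
  }
  f <- f + dye$drift_afu_per_s * time
  if (dye$noise_sd_afu > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + stats::rnorm(length(time), 0, dye$noise_sd_afu)
  }
  f <- pmax(f, .Machine$double.eps)
  out <- fluorescence_trace(time, f, events, protocol$initial_volume_ml, id = id)
  attr(out, "settled") <- settled
  attr(out, "true_em_mV") <- true_em_mV
  out
}

#' Cohort specification for synthetic donors
#'
#' Defaults describe a normospermic donor population: resting
#' (non-capacitated) Em of -37.7 +/- 9.9 mV shifting to -57.8 +/- 12.9 mV
#' after capacitation, with 53.6% of samples hyperpolarizing, 32.8%
#' depolarizing and 13.6% unchanged. `group = "non_normospermic"` switches
#' to a depolarizing-majority mixture (27.3 / 63.6 / 9.1%) with no net
#' capacitation shift.
#'
#' @param n_donors Number of donors.
#' @param group `"normospermic"` or `"non_normospermic"`.
#' @param em_nc_mean_mV,em_nc_sd_mV Non-capacitated Em distribution (mV).
#' @param em_cap_mean_mV,em_cap_sd_mV Capacitated Em distribution (mV);
#'   used to derive the class-conditional shift distributions.
#' @param behavior_mixture Named or ordered proportions
#'   (hyperpolarizing, depolarizing, unchanged) summing to 1.
#' @param depol_shift_mean_mV Mean Em shift of the depolarizing class (mV,
#'   positive). Depolarizing excursions are characteristically smaller than
#'   the hyperpolarizing capacitation shift, so the default is half its
#'   magnitude; the asymmetry is what makes the pooled NC-vs-CAP
#'   comparison significant despite the class mixture.
#' @param measurement_noise_sd_mV SD of the Em measurement error (mV).
#' @param threshold_mV Behaviour-class boundary on |delta Em| (mV).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 49, group = c("normospermic", "non_normospermic"),
                        em_nc_mean_mV = -37.7, em_nc_sd_mV = 9.9,
                        em_cap_mean_mV = -57.8, em_cap_sd_mV = 12.9,
                        behavior_mixture = NULL,
                        depol_shift_mean_mV = abs(em_cap_mean_mV - em_nc_mean_mV) / 2,
                        measurement_noise_sd_mV = 2, threshold_mV = 5) {
  group <- match.arg(group)
  if (is.null(behavior_mixture))
    behavior_mixture <- if (group == "normospermic") c(0.536, 0.328, 0.136)
                        else c(0.273, 0.636, 0.091)
  behavior_mixture <- unname(behavior_mixture)
  if (length(behavior_mixture) != 3 || any(behavior_mixture < 0) ||
      abs(sum(behavior_mixture) - 1) > 1e-8)
    .stop_empredict("behavior_mixture must be 3 proportions summing to 1",
                    "empredict_invalid_input")
  if (em_nc_sd_mV < 0 || em_cap_sd_mV < 0 || measurement_noise_sd_mV < 0)
    .stop_empredict("standard deviations must be >= 0", "empredict_invalid_input")
  structure(list(n_donors = as.integer(n_donors), group = group,
                 em_nc_mean_mV = em_nc_mean_mV, em_nc_sd_mV = em_nc_sd_mV,
                 em_cap_mean_mV = em_cap_mean_mV, em_cap_sd_mV = em_cap_sd_mV,
                 behavior_mixture = behavior_mixture,
                 depol_shift_mean_mV = depol_shift_mean_mV,
                 measurement_noise_sd_mV = measurement_noise_sd_mV,
                 threshold_mV = threshold_mV),
            class = "cohort_spec")
}

# Draw from N(mean, sd) truncated to [lo, hi] by inverse-CDF sampling.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a donor cohort
#'
#' The cohort's class composition is fixed to the mixture proportions by
#' largest-remainder rounding — the mixture describes the realized
#' composition of a study cohort, not a superpopulation probability — and
#' donors are assigned to classes in random order. Each donor gets a true
#' non-capacitated Em, and a true capacitated Em obtained by adding a
#' class-conditional shift: hyperpolarizing shifts are normal with mean
#' `em_cap_mean - em_nc_mean` truncated at or below `-threshold`,
#' depolarizing shifts centre on the (smaller) `depol_shift_mean_mV` above
#' `+threshold`, and unchanged shifts are confined to the open interval
#' `(-threshold, threshold)`. Truncation
#' at generation time guarantees the generated label matches the
#' noise-free classification. Measured values add Gaussian measurement
#' error.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `donor_id`, `group`, `behavior_true`,
#'   `em_nc_true_mV`, `em_cap_true_mV`, `em_nc_mV`, `em_cap_mV`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_donors
  classes <- c("hyperpolarizing", "depolarizing", "unchanged")
  # largest-remainder apportionment of the mixture over n donors
  quota <- n * spec$behavior_mixture
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    bump <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  behavior <- sample(rep(classes, counts))

  shift_mean <- spec$em_cap_mean_mV - spec$em_nc_mean_mV
  shift_sd <- sqrt(max(spec$em_cap_sd_mV^2 - spec$em_nc_sd_mV^2, 1)) # independent-shift decomposition
  thr <- spec$threshold_mV

  em_nc <- stats::rnorm(n, spec$em_nc_mean_mV, spec$em_nc_sd_mV)
  shift <- numeric(n)
  for (cl in classes) {
    idx <- which(behavior == cl)
    if (!length(idx)) next
    shift[idx] <- switch(cl,
      hyperpolarizing = rnorm_trunc(length(idx), -abs(shift_mean), shift_sd,
                                    hi = -thr),
      depolarizing = rnorm_trunc(length(idx), spec$depol_shift_mean_mV,
                                 shift_sd, lo = thr),
      unchanged = rnorm_trunc(length(idx), 0, thr / 2,
                              lo = -thr + 1e-6, hi = thr - 1e-6))
  }
  em_cap <- em_nc + shift
  data.frame(
    donor_id = sprintf("D%03d", seq_len(n)), group = spec$group,
    behavior_true = behavior,
    em_nc_true_mV = em_nc, em_cap_true_mV = em_cap,
    em_nc_mV = em_nc + stats::rnorm(n, 0, spec$measurement_noise_sd_mV),
    em_cap_mV = em_cap + stats::rnorm(n, 0, spec$measurement_noise_sd_mV),
    stringsAsFactors = FALSE
  )
}

#' IVF linkage specification
#'
#' Couples capacitated-sperm Em to per-oocyte fertilization probability
#' through a logistic link: logit(p) = intercept + slope * Em_CAP. The
#' default slope (-0.036 per mV) and intercept place a 60% fertilization
#' probability at about -48.6 mV, so that more hyperpolarized capacitated
#' sperm fertilize better, and yield cohort-level discrimination (ROC AUC)
#' around 0.86 at the default cohort's Em dispersion.
#'
#' @param intercept,slope Logistic-link coefficients (slope per mV).
#' @param oocytes_min,oocytes_max Range of the discrete-uniform oocyte
#'   count per patient.
#' @param success_threshold Fertilization-rate threshold for a successful
#'   IVF procedure (fraction, default 0.60, inclusive).
#' @return An object of class `ivf_link_spec`.
#' @export
ivf_link_spec <- function(intercept = -1.344, slope = -0.036,
                          oocytes_min = 4, oocytes_max = 12,
                          success_threshold = 0.60) {
  if (success_threshold <= 0 || success_threshold >= 1)
    .stop_empredict("success_threshold must be in (0,1)", "empredict_invalid_input")
  if (oocytes_min < 1 || oocytes_max < oocytes_min)
    .stop_empredict("invalid oocyte count range", "empredict_invalid_input")
  structure(list(intercept = intercept, slope = slope,
                 oocytes_min = as.integer(oocytes_min),
                 oocytes_max = as.integer(oocytes_max),
                 success_threshold = success_threshold),
            class = "ivf_link_spec")
}

#' Simulate IVF outcomes for a set of patients
#'
#' For each capacitated-sperm Em, draws an oocyte count (discrete uniform),
#' a fertilized count from Binomial(oocytes, logistic(intercept + slope *
#' Em_CAP)), and labels the procedure successful when the fertilization
#' rate reaches the threshold.
#'
#' @param spec An [ivf_link_spec()].
#' @param em_cap_mV Vector of capacitated-sperm Em values (mV).
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `em_cap_mV`, `oocytes`,
#'   `fertilized_2pn`, `fertilization_rate`, `successful`.
#' @export
simulate_ivf_cohort <- function(spec = ivf_link_spec(), em_cap_mV, seed = 1) {
  stopifnot(inherits(spec, "ivf_link_spec"))
  set.seed(seed)
  n <- length(em_cap_mV)
  p <- stats::plogis(spec$intercept + spec$slope * em_cap_mV)
  oocytes <- sample(spec$oocytes_min:spec$oocytes_max, n, replace = TRUE)
  fert <- stats::rbinom(n, oocytes, p)
  rate <- fert / oocytes
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    em_cap_mV = em_cap_mV, oocytes = oocytes, fertilized_2pn = fert,
    fertilization_rate = rate,
    successful = rate >= spec$success_threshold,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-sperm CASA kinematics
#'
#' Two-component mixture per sample: a hyperactivation-enriched component
#' (high curvilinear velocity, wide lateral head displacement, low
#' linearity) and a progressive component. The hyperactivated weight is
#' coupled to the sample's Em through a logistic link so that
#' hyperpolarized samples show more hyperactivation; a fixed weight can be
#' supplied instead.
#'
#' @param n_sperm Sperm tracked per sample (>= 200, the CASA design
#'   minimum).
#' @param em_mV Sample Em used by the coupling (ignored when `ha_weight`
#'   is given).
#' @param ha_weight Optional fixed hyperactivated fraction in `[0,1]`.
#' @param ha_link Coefficients `c(intercept, slope)` of
#'   `plogis(intercept + slope * Em)` for the hyperactivated weight.
#' @param seed Integer seed.
#' @return Data frame with columns `VCL`, `VSL`, `VAP` (um/s), `LIN`,
#'   `STR` (%), `ALH` (um) and the latent `component`.
#' @export
simulate_casa <- function(n_sperm = 200, em_mV = -40, ha_weight = NULL,
                          ha_link = c(-4.5, -0.045), seed = 1) {
  if (n_sperm < 200)
    .stop_empredict("n_sperm must be >= 200 (CASA design minimum)",
                    "empredict_invalid_input")
  set.seed(seed)
  w <- if (is.null(ha_weight)) stats::plogis(ha_link[1] + ha_link[2] * em_mV)
       else ha_weight
  if (w < 0 || w > 1)
    .stop_empredict("hyperactivated weight must be in [0,1]", "empredict_invalid_input")
  comp <- ifelse(stats::runif(n_sperm) < w, "hyperactivated", "progressive")
  n_ha <- sum(comp == "hyperactivated")
  n_pr <- n_sperm - n_ha
  draw <- function(n, mean, sd, lo = 0, hi = Inf) rnorm_trunc(n, mean, sd, lo, hi)
  out <- data.frame(component = comp, VCL = NA_real_, VSL = NA_real_,
                    VAP = NA_real_, LIN = NA_real_, STR = NA_real_,
                    ALH = NA_real_, stringsAsFactors = FALSE)
  if (n_ha) {
    i <- comp == "hyperactivated"
    out$VCL[i] <- draw(n_ha, 185, 20, lo = 150)
    out$LIN[i] <- draw(n_ha, 35, 7, lo = 0, hi = 49.9)
    out$ALH[i] <- draw(n_ha, 6.5, 1, lo = 5)
    out$VSL[i] <- out$VCL[i] * out$LIN[i] / 100
    out$STR[i] <- draw(n_ha, 55, 10, lo = 0, hi = 100)
  }
  if (n_pr) {
    i <- comp == "progressive"
    out$VCL[i] <- draw(n_pr, 105, 30, lo = 0)
    out$LIN[i] <- draw(n_pr, 65, 12, lo = 0, hi = 100)
    out$ALH[i] <- draw(n_pr, 3, 1, lo = 0)
    out$VSL[i] <- out$VCL[i] * out$LIN[i] / 100
    out$STR[i] <- draw(n_pr, 80, 8, lo = 0, hi = 100)
  }
  out$VAP <- (out$VCL + out$VSL) / 2
  out
}

#' Simulate acrosome-reaction counts
#'
#' Binomial counts of acrosome-reacted sperm in the spontaneous and
#' progesterone-stimulated arms of one sample.
#'
#' @param n Sperm scored per arm (design minimum 200).
#' @param p_spont True spontaneous AR probability.
#' @param p_induced True AR probability under progesterone.
#' @param seed Integer seed.
#' @return Data frame with rows `spontaneous` and `progesterone`:
#'   `arm`, `reacted`, `total`, `percent`.
#' @export
simulate_ar <- function(n = 200, p_spont = 0.08, p_induced = 0.2, seed = 1) {
  if (any(c(p_spont, p_induced) < 0) || any(c(p_spont, p_induced) > 1))
    .stop_empredict("AR probabilities must be in [0,1]", "empredict_invalid_input")
  set.seed(seed)
  reacted <- stats::rbinom(2, n, c(p_spont, p_induced))
  data.frame(arm = c("spontaneous", "progesterone"),
             reacted = reacted, total = n, percent = 100 * reacted / n,
             stringsAsFactors = FALSE)
}
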