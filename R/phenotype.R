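#' Classify capacitation-associated Em behaviour
#'
#' The Em change on capacitation, delta = Em_CAP - Em_NC, partitions
#' samples into three classes: changes smaller than the threshold in
#' absolute value are `unchanged`; otherwise a negative change is
#' `hyperpolarizing` and a positive change `depolarizing`. The unchanged
#' band is the open interval (-threshold, threshold): a change of exactly
#' +/- 5 mV is assigned to its signed class.
#'
#' @param em_nc_mV Non-capacitated Em (mV); vectorized.
#' @param em_cap_mV Capacitated Em (mV); vectorized.
#' @param threshold_mV Band half-width (mV), > 0. Default 5.
#' @return Factor with levels `hyperpolarizing`, `depolarizing`,
#'   `unchanged`.
#' @export
#' @examples
#' classify_behavior(-37.7, -57.8)    # hyperpolarizing
#' classify_behavior(-40, -37)        # unchanged (|delta| < 5)
classify_behavior <- function(em_nc_mV, em_cap_mV, threshold_mV = 5) {
  if (threshold_mV <= 0)
    .stop_empredict("threshold must be > 0", "empredict_invalid_input")
  if (any(!is.finite(em_nc_mV)) || any(!is.finite(em_cap_mV)))
    .stop_empredict("Em values must be finite", "empredict_invalid_input")
  delta <- em_cap_mV - em_nc_mV
  cls <- ifelse(abs(delta) < threshold_mV, "unchanged",
                ifelse(delta <= -threshold_mV, "hyperpolarizing", "depolarizing"))
  factor(cls, levels = c("hyperpolarizing", "depolarizing", "unchanged"))
}

#' Hyperactivated-motility classification
#'
#' A sperm is hyperactivated when all three CASA criteria hold:
#' VCL >= 150 um/s, LIN < 50% and ALH >= 5 um (velocity and displacement
#' thresholds inclusive, linearity strict, exactly as defined).
#'
#' @param kinematics Data frame with numeric columns `VCL`, `LIN`, `ALH`
#'   (additional columns such as `VSL`, `VAP`, `STR` are ignored).
#' @param vcl_min VCL threshold (um/s).
#' @param lin_max LIN threshold (%), exclusive.
#' @param alh_min ALH threshold (um).
#' @return Logical vector, one element per row.
#' @export
classify_hyperactivated <- function(kinematics, vcl_min = 150, lin_max = 50,
                                    alh_min = 5) {
  req <- c("VCL", "LIN", "ALH")
  miss <- setdiff(req, names(kinematics))
  if (length(miss))
    .stop_empredict(paste("missing kinematic field(s):", paste(miss, collapse = ", ")),
                    "empredict_invalid_record")
  bad <- !stats::complete.cases(kinematics[req])
  if (any(bad))
    .stop_empredict(sprintf("missing kinematic values in %d record(s)", sum(bad)),
                    "empredict_invalid_record")
  if (any(kinematics$VCL < 0) || any(kinematics$LIN < 0 | kinematics$LIN > 100))
    .stop_empredict("VCL must be >= 0 and LIN within [0,100]", "empredict_invalid_record")
  kinematics$VCL >= vcl_min & kinematics$LIN < lin_max & kinematics$ALH >= alh_min
}

#' Percentage of hyperactivated sperm in a sample
#'
#' @inheritParams classify_hyperactivated
#' @return Percentage in `[0, 100]`.
#' @export
hyperactivation_rate <- function(kinematics, vcl_min = 150, lin_max = 50,
                                 alh_min = 5) {
  ha <- classify_hyperactivated(kinematics, vcl_min, lin_max, alh_min)
  100 * sum(ha) / length(ha)
}

#' Progesterone-induced acrosome reaction
#'
#' Induced AR is the progesterone-stimulated AR percentage minus the
#' spontaneous percentage of the same sample (percentage points; may be
#' negative). Arms scored on fewer sperm than the design minimum trigger a
#' low-count warning but are not excluded.
#'
#' @param pg_reacted,pg_total Counts in the progesterone arm.
#' @param spont_reacted,spont_total Counts in the spontaneous arm.
#' @param min_count Minimum sperm per arm before a low-count warning
#'   (default 200).
#' @return Induced AR in percentage points.
#' @export
#' @examples
#' induced_ar(50, 200, 20, 200)   # 15
induced_ar <- function(pg_reacted, pg_total, spont_reacted, spont_total,
                       min_count = 200) {
  if (any(c(pg_reacted, pg_total, spont_reacted, spont_total) < 0) ||
      any(pg_reacted > pg_total) || any(spont_reacted > spont_total))
    .stop_empredict("reacted counts must lie in [0, total]", "empredict_invalid_input")
  if (any(c(pg_total, spont_total) < min_count))
    warning(sprintf("fewer than %d sperm scored in at least one arm", min_count),
            call. = FALSE)
  100 * pg_reacted / pg_total - 100 * spont_reacted / spont_total
}

#' IVF success classification
#'
#' An IVF procedure is successful when at least the threshold fraction of
#' inseminated oocytes show two pronuclei (inclusive at the threshold).
#'
#' @param fertilized_2pn Number of 2PN-fertilized oocytes; vectorized.
#' @param oocytes Number of oocytes inseminated.
#' @param threshold Success threshold on the fertilization rate
#'   (fraction, default 0.60).
#' @return Logical vector.
#' @export
#' @examples
#' ivf_success(6, 10)    # TRUE: rate of exactly 0.60 counts as success
ivf_success <- function(fertilized_2pn, oocytes, threshold = 0.60) {
  if (any(oocytes < 1) || any(fertilized_2pn < 0) || any(fertilized_2pn > oocytes))
    .stop_empredict("need 0 <= fertilized_2pn <= oocytes and oocytes >= 1",
                    "empredict_invalid_input")
  fertilized_2pn / oocytes >= threshold
}
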