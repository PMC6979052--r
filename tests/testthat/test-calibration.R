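ctx <- ionic_context()

test_that("plateau detection recovers constant segment levels exactly", {
  tr <- step_trace(levels = c(100, 80, 90, 95),
                   event_times = c(60, 120, 180),
                   event_kinds = c("valinomycin", "KCl", "KCl"))
  pl <- detect_plateaus(tr, window = 20, settle_delay = 10)
  expect_equal(pl$event, c("initial", "valinomycin", "KCl", "KCl"))
  expect_equal(pl$plateau_afu, c(100, 80, 90, 95))
  expect_equal(pl$plateau_sd_afu, rep(0, 4))
})

test_that("noisy plateau means stay within the standard error of the mean", {
  # window of 20 s at 0.4 s sampling = 51 samples; sd 1 AFU
  tr <- step_trace(levels = c(100, 80, 90, 95),
                   event_times = c(60, 120, 180),
                   event_kinds = c("valinomycin", "KCl", "KCl"),
                   dt = 0.4, noise_sd = 1, seed = 21)
  pl <- detect_plateaus(tr, window = 20, settle_delay = 10)
  expect_true(all(abs(pl$plateau_afu - c(100, 80, 90, 95)) < 3 / sqrt(50)))
  expect_true(all(pl$n_samples >= 50))
})

test_that("events too close to the trace end raise a window error", {
  tr <- step_trace(levels = c(100, 80, 90), event_times = c(60, 120),
                   event_kinds = c("valinomycin", "KCl"), duration = 140)
  expect_error(detect_plateaus(tr, window = 20, settle_delay = 10),
               class = "empredict_window_too_short")
})

test_that("calibration fit recovers a known line exactly", {
  ev <- default_protocol()$events
  ktab <- cumulative_potassium(ctx, ev, 2)
  em <- nernst_potential(ktab$k_out_mM, ctx$k_in_mM, ctx$temperature_K)
  pl <- data.frame(event = c("initial", ktab$kind),
                   time_s = c(0, ktab$time_s),
                   plateau_afu = c(200 + 1.5 * -50, 200 + 1.5 * em),
                   plateau_sd_afu = 0, n_samples = 100)
  curve <- build_calibration(pl, ctx, ev, 2)
  expect_equal(curve$slope, 1.5)
  expect_equal(curve$intercept, 200)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$points$theoretical_em_mV, em)

  # exactly two points determine the line: drop the valinomycin anchor and
  # keep two KCl steps
  ev2 <- ev[1:3, ]
  pl2 <- pl[1:4, ]
  curve2 <- build_calibration(pl2, ctx, ev2, 2,
                              include_valinomycin_point = FALSE)
  expect_equal(nrow(curve2$points), 2)
  expect_equal(curve2$r_squared, 1)
  expect_equal(curve2$slope, 1.5)

  # a perturbed point gives r^2 < 1 with residuals matching closed-form OLS
  pl3 <- pl
  pl3$plateau_afu[3] <- pl3$plateau_afu[3] + 5
  curve3 <- build_calibration(pl3, ctx, ev, 2)
  expect_lt(curve3$r_squared, 1)
  x <- curve3$points$theoretical_em_mV
  y <- pl3$plateau_afu[-1]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(curve3$slope, b)
  expect_equal(curve3$intercept, a)
})

test_that("degenerate calibrations are rejected", {
  ev1 <- data.frame(time_s = 60, kind = "valinomycin",
                    aliquot_volume_ul = 0, aliquot_concentration_mM = 0)
  tr <- step_trace(levels = c(100, 80), event_times = 60,
                   event_kinds = "valinomycin")
  pl <- detect_plateaus(tr)
  expect_error(build_calibration(pl, ctx, ev1, 2),
               class = "empredict_insufficient_calibration")
})

test_that("em estimation inverts the calibration line", {
  ev <- default_protocol()$events
  ktab <- cumulative_potassium(ctx, ev, 2)
  em <- nernst_potential(ktab$k_out_mM, ctx$k_in_mM, ctx$temperature_K)
  pl <- data.frame(event = c("initial", ktab$kind), time_s = c(0, ktab$time_s),
                   plateau_afu = c(0, 300 + 2 * em), plateau_sd_afu = 0,
                   n_samples = 100)
  curve <- build_calibration(pl, ctx, ev, 2)

  # a calibration plateau's fluorescence maps back to its own potential
  m <- estimate_em(curve$points$plateau_afu[2], curve)
  expect_equal(m$em_mV, curve$points$theoretical_em_mV[2])
  expect_false(m$extrapolated)

  # midpoint fluorescence of an exactly linear curve -> mean potential
  mid_f <- mean(curve$points$plateau_afu[2:3])
  m2 <- estimate_em(mid_f, curve)
  expect_equal(m2$em_mV, mean(curve$points$theoretical_em_mV[2:3]))

  # piecewise inversion agrees on an exactly linear calibration
  m3 <- estimate_em(mid_f, curve, method = "piecewise")
  expect_equal(m3$em_mV, m2$em_mV)

  # outside the plateau span the estimate is flagged, not refused
  lo <- min(curve$points$plateau_afu)
  m4 <- estimate_em(lo - 10, curve)
  expect_true(m4$extrapolated)

  flat <- curve; flat$slope <- 0
  expect_error(estimate_em(100, flat), class = "empredict_flat_calibration")
})

test_that("noise-free traces round-trip to the true Em within 0.1 mV", {
  proto <- fast_protocol()
  for (true_em in c(-90, -60, -35)) {
    for (slope in c(2, -3, 0.5)) {
      dye <- dye_model(baseline_afu = 600, slope_afu_per_mV = slope,
                       equilibration_tau_s = 0.2)
      tr <- simulate_trace(true_em, dye, proto)
      m <- process_trace(tr, ctx)
      expect_lt(abs(m$em_mV - true_em), 0.1)
      expect_gt(m$curve_r_squared, 0.9999)
    }
  }
})

test_that("em estimates are invariant to affine rescaling of fluorescence", {
  # gain/offset changes in AFU must not change the mV answer: the internal
  # calibration compensates instrument- and loading-dependent scaling
  proto <- fast_protocol()
  tr <- simulate_trace(-57.8, dye_model(equilibration_tau_s = 0.2), proto)
  m0 <- process_trace(tr, ctx)
  for (gain in c(0.25, 3)) {
    tr2 <- tr
    tr2$fluorescence <- gain * tr$fluorescence + 37
    m <- process_trace(tr2, ctx)
    expect_equal(m$em_mV, m0$em_mV, tolerance = 1e-9)
  }
})

test_that("process_trace propagates errors and preserves batch order", {
  proto <- fast_protocol()
  # no KCl events -> insufficient calibration
  ev <- proto$events[proto$events$kind == "valinomycin", ]
  p1 <- proto; p1$events <- ev
  tr <- simulate_trace(-50, dye_model(equilibration_tau_s = 0.2), p1)
  expect_error(process_trace(tr, ctx),
               class = "empredict_insufficient_calibration")

  ems <- c(-70, -50, -30)
  traces <- lapply(seq_along(ems), function(i)
    simulate_trace(ems[i], dye_model(equilibration_tau_s = 0.2), proto,
                   id = paste0("tr", i)))
  res <- process_traces(traces, ctx, conditions = c("NC0", "NC_t", "CAP_t"))
  expect_equal(res$trace_id, c("tr1", "tr2", "tr3"))
  expect_equal(res$em_mV, ems, tolerance = 0.1 / 70)
  expect_equal(res$condition, c("NC0", "NC_t", "CAP_t"))
})
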