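test_that("trace simulation is a staircase of Nernst levels in the fast-dye limit", {
  proto <- fast_protocol()
  dye <- dye_model(baseline_afu = 500, slope_afu_per_mV = 4,
                   equilibration_tau_s = 1e-4)
  tr <- simulate_trace(-50, dye, proto)
  ctx <- proto$context
  ktab <- cumulative_potassium(ctx, proto$events, proto$initial_volume_ml)
  em_levels <- nernst_potential(ktab$k_out_mM, ctx$k_in_mM, ctx$temperature_K)
  f_expected <- 500 + 4 * em_levels
  # sample each plateau 5 s before the following addition
  probe_t <- c(proto$events$time_s[-1], proto$duration_s) - 5
  f_at <- approx(tr$time, tr$fluorescence, xout = probe_t)$y
  expect_equal(f_at, f_expected, tolerance = 1e-6)
  # pre-valinomycin segment sits at the sample's own potential
  expect_equal(tr$fluorescence[1], 500 + 4 * -50)
})

test_that("a sample already at E_K shows no valinomycin jump", {
  proto <- fast_protocol()
  ctx <- proto$context
  ek <- nernst_potential(ctx$k_out_initial_mM, ctx$k_in_mM, ctx$temperature_K)
  tr <- simulate_trace(ek, dye_model(equilibration_tau_s = 2), proto)
  val_t <- proto$events$time_s[1]
  before <- tr$fluorescence[max(which(tr$time < val_t))]
  after <- tr$fluorescence[min(which(tr$time > val_t + 10))]
  expect_equal(before, after, tolerance = 1e-9)
})

test_that("trace simulation is reproducible under a fixed seed and warns on crowded protocols", {
  dye <- dye_model(noise_sd_afu = 5)
  t1 <- simulate_trace(-50, dye, fast_protocol(), seed = 42)
  t2 <- simulate_trace(-50, dye, fast_protocol(), seed = 42)
  expect_identical(t1$fluorescence, t2$fluorescence)
  t3 <- simulate_trace(-50, dye, fast_protocol(), seed = 43)
  expect_false(identical(t1$fluorescence, t3$fluorescence))

  slow <- dye_model(equilibration_tau_s = 20)
  expect_warning(simulate_trace(-50, slow, fast_protocol()), "settled")
})

test_that("cohort generation matches its spec and is seed-stable", {
  co <- simulate_cohort(cohort_spec(n_donors = 500), seed = 7)
  expect_identical(co, simulate_cohort(cohort_spec(n_donors = 500), seed = 7))
  expect_equal(nrow(co), 500)
  # noise-free classification agrees with the generated label by construction
  cls <- classify_behavior(co$em_nc_true_mV, co$em_cap_true_mV)
  expect_equal(as.character(cls), co$behavior_true)
  # sample moments converge on the specified values at 1/sqrt(n) rate
  expect_equal(mean(co$em_nc_true_mV), -37.7, tolerance = 3 * 9.9 / sqrt(500) / 37.7)
  # forced single-class mixture
  co_h <- simulate_cohort(cohort_spec(n_donors = 50,
                                      behavior_mixture = c(1, 0, 0)), seed = 1)
  expect_true(all(co_h$behavior_true == "hyperpolarizing"))
  expect_true(all(co_h$em_cap_true_mV - co_h$em_nc_true_mV <= -5))
})

test_that("IVF cohort simulation follows the logistic link", {
  # null link: fertilization is independent of Em, AUC ~ 0.5
  em <- rnorm(2000, -48, 13)
  null_spec <- ivf_link_spec(intercept = qlogis(0.5), slope = 0)
  ivf0 <- simulate_ivf_cohort(null_spec, em, seed = 5)
  r0 <- roc_analysis(ivf0$em_cap_mV, ivf0$successful)
  expect_lt(abs(r0$auc - 0.5), 0.05)

  # strongly separated groups with a steep link: near-perfect discrimination
  em2 <- c(rnorm(300, -75, 3), rnorm(300, -25, 3))
  steep <- ivf_link_spec(intercept = -24.3, slope = -0.5)
  ivf2 <- simulate_ivf_cohort(steep, em2, seed = 5)
  r2 <- roc_analysis(ivf2$em_cap_mV, ivf2$successful)
  expect_gt(r2$auc, 0.99)

  # determinism and bookkeeping
  expect_identical(ivf2, simulate_ivf_cohort(steep, em2, seed = 5))
  expect_true(all(ivf2$fertilized_2pn <= ivf2$oocytes))
  expect_equal(ivf2$successful, ivf2$fertilization_rate >= 0.6)
})

test_that("CASA and AR generators respect their constraints", {
  k <- simulate_casa(n_sperm = 400, em_mV = -58, seed = 3)
  expect_equal(nrow(k), 400)
  expect_true(all(k$VCL >= 0 & k$VSL >= 0 & k$VAP >= 0))
  expect_true(all(k$LIN >= 0 & k$LIN <= 100 & k$STR >= 0 & k$STR <= 100))
  # hyperpolarized samples enrich the hyperactivated component
  k_nc <- simulate_casa(n_sperm = 2000, em_mV = -35, seed = 4)
  k_cap <- simulate_casa(n_sperm = 2000, em_mV = -58, seed = 4)
  expect_gt(hyperactivation_rate(k_cap), hyperactivation_rate(k_nc))
  # all-slow sample: nothing passes the VCL gate
  k_slow <- simulate_casa(n_sperm = 300, ha_weight = 0, seed = 5)
  k_slow$VCL <- pmin(k_slow$VCL, 149)
  expect_equal(hyperactivation_rate(k_slow), 0)
  expect_error(simulate_casa(n_sperm = 50), class = "empredict_invalid_input")

  ar <- simulate_ar(n = 200, p_spont = 0.1, p_induced = 0.25, seed = 6)
  expect_equal(ar$arm, c("spontaneous", "progesterone"))
  expect_true(all(ar$reacted <= ar$total))
  expect_equal(ar$percent, 100 * ar$reacted / ar$total)
  # equal probabilities: induced AR fluctuates around zero
  reps <- vapply(1:200, function(s) {
    a <- simulate_ar(n = 200, p_spont = 0.15, p_induced = 0.15, seed = s)
    induced_ar(a$reacted[2], a$total[2], a$reacted[1], a$total[1])
  }, numeric(1))
  expect_lt(abs(mean(reps)), 1)
  # law of large numbers: a 15-point true difference is recovered
  big <- simulate_ar(n = 2e5, p_spont = 0.10, p_induced = 0.25, seed = 8)
  expect_equal(induced_ar(big$reacted[2], big$total[2],
                          big$reacted[1], big$total[1]),
               15, tolerance = 3 * 100 * sqrt(2 * 0.25 * 0.75 / 2e5) / 15)
})
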