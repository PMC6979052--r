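---
title: "Methods: membrane-potential calibration, phenotyping and IVF prediction"
author: "empredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-potential calibration, phenotyping and IVF prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empredict)
```

# The measurement model

A suspension of sperm loaded with the slow carbocyanine dye DiSC3(5) emits
fluorescence that tracks the population-average plasma-membrane potential
(Em). The assay's central assumption, and this package's, is that over the
physiological range the steady-state suspension fluorescence is an
*affine* function of Em,

$$F = a + b \cdot E_m \quad \text{(AFU)},$$

with instrument- and sample-specific gain and offset. Neither $a$ nor $b$
is knowable in advance — dye loading, cell concentration and detector
settings all move them — which is why every trace carries its own internal
calibration:

1. **Valinomycin.** The K+-selective ionophore makes the membrane
   K+-permeable, clamping Em to the potassium equilibrium (Nernst)
   potential $E_K = (RT/F)\ln([K^+]_o/[K^+]_i)$. With
   $[K^+]_o = 5$ mM, $[K^+]_i = 120$ mM and $T = 310.15$ K this is
   $\approx -84.9$ mV ([`nernst_potential()`]). CODATA values of $R$ and
   $F$ are used.
2. **Sequential KCl aliquots** step $[K^+]_o$ upward; each new plateau sits
   at the new $E_K$. Concentrations are tracked with exact dilution mass
   balance ([`cumulative_potassium()`]); the default protocol (2.0 mL
   cuvette, four aliquots of 1 M KCl sized to reach ~10, 20, 40, 80 mM)
   spans roughly $-85$ to $-11$ mV.
3. **Calibration fit.** Plateau fluorescences are regressed on their
   theoretical potentials by ordinary least squares
   ([`build_calibration()`]); the valinomycin plateau itself is used as
   the most hyperpolarized calibration point (toggleable with
   `include_valinomycin_point`).
4. **Inversion.** The resting, pre-valinomycin fluorescence is mapped to
   mV by inverting the fitted line ([`estimate_em()`]). Because the fit is
   per-trace, any affine transformation of the fluorescence channel cancels
   exactly — a property the test suite asserts.

## Assumptions and their limits

- *Affinity of the dye response.* Real DiSC3(5) responses saturate at
  extreme potentials and are perturbed by dye aggregation and
  mitochondrial uptake; within the −90 to −20 mV working range the affine
  model is the standard operating assumption, and the calibration procedure
  itself is only meaningful under it.
- *Valinomycin clamps Em to $E_K$ exactly.* True to the extent that K+
  conductance dominates after ionophore addition; residual conductances
  bias the anchor point.
- *$[K^+]_i = 120$ mM is configuration, not measurement.* The assumed
  intracellular potassium shifts every calibration potential by a common
  logarithmic term; an error of ±20 mM moves estimates by roughly 4 mV.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k_out_initial_mM` | 5.0 | mM | K+ content of an HTF-type medium (4.7 KCl + 0.3 KH2PO4) |
| `k_in_mM` | 120 | mM | standard literature value for human sperm |
| `temperature_K` | 310.15 | K | 37 °C stirred cuvette |
| `window_s` | 20 | s | plateau averaging window |
| `settle_delay_s` | 10 | s | dead time after each addition before averaging |
| `equilibration_tau_s` (generator) | 2 | s | dye re-equilibration in a small stirred cuvette; settled well within the 10 s delay |
| `behavior_threshold_mV` | 5 | mV | half-width of the "unchanged" ΔEm band |
| HA criteria | 150 / 50 / 5 | µm/s, %, µm | VCL ≥, LIN <, ALH ≥ — conjunction |
| `ivf_success_threshold` | 0.60 | fraction | ≥ 60% of oocytes 2PN-fertilized, inclusive |

Two genuinely open choices are exposed as modes rather than fixed:

- **Fit orientation and inversion.** The default regresses fluorescence on
  potential and inverts the global line (`method = "ols"`), which uses all
  calibration points and is robust to single-plateau noise;
  `method = "piecewise"` linearly interpolates between the bracketing
  plateaus instead, which follows local curvature but inherits the noise
  of the two nearest points. Both agree exactly when the response is truly
  affine.
- **Valinomycin anchor.** Included by default because it is the only
  calibration point on the hyperpolarized side of most resting potentials;
  excluding it (`include_valinomycin_point = FALSE`) restricts the fit to
  KCl steps when ionophore clamping is in doubt.

Estimates whose resting fluorescence falls outside the calibrated plateau
span are returned with `extrapolated = TRUE`, never silently accepted or
rejected. A ΔEm of exactly ±5 mV is assigned to the signed class — the
unchanged band is the open interval $(-5, 5)$ mV; this boundary convention
is a documented package choice.

# The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth. It emulates:

- **Traces** (`simulate_trace()`): affine steady-state response,
  first-order relaxation with time constant τ after each addition,
  additive Gaussian noise, optional linear drift. In the fast-dye limit the
  trace is an exact staircase of Nernst levels.
- **Donor cohorts** (`simulate_cohort()`): resting Em drawn from
  $\mathcal{N}(-37.7,\,9.9^2)$ mV. The class composition
  (53.6% hyperpolarizing / 32.8% depolarizing / 13.6% unchanged for a
  normospermic cohort) is treated as the *realized composition* of a study
  cohort and fixed by largest-remainder apportionment, with donors
  assigned to classes in random order; a multinomial redraw would let a
  49-donor cohort lose its hyperpolarizing majority by sampling noise.
  Capacitated Em adds a class-conditional shift: hyperpolarizing shifts
  are $\mathcal{N}(-20.1,\,8.3^2)$ truncated at $-5$ mV (so the
  hyperpolarizing pool reproduces the $-37.7 \to -57.8$ mV group
  statistics, with the shift taken independent of the resting level:
  $\sqrt{12.9^2-9.9^2}\approx 8.3$); depolarizing shifts centre on
  $+10$ mV above $+5$ — characteristically smaller than the
  hyperpolarizing excursion, which is what leaves the pooled NC-vs-CAP
  comparison significantly hyperpolarized despite the mixture; unchanged
  shifts stay inside the band. Truncation at generation time guarantees
  label/classification agreement on noise-free values. Measurement error
  defaults to 2 mV — a stated assumption, since within-donor repeat
  variance is not otherwise constrained.
- **IVF outcomes** (`simulate_ivf_cohort()`): fertilized counts are
  $\mathrm{Binomial}(\text{oocytes},\ \mathrm{logit}^{-1}(\beta_0 + \beta_1
  E_{m,\mathrm{CAP}}))$ with oocytes discrete-uniform on 4–12. The default
  link ($\beta_1 = -0.036$ per mV, $\beta_0$ placing $p = 0.60$ at
  $-48.6$ mV) was calibrated once, at $n = 20{,}000$, so that the
  population-level ROC AUC of Em_CAP against the ≥ 60% success label is
  ≈ 0.855 — the discrimination strength the method is expected to show —
  and is fully overridable.
- **CASA kinematics and AR counts**: a two-component kinematic mixture
  whose hyperactivated weight is logistically coupled to Em, and binomial
  acrosome-reaction counts per arm.

What the generator does **not** emulate: dye saturation and photobleaching
beyond linear drift, non-affine dye responses, within-trace Em drift
(capacitation during the recording), correlated oocyte outcomes within a
patient, or CASA tracking artefacts. Passing tests therefore demonstrate
the *analysis* is correct under the stated measurement model, not that the
model captures every behaviour of bench data.

# Statistical layer

- Paired and unpaired Student's t tests and Pearson correlation wrap the
  standard R implementations; degenerate inputs (zero-variance
  differences) return the documented conventions ($t=0, p=1$ for identical
  samples; $p=0$ with a flag for an exactly constant nonzero shift)
  instead of erroring.
- The ROC ([`roc_analysis()`]) is empirical: thresholds midway between
  distinct scores, trapezoidal AUC computed over integer true/false
  positive counts so it equals all-pairs Mann–Whitney concordance (ties
  counted ½) *bit-exactly*; standard error by the Hanley–McNeil (1982)
  formula — the exact estimator behind published "AUC ± SE" values is
  rarely stated, so this choice is documented and swappable; 95% CI as
  $\mathrm{AUC} \pm 1.96\,\mathrm{SE}$ clipped to $[0,1]$ (published
  intervals with an upper bound of exactly 1 arise from this clipping);
  cutoff by Youden's $J$ with ties broken toward higher sensitivity.
  Orientation defaults to lower-score-positive: more negative capacitated
  Em predicts IVF success.
- No multiple-testing correction is applied; raw two-sided p-values are
  reported.

# Numerical and testing choices

Problem sizes were chosen so the whole suite runs in seconds: noise-free
calibration recovery is checked on an 8 × 5 grid of true potentials and
dye models (tolerance 0.1 mV); noisy recovery on 200 Monte-Carlo traces at
noise of 2% of each trace's dynamic range (mean absolute error < 2 mV,
bias interval covering 0); AUC/oracle equality on 1,000 random instances
with $n \le 20$; the end-to-end cohort at $n = 49$ with every donor
measured through simulated traces; mixture recovery at $n = 10^4$.
Deliberately independent oracles back the main claims: hand-evaluated
closed forms for the Nernst equation and mass balance, closed-form OLS for
the calibration fit, brute-force pair counting for the AUC, and `pROC` as
an external cross-check of the ROC implementation.

# Known limitations

- Absolute Em accuracy is bounded by the assumed $[K^+]_i$ and by
  valinomycin's clamp quality; the package reports precision (fit $r^2$,
  plateau SDs, extrapolation flags), not these systematic terms.
- The Hanley–McNeil SE is an approximation; for small cohorts a DeLong or
  bootstrap interval would differ, and neither is implemented.
- The synthetic IVF link is a modelling device for testing discrimination
  machinery, not an estimate of any clinical dose-response.
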