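---
title: "Navigator-guided chemical-shift and concentration prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigator-guided chemical-shift and concentration prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In urine ¹H NMR the chemical shift of a metabolite signal is not a constant:
it depends on the whole chemical matrix — pH, ionic composition, temperature
and the concentrations of interacting solutes — and in urine this variability
is large enough to make automated signal assignment unreliable. `shiftnav`
takes the opposite view: if shift variability is a *function* of the mixture
composition, it is predictable. The package

1. models the map from a mixture's composition (concentrations, pH, T) to
   the shifts of its signals, and the inverse map from shifts back to
   composition, with multivariate adaptive regression splines (MARS);
2. bootstraps prediction in an *unknown* spectrum from five easily and
   safely identifiable **navigator signals** — two citrate doublets of
   doublets, two creatinine singlets and one glycine singlet;
3. combines two independent prediction routes into final shift and
   concentration estimates with uncertainties.

Because the laboratory calibration data behind the original predictor are
not distributable, the package ships a synthetic **artificial-urine
generator** that plays the role of the mixture series: it defines a
ground-truth shift physics, samples physiologically plausible compositions,
and renders full 1D spectra. Every quantitative claim the test suite makes
is measured against this generator as the oracle.

## Model structure

### Forward and inverse models

For a spin system with observed shift $\delta_0$, fast exchange between the
free form and transient binary complexes means $\delta_0$ is a smooth
function of the composition,
$$\delta_0 = f(x_1, \dots, x_n),$$
where the $x_i$ are the concentrations of the interacting components plus
pH and temperature. Each such function — and each inverse function
$C_j = g_j(\delta_1, \dots, \delta_m)$ giving a component concentration
from the shift pattern — is represented as a MARS expansion
$$\hat y = c_0 + \sum_{m=1}^{M} c_m B_m(x),$$
with hinge (or truncated-cubic) spline basis functions $B_m$ selected
greedily by the forward pass and pruned by generalized cross-validation
(GCV).

Four model banks are trained by `train_bundle()`:

* **full shift models** — one per spin system, predictors: the shifts of
  the *other* active-metabolite signals (the internal relationships within
  the shift matrix);
* **reduced shift models** — one per non-navigator spin system,
  predictors: the five navigator shifts only;
* **full concentration models** — one per modelled component plus pH and
  T, predictors: all active-signal shifts;
* **reduced concentration models** — the same responses from the five
  navigator shifts only;

plus an auxiliary glycine model (glycine navigator shift from the four
citrate/creatinine shifts), used during detection because no J-coupling or
intensity-ratio constraint is available for a lone singlet.

### The two-route prediction and its combination

Given a spectrum, `run_pipeline()`:

1. detects the five navigators (`find_navigators()`);
2. **reduced route**: evaluates the reduced banks on the navigator
   shifts, giving concentrations, pH, T and a first shift estimate
   $\delta_{\text{reduced}}$ per signal (navigator shifts pass through as
   observed);
3. **full route**: feeds the reduced-route shift vector to the full banks,
   giving a second, independent estimate $\delta_{\text{full}}$;
4. combines the two per signal. When the two uncertainty intervals
   overlap, $|\delta_r - \delta_f| \le \mathrm{err}_r + \mathrm{err}_f$,
   the estimate is the weighted average with weights inversely
   proportional to each route's uncertainty,
   $\delta_{\text{best}} = (\delta_r/\mathrm{err}_r +
   \delta_f/\mathrm{err}_f) / (1/\mathrm{err}_r + 1/\mathrm{err}_f)$;
   otherwise $\delta_{\text{reduced}}$ is taken, it being the bank with
   the lower average relative RMSE. The overlap condition is deliberately
   read as *interval overlap* (equivalently, the two predictions differ by
   no more than their combined uncertainty): the alternative reading, both
   endpoints of the reduced interval inside the full interval, degenerates
   to requiring $\delta_r = \delta_f$ whenever the two uncertainties are
   equal, which cannot be what a weighted-average rule intends.

Per-model uncertainty is the cross-validated rRMSE multiplied by the
response range on training data (i.e. the CV RMSE in response units);
navigator shifts observed directly carry a floor uncertainty of
`navigator_error` (default 5e-5 ppm, the shift-matrix recording
precision). Navigator inputs outside the training hull inflate the
uncertainty by `extrapolation_factor` (default 2) and raise a warning.
Negative concentration estimates are clipped to zero and flagged rather
than rejected.

## Navigator detection

* `pick_peaks()` finds local maxima above `snr_threshold` (default 5)
  times a robust noise estimate (MAD of the 9.5–10 ppm region), requires
  the apex to dominate a neighbourhood of about one linewidth (this
  suppresses noise ripples riding on the tails of strong lines), and
  refines the apex by a three-point parabola.
* `find_citrate()` pairs picked peaks into two-line multiplets whose
  splitting matches the expected J (15.9 Hz, tolerance 1.5 Hz) and whose
  intensity ratio lies in [0.6, 1.4]; implausibly weak pairs (minimum line
  height below 20 % of the strongest candidate pair in the window) are
  discarded before the splitting-closest rule is applied — noise pairs can
  match J by chance, the citrate lines dominate their window.
* `find_creatinine()` selects the cross-window singlet pair whose height
  ratio matches the 3:2 proton-count expectation (relative tolerance
  0.35); among consistent pairs the tallest wins.
* Glycine is taken as the picked peak nearest the auxiliary model's
  prediction, within 3 × its CV RMSE (floor 0.002 ppm).

Any failure stops the analysis with an error instructing manual entry
(`mode = "manual"`), mirroring the operational rule that prediction cannot
proceed without all five navigators.

## The synthetic generator: what it emulates, and what not

### Ground-truth shift physics

Each spin system's shift is
$$\delta = \delta_{\text{free}} + \sum_j a_j \frac{C_j}{K_j + C_j}
  + \frac{\Delta_{\text{acid}}}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a}}
  + c_T (T - 300),$$
a saturating binding isotherm per interacting component, a
Henderson–Hasselbalch protonation term and a linear temperature term —
smooth, nonlinear and monotone in each driver, which is exactly the class
of behaviour the MARS layer must capture. Parameters are drawn once per
panel from documented priors with a fixed seed (`shift_responses()`), so
the ground truth is persistent and inspectable. Key design choices:

* **Shift-active drivers.** pH, temperature and three marker ions (Ca²⁺,
  Na⁺, Cl⁻) drive the shifts. Five observed navigator values can pin down
  at most five independent quantities, so a generator in which many more
  drivers moved the shifts above the 1e-4 ppm level would make the
  navigator-reduced route impossible *for any method* — the small-driver
  regime is the only one in which a navigator-based bootstrap can reach
  sub-1e-4-ppm accuracy at all. The remaining ions and albumin perturb
  shifts below
  the recording precision and are treated as shift-silent.
* **Navigator sensitivity.** Navigator amplitudes are drawn 3–5× larger
  than non-navigator ones and each navigator has a distinct dominant
  driver (citrate dd1: pH + strong Ca binding; dd2: pH with weak Ca, so
  the dd1–dd2 difference isolates calcium; creatinine s1: Na-dominated;
  s2: Cl-dominated with the strongest temperature coefficient; glycine: a
  balanced probe). This is the defining property of navigator signals —
  the most concentration-sensitive signals, differently sensitive to
  different components — and it keeps the navigator-to-driver inversion
  well conditioned.
* **Shared response curves.** The apparent titration pKa (6.45–6.55) is
  common to all signals (protonation in the strongly phosphate-buffered
  matrix follows the common buffer equilibrium) and each marker ion has a
  single half-saturation constant (association dominated by the ion's main
  chelator), drawn once per panel with $K_j$ at 2–5× the upper
  concentration limit (far-from-saturation, weak electrostatic
  association). Consequently the *signal-to-signal* relations are
  near-linear while the concentration→shift and shift→concentration maps
  remain genuinely nonlinear.
* **Window containment and sensitivity floor.** Amplitudes are rescaled so
  every shift stays inside the inner 90 % of its search window, and every
  signal's total excursion is floored at 4e-3 ppm so that no signal is
  effectively composition-insensitive.

### Concentration sampling

`sample_concentrations()` supports plain Latin-hypercube and uniform
schemes (each column independently stratified), and the training default
`"dilution_lhs"`: a Latin-hypercube draw in a space consisting of one
shared log-scale *urinary dilution factor* plus one residual factor per
solute, with the dilution factor carrying weight 0.85 of each solute's
log-range. Urine is dilution-dominated in reality — osmolality spans more
than an order of magnitude with hydration status, and literature
concentration ranges are constructed relative to creatinine, i.e. they are
dilution-correlated by construction. This coupling is also what makes
concentration back-prediction well-posed: components that do not move any
shift directly (K⁺, Mg²⁺, phosphate, sulfate, albumin, most metabolites)
are recoverable *through* the dilution factor, which the marker ions
encode. pH and temperature are sampled independently; training sets use
the two-level temperature design (all mixtures at 300 K, a random ~19 %
subset re-measured at 302.7 K), hold-out sets draw T continuously.

### Spectrum rendering

Lorentzian multiplets (singlet; doublet split by J; doublet-of-doublets as
a two-line multiplet with a roof-effect intensity ratio, default 0.85;
triplet 1:2:1) on a 65,536-point, 12,019 Hz axis at 600.13 MHz, effective
linewidth 0.9 Hz (the 0.3 Hz processing line broadening is folded into the
effective width), TSP reference at exactly 0 ppm, additive Gaussian noise
with a detection limit (SNR 3) near 15 µM-protons.

### What the generator does **not** emulate

Free-induction-decay-level artifacts (phase and baseline distortion, water
suppression residues), albumin line broadening, heavy spectral crowding
beyond the deliberate creatine/hippurate overlap, J-multiplets higher than
triplets, and any metabolite–metabolite shift interaction above the
recording precision. Passing tests therefore demonstrate that the
*algorithmic chain* — simulation, training, detection, two-route
prediction, combination — is correct and accurate in a realistic
small-driver regime; they do not certify performance on real spectra with
uncorrected baseline or unmodelled interactions.

## The MARS engine: numerical choices

* **Forward pass** (C++): reflected hinge pairs
  $\max(0, x_v - t), \max(0, t - x_v)$ with knots at observed values,
  selecting at each step the (parent, variable, knot) triple with the
  largest residual sum-of-squares reduction; ties broken toward the lower
  variable index, then the lower knot. Candidate knots are thinned to at
  most `max_knots` (default 15 for n > 64, all values otherwise) evenly
  spaced order statistics, and the **end-span rule** excludes knots with
  fewer than `max(7, ceil(log2 n))` observations strictly on either side
  — hinges resting on a handful of boundary points otherwise acquire
  enormous coefficients and wreck cross-validation folds.
* **Backward pass**: iterative deletion minimizing
  $\mathrm{GCV} = (\mathrm{RSS}/n) / (1 - \mathrm{enp}/n)^2$ with
  $\mathrm{enp} = M + 1 + \text{penalty} \cdot M/2$, penalty 3 (the
  conventional choice).
* **Interaction degree** defaults to 1 (additive): the simulated physics
  is additive in its drivers and the shared-curve design makes even the
  composed signal-to-signal maps near-additive; degree-2 fits were
  measurably *worse* here (extra product terms chase noise), while
  remaining fully supported for other data.
* **Basis order**: piecewise-linear by default; `order = "cubic"` refits
  the pruned model on truncated-cubic basis functions (side knots midway
  between adjacent knots), giving a continuously differentiable surface.
  The pipeline uses the linear default — the cubic variant's behaviour
  beyond the outermost knots occasionally degrades hull-edge predictions
  on this problem. `select_spline_order()` picks between the two by CV
  RMSE when desired.
* **Degenerate inputs**: rank-deficient candidate pairs fall back to the
  best single hinge or are dropped; constant responses yield
  intercept-only models; constant CV folds are skipped with a warning. An
  optional scale-invariant diagonal ridge (`ridge`) and an
  orthogonal-fraction guard (`ortho_tol`) are available but off by
  default.

## Tunable parameters that matter

| Parameter | Where | Default | Units / meaning |
|---|---|---|---|
| `max_terms` | `mars_control()` | 21 | basis functions incl. intercept |
| `degree` | `mars_control()` | 1 | hinge factors per term |
| `penalty` | `mars_control()` | 3 | GCV cost per knot |
| `endspan` | `mars_control()` | auto | min. observations outside any knot |
| `shift_noise_sigma` | `build_training_set()` | 5e-5 ppm | shift recording noise |
| `frac_second_temp` | `build_training_set()` | 726/3775 | warm re-acquisition fraction |
| `dilution_weight` | `sample_concentrations()` | 0.85 | dilution share of log-variance |
| `passive_presence` | `build_training_set()` | 0.7 | P(passive metabolite present) |
| `linewidth_hz` | `acq_params()` | 0.9 Hz | effective FWHM |
| `noise_sigma` | `acq_params()` | 5 | intensity units (1 = 1 µM·proton) |
| `snr_threshold` | `pick_peaks()` | 5 | apex height in noise sigmas |
| `j_hz_expected`, `j_tol_hz` | `find_citrate()` | 15.9, 1.5 Hz | citrate splitting criterion |
| `navigator_error` | `train_bundle()` | 5e-5 ppm | observed-navigator uncertainty |
| `extrapolation_factor` | `train_bundle()` | 2 | uncertainty inflation outside hull |

## Problem sizes used by the tests and the acceptance script

Training sets of 800 base mixtures (954 rows after the two-temperature
duplication) over five seeds; 200 hold-out mixtures for concentration
recovery; 20 rendered hold-out spectra for the end-to-end run; 200
rendered spectra for the navigator-robustness property. These sizes make
the whole calibration-and-validation cycle reproducible on a single CPU in
minutes while keeping at least ten samples per degree of freedom of every
model fitted.

## Known limitations

* The demo panel is a reduced roster (12 active metabolites, 2 passive,
  7 ions, albumin; 16 spin systems) with literature-typical reference
  shifts — a configurable stand-in, not a validated clinical panel.
* The reduced concentration route is only as good as the dilution
  coupling: for a hypothetical design with fully independent
  concentrations, five navigator values cannot recover dozens of
  components, and the reduced-route R² would collapse accordingly.
* Temperature is trained at two levels but predicted as continuous;
  predictions at intermediate T rely on the linearity of the temperature
  term.
* No lineshape-fitting quantitation of visible metabolites is included:
  concentrations come from the inverse MARS models alone.
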