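---
title: "Models and methods behind quadcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadcal)
```

`quadcal` analyses the thermal unfolding of unimolecular DNA G-quadruplexes
from three calorimetric/spectroscopic modalities — DSC, osmotic-stress
melting and pressure-perturbation calorimetry — plus a CD fold check. This
vignette records the models, the conventions, the numerical choices, and
the places where a genuine design decision had to be made.

Internally everything is computed in kelvin, kilojoule, mole and SI
pressure units with R = 8.3145 J/(mol·K); files and printed reports use the
instrument conventions (°C, psi, mL/mol). Temperature intervals are
half-open `[lo, hi)` in kelvin.

## The van't Hoff "non-2-state" DSC model

A unimolecular two-state transition with temperature-independent enthalpy
has equilibrium constant

$$K(T) = \exp\!\left[-\frac{\Delta H_{vH}}{R}\left(\frac{1}{T} -
\frac{1}{T_m}\right)\right],$$

so $K(T_m) = 1$ and the excess heat capacity of a sum of independent
transitions is

$$C_p(T) = \sum_i \Delta H_{cal,i}\,
\frac{\Delta H_{vH,i}}{R T^2}\,\frac{K_i}{(1+K_i)^2}.$$

Assumptions worth stating explicitly:

* **ΔCp of unfolding is fixed at zero.** The model family carries no
  heat-capacity increment between folded and unfolded baselines; a real
  increment, if present, is absorbed by the cubic instrument baseline.
  This is a documented limitation, not an oversight.
* **Transitions are independent and unimolecular.** No scan-rate kinetics,
  no intermolecular dissociation stoichiometry.
* **ΔH_cal may differ from ΔH_vH.** Tying them (the default) gives a true
  two-state peak; freeing the calorimetric amplitude per transition
  (`free_amplitude = TRUE`) is exactly what makes a multi-peak fit
  "non-2-state" and is how a curve whose total area differs from the sum of
  the per-peak van't Hoff enthalpies is represented.

### Totals by integration

`total_enthalpy()` is the trapezoidal integral of the baseline-corrected
trace — the model-free calorimetric total. `tm_total()` returns the
**area-median temperature**: the T at which the cumulative integral reaches
half the total area (linear interpolation between grid points). An
"average melting temperature from integrating the curve" admits more than
one reading (area median vs. enthalpy-weighted mean of peak Tms); the area
median was chosen because it is defined directly on the measured curve,
needs no deconvolution, and reduces to the peak Tm for a single symmetric
transition. This is a package design decision.

### Window truncation is real

The analytic identity $\int C_p\,dT = \sum_i \Delta H_{cal,i}$ holds over
an infinite temperature axis. Over a finite scan (default 5–110 °C,
0.1 K pitch) a transition retains fraction
$K/(1+K)$ unfolded at each edge, so broad (low-enthalpy) transitions lose
several percent of their area: a 57.4 kJ/mol transition centred at 53.5 °C
is still ~4 % folded at 110 °C and ~2.5 % unfolded at 5 °C. Consequently
the windowed integral of a two-peak telomeric curve sits 2–4 % below the
sum of amplitudes, and flanking "signal-free" baseline windows are never
perfectly signal-free for such a peak. The parameter-recovery tests
therefore assert the integral identity only for sharp transitions (ΔH ≳
150 kJ/mol well inside the window); the nonlinear fit is unaffected,
because it matches the curve pointwise rather than by area.

## Baseline correction

`fit_baseline()` fits a cubic polynomial by ordinary least squares to the
points inside two user-chosen windows flanking the transition region and
subtracts it everywhere. Coefficients are expressed in powers of
temperature in °C — the instrument convention, and far better conditioned
than raw kelvin powers. At least 4 points per window are expected (an
error below 4 in total); windows overlapping the transition region
visibly corrupt the recovered area, and a regression test documents that
sensitivity rather than hiding it.

## The deconvolution fit

`fit_non2state()` minimises the sum of squared residuals between the trace
and the model with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`):

* bounds: ΔH ∈ (0, 1000] kJ/mol, Tm within the data range — unconstrained
  fits drift on noisy shoulders;
* initialisation: local maxima of a 5-point moving-average smooth,
  separated by ≥ 3 K, ties broken toward lower temperature; peak height
  seeds ΔH through $\Delta H \approx \sqrt{4 R T_m^2 C_{p,\mathrm{peak}}}$;
* degenerate traces (no interior maximum) fall back to midpoint
  initialisation and set a `degenerate` flag;
* non-convergence triggers up to three seeded, jittered restarts and is
  reported as a flag, never an exception;
* output transitions are sorted by ascending Tm, making the result
  invariant to initial-guess order.

Parameter covariance is taken from the LM normal-equations hessian scaled
by the residual variance; it is reported as `NA` when the hessian is
singular (e.g. a redundant transition pinned at a bound).

## Osmotic-stress water counting

The water count uses the standard osmotic-stress identity
$\Delta n_w = d\ln K / d\ln[\mathrm{H_2O}]$: each glycerol level's melt is
extrapolated to a common reference temperature,
$\ln K(T_{ref}) = -(\Delta H/R)(1/T_{ref} - 1/T_m)$, and regressed by OLS
on $\ln[\mathrm{H_2O}]$. Conventions:

* **Concentration, not activity.** The abscissa is molar water
  concentration under additive volumes, $[\mathrm{H_2O}] = (1000 -
  10\,pct)/18.015$ mol/L; activity-coefficient and density corrections are
  out of scope.
* **Reference anchors.** `T_ref` defaults to the 0 %-glycerol Tm (so
  ln K(0 %) = 0) and `dH_ref` to the 0 %-glycerol enthalpy, used at every
  level. Whether a per-level enthalpy should enter each point's ln K is
  ambiguous in practice; anchoring on the measured 0 % values keeps the
  extrapolation in measured quantities and makes the noiseless
  generate→regress round trip exact.
* The slope's standard error and R² come from the same regression; a
  perfectly flat collinear series returns slope 0 with zero error.

The matching generator inverts the relation in closed form,
$1/T_m = 1/T_{m,0} + R\,\ln K_{target}/\Delta H$, so a positive injected
uptake makes Tm rise with glycerol, consistent with the sign convention
(positive slope = water uptake on unfolding).

## Pressure-perturbation volumetrics

Four scans are chained: corrected solute heat is sample/buffer minus
buffer/buffer, and the solvent expansion trace is derived from the two
water-referenced scans as
$\alpha_o(T) = (\Delta Q_{bw} - \Delta Q_{ww})/(T\,\Delta P\,V_{cell})$
with the calorimeter cell volume defaulting to 0.5 mL. Which reference
scan defines $\alpha_o$ is a convention the package had to fix; the
generator and the analysis share it. The conversion
$\alpha_s = \alpha_o - \Delta Q/(T \Delta P m_s V_s)$ is evaluated
pointwise in SI units (70 psi = 4.826 × 10⁵ Pa; $m_s V_s$ in m³).

### The progress baseline

"Integrating the area above the peak" needs a reference level. The package
joins straight lines fitted to ≥ 4 flanking points on each side of the
window by a sigmoid progress weight. The progress itself is estimated by a
small profiled fit: a logistic progress curve plus a logistic-derivative
peak is matched to the windowed trace, the peak amplitude is profiled out
in closed form, and the profiled SSR is minimised over (midpoint, width)
with multi-start L-BFGS-B. Two numerical facts forced this design:

* the textbook alternative — iterate "progress = normalised cumulative
  excess area" to a fixed point — **diverges** whenever the pre/post
  baseline step area exceeds the peak area (the update amplifies progress
  errors by the ratio of step area to peak area, ~30 under the default
  synthetic conditions);
* a joint 3-parameter nonlinear fit stalls, because the derivative of the
  progress curve with respect to its midpoint *is* the peak shape — the
  (midpoint, amplitude) pair is degenerate to first order.

Only the fitted progress shapes the baseline; the reported
$\Delta V = V_m \int (\alpha_s - \alpha_{baseline})\,dT$ integrates the
data, not the fitted peak, so the amplitude degeneracy never touches the
result. ΔV is reported in mL/mol via a molar volume $V_m = M \cdot V_s$
(partial specific volume defaulting to 0.55 mL/g for DNA). The mL/mol unit
with magnitudes ~0.1 is the field's reporting convention for these
experiments even though it blends specific- and molar-volume language; the
package reports it verbatim and leaves the interpretation to the reader.

With a Tm ± 25 K window the noiseless chain recovers injected ΔV across
±0.3 mL/mol to ~0.3 %; a Tm ± 15 K window already loses ~1 % to peak-tail
truncation.

## CD topology calls

Band finding smooths with a Savitzky–Golay filter (cubic, 7-point window,
matched to the 0.5 nm instrument pitch) and keeps local extrema whose
topographic prominence reaches 5 % of the largest absolute ellipticity; a
positive-valued local minimum (an inter-band saddle) is not a band. The
classification windows encode standard quadruplex CD practice — dual
positive 270/290 nm bands → hybrid; positive 260–270 nm with negative
235–245 nm → parallel; positive 290–300 nm with negative 255–270 nm →
antiparallel; anything else → undetermined. Only the hybrid signature is
anchored in the motivating experiments; the other windows are configurable
design decisions. Calls are invariant to uniform positive scaling and, by
test, stable under seeded noise at 5 % of peak amplitude.

## What the generators emulate — and what they do not

The generators reproduce the *structure* of instrument output: DSC excess
heat capacity on a 5–110 °C, 0.1 K grid with a cubic baseline and Gaussian
noise; glycerol series at 0–5 % w/v; PPC pulse quartets at 1 K spacing
over 5–120 °C with 70 psi steps, a water-like solvent expansivity trace
and a shared smooth instrument offset; CD spectra as Gaussian band
mixtures on a 225–325 nm, 0.5 nm grid. Default noise levels and the
solute expansion levels (3.0–3.2 × 10⁻⁴ K⁻¹ around the transition) were
chosen once as instrument-plausible values.

They deliberately do **not** model feedback lag, scan-rate convolution,
concentration normalisation errors, osmolyte–DNA preferential
interactions, or baseline drift between the four PPC scans. Passing
round-trip tests therefore demonstrates that the analysis inverts the
stated physical model correctly — not that it is robust to every artefact
of real instruments. Every generator draws from a local seeded RNG and
never perturbs the caller's random stream.

## Problem sizes and runtime

The test suite and the acceptance script run on desk-scale problems chosen
as the package's own defaults: 1051-point thermograms, 6-level glycerol
series, 116-pulse PPC quartets, 201-point CD spectra, with a handful of
multi-start optimisations per fit. The full suite completes in well under
a minute on a single core.

## Known limitations

* No heat-capacity increment (ΔCp = 0) between folded and unfolded states.
* Broad transitions are truncated by any finite scan window; totals by
  integration are systematically a few percent low for such peaks (see
  above), and baseline windows cannot be made fully signal-free for them.
* Water counting uses concentration rather than activity and a single
  reference enthalpy per series.
* The PPC chain assumes the four scans share pulse amplitude and cell
  volume, and that the compression-pulse sign convention was applied
  upstream.
* CD classification is rule-based on band positions; it does not estimate
  fold fractions and will return `undetermined` for mixtures that blur the
  band structure.
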