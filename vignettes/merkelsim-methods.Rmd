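---
title: "Modelling touch-evoked firing in branched Merkel-cell afferents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling touch-evoked firing in branched Merkel-cell afferents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merkelsim)
```

## The model

Slowly adapting type I (SAI) tactile afferents innervate Merkel cells in
touch domes through a branched arbor: clusters of Merkel cell-neurite
complexes (the transduction units) converge on heminodes, the most distal
nodes of Ranvier, which act as spike-initiation zones.  `merkelsim`
simulates this architecture as a three-stage network:

1. **Skin mechanics.** A ramp-and-hold indentation (depth $D$ in mm,
   constant ramp acceleration $a$ in mm s$^{-2}$, hold duration in s) is
   converted into strain energy density (SED) $\varepsilon(t)$ at the end
   organ.  The tissue is a uniaxial incompressible Mooney-Rivlin column
   ($C_{10} = 14{,}847$ Pa, $C_{01} = 41{,}410$ Pa; 342 µm of epidermis,
   dermis and subcutaneous tissue) in series with a linear-elastic
   substrate ($E = 906{,}098$ Pa), solved by force balance at each depth.
   The elastic SED is then passed through a quasi-linear viscoelastic
   hereditary integral with reduced relaxation
   $G(t) = g_\infty + g_1 e^{-t/\tau_1} + g_2 e^{-t/\tau_2}$
   ($g_1 = 0.391$, $\tau_1 = 0.25$ s, $g_2 = 0.226$, $\tau_2 = 9.371$ s,
   so $g_\infty = 0.383$), discretized with the recursive exponential
   update that is exact for piecewise-linear loading.

2. **Transduction.** Each cluster of $M$ transduction units produces a
   receptor current
   $$I(t) = \beta + M\left(\alpha\,\varepsilon(t)
     + \lambda\,\tfrac{d\varepsilon}{dt}\right) + \omega(t),$$
   with offset $\beta$ (mA), static gain $\alpha$ (mA/Pa) and dynamic gain
   $\lambda$ (mA·ms/Pa).  $\omega(t)$ is a 7-point moving average of
   Box-Muller Gaussian deviates, drawn independently per cluster and not
   scaled by $M$ (it sits outside the parenthesis).  The SED derivative is
   a backward difference on the 1-ms grid (Pa/ms), so $\lambda$ needs no
   unit conversion.

3. **Spike initiation.** Each zone is a leaky integrate-and-fire unit
   $RC\,du/dt = -u + R I(t)$ with $\tau = RC = 5$ ms, $C = 10^{-8}$ mF
   (hence $R = 5\times 10^8\,\Omega$, mapping mA-scale currents to tens of
   mV), threshold $\bar v = 30$ mV, integrated by classical RK4 with the
   current held constant over each 1-ms sample.  A spike in any zone
   antidromically resets *all* zones and imposes a shared 1-ms absolute
   refractory period, so the most strongly driven zone drives the merged
   train (the driver effect).

## Numerical choices

* **Reset and refractoriness.** The reset potential is 0 mV (the membrane
  equation's rest).  During refractoriness integration is suspended with
  the membrane clamped at reset; a configuration flag instead allows
  integration to continue with the threshold ignored.  Simultaneous
  same-step crossings are resolved by largest overshoot, then lowest zone
  id — deterministic and seed-free.
* **Spike timing resolution.** Spike times are assigned to the end of the
  integration substep in which threshold is crossed.  At the default 1-ms
  step the interspike interval is therefore quantized to 1 ms; against the
  constant-drive closed form
  $\mathrm{ISI} = t_{\mathrm{ref}} + \tau\log\!\big(RI/(RI-\bar v)\big)$
  this bounds the error by one step, and 0.1-ms substeps
  (`lif_parameters(step = 0.1)`) bring the relative error below 2% even at
  several times rheobase.  A side effect of grid quantization: at the
  fastest acceleration and the smallest depth the ramp lasts only ~8 ms
  and cannot contain a spike in noise-free runs, so ramp rates are
  monotone in acceleration only where the ramp window can hold a spike.
* **Viscoelasticity.** The recursive Prony update is cross-checked in the
  tests against a direct $O(n^2)$ trapezoidal evaluation of the hereditary
  integral; the two agree to 0.1% on smooth loading and to the expected
  $O(\Delta t)$ smear at the ramp-to-hold derivative discontinuity.
* **Substrate thickness.** Not reported with the material constants;
  default 2,000 µm.  Commanded depths (up to 0.36 mm) exceed the 342-µm
  tissue stack, so series substrate compliance is required for the
  surrogate to stay physical.  Prony time constants are interpreted in
  seconds: 0.25 s and 9.37 s bracket the rapid-adaptation and
  slow-relaxation phases of a 5-s stimulus.

## Noise calibration

The noise standard deviation applies to the pre-averaging deviates; the
7-point average reduces the interior variance to $\sigma^2/7$ and confines
autocorrelation to lags below 7 ms.  Its default, $\sigma = 5\times10^{-9}$
mA, was chosen once so that the pooled normalized interspike-interval
distribution of the reference {8,5,3,1} model has a coefficient of
variation within the 0.3-0.8 range typical of SAI afferents (measured
~0.75 at the reference parameters).  In this regime static-phase firing is
noise-driven near threshold, which is what produces the characteristic
irregular static discharge; the CV is only weakly sensitive to $\sigma$
itself, while the *rate* scale is strongly sensitive, which effectively
pins $\sigma$ near this value.

## The stimulation protocol and response statistics

The default protocol crosses five depths (0.04-0.36 mm) with three ramp
accelerations (20, 81, 1143 mm s$^{-2}$), five repetitions each: 75
indexed simulations.  Ramp rate is spikes during the ramp divided by ramp
duration; static rate is spikes in the final 2.5 s of the hold divided by
2.5 s, a window placed at the end of the hold to exclude rapid adaptation.
Displacement-response relations are fitted with
$\mathrm{rate} = Y_0 e^{\kappa D}$ ($Y_0$: threshold firing rate, Hz;
$\kappa$: mechanical sensitivity, mm$^{-1}$) and compared by extra
sum-of-squares F tests on shared-parameter nested models.  Percent
firing-rate change between two configurations is the difference in summed
static rates across all stimulations divided by the lower sum.  (The
source text does not state which phase enters this statistic; both the
static-phase and whole-stimulus readings were measured and agree within
about one percentage point because static-phase spikes dominate a 5-s
stimulation, so the static-phase reading is used.)

## Fitting

The three free parameters $(\beta, \alpha, \lambda)$ are fitted per arbor
configuration by maximizing the combined fractional sum of squares
$$\mathrm{fss} = \Big(1 - \tfrac{\sum_i(\bar h_i - h_i)^2}{\sum_i \bar h_i^2}\Big)
 + \Big(1 - \tfrac{\sum_i(\bar r_i - r_i)^2}{\sum_i \bar r_i^2}\Big),$$
which equals 2 at a perfect match, over the 75 indexed stimulations.  The
search is gradient-free response-surface methodology on Latin-hypercube
designs: a 50-point domain search, then iterated 20-point designs
recentred on the incumbent with the region shrinking by 0.6 per iteration.
Two additions make the search robust on this model's surface: the top two
domain-search points seed independent shrink sequences (the surface has a
secondary basin along the $\beta$ bound), and after each design a full
quadratic response surface is fitted to the design points and its
predicted optimum evaluated as one extra candidate (the classic Box-Wilson
step).  The latter matters because $\beta$ and $\alpha$ trade off along a
diagonal ridge (both raise the static drive $R(\beta + M\alpha\varepsilon)$)
that axis-aligned boxes track slowly; without it, noise-free parameter
recovery left 25-45% error in $\alpha$, with it recovery is within a few
percent.

Search bounds come from dimensional analysis of the membrane drive rather
than fiat: $\beta \in [0.85, 0.999]\,\bar v/R$ (the offset must sit close
below threshold for low-rate noise-driven static firing to exist), and
$\alpha$, $\lambda$ bounded so the primary cluster's static and ramp drive
contributions span roughly 0.1-30 mV and 1-300 mV at the model's SED
scales ($10^4$ Pa plateau, $1.5\times10^3$ Pa/ms peak rate).  $\alpha$ and
$\lambda$ are searched in $\log_{10}$ space, $\beta$ linearly.  Noise is
held on, with fixed $\sigma$, during fitting: with noise off the
rate-versus-drive curve of the deterministic integrate-and-fire unit is
nearly discontinuous at threshold and cannot reproduce low static rates at
all, so a deterministic fit of the static phase is ill-posed.

## Synthetic inputs

No recordings ship with the package, so the fitting target is synthetic: a
prototypical SAI response defined by linear regressions of rate against
depth — one ramp regression per acceleration (slopes 150/300/700 Hz/mm,
intercepts 5/10/20 Hz for 20/81/1143 mm s$^{-2}$) and one pooled static
regression (30 Hz/mm, 1 Hz), evaluated over the protocol and clipped at
zero.  These coefficients are configuration values chosen to be
qualitatively consistent with published mouse SAI displacement-response
data; they are not measurements, and quantities that depend on them (fit
scores, percent-change magnitudes) are approximate accordingly.  The
synthetic arbor generator draws zone counts (3-5), total units (13-20) and
cluster partitions by rejection until the skew — the |OLS slope| of
cluster size against rank — falls in the observed 0.6-4.5 range; it
emulates the observed ranges, not the exact histograms, and carries no
spatial geometry.

What passing tests on these synthetic inputs show is that the *machinery*
(mechanics, transduction, spike initiation, fitting, statistics) behaves
as specified, and that the structural effects of regrouping transduction
units have the right signs and orderings; they do not validate the model
against real recordings.

## Reproducing the structural experiments

`prototypical_arbors()` provides the four reference configurations
({8,5,3,1}, {7,6,4,2,1}, {5,4,3,1}, {6,4,3}) with their published fitted
parameters and the averaged set.  Because the reduced-order skin surrogate
shifts the absolute SED scale relative to a finite-element solution, the
experiment drivers refit each arbor to the synthetic target before
comparing architectures (`rsm_fit`), rather than reusing the printed
parameter values verbatim.  The experiments then measure, with paired
noise seeds across configurations:

* regrouping of the 17-unit arbor ({8,5,3,1} to {10,5,1,1} or {6,5,3,3});
* per-unit primary vs secondary gains over eight conserved-total pairs
  across the four arbors;
* cluster fill-up from 17 to 24 units under the secondary-first and
  smallest-first strategies;
* the displacement-response comparison of a small skewed {10,1,1} arbor
  against a large even {4,4,4,4,4} arbor with the averaged parameters.

In our hands the signs and orderings all reproduce (skew-increasing moves
raise firing, primary gains exceed secondary gains, the secondary fill
strategy beats the smallest-first strategy, the small skewed arbor is more
mechanically sensitive with a lower threshold rate).  The *magnitudes* of
the regrouping effects are about a third of those reported with a full
finite-element skin model: static firing here is noise-near-threshold, the
drive increment from moving two units is ~0.2 mV against ~1 mV of noise,
and because the fitted $\alpha$ scales with $\sigma$ the normalized effect
size is largely $\sigma$-invariant — the shortfall is structural to the
surrogate-plus-synthetic-target setting, not a tunable.  Fill-up
magnitudes and the $\kappa$/$Y_0$ comparison land close to the published
values.

## Cable-theory checks

`length_constant()`, `conduction_delay()` and `point_neuron_report()`
implement the closed-form justification for treating zones as point
neurons with zero inter-zone delay: with $R_m = 15{,}000\,\Omega$ cm$^2$,
$R_i = 125\,\Omega$ cm and 1-µm neurites the passive length constant is
$\sqrt{R_m d / 4 R_i} \approx 548$ µm, an order of magnitude beyond
measured neurite paths; neurite conduction delays (0.7 m/s) are far below
the sodium-channel inactivation timescale (assumed 1 ms — cited but not
printed in the source literature, so it is a stated assumption of the
report); and myelinated-branch delays (13 m/s over ≤245 µm, ~0.02 ms) are
far below the 1-ms refractory period.

## Problem sizes and limitations

The default experiment suite (four response-surface fits of ~500
evaluations each, plus the structural comparisons, all on the 75-run
protocol at 1000 Hz) completes in roughly ten minutes on one core; the
test suite uses the same sizes.  Known limitations: no spatial SED
variation across clusters (a uniform field is assumed, consistent with a
probe much wider than a touch dome), no receptive-field or punctate-probe
predictions, no conductance-based dynamics or adaptive thresholds, and no
real-recording analyses — first-spike-latency and latency-variance
statistics on recorded afferents need data the package does not ship.
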