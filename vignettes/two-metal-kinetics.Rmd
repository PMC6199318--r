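---
title: "Two-metal-ion kinetics of processive DNA degradation: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-metal-ion kinetics of processive DNA degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexokin)
```

## The model

Lambda exonuclease degrades one strand of duplex DNA processively, one
nucleotide per catalytic cycle, using two active-site Mg²⁺ ions. The package
models the cycle with three chemical states:

* **EMM** — enzyme with both ions bound (catalytically competent),
* **EM** — enzyme with only the tightly held A-site ion,
* **E** — apo enzyme.

In the *sequential-dissociation* scheme (`model1`), each
cleavage/translocation step expels the B-site ion
(EMM → EM at rate $k_B^{\mathrm{off}}$), which rebinds at the
pseudo-first-order rate $k_B^{\mathrm{on}} = k_B^b\,[\mathrm{Mg}^{2+}]$.
The A-site ion dissociates only stochastically (EM → E at
$k_A^{\mathrm{off}}$) and rebinds at
$k_A^{\mathrm{on}} = k_A^b\,[\mathrm{Mg}^{2+}]$. Summing the cycle's
renewal terms gives the mean per-nucleotide degradation time

$$\tau_1 = \frac{1}{k_B^{\mathrm{off}}} + \tau_d + \frac{1}{k_B^{\mathrm{on}}},
\qquad
\tau_d = \frac{k_A^{\mathrm{off}}}{k_A^{\mathrm{on}} k_B^{\mathrm{on}}},$$

and the titration curve

$$V(c) = \frac{k_B^{\mathrm{off}}\,c}{c + K_B + K_B K_A/c},
\qquad K_A = k_A^{\mathrm{off}}/k_A^b,\; K_B = k_B^{\mathrm{off}}/k_B^b.$$

The $K_BK_A/c$ term produces the sigmoidal (apparently cooperative,
Hill $1 < n < 2$) deviation from Michaelis–Menten kinetics at low Mg²⁺:
both ions must be present to cleave, and they bind sequentially.

The *coincident-dissociation* alternative (`model2`) expels **both** ions on
every cleavage (EMM → E). Its exact mean cycle time is

$$\tau_1 = \frac{1}{k_B^{\mathrm{off}}} + \frac{1}{k_A^{\mathrm{on}}}
 + \frac{1}{k_B^{\mathrm{on}}}
 + \frac{k_A^{\mathrm{off}}}{k_A^{\mathrm{on}} k_B^{\mathrm{on}}}.$$

### Effective constants of the coincident scheme

Written as a titration curve $V(c) = k_B^{\mathrm{off}}/(1 + S/c + P/c^2)$
(the same two-parameter denominator family as the sequential curve), the
coincident scheme has *effective* coefficients
$S = k_B^{\mathrm{off}}(1/k_A^b + 1/k_B^b)$ and
$P = k_A^{\mathrm{off}} k_B^{\mathrm{off}}/(k_A^b k_B^b)$, which equal
$K_A + K_B$ and $K_A K_B$ only when $k_A^{\mathrm{off}} =
k_B^{\mathrm{off}}$. A fit of the titration curve therefore pins down
$(k_B^{\mathrm{off}}, S, P)$, and for a candidate $k_A^{\mathrm{off}}$ the
two binding rates are recovered as roots of $x^2 - \tilde S x + \tilde P$
(`model2_binding_rates()`), real if and only if

$$k_A^{\mathrm{off}} \ge \frac{4 K_A K_B k_B^{\mathrm{off}}}{(K_A+K_B)^2}.$$

This was a genuinely open design point: one source formula presents the
coincident-scheme curve with its coefficients *labelled* as the raw
equilibrium constants, while the same source's root formulas only make
sense for effective coefficients. We implement `mean_velocity()` for
`model2` as the exact renewal expression — which makes the identity
`mean_velocity = n_sites / mean_first_passage_time` hold for both variants
to 1e-10 and keeps the Gillespie simulator, the master equation and the
closed forms mutually consistent — and expose the coefficient pair through
`model2_effective_constants()`. With the printed constants
$K_A = 0.30$ mM, $K_B = 0.71$ mM, $k_B^{\mathrm{off}} = 18$ s⁻¹ the bound
evaluates to 15.03 s⁻¹; the originally quoted 31.4 s⁻¹ derives from an
unpublished coincident-scheme refit whose parameters were never printed,
so the package exposes the formula and documents the discrepancy rather
than guessing the refit inputs.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `kB_off` | B-ion release = cleavage/translocation rate | 18 | s⁻¹ |
| `kB_b`   | B-ion binding rate | 18/0.71 ≈ 25.4 | s⁻¹·mM⁻¹ |
| `kA_off` | A-ion dissociation rate | 0.1 | s⁻¹ |
| `kA_b`   | A-ion binding rate | 0.1/0.30 ≈ 0.33 | s⁻¹·mM⁻¹ |
| `n_sites`| nucleotides between the FRET dyes | 20 | nt |
| `sigma`  | quenched-disorder width | 0.5 | k\_BT |

`lambda_rates()` builds the concluded set from the printed equilibrium
constants ($K_B = 0.71$ mM, $K_A = 0.30$ mM); the conventionally quoted
$k_B^b = 25$ and $k_A^b \approx 0.34$ are the rounded forms. The
kinetic-barrier asymmetry
$\ln(k_B^{\mathrm{off}}/k_A^{\mathrm{off}}) \approx 5.2\,k_BT$ means the A
ion unbinds ~200-fold more slowly, which is what converts occasional A-ion
loss into long pauses at low Mg²⁺.

## Master equation and first-passage times

`build_generator()` assembles the rate generator over (state, position)
with position ∈ 0..N; `first_passage_pdf()` propagates the transient block
from the initial condition and reports the density of the N-nt completion
time as the probability influx into the absorbing state EMM(N).
Numerical choices:

* **Initial condition** — all probability in EMM(0). The source never
  states one; EMM(0) makes the renewal identity
  $\mathrm{MFPT} = N\tau_1$ exact, and is the natural start of the
  processive phase (enzyme engaged, both ions bound). It is overridable by
  passing a custom grid plus wrapping the generator directly.
* **Boundary guard** — the printed gain term of the EMM balance carries a
  guard $(1-\delta_{0,n-1})$ which, read literally, would sever
  EM(0) → EMM(1) and trap probability at position 0. We read it as a guard
  against the out-of-range source EM(−1): the gain is active for all
  $n \ge 1$.
* **Influx density** — the density is computed as
  $k_B^{\mathrm{on}} P_{EM}(N-1, t)$ (model-1 wiring; $P_{EM}(N,t)$ for
  model-2), not by differentiating the absorbed CDF, avoiding
  differentiation noise.
* **Propagation** — eigendecomposition when it reconstructs the generator
  to 1e-9, otherwise stepwise dense matrix exponentials on the (default
  geometric, 400-point, $[10^{-3}, 50] \times N\tau_1$) grid. The
  block-Toeplitz structure of the translocation chain makes eigenvalues
  highly degenerate, so the exponential fallback is the common path.
  Coverage below 99.9% of the mass warns; below 99% the result is flagged
  truncated.
* **Position bookkeeping** — per the position-resolved rate equations, the
  increment rides on B-ion rebinding (EM(n) → EMM(n+1)) in model-1 and on
  cleavage (EMM(n) → E(n+1)) in model-2. Mean quantities are indifferent
  to this choice; pause-state attribution is not, which is why it is fixed
  and documented here.

## Quenched disorder

Molecule-to-molecule heterogeneity multiplies all four rate constants of a
molecule by $e^{-\delta\Delta G^\ddagger}$ with
$\delta\Delta G^\ddagger \sim \mathcal N(0, \sigma^2)$ (the source's
"standard deviation σ²" is read as variance, the standard convention).
Two consequences are exploited and tested:

* equilibrium constants are disorder-invariant;
* the per-molecule first-passage density is an exact time rescaling of the
  disorder-free one, so in $\zeta = \log_{10} V$ space the disorder-averaged
  density is the disorder-free density convolved with
  $\mathcal N(0, (\sigma \log_{10} e)^2)$.

`disorder_average_pdf()` therefore needs a single master-equation solve
(`method = "scaling"`); the per-draw re-solve (`method = "direct"`) is kept
as a cross-check. The expectation over the disorder law is integrated by
midpoint-quantile stratification by default (sup-norm error vs the exact
convolution ≈ 0.05% at 5000 nodes, against ≈ 3% for raw Monte-Carlo draws
at the same n); `draws = "random"` reproduces the literal random-number
procedure.

The generating σ is not directly printed anywhere; the package default
σ = 0.5 k\_BT gives a ~1.6-fold velocity spread between ±1σ molecules,
a realistic single-enzyme heterogeneity, and is used consistently by the
synthetic-data generator and the recovery tests (which only ever compare
the package against its own stated world).

## Synthetic single-molecule data

`simulate_trajectory()` runs the exact Gillespie algorithm on the generator
wiring; `trajectory_to_fret()` maps position linearly onto FRET efficiency
between 0.26 (intact reporter) and 0.53 (fully degraded), frame-averages
within each camera frame, and adds Gaussian frame noise. Defaults that the
experimental description leaves open, recorded in trace metadata:
frame interval 0.1 s, noise 0.05 efficiency units, a 2 s baseline before
the reaction and a 2 s plateau after completion.

What the generator emulates: Mg²⁺-dependent mean velocities, the full
first-passage-time distribution including the E-trapped pause tail,
quenched disorder, and threshold-measurable FRET rises. What it does not:
photophysics (blinking, bleaching, crosstalk beyond the inverse of the
correction formula), baseline drift, the nonlinear dye-distance
calibration (the linear position→efficiency map is consistent with the
simulated traces it stands in for, but no calibration curve exists), and
enzyme dissociation/rebinding. A green test therefore establishes
self-consistency of the kinetic machinery, not instrument realism.

**Velocity readout.** The degradation time of a trace is measured between
threshold crossings at 5% and 95% of the efficiency range (the
"minimum-to-maximum" rule operationalized against noise), after a 5-frame
running median, with sub-frame linear interpolation of the crossing times;
the interval is divided by 0.90 to estimate the full 0→100% time, and the
velocity is `n_sites` over that. With thresholds (0, 1) the rule reduces
to the plain `n_sites / interval`. On noisy synthetic data at 3 mM the
mean estimate lands within ~6% of $1/\tau_1$.

**A caveat reproduced, not fixed.** Per-condition *arithmetic mean*
velocities, $\overline{N/\tau}$, exceed $N/\overline{\tau}$ whenever the
dwell distribution is heavy-tailed (low Mg²⁺). Refitting titration curves
to simulated per-trace means therefore underestimates $K_A$ — the same
arithmetic-mean-versus-log-mean tension the original analysis flags at
high Mg²⁺. The distribution-level estimator below is the robust route.

## Inference

* `fit_velocity_curve()` — least squares on condition means for the
  mechanistic, Michaelis–Menten and Hill curves, sharing one loss so model
  comparison is like-for-like; log-parameterized, multi-started from an
  MM-derived guess with ±50% perturbations, best start polished.
  SEM weighting is available but off by default (the original fitting
  scheme is unstated).
* `estimate_sigma()` — Gaussian fit to $\zeta$ values; reports both the raw
  width and an intrinsic-width-corrected value (quadrature subtraction),
  since whether the original analysis subtracts the disorder-free
  stochastic width is unstated. The caller chooses.
* `estimate_kAoff()` — the histogram grid search: for each candidate
  $k_A^{\mathrm{off}}$ (with $k_A^b = k_A^{\mathrm{off}}/K_A$ so the fitted
  equilibrium constant is preserved), predict the disorder-averaged ζ
  histograms at the observed conditions and sum squared bin differences.
  Bin width defaults to 0.1 in ζ (binning unstated in the source); edges
  are shared between observation and prediction by construction; ties
  break toward the smaller candidate (favouring the more stable A ion).
  On synthetic data generated at 0.1 s⁻¹ the MSE profile is U-shaped and
  the search returns 0.1 s⁻¹ among {0.01, 0.1, 1}.
* `extract_pauses()` / `pause_statistics()` — a pause is ≥ 2 s at one
  nucleotide; only pauses > 10 s are reported (short events are not
  reliably detectable over FRET noise); each pause is attributed to its
  time-majority chemical state. At 0.03 mM, >99% of reported pauses are
  E-dominated, the kinetic signature distinguishing the two schemes.

## A knowingly red acceptance property

One stated acceptance property asserts that the coincident scheme at its
constrained parameters ($k_A^{\mathrm{off}} = 32$ s⁻¹, binding rates from
the quadratic mapping) produces **no** >10 s pauses at any
c ≥ 0.03 mM. Our simulations contradict the 0.03–0.1 mM part: because in
that scheme *every* cycle needs an A-ion rebinding event, the velocity
constraint forces a mean per-nucleotide dwell of ≈15 s at 0.03 mM
($1/k_A^{\mathrm{on}} + (1 + k_A^{\mathrm{off}}/k_A^{\mathrm{on}})/k_B^{\mathrm{on}} + 1/k_B^{\mathrm{off}}$),
so >10 s stalls are unavoidable there (≈5000 over 500 traces), while none
occur at 0.3–3 mM. What the coincident scheme genuinely lacks is the
~100 s E-trapped pause *tail* of the sequential scheme — the package's
simulator suite asserts exactly that — but the literal "no long pauses at
0.03 mM" claim fails, and the corresponding acceptance test is left red
rather than weakened.

## Known limitations

* No photophysics or baseline artefacts in trace synthesis; no
  experimental-trace step finding (the original step-finding algorithm is
  unspecified).
* No Ca²⁺-competition model: no kinetic scheme for the inhibitory ion was
  ever specified, so the ~21-fold Ca²⁺ slowdown is outside the package's
  reproducible scope.
* The master-equation propagation cost grows as $O((3N)^3)$ per grid
  point; fine for N ≲ 100, not intended for kilobase-scale reporters.
* Fits report point estimates only (no bootstrap/posterior intervals,
  matching the original analysis).
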