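---
title: "Surface-to-volume scaling and the FtsZ threshold model of aspect-ratio homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-to-volume scaling and the FtsZ threshold model of aspect-ratio homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodscale)
```

## The scaling observation

Rod-shaped bacteria adapt both length and width to growth conditions, yet
across nutrient conditions, antibiotic challenges, protein depletions and
even across species, their population-averaged surface area and volume fall
on a single power law,

$$S = \gamma\, V^{2/3}, \qquad \gamma \approx 2\pi,$$

spanning about two orders of magnitude in volume. For a spherocylinder
(a cylinder of diameter $w$ capped by hemispheres, pole-to-pole length $L$),

$$S = \pi w L, \qquad V = \tfrac{\pi}{4} w^2 L - \tfrac{\pi}{12} w^3,$$

and the prefactor is a function of the aspect ratio $\eta = L/w$ alone:

$$\gamma(\eta) = \eta \pi \left(\frac{\eta\pi}{4} - \frac{\pi}{12}\right)^{-2/3}.$$

$\gamma(\eta)$ is scale-free and strictly increasing, with the sphere value
$6^{2/3}\pi^{1/3} \approx 4.836$ at $\eta = 1$. A constant $\gamma$ over a
broad size range is therefore equivalent to a constant aspect ratio: a
fitted $\gamma = 6.24$ inverts to $\eta \approx 4.08$, inside the measured
steady-state band $4.14 \pm 0.17$. Coccoid cells follow the analogous
prolate-spheroid curve (`gamma_from_eta_spheroid()`; $\gamma = 4.92$ at
$\eta = 1.38$), and filamentous cells at frozen width leave the $2/3$
family altogether, approaching $S \propto V$.

Throughout the package **width means diameter** and the spheroid functions
take **semi-axes**; mixing radius and diameter conventions silently
corrupts $\gamma$, which is why every function documents its convention.

One caveat we inherit from the source material and document rather than
reproduce: for $\eta \approx 4$ the exact spherocylinder geometry gives
$V = (11\pi/12)\,w^3 \approx 2.88\,w^3$ (and $S \approx 4\pi w^2$ together
with $S = 2\pi V^{2/3}$ forces $V = \sqrt{8}\,w^3 \approx 2.83\,w^3$),
whereas the relation is sometimes quoted as $V \approx 8 w^3$ — consistent
with a dropped radical. `rod_volume_eta4_approx()` exposes the quoted form
for comparison only; all computations here use the exact cubic.

## Fitting the law

`fit_power_law()` is ordinary least squares in log–log space,
$\log S = \log\gamma + \beta \log V$, either with $\beta$ free or pinned to
$2/3$. The data this law describes have multiplicative scatter over two
decades of volume, which is exactly the error model unweighted log-space
least squares assumes; weighting rows by sample size (which the pooled
tables do not consistently report) moves $\gamma$ only in the third digit
at realistic scatter. Standard errors come from the linear model, with the
delta method for $\gamma = e^{\log\gamma}$; in fixed-$2/3$ mode the
exponent standard error is reported as exactly 0. Note one property worth
knowing: under a uniform rescaling of all lengths, the fitted exponent is
invariant in both modes, but $\gamma$ is exactly invariant only in
fixed-$2/3$ mode (in free mode the deviation of $\hat\beta$ from $2/3$
couples the intercept to the unit choice).

The growth-law companion `fit_growth_law()` fits $V = V_0 e^{\alpha\kappa}$
log-linearly; combining the two laws gives the testable prediction
`sv_ratio_prediction()`: $S/V \approx 2\pi V_0^{-1/3} e^{-\alpha\kappa/3}$,
a negative correlation between surface-to-volume ratio and growth rate —
slow-growing cells raise $S/V$, favouring nutrient uptake.

## The division model

The mechanistic core couples three processes per cell:

1. **Elongation**: $dL/dt = kL$, exponential at rate $k$ (1/h).
2. **Division-protein accumulation**: FtsZ is produced in proportion to
   cell length at rate $k_P$ (molecules/(µm·h)). In the two-component
   form, cytoplasmic and ring-bound pools exchange:
   $$\frac{dP_c}{dt} = -k_b P_c + k_d P_r + k_P L, \qquad
     \frac{dP_r}{dt} = k_b P_c - k_d P_r,$$
   with binding much faster than growth ($k_b \gg k_d$, $k_b \gg k$). In
   that limit all newly made protein is promptly ring-bound and the model
   reduces to the *simple accumulation* form $dP/dt = k_P L$, the package
   default. The cell divides when the (ring-bound) amount reaches a
   threshold proportional to the **circumference**, $P_0 = \rho \pi w$,
   preserving the ring density $\rho$ (molecules/µm).
3. **Width control**: surface synthesis proportional to volume,
   $dS/dt = \beta V$, yields for a spherocylinder
   $$\frac{dw}{dt} = w\left(k - \frac{\beta w}{4}\right)
     \frac{1 - w/3L}{1 - w/L},$$
   with stable fixed point $w = 4k/\beta$. Empirically $\beta$ increases
   linearly with growth rate, $\beta(k) = 3.701\,k + 0.996$ (1/(h·µm)),
   which `beta_of_k()` implements.

At constant width the simple mode integrates in closed form
(`analytic_cycle()`): division occurs after
$T = k^{-1}\ln(1 + \rho\pi w k / (k_P L_{birth}))$ and the added length is

$$\Delta L = \frac{\rho \pi w\, k}{k_P},$$

independent of birth length — the **adder**, and the origin of aspect-ratio
homeostasis: the homeostatic newborn length is $\Delta L$, so the newborn
aspect ratio is $\Delta L / w = \rho\pi k / k_P$, set purely by the balance
of elongation and protein production, independent of $\beta$, width, and
nutrient condition. Division is binary with fractions $0.5 \pm \delta$,
$\delta \sim N(0, 0.05)$.

### Parameters, defaults, and the one calibration

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| $k$ | elongation rate | 1/h | 0.75 |
| $k_P$ | FtsZ production per unit length | molec/(µm·h) | $\rho\pi k/2.83$ |
| $\rho$ | ring density at completion | molec/µm | 1 |
| $k_b$, $k_d$ | ring binding / disassembly | 1/h | $100k$, $k_b/100$ |
| $\beta$ | surface synthesis relative to volume | 1/(h·µm) | $\beta(k)$ |
| $\sigma_\delta$ | division asymmetry SD | — | 0.05 |

Only the ratio $\rho\pi k/k_P$ is observable, so $\rho$ is fixed at 1 and
$k_P$ is calibrated from a **newborn aspect-ratio target** of 2.83. This is
the package's one calibrated number: over an exponential division cycle a
newborn at $\eta = 2.83$ sweeps up to $2\eta$ at division, giving a
snapshot-averaged aspect ratio of $\eta/\ln 2 \approx 4.1$, consistent with
the steady-state population value. It is a calibration to a printed summary
statistic, not a fitted microscopic constant.

The two-component defaults honour the fast-binding regime. The reduction to
simple mode is not instantaneous, though: the division time lags the
simple-mode time by $O(1/(k_b T))$ because an extra $\sim k_P L / k_b$
molecules sit in the cytoplasm at any moment. At $k_b = 100k$ that is a
$\sim$1–2% effect at the default calibration, vanishing as $k_b$ grows; the
test suite asserts exactly this convergence law against the closed-form
oracle. `kb`/`kd` are exposed as scannable parameters rather than fixed
"true" values.

## Numerical scheme

The coupled ODEs are smooth and non-stiff at these rates, so the engine
uses fixed-step classical Runge–Kutta (RK4), vectorised across an ensemble
of cells; the single-cell default step is `min(0.001 h, 0.01/k)` and
ensemble protocols default to 0.002 h, where RK4 error is far below
sampling noise. What dominates accuracy is the *division event time*, so
the threshold crossing $P = \rho\pi w$ is located inside the step by
bisection (52 halvings, i.e. to machine precision in the step) on
interpolants: length and, in simple mode, accumulated protein are evaluated
**exactly** from the exponential solution within the step; width and the
two-component pools use cubic Hermite interpolation, consistent with RK4's
fourth order. The daughter then completes the remainder of the step; a step
so large that a second division would fall inside it is rejected as an
error rather than silently mis-handled.

Degenerate-input choices: the width ODE's shape factor is singular at
$L = w$, so the rate clamps $L$ at $1.001\,w$ (newborns in all supported
regimes satisfy $L > w$ comfortably; the clamp exists to make the function
total). Daughter fractions are redrawn outside $[0.1, 0.9]$ — an
$8\sigma$ event at the default noise, so the truncation is cosmetic.
Division resets $P = 0$ (two-component: $P_r = 0$, $P_c = P^*$, with
$P^* = 0$ by default since it cancels from every observable); daughters
inherit the mother's width unchanged, since hemispherical-cap bookkeeping
is ignored consistently with the $S$, $V$ conventions above.

## Ensemble protocols

A population here is a **fixed-size ensemble of independent lineages**, one
daughter kept at random per division — mother-machine semantics. Tracking
every descendant would grow exponentially; the lineage ensemble keeps cost
linear and matches the single-cell data source this model family was built
on. Lineage sampling weights cells differently from a true exponentially
growing population (which over-represents fast divisions), but in this
noise model the steady-state *newborn* aspect ratio — the homeostatic
observable — is unaffected. Lineages are initialised at uniformly random
phases of the analytic cycle and burned in for 10 generations (configurable)
before anything is recorded.

**Nutrient shifts** (`run_protocol()`): at $t = 0$, $k$ steps to its
post-shift value, $\beta$ follows $\beta(k)$ instantaneously (the source
protocol is silent on a relaxation time; instantaneous is the cleanest
reading and is the default), and $k_P$ is rescaled to keep $k/k_P$ — and
hence the homeostatic aspect ratio — unchanged: a nutrient shift moves
$k/\beta$ (width) but not $k/k_P$. The transient in the newborn aspect
ratio then has a clean mechanism: width relaxes within a cell cycle toward
the new $4k/\beta$, while birth *length* can only relax through successive
divisions (the adder halves the gap each generation), so a downshift
(width shrinks first) transiently raises $\eta$ and an upshift dips it,
with recovery over a few generations, faster in faster media
($\propto 1/k$). Newborn aspect ratios are binned at 10 min.

**FtsZ knockdown** (`run_ftsz_knockdown()`): width fixed at 1 µm (width
dynamics off), $k_P$ scaled to 40% (configurable); steady-state newborn
length rises by exactly $1/0.4 = 2.5$ via the adder relation, and the
emitted S–V trace bends toward $S \propto V$ as cells lengthen at fixed
width. Zero production filaments without bound; lengths are then capped at
a configurable maximum and flagged.

**MreB depletion and filamentation** (`run_mreb_depletion()`,
`run_filamentation()`): the source experiments were matched by varying
$\beta$ (width) and $k_P$ together at effective aspect ratios of about 2.7
(widths 0.9–1.8 µm) and 11.0 (widths 0.9–1.4 µm) respectively. No
functional form for the co-variation is given, so the package's sweep
**reconstruction** holds the newborn aspect-ratio target fixed
($k_P = \rho\pi k/\eta$) while $\beta = 4k/w$ walks the width range; each
sweep point is simulated to steady state and the mean newborn shape emitted
as an S–V point. The resulting locus coincides with the constant-$\eta$
curve $S = \gamma(\eta) V^{2/3}$ — by construction in expectation, and the
tests verify the simulated loci land there within a few percent. The 11.0
is a target parameter matched to data, not a model prediction; likewise a
small caveat applies to comparing a *fitted* locus $\gamma$ with
$\gamma(\bar\eta)$ at the *mean* newborn $\eta$: division noise makes these
agree only to within sampling error, which is why the tests carry a 3%
tolerance.

## What the synthetic data emulate — and what they do not

`make_population_table()` draws volumes log-uniformly over two decades (so
the log–log fit has balanced leverage, mimicking a pooled multi-condition
compilation without modelling each source), puts surfaces on
$S = \gamma V^\beta$ with log-normal scatter ($\sigma_{\log} = 0.05$ by
default), rejects-and-redraws rows that scatter below the sphere bound,
and back-solves exact spherocylinder dimensions per row. Growth rates are
attached per volume stratum by inverting the growth law with
representative defaults ($V_0 = 0.5$ µm³, $\alpha = 1$ h).
`make_newborn_table()` draws condition-independent log-normal aspect
ratios (calibrated so the arithmetic mean is 4.14 and CV $\approx$ 14%)
around growth-rate-dependent widths $4\kappa/\beta(\kappa)$.
`make_lineage_table()` wraps the simulator itself.

These generators reproduce summary statistics, not raw data: there is no
segmentation/pixelation error, no condition-specific sample-size
imbalance, no correlated measurement error between $S$ and $V$. Passing
the recovery tests therefore shows the estimators are consistent under the
assumed noise model, not that any particular experimental fit is correct.
One deliberate feature: because newborn length fluctuates at fixed width,
a free-exponent fit to *single-cell* newborn tables sits slightly above
$2/3$ even though the population backbone is exactly $2/3$ — volume
conditions on length, so large-volume bins over-select long cells. The
generators reproduce this known deviation, and the tests assert it.

## Problem sizes and reproducibility

All randomness flows from one seed per run (recorded, along with a config
hash, in every output CSV header). Identical seed and configuration give
bit-identical event logs. Full-scale shift runs use $10^5$ lineages; the
test suite and examples run the same protocols at $10^2$–$10^3$ lineages
with correspondingly widened (and stated) tolerances — e.g. the
homeostasis checks use 1000 lineages, where 10-min newborn bins hold
enough events that a 2% band on the binned mean is several standard
errors wide. Convergence and adder checks run against closed-form oracles
at machine-level tolerances.

## Limitations

- No spatial mechanism: Z-ring positioning, Min oscillations and septum
  constriction geometry are out of scope; division is a point event.
- Protein production is deterministic given length; the only noise source
  is division asymmetry, as in the model this package implements. Real
  lineages carry growth-rate and production noise that widen
  distributions.
- The width ODE is quasi-static in the cap geometry and daughters inherit
  the mother's width; regimes where septal geometry dominates (e.g. strong
  MreB depletion toward cocci) are outside its validity.
- Species whose division licensing is additionally nutrient-gated (e.g.
  UgtP-like effectors reducing $k_P$ with $k$) will show growth-rate
  dependent aspect ratios; modelling that requires making $k_P$ a function
  of $k$, which the parameter interface permits but no default encodes.
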