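---
title: "Kinetic quantification and test-retest reliability: models and methods"
author: "petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification and test-retest reliability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

# Scope

petkin quantifies reversible radioligand binding from dynamic small-animal
PET data that arrive as extracted curves: regional time-activity curves
(TACs) averaged over acquisition frames, a whole-blood curve taken from the
heart of the image (an image-derived input function, IDIF), and a small
table of blood samples with plasma, whole-blood and intact-parent-fraction
measurements. Everything upstream of those curves — reconstruction, spatial
normalization, VOI delineation, cardiac segmentation — is out of scope.

The package was built around a use case from Huntington-disease imaging:
radioligands for mutant-huntingtin (mHTT) aggregates evaluated in zQ175DN
knock-in mice against wild-type littermates, with a 120-minute dynamic
acquisition, metabolite-corrected IDIF quantification by a two-tissue
compartment model (2TCM) and Logan graphical analysis, a late-window SUV
alternative, and a test-retest reliability battery. There is no reference
region for mHTT, so all quantification runs through the input function or
the dose-normalized SUV.

# The input function

The metabolite-corrected plasma-parent input is built multiplicatively from
the whole-blood curve:

$$C_p(t) = C_{wb}(t)\,\bigl(r_0 + r_1 t\bigr)\, f(t)$$

* $r_0 + r_1 t$ is the plasma-to-whole-blood ratio, fitted by ordinary least
  squares to the per-sample ratios (`fitPlasmaToBlood`). A linear form is
  standard for small radioligands over a two-hour window.
* $f(t) = a_1 e^{-\mu_1 t} + a_2 e^{-\mu_2 t}$ is the intact-parent
  fraction, fitted by weighted least squares (`fitParentFraction`,
  Levenberg-Marquardt from five deterministic starts). By default
  $a_1 + a_2 = 1$ is enforced: the injectate is radiochemically pure, so the
  fraction at injection time is 1. Fit weights are uniform unless replicate
  SDs are supplied; an optional extraction-efficiency pre-division (default
  off) supports counting protocols where measured fractions are not already
  efficiency-corrected.

Because correction is a pointwise product, the order of the two corrections
is immaterial; the tests assert this. A single pooled parent-fraction model
is fitted by default — appropriate when genotypes show comparable metabolite
profiles — with per-group fitting available by filtering the blood table.

The default synthetic parent-fraction model is calibrated so that
$f(0) = 1$ and $f(90\ \mathrm{min}) = 0.799$, i.e. about 80% intact parent
in plasma at 90 minutes, typical of the metabolically stable aggregate
ligands this pipeline targets. The fast decay rate is solved in closed form
from the fixed slow component, so the calibration is exact by construction.

The whole-blood samples are interpolated piecewise-linearly onto a uniform
grid (0.05 min by default). At that sampling density higher-order
interpolation makes no measurable difference to any downstream quantity.
When the whole-blood curve arrives as frame averages (the IDIF case), frame
midpoints are used as sample times and the grid is extended to the scan end
by last-value carry-forward.

# The kinetic model

The reversible two-tissue compartment model with rate constants
$K_1$ (mL cm$^{-3}$ min$^{-1}$), $k_2, k_3, k_4$ (min$^{-1}$) and fractional
blood volume $v_B$ predicts

$$C_{model}(t) = (1 - v_B)\,\bigl(h \otimes C_p\bigr)(t) + v_B\,C_{wb}(t)$$

with impulse response

$$h(t) = \frac{K_1}{\alpha_2 - \alpha_1}\Bigl[(k_3 + k_4 - \alpha_1)
e^{-\alpha_1 t} + (\alpha_2 - k_3 - k_4) e^{-\alpha_2 t}\Bigr],\qquad
\alpha_{1,2} = \tfrac12\Bigl[(k_2+k_3+k_4) \mp
\sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}\Bigr].$$

The total volume of distribution is the macro-parameter
$V_T = (K_1/k_2)(1 + k_3/k_4)$, which equals $\int_0^\infty h$.

**Numerics.** The exponential convolutions are evaluated exactly for a
piecewise-linear $C_p$ by a recursive update (implemented with a linear
recursive filter), so the only discretization error is the linear
interpolation of the input between grid points. Model curves are averaged
over each frame via the cumulative trapezoid integral interpolated at frame
boundaries; frame boundaries need not align with the grid. The discriminant
is guarded at zero and near-repeated roots ($\alpha_1 \approx \alpha_2$,
possible when $k_3 = 0$ and $k_2 \approx k_4$) are separated by a relative
$10^{-6}$ nudge of $k_4$ rather than switching to the repeated-root limit
form.

**Fitting.** `fit2tcm` minimizes $\sum_i w_i (C_{obs,i} - C_{model,i})^2$
with $w_i = \Delta t_i$ by default (longer frames carry proportionally more
counts); inverse-variance weighting can be supplied as a numeric vector.
Rate constants are optimized on the log scale — their plausible values span
two orders of magnitude, and log-scale Levenberg-Marquardt steps are far
better conditioned; $v_B$ stays linear within $[0, 0.2]$. Bounds default to
$K_1 \in (0, 2]$, $k_{2,3,4} \in (0, 1]$ min$^{-1}$. The optimizer restarts
from three deterministic starts covering slow, mid and fast kinetic regimes
plus seeded log-uniform draws (10 starts total by default); the best
weighted RSS wins, and the whole procedure is deterministic under a fixed
seed. Parameters ending at bounds are flagged, including the unidentifiable
pure-blood case ($K_1$ at its lower bound).

On the 45-frame schedule with noise-free synthetic TACs the fit recovers
$V_T$ to well under 1% across a 27-point grid of rate constants; under
Gaussian frame noise at scale 0.05 the median $|V_T|$ error stays in the
low percents. The acceptance script recomputes both numbers.

# Logan graphical analysis

For reversible tracers, the late-time regression of
$\int_0^T C_{obs}\,dt / C_{obs}(T)$ on
$\int_0^T C_p\,dt / C_{obs}(T)$ has slope $V_T$. Tissue integrals use the
trapezoid rule on frame midpoints anchored at the origin; the input is
integrated on its fine grid and read off at the midpoints. The start of the
linear segment, $t^*$, defaults to 30 min; `tStar = "auto"` picks the
smallest frame boundary at which the maximum relative residual of the
linear fit is at most 10%, skipping candidates whose segment still contains
nonpositive frames.

Two properties are worth stating because the tests rely on them:

* Linearization bias is nonpositive: with a finite $t^*$ and slow $k_4$ the
  slope slightly underestimates the analytic $V_T$ (about 3% at
  $t^* = 30$ min for the slowest synthetic kinetics used here), and noise in
  $C_{obs}$ adds a further nonpositive median bias. A fractional blood
  volume in the TAC adds a separate small negative bias because the blood
  contribution is not part of the Logan model; the analytic-agreement tests
  therefore use $v_B = 0$, while fitting tests keep $v_B$ free.
* The slope is invariant to a common rescaling of TAC and input, and scales
  as $1/c$ when only the input is scaled by $c$.

**Time stability.** `timeStability` truncates the acquisition to each
requested duration, keeps $t^*$ fixed, and reports $V_T$ as a percentage of
the full-scan value. Slow kinetics ($k_4$ of a few $10^{-3}$ min$^{-1}$)
underestimate $V_T$ at 60 min by design; fast kinetics sit within a few
percent of 100% at all durations. This mirrors the practical question of
whether shorter scans are admissible: when the genotype with higher binding
also has the slower kinetics, truncation shrinks the measured group
difference.

# SUV

`computeSuv` averages the frames lying fully inside the late window
(default 100–120 min, exactly the last four 300-s frames of the default
schedule; partial frames are excluded rather than weighted) and divides by
injected dose over body weight. With concentrations in kBq/mL, dose in MBq
and weight in g, SUV comes out in g/mL. Activities are assumed
decay-corrected to injection time throughout; the F-18 half-life
(109.8 min) is only used by the optional `decayedDose` utility.

# Test-retest battery

For paired sessions, per animal and region:

$$\mathrm{rTRV} = 100\,\frac{\mathrm{test} - \mathrm{retest}}
{\mathrm{mean}(\mathrm{test}, \mathrm{retest})},\qquad
\mathrm{aTRV} = |\mathrm{rTRV}|.$$

Bland-Altman agreement uses the rTRV values as the per-animal differences:
bias is their mean and the limits of agreement are bias ± 1.96 SD with the
$n-1$ sample SD (the estimator is not specified in common practice; the
sample SD is the conservative choice).

The ICC comes from a REML mixed model: genotype, session and their
interaction as fixed effects, animal as a random intercept, with
$$\mathrm{ICC} = \frac{\sigma^2_{animal}}
{\text{sum of positive variance components}}.$$
Negative component estimates are truncated at zero and excluded from the
denominator. Random animal-by-genotype and animal-by-session interaction
terms can be enabled by flag; on balanced two-session designs they
typically estimate to zero and leave the ICC unchanged, which is why they
are off by default. ICC is computed per region and metric, pooling
genotypes.

One numerical detail: derivative-free optimizers used by mixed-model
software stop within about $10^{-7}$ of the REML optimum, which is visible
when comparing against the closed-form one-way ANOVA estimator on balanced
data (an exact algebraic identity). `iccReml` therefore polishes the
variance-ratio parameter with coordinate-wise Newton steps on the REML
deviance before extracting components; `iccAnova` provides the closed-form
estimator as an independent cross-check.

# Group statistics and planning

Effect sizes are Cohen's $d$ with the pooled SD; genotype percent
differences are expressed relative to the wild-type mean, so a doubling
reads as +100% (this convention matters and is easy to get wrong — it is
stated here because group differences above 100% are routinely reported for
high-binding regions). When both groups have zero spread, the percent
difference is still defined but $d$ is returned as `NA` with a warning.

Sample sizes for a one-tailed two-sample t-test ($\alpha = 0.05$, power
0.80 by default) are found by iterating the exact noncentral-t power
$1 - F_{t,2n-2}\bigl(t_{1-\alpha,2n-2};\ \delta = d\sqrt{n/2}\bigr)$ over
integer $n$, the same algorithm class as the standard power tools. The
returned $n$ satisfies a minimality contract: power $\ge$ target at $n$ and
$<$ target at $n - 1$; tests verify this against both `stats::power.t.test`
and a $10^5$-replicate Monte Carlo oracle. `dForRelativeDifference` encodes
one explicit convention for converting an anticipated relative group
difference into $d$ — the difference is taken against the reference-group
mean and divided by the pooled SD — because published power statements
rarely say which mean and which SD they used.

The mass-dose relationship (self-blocking: $V_T$ declines with increasing
injected mass) is modeled with a four-parameter logistic on
$x = \log_{10}(\mathrm{mass})$, and `massAtDrop` inverts it to report, for
example, the mass at which $V_T$ has lost half the asymptote span — the
basis for capping injected mass in study protocols (1 µg/kg in the
motivating use case).

# The synthetic-data generator

The generator exists so that every downstream stage has a recoverable
ground truth; its defaults are the study conditions under which the test
suite and the acceptance script operate.

* **Whole-blood bolus**: a delayed Feng-type tri-exponential,
  $(A_1 s - A_2 - A_3)e^{-\lambda_1 s} + A_2 e^{-\lambda_2 s} +
  A_3 e^{-\lambda_3 s}$ with $s = t - \tau$ — zero before arrival,
  linear rise, peak inside two minutes, biexponential washout. Chosen for
  closed-form integrability and because any smooth bolus-like form
  suffices for exercising the pipeline.
* **Plasma correction**: ratio $1.1 + 0.001t$ and the calibrated parent
  fraction above.
* **Kinetics by genotype**: the binding effect enters through $k_3$
  (WT 0.015, HET 0.06 min$^{-1}$) with $K_1 = 0.3$, $k_2 = 0.15$,
  $k_4 = 0.03$, $v_B = 0.03$ shared, giving true $V_T$ of 3 vs 6 mL/cm$^3$.
  Binding-site density is the genotype-dependent quantity, so $k_3$ is the
  natural carrier of the effect; it is configurable.
* **Frame noise**: zero-mean Gaussian with SD
  $\mathrm{scale}\cdot\sqrt{C_{model}/\Delta t}$ — the count-statistics
  heuristic under which short early frames are noisiest. Scale 0.05
  corresponds to a visually realistic TAC for mouse-brain VOIs.
* **Test-retest cohorts**: animal value = genotype mean + between-animal
  effect ($\sigma_b$) + session noise ($\sigma_w$), two sessions per
  animal, so the generative ICC is $\sigma_b^2/(\sigma_b^2+\sigma_w^2)$
  exactly.
* **Study fixture**: `writeSyntheticStudy` emits a full two-genotype,
  two-session directory (TACs for five brain regions with region-dependent
  binding, a frame-averaged IDIF, pooled blood table at 5/15/30/60/90 min,
  subject table with doses near 4.1 MBq and weights near 30 g).

What the generator does **not** emulate: voxel-level noise correlation,
reconstruction artifacts, motion, dispersion/delay of the input (the
synthetic input is taken as the true plasma curve), or non-Gaussian frame
noise. Passing tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every failure mode of real data.

All randomness flows through explicit integer seeds; two runs with the same
seed are bit-identical, including the full pipeline reports.

# Problem sizes and reproducibility

The validation studies use deliberately modest sizes chosen to give stable
statistics: a 27-point parameter grid and 100 noisy replicates for fit
recovery, 500-animal cohorts for coverage and variance-component checks,
200-animal cohorts (with a median over 9 draws) for ICC recovery, and a
2-animals-per-genotype pipeline fixture for the determinism check.
`scripts/acceptance.R` recomputes all headline quantities from scratch for
any seed.

# Known limitations

* Logan $V_T$ inherits the classic noise-dependent and truncation biases;
  the 2TCM fit is the less biased estimator and both are always reported.
* $v_B$ is fitted within $[0, 0.2]$ by default; with very low binding the
  $K_1$/$v_B$ trade-off can leave $v_B$ at a bound (flagged).
* The ICC denominator under extended random structures is ambiguous when
  the extra components are positive; the default structure avoids the
  ambiguity and the flag-enabled mode simply includes all positive
  components in the denominator.
* No confidence intervals on ICC, and no repeated-measures or mixed-design
  power planning.
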