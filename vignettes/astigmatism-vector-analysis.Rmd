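---
title: "Power-vector analysis of corneal astigmatism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-vector analysis of corneal astigmatism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigvec)
```

## The problem

Two instruments routinely measure corneal astigmatism before cataract
surgery: automated keratometry (AK), which samples the anterior surface
near the 2.5 mm ring under a fixed keratometric index, and ray-traced total
corneal refractive power (TCRP) from Scheimpflug tomography, which
propagates rays through both corneal surfaces and averages a pupil-centered
zone (3 or 4 mm). On regular corneas they agree; on irregular corneas they
can diverge enough to change a toric-IOL plan. This package implements the
vector framework needed to quantify that divergence and to ask, per eye,
which modality better predicted the refraction the patient actually ended
up with.

## Representation and metrics

Astigmatism is a magnitude-and-meridian quantity, so arithmetic on raw
(cylinder, axis) pairs is meaningless across the 0°/180° wrap. The standard
remedy is the double-angle (Jackson) representation

$$J_0 = \tfrac{C}{2}\cos 2A, \qquad J_{45} = \tfrac{C}{2}\sin 2A,$$

with $C$ the positive cylinder and $A$ the flat meridian in degrees. In
this Cartesian space astigmatisms add, subtract and average like ordinary
vectors; `cyl_to_pv()` / `pv_to_cyl()` convert in both directions, using
`cospi`/`sinpi` so cardinal meridians stay numerically exact.

All difference quantities — the inter-modality discrepancy
$\Delta_{\mathrm{TCRP-AK}}$ and ocular residual astigmatism (ORA) — are
Euclidean distances $\sqrt{\Delta J_0^2 + \Delta J_{45}^2}$. Note the
scale: this is the J-space distance, *half* the cylinder that would express
the same astigmatic difference. Some authors double it; we keep the
undoubled form as the default because it is the literal "root of the sum of
squared J-differences" and expose `as_cylinder = TRUE` everywhere the
quantity is computed for readers who want cylinder scale. The tests pin the
metric to an independent oracle: sampling the meridional half-power profile
$F(\theta) = \frac{C}{2}\cos 2(\theta - A)$ of both astigmatisms on a 1°
grid and taking $\sqrt{\mathrm{mean}\, 2\,\Delta F(\theta)^2}$ reproduces
the vector distance to $10^{-6}$.

## From manifest refraction to ORA

The postoperative manifest refraction is measured at the spectacle plane;
keratometry lives at the cornea. Each principal meridian power $F$ (sphere
and sphere + cylinder) is transported with

$$F_c = \frac{F}{1 - d\,F},$$

$d$ = 0.012 m by default, and the spherocylinder reassembled with the same
axis. We transport meridians, not (sphere, cylinder) directly, because the
formula is a single-power relation and the meridian-wise application is the
optically correct extension; it also makes the map exactly invertible
(`refraction_to_spectacle_plane()` uses $-d$), which the tests exploit as a
round-trip property. Refractions may arrive in negative-cylinder clinical
notation; they are transposed internally to the positive-cylinder,
flat-meridian convention before decomposition, and transposition provably
commutes with the transport.

The cataract incision itself flattens the cornea. A temporal clear corneal
incision with SIA magnitude $m$ flattening the horizontal meridian has
flattening vector `sia_flattening_vector(m, 0)`; for $m = 0.40$ D that is
$(J_0, J_{45}) = (0.20, 0)$. Because per-eye SIA cannot be estimated
without postoperative keratometry, the analysis applies assumed SIAs of 0,
0.20 and 0.40 D, giving refraction variants RA, RA1, RA2. The sign of the
application is a genuine ambiguity: we *add* the flattening vector back to
the postoperative refraction (default `sia_sign = +1`), so preoperative
keratometry and the SIA-restored refraction are compared on the same basis,
and expose `sia_sign = -1` for sensitivity analysis. ORA is then the
J-space distance between a keratometry vector (AK, TCRP3 or TCRP4) and the
adjusted refraction — nine values per eye under the defaults
(`compute_ora_set()`).

## Cohort analysis

`analyze_cohort()` derives per-eye columns and four summary tables. Axis
classification: with-the-rule iff the steep AK meridian lies in the
*closed* interval [45°, 135°] — the boundary is measure-zero in practice
and the closed reading is the most literal one. Eyes with zero AK cylinder
have no meridian; rather than invent a label they are excluded from the
axis-classified tables with a logged count and retained everywhere else.
Irregularity groupings threshold the Fourier-analysis irregularity index IR
(mm) at the cohort median (grouping 1) and at mean + 2 SD (grouping 2),
with `high` defined by $IR \ge$ threshold. Thresholds are recomputed from
the analyzed cohort by default because the published cut-offs (0.036 and
0.077 mm) are statistics of one particular 207-eye cohort, not constants;
`ir_grouping = "fixed"` reproduces them exactly when wanted.

Group comparisons use the equal-variance Student t test and the
Mann–Whitney U test (both reported — the field uses either depending on
normality); paired AK-vs-TCRP ORA contrasts within the high-IR subgroup use
the paired t test plus a Pearson correlation. No multiplicity correction is
applied; p-values are reported raw. A degenerate paired test (all
differences zero) reports p = 1 with a warning rather than NaN.

The regression of interest is "logarithmic": published wording of such
analyses is often ambiguous about *what* is logged, and printed equations
on the raw scale can be dimensionally inconsistent with a logged response.
We therefore fit $\ln y$ on raw-scale predictors (`fit_log_linear()`,
response must be strictly positive; zero deltas are dropped with their
count) *and* emit the raw-scale OLS fit alongside, so neither reading is
lost. Both reduce to `lm()`; the tests check the log fit against explicit
normal equations.

## The synthetic cohort

`generate_cohort()` emulates an elderly cataract-surgery population so that
every pipeline stage is exercisable without patient data. Generation order
and defaults (all overridable via `sim_params()`):

* **Age** ~ N(68.25, 11.33²) years, truncated to 40–95 by resampling.
* **IR** log-linear in age: $\ln IR = -4.41 + 0.0168\,\mathrm{age} +
  N(0, 0.387^2)$, floored at 0.005 mm. These values are solved, not tuned:
  they give mean ≈ 0.042 mm, SD ≈ 0.019 mm and an age–IR correlation ≈
  0.44 simultaneously.
* **Axis class** logistic in age: $P(\mathrm{ATR}) =
  \mathrm{logit}^{-1}(-4.23 + 0.062\,\mathrm{age})$, chosen so ATR eyes run
  about 8 years older at a roughly even split; the flat meridian is jittered
  (SD 15°) around 0° (WTR) or 90° (ATR), resampling draws that would flip
  the intended class. No joint axis–magnitude distribution is published for
  such cohorts; the logistic-age model is an emulation choice, documented
  as such.
* **AK magnitude** lognormal($\ln 0.9$, 0.5) D, truncated to 0.1–6 D
  (mean ≈ 1 D).
* **TCRP discrepancy**: magnitude $\exp(-2.14 + 0.01\,\mathrm{age} +
  4.0\,IR + 0.25\,AK + N(0, 0.6^2))$ D — positive age/IR/AK effects with a
  mean near 0.43 D — with uniform direction in double-angle space;
  TCRP3 = AK + discrepancy, TCRP4 = AK + 0.9 × discrepancy (the damping
  mirrors the smaller 4 mm-zone discrepancy).
* **Postoperative refraction**: TCRP3 is the generative "true cornea"
  (configurable to AK for falsification tests); the corneal-plane
  refractive astigmatism is truth − SIA(0.40 D @ 0°) + bivariate noise of
  SD $0.20(1 + 5\,IR)$ D per component, so irregular corneas refract more
  noisily; the spherical equivalent is N(−0.25, 0.40²) D; the result is
  transported to the spectacle plane by the inverse vertex map and stored
  in negative-cylinder notation.
* **Radii**: anterior ≈ N(7.7, 0.25²) mm; the anterior/posterior ratio
  falls with IR (1.25 − 1.2 IR + noise), so high-IR eyes have the lower
  ratio. Irregular astigmatism (µm) is log-linear in $\ln IR$; spherical
  aberration is ≈ 0.33 µm (WTR) / 0.41 µm (ATR).

Everything is driven by one integer seed; a fixed seed gives byte-identical
CSV output.

What passing tests on this cohort do and do not show: they demonstrate that
the *pipeline* is correct — the noise-free limit returns ORA(TCRP3) = 0
exactly and ORA(AK) equal to the injected discrepancy; regression recovers
the injected coefficients within sampling error; the high-IR subgroup shows
smaller TCRP than AK ORAs *because the generator builds that in*. They say
nothing about real corneas: real measurement error is not isotropic in
J-space, axis and magnitude are not independent, triplicate-averaging
artifacts and device-specific biases are absent, and the "true cornea"
designation is an assumption, not a finding.

## Numerical choices and limitations

Angles are degrees throughout the public interface (radians only
internally). Zero-magnitude cylinders store axis 0 by convention; the zero
power vector maps back to (0 D, 0°). `normalize_axis()` guards the
floating-point wrap where `x %% 180` can return exactly 180 for tiny
negative inputs. Vertex conversion refuses inputs within 1e−9 of its
singularity $dF = 1$. Truncated distributions are sampled by resampling
(not clipping), preserving distributional shape near the bounds.

Problem sizes used by the checks — 10,000 round-trip cylinders, 1,000
oracle pairs, cohorts of 1,000–2,000 eyes, 20 recovery seeds — are the
package's chosen balance of statistical resolution against a test suite
that runs in seconds.

Out of scope by design: device file parsing and image acquisition, the
Fourier analysis that produces IR (IR is an input), per-eye SIA estimation,
IOL power formulas, full Alpins-style analysis (target induced astigmatism,
correction indices), and three-component power vectors carrying the
spherical equivalent M (M is carried only inside the spherocylinder type).
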