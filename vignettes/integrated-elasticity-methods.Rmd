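---
title: "Methods: the integrated-elasticity regression and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrated-elasticity regression and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ielastic)
```

## The model

Parallel-plate compression of a whole multicellular cluster produces a
force–displacement curve whose shape is governed by how the contact area
grows as the plate advances. Two limits are solved exactly by classical
contact mechanics. A constant planar, parallel, frictionless and
adhesion-free contact gives a linear law, $F = (\pi x^2/4h)\,E\,\delta$,
for a cylindrical sample of diameter $x$ and rest height $h$. A spherical
sample gives the Hertz law, $F = \tfrac{4}{3} E \sqrt{R}\, \delta^{3/2}$.
Both are power laws $F = E\,C\,\delta^{\alpha}$ differing only in $(C,
\alpha)$.

The integrated-elasticity (IE) regression treats the exponent as a
per-sample fit parameter and interpolates the prefactor between the two
solved limits:

$$C(\alpha, x, h) = 2\left[(1.5-\alpha)\left(\tfrac{\pi}{4}\right)^{3-2\alpha}
 + (\alpha-1)\left(\tfrac{4}{3\sqrt 2}\right)^{2\alpha-2}\right]
 \left(\tfrac{x^2}{h}\right)^{2-\alpha}.$$

This expression is implemented verbatim, including its printed exponents
$(3-2\alpha)$ and $(2\alpha-2)$; no re-derivation or smoothing is applied.
At $\alpha = 1$ it reduces exactly to $\pi x^2/4h$ and at $\alpha = 1.5$,
with $x = h = 2R$, to $\tfrac{4}{3}\sqrt R$ (both identities are tested to
$10^{-12}$ relative). $x$ stands for both the width and the length of the
sample; when width and length are measured separately, an optional
geometric-mean reduction is available (`reduce_width = "geometric_mean"`)
but off by default.

The assumptions inherited from contact mechanics: the compression is
elastic (analyze the approach branch, and only small strains), the sample
is homogeneous and isotropic at macro-scale, the upper margin is coarsely
concave with curvature between planar and spherical, friction and adhesion
are negligible, and the plate is rigid. The fitted $E$ is the *effective*
elastic constant; it relates to the Young's modulus through
$1/E = (1-\nu^2)/\tilde E$. Because no accepted Poisson's ratio exists for
spheroids, the package reports $E$ as-is and converts only when the user
supplies $\nu$ (`young_modulus()`).

## Fitting: parameters and numerics

* **Strain truncation** (`truncate_to_strain()`, default fraction 0.10):
  curves are cut at $\delta \le 0.1\,h$. Ten-percent squeezing keeps
  clusters in the regime where they recover their shape on release, and
  keeps the small-deformation theory honest.
* **Objective**: sum of squared *force* residuals (default). This keeps the
  IE/linear comparison on a single objective; a log-force option exists for
  users who prefer relative weighting. Which objective the original
  analysis used is not documented anywhere we know of, so it is exposed
  rather than hidden.
* **Profiling**: given $\alpha$, $E$ enters linearly, so the least-squares
  $E(\alpha)$ is closed-form and the solver is a bounded scalar
  minimization over $\alpha$ alone (`stats::optimize`, absolute tolerance
  $10^{-8}$). The interval endpoints are always evaluated as candidates, so
  a boundary optimum is returned exactly rather than to within the
  optimizer's tolerance. This removes the scaling pathologies of a joint
  two-parameter descent and makes fits deterministic — no starting values,
  no restarts. The log–log regression slope is still computed and recorded
  in the result notes as a diagnostic.
* **Bounds**: $\alpha \in [1, 1.5]$ by default — the physically motivated
  interpolation range (planar to spherical). The prefactor is evaluable
  outside it, and the bounds are a plain argument, but estimates at a bound
  are flagged (`at_bound`) since they usually mean the model family is
  being stretched. Whether bounds should be enforced during fitting or
  merely observed afterwards is genuinely open; enforcing with a flag keeps
  both readings available.
* **Linear fits** are through the origin by default: the planar law has no
  intercept and curves are zeroed at contact. An intercept flag exists for
  drifting baselines. The two-point variant uses the first two consecutive
  points above the noise floor — a deterministic reading of "points at the
  onset of the force increase" — and reports its $R^2$ against the whole
  curve, which is exactly where its fragility shows.
* **Degeneracies**: repeated displacements (instrument step-hold phases)
  are averaged before fitting; zero-displacement points are dropped;
  all-non-positive forces are an error; optimizer failure is reported via
  `converged = FALSE` rather than an exception.
* **Units**: lengths µm, forces µN, moduli Pa, with
  $1\,\mathrm{Pa\,\mu m^2} = 10^{-6}\,\mu N$ applied inside the force and
  fit functions. Fitted $(E, \alpha)$ are invariant under geometric
  rescaling $(x, h, \delta) \to s(x, h, \delta)$, $F \to s^2 F$ (tested to
  $10^{-9}$).

## Silhouette geometry

The rest geometry of the upper 10% of a silhouette is summarized by two
numbers. Non-planarity,
$\chi = \sqrt{\tfrac1N \sum_i (y_i - \langle y\rangle)^2} / (h\langle
y\rangle)$, measures deviation of the contact-facing cap from a flat line;
smoothness $l/d$ is the chord-to-arc ratio of the same segment.

Choices the definitions leave open, and what this package does:

* **Frame for $\chi$**: the formula divides by $\langle y\rangle$, which
  depends on where $y = 0$ is. The origin is placed at the sample's lowest
  point with $y$ up, so $\langle y\rangle \approx h$ for the upper cap and
  $\chi$ is well defined. The denominator is read literally as the product
  $h\,\langle y\rangle$, giving $\chi$ units of 1/length; raw $\chi$ is
  therefore only compared through the dimensionless ratio
  $\chi_{sample}/\chi_{circle}$.
* **Circle reference**: diameter equal to the sample height (the extent
  along the compression axis sets the planarity contrast), sampled
  uniformly along its upper arc at the same point count as the measured
  segment; a width-matched option exists.
* **Sampling density**: marching-squares boundaries put up to $\sqrt 2$
  more points per unit length where the curve runs diagonal to the pixel
  grid. The normalized ratio therefore resamples the measured segment to
  uniform arc-length spacing first, so both sides of the ratio weight the
  curve by length rather than by grid crossings. With this, a rasterized
  circle of 200 px diameter reads $\chi_{norm} = 1.01$; without it, 1.02–
  1.03. `non_planarity()` itself stays a plain point-array statistic.
* **A property worth knowing**: vertical stretching is self-similar under
  the height-matched reference — the $y$-distribution over the relative
  upper window of a stretched circle equals that of the matched reference
  circle — so smooth ellipses read $\chi_{norm} \approx 1$ regardless of
  aspect ratio. What pushes the ratio above 1 is concentration of boundary
  $y$ values at the window extremes: roughness, castellation, lobes. What
  pushes it toward 0 is a genuine plateau.
* **Smoothness** uses the sub-pixel polyline with a light 3-point moving
  average before the arc length (raw mode available): staircase zigzag
  otherwise inflates $d$ by about 1% at 200 px diameter and more at small
  sizes. The upper-10% arc of an ideal circle has
  $l/d = 1.2R / 1.28700R = 0.93240$, used as an oracle in the tests.
* **Upper-fraction selection** takes the connected contour run containing
  the topmost point with $y \ge y_{max} - f\,h$. On a strongly flattened
  shape this window inevitably dips below the plateau onto the shoulders,
  so a fully flattened *mask* reads $\chi_{norm} \approx 0.6$, not 0;
  exactly 0 is reached by a perfectly flat contour segment. The monotone
  ordering — flatter caps never score above rounder ones — is the tested
  property.

## The synthetic generators

`simulate_curve()` draws displacements evenly on $(0, f\,h]$ and evaluates
the chosen force law exactly, adding Gaussian noise with standard deviation
`noise_rel` times the maximum noise-free force (additive by default;
multiplicative as an option — instrument noise specifications differ and no
noise model is canonical here). `simulate_mask()` builds a radial outline
$r(\theta) = R[1 + \text{roughness}(\theta)]$ from three seeded harmonics
at the bump frequency and its first two multiples (amplitude-normalized so
the outline stays simple below `roughness_amp` 0.3), then squashes the
upper half toward the equatorial plane by `cap_flattening`: 0 is a
spherical cap, 1 a flat-topped half-disk. `simulate_cohort()` draws
per-sample $(E, \alpha, x = h)$ from user distributions and derives
per-curve seeds from one master seed, so cohorts are bit-reproducible.

Default study conditions used across the test-suite recovery studies: 50
points per curve, 10% strain, 5% relative noise, spheroid sizes of order
100–500 µm and moduli of order $10^2$–$10^3$ Pa; noise-recovery checks use
200 curves per exponent and the cohort size-independence check uses 80
samples. These sizes keep the whole suite under a few seconds while leaving
the Monte-Carlo medians far from their thresholds.

What the generators deliberately do *not* emulate: viscoelastic relaxation
and hysteresis (only the approach branch is modeled), adhesion, force
drift, cell-scale texture in masks, or 3D surface structure. Passing
recovery tests on these synthetic curves shows the estimator is correct for
the model family and robust to additive noise — it does not certify
real-tissue behavior where those excluded effects are present.

## Reference samples and relative moduli

Absolute moduli from parallel compression lack an accepted validation
reference, so comparisons are most reliable as ratios. `fit_cube_linear()`
implements the cube-specific linear law $F = L E \delta$;
`cube_effective_diameter()` maps a cube to the equal-volume sphere diameter
$L(6/\pi)^{1/3}$ used as $x = h$ in its IE fit. `relative_modulus()`
enforces that numerator and denominator come from the same model family —
the entire point of the construction — and `cohort_ratio()` reports a
ratio of group means with a seeded bootstrap percentile interval (whether
historical ratio figures were ratios of means or means of ratios is not
stated anywhere; ratio-of-means is the default, the other is a flag, and
the bootstrap is this package's addition since no uncertainty procedure is
prescribed). The nominal fabrication stiffness of a gel (e.g. 1 kPa) is
carried as metadata only and never substitutes for a fitted $E^{ref}$.

## Known limitations

* The IE prefactor is an interpolation ansatz, not a derived solution;
  between its endpoints it is plausible, smooth and dimensionally
  consistent, but carries no error bound.
* $\alpha$ and $E$ are correlated in the fit; on short or noisy curves the
  profile in $\alpha$ is shallow and single-curve $E$ estimates inherit
  that uncertainty (the Monte-Carlo tests quantify it under the stated
  conditions).
* Surface roughness violates the smooth-contact assumption underlying all
  the force laws here; the geometry metrics flag it but the fits do not
  correct for it.
* $\chi$ as printed is frame- and scale-dependent; only the normalized
  ratio should be compared across samples, and only with the same
  `fraction` and reference convention.
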