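---
title: "Characterizing in-air proton spot fluence from field size factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing in-air proton spot fluence from field size factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotfluence)
```

## The problem

A pencil-beam-scanning (PBS) proton machine paints dose spot by spot. When a
fixed range shifter (RS) sits at the nozzle exit, scattering in the slab
broadens every spot and adds a long low-dose lateral tail. A treatment
planning system that models the in-air fluence of one spot as a **double
Gaussian**

$$\phi(r) \;=\; \Phi\left[\frac{1-w_2}{2\pi\sigma_1^2}
  \exp\!\left(-\frac{r^2}{2\sigma_1^2}\right)
  + \frac{w_2}{2\pi\sigma_2^2}
  \exp\!\left(-\frac{r^2}{2\sigma_2^2}\right)\right]$$

needs, per energy $E$ and measurement plane $z$, the core width
$\sigma_1(E,z)$, the halo width $\sigma_2(E,z)$, and the halo weight
$w_2(E)$ (the weight depends on energy only). Measuring the faint tails
directly is slow and error-prone. This package implements the indirect
route: **field size factors** (FSFs).

Deliver a uniform square array of spots with spacing $SS$ and side $FS$;
the fluence at the field center is the lattice sum

$$PF(FS) \;=\; \sum_{i=-N}^{N}\sum_{j=-N}^{N}
  \phi\!\left(\sqrt{(i\,SS'_x)^2 + (j\,SS'_y)^2}\right),
  \qquad N = \tfrac{1}{2}\,FS/SS,$$

where $SS'_a = SS\,(VSAD_a + z)/VSAD_a$ is the spacing projected onto the
plane at offset $z$ through the virtual source-to-axis distance of each
scanning axis. The FSF is $PF(FS)/PF(10\,\mathrm{cm})$. Because the center
of a large field accumulates the tails of *every* spot, FSFs over a range
of field sizes encode the whole profile: small fields pin down $\sigma_1$,
large fields $\sigma_2$ and $w_2$.

## Conventions and geometry

* All lengths are millimetres internally; field sizes are quoted in cm
  (the field convention) and converted at the interface.
* Plane offsets $z$ are signed, measured from isocenter, positive
  downstream (away from the nozzle). The five-plane default is
  $z \in \{-200, -100, 0, +100, +200\}$ mm. Which sign is "toward the
  nozzle" is a package convention — the physical direction depends on how
  the couch is moved, and only consistency matters for the fit.
* The source-to-plane distance is written $VSAD + z$, so no separate
  SSD/depth bookkeeping exists for in-air planes.
* VSADs are configuration, not constants; the default is 2000 mm on both
  axes, with a `parallel = TRUE` switch for idealized-geometry work.
* Field size is measured center-to-center of the edge spots. A field size
  that is not an even multiple of the spacing is **rejected**, not
  rounded: silent rounding changes FSFs at the 0.1% level, which is the
  same order as the measurement noise.

## Forward model and numerics

The isotropic Gaussian lattice sum factorizes,
$\sum_{ij} e^{-(i^2 a + j^2 b)} = \sum_i e^{-i^2 a}\sum_j e^{-j^2 b}$, so
`central_fluence()` costs $O(N)$ per Gaussian rather than $O(N^2)$; the
full grid is always summed (at most $41^2$ spots for a 20 cm field at 5 mm
spacing — no truncation or series acceleration is warranted at this
scale). The test suite checks the separable path against a brute-force
double summation to $10^{-12}$ relative. The per-spot amplitude cancels
exactly in every FSF, and the FSF at the reference field size is exactly 1
by construction.

```{r forward}
geom <- beam_geometry()           # 2000 mm VSADs, 5 mm spacing, 5 planes
p <- spot_params(7, 20, w2 = 0.1) # RS-like spot
sapply(c(2, 4, 6, 8, 10, 20), function(fs) fsf(p, geom, 0, fs))
```

## Measurement design: one spiral, six field sizes

`spiral_pattern()` orders the spots of the largest (20 cm) field
center-outward by Chebyshev ring, with control points pausing the beam
after each nested square sub-field (2, 4, 6, 8, 10 cm). Every completed
ring closes a nested square, so the cumulative charge at control point $k$
is the central fluence of field size $k$ — six field sizes from one
delivery. Within a ring, spots are ordered counter-clockwise by angle from
the +x axis; only the prefix property matters for the FSFs, the in-ring
order is a free choice. `cumulative_fsf_from_charges()` converts the
readings to FSF records by normalizing to the 10 cm reading.

## Fitting

`fit_energy()` minimizes the unweighted sum of squared *relative*
differences between modeled and measured FSFs, jointly over all planes of
one energy: $\sigma_1$ and $\sigma_2$ free per plane, $w_2$ shared across
planes (11 parameters from 25 records in the default design). Relative
differences are used because that is the scale on which agreement is
reported and judged; with ratios near 1 the distinction from absolute
differences is minor. Bounds are $\sigma_1 \in [0.5, 30]$ mm,
$\sigma_2 \in [\sigma_1, 150]$ mm, $w_2 \in [0, 0.5]$.

The optimizer is deterministic and derivative-free:

1. **Coarse grid** — 20 log-spaced $\sigma_1$ candidates in $[1, 20]$ mm
   $\times$ 10 ratios $\sigma_2/\sigma_1 \in [1.5, 10]$ $\times$ 11
   weights $w_2 \in [0, 0.3]$. For fixed $w_2$ the objective separates by
   plane, so the exact grid minimum is the sum of per-plane minima. Ties
   break toward smaller $\sigma_1$, then smaller $w_2$.
2. **Refinement** — at each grid $w_2$, Nelder-Mead polishes
   $(\log\sigma_1, \log(\sigma_2/\sigma_1 - 1))$ per plane. The objective
   has a second basin where a very wide $\sigma_2$ imitates a flat
   pedestal; refinement therefore starts from the best grid candidate of
   each of several distinct ratios and keeps the best outcome. A final
   golden-section pass polishes $w_2$ between the neighbouring grid
   points.
3. The returned optimum is never worse than the best coarse-grid
   candidate, and `fit_settings(refine = FALSE)` recovers the pure
   grid-search answer.

On noise-free double-Gaussian data the fit recovers the generating
parameters essentially exactly (residuals $<10^{-6}$). Under realistic
0.2% noise an **identifiability caveat** applies: where the spot is small
compared with both the spacing and the smallest field, the FSFs respond
only weakly to $\sigma_1$, and the fitted $\sigma_1$ can wander far from
truth while every *predicted FSF* stays within a fraction of a percent.
The fit is a fluence-prediction tool, not a spot-profilometer; judge it by
FSF residuals (via `fit_quality_summary()`), which is also how the
sensitivity analysis says it should be judged.

## Sensitivity

`perturb_and_compare()` performs one-at-a-time perturbations (default
$\sigma_1\pm10\%$, $\sigma_2\pm20\%$, $w_2\pm20\%$) and reports the
relative FSF change per field size. For an RS-like spot
($\sigma_1 = 7$ mm, $\sigma_2 = 20$ mm, $w_2 = 0.1$, 5 mm spacing), a
+10% $\sigma_1$ change moves the 2 cm FSF by 6.2% while $\sigma_2$
changes of $\pm$20% move it by about 0.4–1.1%; at 20 cm the ordering
inverts. Perturbations that would violate $\sigma_2 \ge \sigma_1$ are
reported as invalid cells rather than errors, so a full report is always
produced.

## Energy interpolation

A campaign measures ~10 of the ~68 energy layers; `interpolate_table()`
fills in the rest. The interpolant is a **monotone (Fritsch-Carlson)
piecewise-cubic Hermite spline** in nominal energy, chosen over a natural
cubic spline because it passes exactly through the fitted values and never
overshoots the bracketing fitted values — positivity of the widths and
$w_2 \in [0, 0.5]$ hold without clipping. Nominal energy, not range, is
the interpolation axis: the fitted quantities vary smoothly and gently in
energy, and no range calibration is assumed in air. Layers outside the
fitted range are extrapolated linearly with the boundary slope, clamped to
the parameter bounds, and flagged with a message.

## The synthetic truth machine

`truth_machine()` + `generate_campaign()` simulate a campaign with known
truth so the whole chain is testable without measured data. Defaults are
plausible RS-machine magnitudes, declared (not inferred from any
machine): $\sigma_1$ at isocenter falling linearly from 9 mm to 4.5 mm
over 80.3–175.9 MeV, growing 8% per 100 mm downstream;
$\sigma_2 = 3.5\,\sigma_1$; $w_2$ falling from 0.12 to 0.04; multiplicative
Gaussian noise with 0.2% standard deviation, the reproducibility of
repeated charge-ratio measurements. Noise can enter per FSF (`"direct"`)
or per cumulative charge reading including the reference (`"charge"`),
matching the two ways a real campaign can be reduced.

The generator can also inject a unit-normalized Lorentzian tail
($\le$10% fraction, width > $\sigma_2$) into the *generated* fluence while
the *fitted* model stays double-Gaussian — emulating the fact that real
spot profiles are not intrinsically double-Gaussian in their far tails and
producing structured residuals like those seen when fitting real data.

What the generator does **not** emulate: chamber volume averaging, setup
and centering errors, beam-current drift, charge-integration electronics,
and any in-water effect. A green synthetic acceptance therefore
demonstrates correctness of the estimation machinery under the stated
noise model, not agreement with any particular physical machine.

```{r campaign}
camp <- generate_campaign(truth_machine(), geom, seed = 1)
fits <- fit_campaign(camp$records, geom)
fit_quality_summary(fits)$overall
```

## Problem sizes and runtimes

The default study: 250 records (10 energies $\times$ 5 planes $\times$
field sizes {2,4,6,8,20} cm against 10 cm), fit of all 10 energies
(~1 s each), interpolation to a 68-layer list, and a 50-record held-out
validation at 10 new energies on the isocenter plane. These sizes mirror
the measurement design the package supports and run in well under a
minute on one core.

## Known limitations

* The double-Gaussian family is an approximation; with the Lorentzian
  mismatch fraction at 3% the synthetic residuals grow measurably, as
  they do on real machines at the largest field sizes and most upstream
  planes. A third (Cauchy-Lorentz) fitted component is out of scope.
* $w_2$ is assumed plane-independent per energy. If a machine's halo
  weight varies materially with air gap, the shared-$w_2$ fit will fold
  that variation into $\sigma_2$.
* The energy-to-range mapping, in-water behaviour, absolute dose and any
  TPS-specific beam-data format are outside the package's scope.
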