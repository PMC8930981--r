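---
title: "Static bite-force modelling from jaw-muscle geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static bite-force modelling from jaw-muscle geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawstatics)
```

## The model and its assumptions

`jawstatics` implements the classic static lever model of lepidosaur
biting. The mandible is a rigid body articulated on an ideal hinge: both
quadrate–articular joints are collapsed onto the single axis through
their centers, so the model reports one resultant joint force rather than
attempting to split the statically indeterminate load between the two
condyles. Three force systems act on the mandible:

1. **Muscle forces.** Every adductor bundle is maximally active. Its
   force is `ACSA × stress`, applied at the insertion centroid, directed
   along the straight insertion-to-origin line. There is no wrapping, no
   force–length or force–velocity scaling, and no pennation correction —
   anatomical and physiological cross-sectional area coincide here, so
   the model consumes a single `acsa` field (cm²). (The muscle-stress
   literature this model family draws on prints values in N/cm²; the
   default of 30 N/cm² is the conventional squamate estimate and is
   overridable everywhere.)
2. **The food reaction** at one bite point, with a direction chosen in
   the plane perpendicular to the hinge axis.
3. **The joint reaction**, defined as whatever force closes the vector
   balance.

Moment equilibrium about the hinge axis is one scalar equation in one
unknown (the bite-force magnitude); force equilibrium then fixes the
joint reaction. Components of the torque perpendicular to the hinge axis
are reacted by the hinge itself, as in any ideal-hinge model.

Gape is realised by rigidly rotating all mandibular points (muscle
insertions, bite points) about the hinge axis; cranial points are fixed.
The opening sense is derived from the geometry — the rotation direction
that moves the jaw tip ventrally — never hard-coded, so the model is
indifferent to how the specimen was digitized. The digitized pose is
assumed closed unless the geometry file's `gape_reference_deg` says
otherwise; scan poses of fluid-preserved specimens are occasionally
slightly agape, and that field is the escape hatch.

## Coordinates, units, and the geometry file

One convention must be canonical for moments to have well-defined signs:
coordinates are millimetres in a right-handed frame with +x anterior, +y
toward the animal's left, +z dorsal; areas are cm². The JSON geometry
schema (see `load_jaw_model()`) declares its units and the loader
converts `cm` lengths and `mm²` areas on ingestion. Unilateral
(single-side) digitizations — the norm for a scanned holotype — are
completed by `mirror_unilateral()` under bilateral symmetry.

## The food-reaction orientation, and a caveat about sweeps

Orientation 0 is "vertical": the projection of +z (the closed-skull
dorsal direction) into the plane perpendicular to the hinge axis. The
food sets the reaction direction, not the jaw, so this reference does
**not** rotate with gape. The default sweep is −30° to +30° in 5° steps,
a documented choice; per (gape, bite point) cell the maximum over the
sweep is flagged.

One consequence deserves emphasis. The moment arm of a reaction tilted
by α at gape θ scales with cos(θ − α); as α approaches θ − 90° the
reaction's line of action passes through the hinge axis and static
equilibrium permits arbitrarily large bite forces. At 60° gape the
default sweep's far end approaches this singularity, so *maxima over the
sweep* at large gape reflect degenerate reaction geometry rather than
muscle performance (the exactly singular orientation raises an
unsolvable-orientation error; orientations the jaw cannot resist at all
are clamped to zero and flagged rather than reported as negative). The
analysis drivers therefore present the vertical-reaction table as the
headline and the sweep as sensitivity, and the gape-decline property is
asserted at the vertical reaction, where it is provable in closed form
(below).

## Closed-form oracles

The solver is validated against solutions derived by hand, not against
itself. For a planar jaw with hinge axis +y, insertions at horizontal
in-levers $r_i$, all origins at $(0, \pm w, h)$ — dorsal to the joint, as
temporal-fossa origins are — and a vertical reaction at out-lever $R$,
the bite force at gape $\theta$ is

$$F(\theta) \;=\; \sum_i \frac{F_i\, r_i\, h}{R\,\sqrt{r_i^2 + h^2 + 2 h r_i \sin\theta}},$$

strictly decreasing in $\theta$: the muscle's perpendicular arm degrades
as the insertion swings away from under the origin, while the
vertical-reaction out-lever shrinks by the same cos θ factor and cancels.
A second family places each origin directly dorsal to its insertion
("vertical" mode), recovering the textbook closed-pose lever law
$F = \sum_i F_i r_i / R$ with
$F(\theta) = \sum_i F_i r_i (r_i\sin\theta + h\cos\theta) / (L_i(\theta)\, R\cos\theta)$,
$L_i(\theta) = \sqrt{r_i^2(1-\cos\theta)^2 + (h + r_i\sin\theta)^2}$, at
gape. Notably this second family *gains* force with gape under a
food-fixed vertical reaction — directly-dorsal origins are not what makes
real jaws weaken as they open; origins concentrated above the joint are.
`make_planar_jaw()` returns the model and its expected-force table; the
test suite holds the solver to these closed forms at 1e-9 relative, and
additionally to an independent brute-force oracle (axis-angle rotation
matrix plus a 4×4 linear solve of force balance and axis moment) on 100
seeded random jaws.

## Numerical choices

* Moment-arm cutoff 1e-9 mm: a reaction orientation with a smaller arm at
  the bite point is reported unsolvable rather than dividing by ~0.
* Negative solved forces (the reaction would open the jaw) are clamped to
  0 and flagged; in sweeps they mark orientations the jaw cannot resist.
* Equilibrium residuals (force, and moment about the hinge axis) are
  asserted below 1e-9 in the tests for every non-clamped solution.
* Percent-of-max is rounded half-up to integer percent; the row attaining
  the maximum reads 100%.
* Degenerate inputs (coincident joints, bite points on the hinge axis,
  zero-length lines of action, non-positive areas) are rejected at
  validation with messages naming every offending field.

## What the synthetic data emulate — and what they do not

**Comparative dataset.** 44 species' mean head widths log-spaced over
4–38 mm; 332 specimens spread as evenly as possible; per-specimen log₁₀
bite capacity `-1 + 2·log10(HW)` plus species-level (sd 0.08) and
specimen-level (sd 0.05) Gaussian effects on the log scale. A generating
slope of 2 is the isometric expectation for a force set by muscle
cross-sectional area against a linear head dimension; the intercept puts
a 20 mm-headed skink at ~40 N, in the range of published in vivo values.
The recorded value is the maximum of five trials with lognormal noise
(CV 0.1). Trials model submaximal efforts, location-calibrated so the
recorded maximum is log-unbiased for capacity — the premise of a
best-of-five protocol is precisely that the best trial *is* the animal's
maximum, and an uncalibrated max-of-five would drift the whole dataset
above the generating allometry by ~0.05 log₁₀ units and bias the
recovered intercept. The calibration constant, E[max of k standard
normals], is computed by quadrature, not hard-coded.

**Fitting choices.** The default `fit_loglog()` treats specimens as
exchangeable points, matching how specimen-level comparative bite-force
plots are drawn; no phylogenetic correction is attempted (the focal
species never enters the fit — it has no in vivo measurement — and is
placed only via its signed residual). Because specimens cluster within
species, specimen-level OLS standard errors are anti-conservative and
their confidence intervals cover well below the nominal rate; whenever
interval validity matters — coverage checks, on-the-line
placement bands — the `species_means = TRUE` fit is used, whose points
are approximately iid and whose observed coverage is ~0.95. The same
reasoning picks the focal head width near the centre of the head-width
range for the placement logic check: at the range edge the fitted line's
own sampling error is comparable to a 3·SD/√n band.

**Hardness dataset.** Carapace widths uniform on 2–6 cm (the modelled
land crab reaches ~6 cm as an adult; the mass column scales with width³
up to ~50 g), failure force 30 N/cm × width plus Gaussian noise (sd
10 N), floored at 0.1 N. The 30 N/cm slope puts a 4.5 cm crab at ~135 N
and a full-size adult at ~180 N, inside the modelled predator's reach —
the regime the predator-prey comparison is about. Hardness is fitted
untransformed because the emulated relationship is linear in size. Note
the standing caveat of flat-tipped hardness testers: pointed teeth
concentrate force on a smaller area, so a tester-derived hardness
threshold overestimates the force a biting animal actually needs; no
correction factor is applied.

**What passing tests do not show.** The generators produce clean
power-law and linear worlds with known parameters. Recovery and coverage
results validate the estimation machinery, not any real dataset: real
comparative data carry phylogenetic structure, measurement-protocol
heterogeneity and species-specific motivation effects that these
generators deliberately omit. Likewise, synthetic jaws validate the
solver's statics exactly, but say nothing about segmentation error,
muscle-path curvature, or activation patterns in a real skull — absolute
published forces for any particular specimen are reproducible only with
that specimen's segmented geometry.

## Problem sizes

The test suite and acceptance script run: 100-seed oracle-equivalence
sweeps; two planar-toy families at four gapes each; full
3 gapes × 4 points × 13 orientations simulations; 200-replicate coverage
experiments on 332-record datasets. These sizes give Monte-Carlo noise
well inside every asserted band while keeping a full run in seconds on
one core.

## Limitations

Static, bilateral, maximally-activated, straight-line-muscle mechanics
on an ideal hinge: no dynamics, no unilateral biting, no bone or tooth
stress, no cranial kinesis. The two-joint load split is not resolved
(only the resultant joint force is reported). These match the model
family the package implements; anything beyond it belongs to
finite-element or multibody-dynamics tooling.
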