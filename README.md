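# jawstatics

Static bite-force estimation from jaw-muscle geometry, with a comparative
allometric layer — built around the kind of question a functional
morphologist asks of a rare museum specimen: *given the 3D geometry of the
jaw adductors segmented from scans, how hard can this animal bite, and is
that enough to crack the prey it is thought to eat?*

## The model

The mandible is treated as a rigid body on an ideal hinge through the two
quadrate–articular joint centers. Each adductor bundle is maximally
active and pulls along the straight line from its insertion (mandible)
to its origin (cranium) with magnitude

    F_i = ACSA_i × σ

where `ACSA_i` is the bundle's cross-sectional area (cm²) and σ the
muscle stress (30 N/cm² by default; no pennation correction). At a gape
angle θ all mandibular points are rigidly rotated about the hinge axis.
For a food reaction of direction **û** at a bite point **p**, moment
equilibrium about the hinge axis **â** (through the joint midpoint **c**)
gives the bite force

    F_bite = Σ_i ((r_i × F_i) · â) / (((p − c) × û) · â)

and the joint reaction force is whatever closes the force balance,
`J = −(Σ F_i − F_bite û)`. Simulations sweep gape (10/30/60°), four bite
points along the tooth row (jaw tip, anterior and posterior caniniform,
posterior-most tooth) and food-reaction orientations (−30°…+30°).

On top of the solver sit (i) a log₁₀–log₁₀ OLS allometry of in vivo bite
force against head width across skink species, with signed-residual
placement of a model-estimated animal on that line, and (ii) a linear fit
of crab exoskeleton failure force against carapace width, with a
bite-force-versus-prey-hardness verdict. Seeded generators synthesise
every input: planar jaws with hand-derived closed-form lever solutions,
random 3D jaws, a 332-specimen / 44-species comparative dataset emulating
a max-of-five-trials protocol, and crab hardness records.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_build_jaw.R     # geometries (+ closed-form solutions)
Rscript analysis/02_simulate_bite.R # gape x bite point x orientation sweep
Rscript analysis/03_allometry.R     # comparative fit + placement
Rscript analysis/04_hardness.R      # prey hardness + verdict
```

`02_simulate_bite.R` prints, for the seed-42 random jaw:

```
vertical bite: max force 17.4 N at posterior_most, gape 10 deg
vertical-bite forces (N, % of max):
  posterior_most         gape 10:   17.38 N  (100%)
  posterior_caniniform   gape 10:   12.97 N  (75%)
  anterior_caniniform    gape 10:   11.98 N  (69%)
  jaw_tip                gape 10:   11.33 N  (65%)
  posterior_most         gape 30:   15.95 N  (92%)
  ...
```

i.e. the strongest bite is at the most posterior tooth (shortest
out-lever) at the smallest gape, force declines toward the jaw tip and as
the jaw opens — the signature of a jaw-lever system. `03_allometry.R`
fits the synthetic comparative data (slope 1.992, r² 0.977 against a
generating slope of 2) and places the modelled animal's jaw-tip force at
30° gape on the line (log₁₀ residual −0.27 for this random jaw);
`04_hardness.R` predicts the failure force of a 6 cm crab carapace
(180.5 N from the fitted 29.9 N/cm slope) and reports whether the
modelled maximum bite exceeds it.

The same functions are available interactively:

```r
library(jawstatics)
toy <- load_jaw_model(system.file("extdata", "planar_toy.json",
                                  package = "jawstatics"))
solve_bite_force(toy, "jaw_tip", gape_deg = 0)$bite_force
#> [1] 7.5    # 30 N of muscle at in-lever 10 mm, out-lever 40 mm
```

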