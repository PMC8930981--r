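Package: jawstatics
Title: Static Bite-Force Estimation from Jaw-Muscle Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Static three-dimensional bite-force model for lepidosaur jaws:
    muscle forces from cross-sectional area and muscle stress, moment
    equilibrium about the quadrate-articular hinge axis at arbitrary gape
    angles, bite points and food-reaction orientations, and the joint
    reaction force that closes the force balance. Includes a comparative
    layer (log-log allometry of in vivo bite force against head width,
    placement of a model-estimated species on the regression line, prey
    exoskeleton hardness versus size) and seeded synthetic-data generators
    for jaw geometries with closed-form lever solutions, comparative bite
    force datasets emulating a max-of-five-trials protocol, and crab
    hardness records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
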