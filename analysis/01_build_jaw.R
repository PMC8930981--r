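#!/usr/bin/env Rscript
# Build the jaw geometries the downstream analyses run on: a planar toy
# family with known closed-form lever solutions (the solver's ground
# truth) and a random anatomically plausible 3D jaw. Both are written as
# geometry JSON under results/.

suppressPackageStartupMessages(library(jawstatics))
dir.create("results", showWarnings = FALSE)

planar <- make_planar_jaw(seed = 0)
write_jaw_model(planar$model, "results/planar_jaw.json")
write.table(planar$expected, "results/planar_expected.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

random <- make_random_jaw(seed = 42)
write_jaw_model(random, "results/random_jaw.json")

cat(sprintf("planar jaw: %d bundles, in-levers %s mm, origins above the joint\n",
            nrow(planar$model$muscles),
            paste(signif(planar$params$in_levers, 3), collapse = "/")))
cat(sprintf("closed-pose closed-form forces (N): %s\n",
            paste(sprintf("%s %.1f",
                          planar$expected$bite_point[planar$expected$gape_deg == 0],
                          planar$expected$bite_force_N[planar$expected$gape_deg == 0]),
                  collapse = ", ")))
cat("wrote results/planar_jaw.json, results/planar_expected.tsv, results/random_jaw.json\n")
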