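#!/usr/bin/env Rscript
# Prey-hardness layer: generate synthetic crab exoskeleton failure-force
# records, fit hardness against carapace width (linear, untransformed),
# predict the hardness of a full-sized (6 cm) adult crab and ask whether
# the modelled maximum bite force exceeds it.

suppressPackageStartupMessages(library(jawstatics))
dir.create("results", showWarnings = FALSE)

hard <- make_hardness_dataset(n = 30, seed = 1)
write.csv(hard, "results/hardness_dataset.csv", row.names = FALSE)

hfit <- fit_hardness_vs_size(hard)
cat(sprintf("hardness fit (n = %d): F = %.1f + %.1f * width, r2 = %.3f\n",
            hfit$n, hfit$intercept, hfit$slope, hfit$r2))

res <- read.delim("results/bite_vertical.tsv")
comp <- read.csv("results/comparative_dataset.csv")
fit <- fit_loglog(comp)
jaw <- load_jaw_model("results/random_jaw.json")
focal_hw <- sqrt(sum((jaw$joint_left - jaw$joint_right)^2))
report <- bite_performance_report(res, fit, focal_head_width = focal_hw,
                                  hardness_fit = hfit, crab_width = 6)
hz <- report$hardness
cat(sprintf("predicted hardness of a %.1f cm crab: %.1f N\n",
            hz$crab_width, hz$predicted_hardness))
cat(sprintf("max model bite force: %.1f N -> %s (margin %+.1f N, ratio %.2f)\n",
            hz$max_bite_force,
            if (hz$exceeds) "exceeds prey hardness" else "below prey hardness",
            hz$margin, hz$ratio))

jsonlite::write_json(list(
  hardness_fit = hfit[c("slope", "intercept", "r2", "residual_sd", "n")],
  verdict = hz
), "results/hardness.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/hardness_dataset.csv, results/hardness.json\n")
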