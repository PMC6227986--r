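#!/usr/bin/env Rscript
# Step 1 -- synthetic study material.
#
# The patient surfaces behind the published cohort are not deposited, so
# the study is reproduced on synthetic material with known ground truth:
# (a) three watertight fusiform-vessel phantoms (baseline Gaussian bulge,
#     a distally skewed bulge, and a dimpled bulge) written as STL, with
#     their generating parameters recorded;
# (b) a labeled 12 ruptured / 25 un-ruptured feature cohort with the five
#     published discriminative features planted at their reported group
#     means and standard deviations.

suppressPackageStartupMessages(library(vafamorph))

dir.create("results/meshes", recursive = TRUE, showWarnings = FALSE)

cases <- list(
  baseline = list(skew = 0,   dimple_depth = 0),
  skewed   = list(skew = 0.2, dimple_depth = 0),
  dimpled  = list(skew = 0,   dimple_depth = 1.2)
)

truth <- do.call(rbind, lapply(names(cases), function(nm) {
  p <- cases[[nm]]
  mesh <- fusiform_phantom(length = 40, r0 = 2, amplitude = 2, center = 20,
                           width = 3, skew = p$skew,
                           dimple_depth = p$dimple_depth)
  write_stl(mesh, file.path("results/meshes", paste0(nm, ".stl")))
  data.frame(case = nm, skew = p$skew, dimple_depth = p$dimple_depth,
             true_max_diameter = 8,
             # closed-form aneurysm length at detection factor 1.5
             true_L = 2 * sqrt(18 * log(2 / (2 * (sqrt(1.5) - 1)))))
}))
write.csv(truth, "results/meshes/ground_truth.csv", row.names = FALSE)
cat("wrote", nrow(truth), "phantom meshes (ground truth in results/meshes/ground_truth.csv)\n")

cohort <- simulate_cohort(cohort_spec(n_ruptured = 12, n_unruptured = 25,
                                      seed = 42))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
cat(sprintf("wrote synthetic cohort: %d cases x %d features (%d ruptured)\n",
            nrow(cohort), ncol(cohort) - 2, sum(cohort$ruptured)))
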