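#!/usr/bin/env Rscript
# Step 1: generate the synthetic dye-swap experiment.
#
# Two biological replicate pools, each hybridised in both dye orientations
# for each of the four competitive comparisons (T vs control, MAA vs
# control, T+MAA vs T, T+MAA vs MAA) — 16 hybridizations in all. 20% of
# the 2,000 genes are planted into the 27 named TFS groups in proportion
# to the published group sizes; 10% of genes carry a redundant second
# probe and 5% of probes are unannotated. Noise: additive SD 20
# fluorescence units, multiplicative SD 0.1 log2 per channel, smooth
# intensity-dependent dye bias of amplitude 0.3 log2.

library(tfsarray)

design <- simulation_design(n_genes = 2000, seed = 1234)
sim <- simulate_experiment(design)
print(sim)

out <- "results/experiment"
write_experiment(sim, out, overwrite = TRUE)
cat("wrote", length(list.files(out, pattern = "^hyb_")),
    "hybridization tables, manifest, truth and annotation to", out, "\n")
cat("planted non-null genes:", sum(sim$truth$tfs != "0.0000"),
    "across", length(unique(setdiff(sim$truth$tfs, "0.0000"))),
    "TFS groups\n")
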