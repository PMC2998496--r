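#!/usr/bin/env Rscript
# Stage 1: generate the paired two-system benchmark.
#
# Plants two regulatory truth networks over one gene namespace (10 TF
# modules of 8 targets; 4 modules conserved between systems), then simulates
# every dataset the comparison needs: an in-vivo-style dose series
# (0/4.8/48/96/192 mg/kg x 24/48 h x 4 replicates), an in-vitro-style
# control-vs-treated design (3 replicates), and a 120-condition expression
# compendium per system for network inference. All files land under
# scratch/fixtures/ (regenerated on demand; deterministic in the seed).

library(crossclr)

fixture_dir <- "scratch/fixtures"
cfg <- sim_config(seed = 1)
files <- write_fixture_bundle(cfg, fixture_dir)

truths <- generate_truth_networks(cfg)
message("Truth networks: ", nrow(truths$a), " edges per system, ",
        sum(truths$a$label == "shared"), " conserved (",
        cfg$shared_module_count, " of ", cfg$n_tfs, " TF modules).")
message("Wrote ", length(files), " files to ", fixture_dir)
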