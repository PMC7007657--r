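#!/usr/bin/env Rscript
# Step 1: simulate the synthetic pelvic cohort to disk.
#
# Twelve patients, each with a planning CT surrogate, a planning MR and
# three follow-up MRs; eight structures per scan; deformable propagation
# emulated per registration arm (CT-MR residual 2.0 mm, MR-MR 1.0 mm,
# intra-observer 0.8 mm); one patient delineated with a pinhole bladder.
# Masks are written as NIfTI with a CSV manifest binding each file to its
# study role. Everything below derives deterministically from the seed.

suppressPackageStartupMessages(library(dirqa))

seed <- as.integer(Sys.getenv("DIRQA_SEED", "1"))
out_dir <- "results/cohort"

cfg <- cohort_config(resolution = "reduced", seed = seed,
                     pinhole_patients = 1L)
man <- simulate_cohort(cfg, out_dir = out_dir)

cat(sprintf("cohort written to %s\n", out_dir))
cat(sprintf("  ground truth masks: %d\n",
            sum(man$role == "ground_truth")))
cat(sprintf("  propagated structures: %d (CT-MR %d, MR-MR %d)\n",
            sum(grepl("propagated", man$role)),
            sum(man$role == "propagated_CT_MR"),
            sum(man$role == "propagated_MR_MR")))
cat(sprintf("  re-delineations: %d\n",
            sum(man$role == "redelineation_IOV")))
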