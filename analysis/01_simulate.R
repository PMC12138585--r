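#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic lifespan cohort.
#
# Generates the 49-participant cohort (ages uniform over 21-83, 27
# female) and the ground-truth region/tract metric table: each of the 18
# (target, metric) reference trajectories evaluated at every
# participant's age, per hemisphere, plus Gaussian residual noise at 5%
# of each trajectory's dynamic range. Writes the shared config and the
# cohort/truth tables under results/, and one participant's phantom
# volumes under scratch/ as a format demonstration (NIfTI-1 + direction
# sidecar).

suppressMessages(library(stopnet))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/volumes", recursive = TRUE, showWarnings = FALSE)

config <- pipeline_config(noise_frac = 0.05, seed = 20260927L %% 1000L)
save_config(config, "analysis/config.yaml")

participants <- generate_participants(config$cohort$n,
                                      config$cohort$age_range,
                                      config$cohort$n_female,
                                      seed = config$seed)
truth <- cohort_truth(participants,
                      reference_trajectories(config$noise_frac),
                      seed = config$seed + 1L)

write_tsv_table(participants, "results/participants.tsv")
write_tsv_table(truth, "results/truth.tsv")

message(sprintf("cohort: %d participants, %d female, ages %.1f-%.1f",
                nrow(participants), sum(participants$sex == "F"),
                min(participants$age), max(participants$age)))
message(sprintf("truth table: %d rows (%d trajectories x 2 hemispheres x n)",
                nrow(truth), 18L))

# phantom volumes for the first participant, written to disk as examples
layout <- phantom_layout(config$layout$grid_dim, cube = config$layout$cube)
one <- truth[truth$participant_id == participants$participant_id[1], ]
qmri <- synthesize_qmri_volumes(one, layout,
                                r2star_baseline = config$metrics$r2star_baseline)[[1]]
write_volume(qmri$R1, "scratch/volumes/sub-001_R1.nii.gz")
write_volume(qmri$R2star, "scratch/volumes/sub-001_R2star.nii.gz")
write_volume(qmri$QSM, "scratch/volumes/sub-001_QSM.nii.gz")
tracts <- paste(rep(c("IFG-preSMA", "STN-IFG", "STN-preSMA"), each = 2),
                c("L", "R"), sep = "_")
dwi <- synthesize_dwi_signals(one, layout, s0 = config$metrics$s0,
                              b = config$metrics$b_values,
                              labels = tracts)[[1]]
write_volume(dwi$S0, "scratch/volumes/sub-001_b0.nii.gz")
for (b in names(dwi$shells))
  write_volume(dwi$shells[[b]],
               sprintf("scratch/volumes/sub-001_b%s.nii.gz", b))
fod <- synthesize_fod_samples(one, layout, n_dirs = config$metrics$n_dirs,
                              labels = tracts)[[1]]
write_fod(fod, "scratch/volumes/sub-001_fod.nii.gz")
message("example phantom volumes for sub-001 written to scratch/volumes/")
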