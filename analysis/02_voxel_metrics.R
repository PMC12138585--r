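#!/usr/bin/env Rscript

# Stage 2 — voxelwise maps and regional extraction.
#
# Rebuilds every participant's phantom volumes from the stage-1 truth
# table, computes the four voxelwise metric maps (iron and myelin from
# the R1/R2*/QSM contrasts; ADC from the three diffusion shells; GFA
# from the FOD amplitude samples), averages them over the region and
# tract masks, tests left-right hemisphere differences, and collapses
# hemispheres. Writes the long-format region-metric table and the
# hemisphere-test report under results/.

suppressMessages(library(stopnet))

config <- load_config("analysis/config.yaml")
participants <- read_tsv_table("results/participants.tsv")
truth <- read_tsv_table("results/truth.tsv")
layout <- phantom_layout(config$layout$grid_dim, cube = config$layout$cube)

tracts <- paste(rep(c("IFG-preSMA", "STN-IFG", "STN-preSMA"), each = 2),
                c("L", "R"), sep = "_")
qmri <- synthesize_qmri_volumes(truth, layout,
                                r2star_baseline = config$metrics$r2star_baseline)
dwi <- synthesize_dwi_signals(truth, layout, s0 = config$metrics$s0,
                              b = config$metrics$b_values, labels = tracts)
fod <- synthesize_fod_samples(truth, layout,
                              n_dirs = config$metrics$n_dirs,
                              labels = tracts)

ids <- participants$participant_id
volumes <- lapply(setNames(ids, ids), function(id)
  list(iron = compute_iron(qmri[[id]]),
       myelin = compute_myelin(qmri[[id]]),
       ADC = compute_adc(dwi[[id]]$S0, dwi[[id]]$shells,
                         b = config$metrics$b_values),
       GFA = compute_gfa(fod[[id]]$amplitudes)))

metrics_lr <- extract_region_metrics(volumes, layout)
hemi <- test_hemisphere_difference(metrics_lr)
metrics <- collapse_hemispheres(metrics_lr)

write_tsv_table(metrics_lr, "results/region_metrics_by_hemisphere.tsv")
write_tsv_table(metrics, "results/region_metrics.tsv")
write_tsv_table(hemi, "results/hemisphere_tests.tsv")

message(sprintf("extracted %d regional values (%d after collapsing)",
                nrow(metrics_lr), nrow(metrics)))
message(sprintf("hemisphere tests: %d/%d with p > 0.05 (min p = %.3f)",
                sum(hemi$p > 0.05), nrow(hemi), min(hemi$p)))
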