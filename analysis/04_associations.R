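#!/usr/bin/env Rscript

# Stage 4 — mediation and age-partialled correlations.
#
# Two mediation families (Holm-corrected within family): whether tract
# iron/myelin mediates the age -> tract ADC/GFA associations, and
# whether region-level iron/myelin mediates the age -> tract iron/myelin
# associations. Then, per tract, the partial-correlation matrix of the
# four metrics with age as covariate. Writes a mediation summary TSV and
# the correlation matrices as JSON under results/.

suppressMessages(library(stopnet))

config <- load_config("analysis/config.yaml")
participants <- read_tsv_table("results/participants.tsv")
metrics <- read_tsv_table("results/region_metrics.tsv")

age <- participants$age
vals <- function(tg, mt) {
  v <- metrics[metrics$target == tg & metrics$metric == mt, ]
  v$value[match(participants$participant_id, v$participant_id)]
}

tracts <- c("IFG-preSMA", "STN-IFG", "STN-preSMA")
rows <- list(); k <- 0L
for (tr in tracts) for (md in c("iron", "myelin")) for (oc in c("ADC", "GFA")) {
  k <- k + 1L
  m <- mediate(age, vals(tr, md), vals(tr, oc),
               n_boot = config$associations$n_boot,
               seed = config$seed + 100L + k)
  rows[[k]] <- data.frame(family = "age_to_diffusion", tract = tr,
                          mediator = md, outcome = oc, indirect = m$indirect,
                          ci_lo = m$ci[1], ci_hi = m$ci[2], p = m$p_boot)
}
for (tr in tracts) for (rg in strsplit(tr, "-")[[1]])
  for (md in c("iron", "myelin")) {
    k <- k + 1L
    m <- mediate(age, vals(rg, md), vals(tr, md),
                 n_boot = config$associations$n_boot,
                 seed = config$seed + 100L + k)
    rows[[k]] <- data.frame(family = "region_to_tract", tract = tr,
                            mediator = paste(rg, md),
                            outcome = paste(tr, md), indirect = m$indirect,
                            ci_lo = m$ci[1], ci_hi = m$ci[2], p = m$p_boot)
  }
med <- do.call(rbind, rows)
med$p_adjusted <- NA_real_
for (fam in unique(med$family)) {
  idx <- med$family == fam
  med$p_adjusted[idx] <- adjust_pvalues(med$p[idx],
                                        config$associations$p_adjust)
}
write_tsv_table(med, "results/mediations.tsv")

pc <- partial_correlations(metrics, participants)
jsonlite::write_json(lapply(pc, function(m) as.data.frame(as.table(m))),
                     "results/partial_correlations.json", digits = NA)

message(sprintf("mediations: %d significant after %s correction (of %d)",
                sum(med$p_adjusted < 0.05), config$associations$p_adjust,
                nrow(med)))
for (tr in tracts)
  message(sprintf("  %-11s iron-myelin partial r = % .3f", tr,
                  pc[[tr]]["iron", "myelin"]))
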