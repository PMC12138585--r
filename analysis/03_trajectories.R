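#!/usr/bin/env Rscript

# Stage 3 — lifespan trajectory selection.
#
# For each region (iron, myelin) and tract (iron, myelin, ADC, GFA):
# fits the six candidate polynomial age models by OLS, selects the
# winner by BIC, prunes influential participants at Cook's distance
# 4/n, refits and reselects. Also screens every series for sex main
# effects and age-by-sex interactions. Writes the winning-model table
# (formula, BIC, exclusions) and the sex-model table under results/.

suppressMessages(library(stopnet))

config <- load_config("analysis/config.yaml")
participants <- read_tsv_table("results/participants.tsv")
metrics <- read_tsv_table("results/region_metrics.tsv")
candidates <- lapply(config$selection$candidates,
                     function(s) as.integer(strsplit(s, ",")[[1]]))

# regions carry the biophysical metrics only; tracts carry all four
combos <- data.frame(
  target = c(rep(c("IFG", "preSMA", "STN"), each = 2),
             rep(c("IFG-preSMA", "STN-IFG", "STN-preSMA"), each = 4)),
  metric = c(rep(c("iron", "myelin"), 3),
             rep(c("iron", "myelin", "ADC", "GFA"), 3)),
  stringsAsFactors = FALSE)
sel_rows <- list()
sex_rows <- list()
for (i in seq_len(nrow(combos))) {
  tg <- combos$target[i]; mt <- combos$metric[i]
  sub <- metrics[metrics$target == tg & metrics$metric == mt, ]
  vals <- sub$value[match(participants$participant_id, sub$participant_id)]
  sel <- select_trajectory(participants$age, vals, candidates = candidates,
                           ids = participants$participant_id,
                           prune = config$selection$prune)
  sel_rows[[i]] <- data.frame(
    target = tg, metric = mt,
    winning_model = format_model(sel$post$coefficients, sel$post$powers,
                                 scientific = mt %in% c("ADC", "GFA")),
    bic = round(sel$post$BIC, 1), delta_bic = round(sel$delta_bic, 1),
    n_excluded = length(sel$excluded_ids), caution = sel$caution,
    stringsAsFactors = FALSE)
  sx <- fit_sex_models(participants$age, vals, participants$sex)
  sex_rows[[i]] <- cbind(target = tg, metric = mt, sx)
}
selection <- do.call(rbind, sel_rows)
sex_models <- do.call(rbind, sex_rows)

write_tsv_table(selection, "results/winning_models.tsv")
write_tsv_table(sex_models, "results/sex_models.tsv")

message("winning models:")
for (i in seq_len(nrow(selection)))
  message(sprintf("  %-11s %-6s %-30s BIC %7.1f  excluded %d%s",
                  selection$target[i], selection$metric[i],
                  selection$winning_model[i], selection$bic[i],
                  selection$n_excluded[i],
                  if (selection$caution[i]) "  (dBIC < 6, caution)" else ""))
sex_p <- sex_models$p[sex_models$term %in% c("sex", "age:sex")]
message(sprintf("sex effects: smallest (uncorrected) p = %.3f across %d tests",
                min(sex_p), length(sex_p)))
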