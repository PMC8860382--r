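#!/usr/bin/env Rscript
# Generate the synthetic imaging sessions used by the downstream analyses:
# a matched learning-style (pre/post, suppression-dominated) and
# attention-style (ignore/attend, mixed) contrast pair over the same cells,
# plus their ground truth. Writes the session tables under results/sessions/.

library(selattn)

seed <- 1
cfg <- synth_config(n_cells_per_class = c(PYR = 40, PV = 12, SOM = 12, VIP = 12),
                    n_trials_per_stim_per_cond = 100, seed = seed)
pair <- generate_contrast_pair(cfg)

dir.create("results/sessions", showWarnings = FALSE, recursive = TRUE)
write_session_csv(pair$learning$session, "results/sessions/learning")
write_session_csv(pair$attention$session, "results/sessions/attention")

for (nm in names(pair)) {
  gt <- pair[[nm]]$ground_truth
  write.csv(data.frame(cell_id = pair[[nm]]$session$cells$cell_id,
                       class = gt$classes,
                       si_true_c1 = gt$si_true[, 1],
                       si_true_c2 = gt$si_true[, 2],
                       branch = gt$branch),
            sprintf("results/sessions/ground_truth_%s.csv", nm),
            row.names = FALSE)
}

cat(sprintf("wrote 2 sessions (%d cells, %d trials each) under results/sessions/\n",
            sum(cfg$n_cells_per_class), 4 * cfg$n_trials_per_stim_per_cond))
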