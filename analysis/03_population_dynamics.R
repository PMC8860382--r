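#!/usr/bin/env Rscript
# Population-level analyses: difference-PSTHs with PCA on the 0-1 s window,
# class-pair noise correlations and their condition changes, and the
# running-speed stratification and lick-exclusion controls.

library(selattn)

seed <- 1
cfg <- synth_config(n_cells_per_class = c(PYR = 40, PV = 12, SOM = 12, VIP = 12),
                    n_trials_per_stim_per_cond = 100, seed = seed)
pair <- generate_contrast_pair(cfg)
dir.create("results", showWarnings = FALSE)

for (nm in names(pair)) {
  sess <- pair[[nm]]$session
  conds <- unique(sess$trials$condition)
  al <- align_to_trials(sess)

  for (stim in c("vertical", "angled")) {
    dp <- difference_psth(al, al, stim, conds[1], conds[2])
    pc <- pca_difference_psths(dp)
    cat(sprintf("%s %s difference-PSTH: PC1 explains %.1f%% of variance\n",
                nm, stim, pc$variance_explained[1]))
    write.csv(data.frame(cell_id = sess$cells$cell_id,
                         class = sess$cells$class,
                         weight_pc1 = pc$weights[, 1]),
              sprintf("results/pca_weights_%s_%s.csv", nm, stim),
              row.names = FALSE)
  }

  r1 <- selectivity_records(al, conds[1])
  mask <- r1$is_responsive
  nc1 <- noise_correlations(al, "vertical", conds[1], mask)
  nc2 <- noise_correlations(al, "vertical", conds[2], mask)
  cmp <- compare_noise_correlations(nc1, nc2)
  write.csv(cmp, sprintf("results/nc_change_%s.csv", nm), row.names = FALSE)
  sig <- cmp[cmp$p_bonf < 0.05, ]
  cat(sprintf("%s: %d/%d class pairs change NC significantly (Bonferroni)\n",
              nm, nrow(sig), nrow(cmp)))

  # running-speed stratification control on the attention-style contrast
  if (nm == "attention") {
    tt <- sess$trials
    tt$speed <- trial_speeds(sess)
    kept <- sort(unique(c(
      stratify_by_running(tt, conds, "vertical", seed = seed),
      stratify_by_running(tt, conds, "angled", seed = seed))))
    cat(sprintf("stratification keeps %d/%d trials with matched speeds\n",
                length(kept), nrow(tt)))
    licky <- setdiff(seq_len(nrow(tt)),
                     exclude_lick_trials(tt, frame_rate = sess$frame_rate))
    cat(sprintf("lick exclusion removes %d trials with licks in 0-1 s\n",
                length(licky)))
  }
}
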