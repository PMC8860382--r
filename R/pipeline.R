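#' End-to-end analysis of a matched learning/attention contrast pair
#'
#' Generates a learning-style (pre/post, suppression-dominated) and an
#' attention-style (ignore/attend, mixed enhancement/suppression) synthetic
#' session over the same cells, then runs the full analysis chain on each:
#' trial alignment, per-cell selectivity records in both conditions,
#' class-level mean absolute selectivity, per-cell selectivity change,
#' difference-PSTH with PCA on the 0-1 s window, class-pair noise
#' correlations and their change, and (optionally) the shared-versus-free
#' MVAR cross-validation comparison on the attention-style session.
#' Finally, correlates the per-cell selectivity changes of the two
#' contrasts, the single-cell dissociation measure.
#'
#' @param config a [synth_config()] object (condition labels and modulation
#'   mode are set per contrast internally).
#' @param alpha significance level for the rank tests.
#' @param shared_modulation logical; TRUE gives both contrasts identical
#'   per-cell true selectivity changes (positive control), FALSE (default)
#'   draws them independently.
#' @param include_mvar run the MVAR shared/free comparison (default TRUE).
#' @param mvar_max_cells,mvar_max_folds size caps for the MVAR stage.
#' @param out_dir optional directory; when given, per-cell records, NC
#'   tables and a JSON report are written there.
#' @return object of class `run_report`: list with `class_si` (per contrast
#'   x condition x class: mean |SI|, SEM, n), `dsi` (merged per-cell
#'   selectivity changes of both contrasts), `dsi_correlation` (Pearson R,
#'   its n, and the `2/sqrt(n)` null bound), `pca` (per contrast variance
#'   explained), `nc_change` (per contrast class-pair table), `mvar`
#'   (shared/free test R-squared summary), `provenance`.
#' @export
run_analysis <- function(config, alpha = 0.05, shared_modulation = FALSE,
                         include_mvar = TRUE, mvar_max_cells = 20,
                         mvar_max_folds = 20, out_dir = NULL) {
  pair <- generate_contrast_pair(config, shared_modulation = shared_modulation)
  contrasts <- list(learning = pair$learning, attention = pair$attention)
  class_si <- list(); recs <- list(); dsis <- list(); pca_tab <- list()
  nc_change <- list()
  for (nm in names(contrasts)) {
    sess <- contrasts[[nm]]$session
    conds <- unique(sess$trials$condition)
    al <- align_to_trials(sess)
    r1 <- selectivity_records(al, conds[1L], alpha)
    r2 <- selectivity_records(al, conds[2L], alpha)
    recs[[nm]] <- rbind(r1, r2)
    for (r in list(r1, r2)) {
      agg <- do.call(rbind, lapply(split(abs(r$SI), r$class), function(x) {
        data.frame(mean_abs_si = mean(x), sem = stats::sd(x) / sqrt(length(x)),
                   n = length(x))
      }))
      agg$class <- rownames(agg); agg$condition <- r$condition[1L]
      agg$contrast <- nm
      class_si[[length(class_si) + 1L]] <- agg
    }
    dsis[[nm]] <- delta_selectivity(r1, r2)
    dp <- difference_psth(al, al, "vertical",
                          condition_c1 = conds[1L], condition_c2 = conds[2L])
    pca_tab[[nm]] <- pca_difference_psths(dp)$variance_explained
    resp_mask <- recs[[nm]]$is_responsive[seq_len(nrow(r1))]
    nc1 <- noise_correlations(al, "vertical", conds[1L], resp_mask)
    nc2 <- noise_correlations(al, "vertical", conds[2L], resp_mask)
    nc_change[[nm]] <- compare_noise_correlations(nc1, nc2)
  }
  dsi <- merge(dsis$learning, dsis$attention, by = c("cell_id", "class"),
               suffixes = c("_learning", "_attention"))
  R <- stats::cor(dsi$dSI_learning, dsi$dSI_attention)
  mvar_cmp <- NULL
  if (include_mvar) {
    sess <- contrasts$attention$session
    keep_cells <- seq_len(min(mvar_max_cells, nrow(sess$traces)))
    al <- align_to_trials(sess)
    sub <- list(tensor = al$tensor[keep_cells, , , drop = FALSE],
                trials = al$trials)
    cvs <- lapply(c("shared", "per_condition"), function(wm) {
      crossvalidate_mvar(sub, mvar_spec(weight_mode = wm),
                         max_folds = mvar_max_folds)
    })
    names(cvs) <- c("shared", "per_condition")
    mvar_cmp <- list(
      test_R2_shared = mean(cvs$shared$test_R2, na.rm = TRUE),
      test_R2_free = mean(cvs$per_condition$test_R2, na.rm = TRUE),
      overfit_shared = cvs$shared$overfit,
      overfit_free = cvs$per_condition$overfit,
      n_cells = length(keep_cells))
  }
  report <- structure(list(
    class_si = do.call(rbind, class_si),
    records = recs, dsi = dsi,
    dsi_correlation = list(R = R, n = nrow(dsi),
                           null_bound = 2 / sqrt(nrow(dsi))),
    pca = pca_tab, nc_change = nc_change, mvar = mvar_cmp,
    provenance = list(seed = config$seed,
                      shared_modulation = shared_modulation,
                      n_cells = sum(config$n_cells_per_class),
                      n_trials_per_stim_per_cond = config$n_trials_per_stim_per_cond)
  ), class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Circuit-model study: target sweep, ratio scan, match evaluation
#'
#' Estimates the sampling-scale match thresholds from unmodulated control
#' runs, sweeps all 15 target subsets under both modulation modes, flags
#' each row against the experimental signature (selectivity up in PYR and
#' PV only; SOM-SOM noise correlation up, VIP-VIP down), and runs the
#' PYR/SOM modulation-ratio scan.
#'
#' @param n_trials trials per condition (default 100).
#' @param seed root seed.
#' @param n_seeds replicate simulation pairs averaged per sweep row and
#'   scan point; the match thresholds are scaled by `1/sqrt(n_seeds)` to
#'   stay two control-run standard errors of the averaged statistics.
#' @param modes modulation modes to sweep.
#' @param ratio PYR/SOM modulation ratio for the scan (default 0.7).
#' @param som_values SOM attend values for the scan.
#' @param out_dir optional directory for CSV outputs.
#' @return list with `thresholds`, `sweep` (with `criterion1`, `criterion2`,
#'   `match` columns), `scan`.
#' @export
run_circuit_study <- function(n_trials = 100, seed = 1, n_seeds = 1,
                              modes = c("additive", "multiplicative"),
                              ratio = 0.7,
                              som_values = seq(1.0, 2.2, by = 0.1),
                              out_dir = NULL) {
  thr <- estimate_match_thresholds(n_trials = n_trials, seed = seed)
  thr_eff <- list(theta_si = thr$theta_si / sqrt(n_seeds),
                  theta_nc = thr$theta_nc / sqrt(n_seeds))
  sweep_tab <- attention_sweep(modes = modes, n_trials = n_trials,
                               seed = seed, n_seeds = n_seeds)
  flags <- t(vapply(seq_len(nrow(sweep_tab)), function(i) {
    unlist(evaluate_match(sweep_tab[i, ], thr_eff))
  }, logical(3)))
  sweep_tab$criterion1 <- flags[, 1L]
  sweep_tab$criterion2 <- flags[, 2L]
  sweep_tab$match <- flags[, 3L]
  scan <- modulation_ratio_scan(som_values = som_values, ratio = ratio,
                                n_trials = n_trials, seed = seed,
                                n_seeds = n_seeds)
  out <- list(thresholds = thr, thresholds_effective = thr_eff,
              sweep = sweep_tab, scan = scan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep_tab, file.path(out_dir, "attention_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(scan, file.path(out_dir, "modulation_ratio_scan.csv"),
                     row.names = FALSE)
  }
  out
}

#' Write a run report to disk
#'
#' Per-cell selectivity records and NC-change tables as CSV plus a JSON
#' summary of the scalar results.
#'
#' @param report a `run_report` from [run_analysis()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$records)) {
    p <- file.path(out_dir, sprintf("selectivity_%s.csv", nm))
    utils::write.csv(report$records[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("nc_change_%s.csv", nm))
    utils::write.csv(report$nc_change[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    class_si = report$class_si,
    dsi_correlation = report$dsi_correlation,
    pca_variance_explained = report$pca,
    mvar = report$mvar,
    provenance = report$provenance
  ), p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}

#' Export a session's tables and traces as plain text
#'
#' Writes `cells.csv`, `trials.csv` (lick frames joined with `;`),
#' `running_speed.csv` and `traces.csv` (cells x frames) to a directory.
#'
#' @param session a `session` object.
#' @param out_dir output directory.
#' @return invisibly, the directory.
#' @export
write_session_csv <- function(session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  tr <- session$trials
  tr$lick_frames <- vapply(tr$lick_frames, paste, character(1), collapse = ";")
  utils::write.csv(tr, file.path(out_dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(session$running_speed),
                              speed = session$running_speed),
                   file.path(out_dir, "running_speed.csv"), row.names = FALSE)
  utils::write.table(session$traces, file.path(out_dir, "traces.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  per-cell dSI correlation (learning vs attention): R = %.3f (n = %d, null bound %.3f)\n",
              x$dsi_correlation$R, x$dsi_correlation$n, x$dsi_correlation$null_bound))
  for (nm in names(x$pca)) {
    cat(sprintf("  %s difference-PSTH PC1 variance explained: %.1f%%\n",
                nm, x$pca[[nm]][1L]))
  }
  if (!is.null(x$mvar)) {
    cat(sprintf("  MVAR test R2: shared %.3f vs free %.3f (n = %d cells)\n",
                x$mvar$test_R2_shared, x$mvar$test_R2_free, x$mvar$n_cells))
  }
  invisible(x)
}
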