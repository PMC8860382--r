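#' Difference-PSTH between two conditions
#'
#' For one stimulus, computes each cell's trial-averaged peri-stimulus
#' response in both conditions, baseline-corrects each (subtracting the
#' cell's mean pre-stimulus baseline in that condition), and returns the
#' condition-2 minus condition-1 difference per cell and frame.
#'
#' @param aligned_c1,aligned_c2 `aligned` objects with identical cells and
#'   peri-stimulus grids. They may be the same object, with conditions
#'   selected via `condition_c1`/`condition_c2`.
#' @param stimulus `"vertical"` or `"angled"`.
#' @param condition_c1,condition_c2 optional condition labels to filter
#'   trials within each object.
#' @return object of class `difference_psth`: `matrix` (cells x frames),
#'   `offsets`, `stimulus`, `frame_rate`.
#' @export
difference_psth <- function(aligned_c1, aligned_c2, stimulus,
                            condition_c1 = NULL, condition_c2 = NULL) {
  if (!identical(aligned_c1$offsets, aligned_c2$offsets)) {
    stopf("peri-stimulus grids differ between conditions")
  }
  if (dim(aligned_c1$tensor)[1L] != dim(aligned_c2$tensor)[1L]) {
    stopf("cell counts differ between conditions")
  }
  base_idx <- match(win_to_offsets(aligned_c1$baseline_win, aligned_c1$frame_rate),
                    aligned_c1$offsets)
  mean_psth <- function(al, condition) {
    keep <- al$trials$stimulus == stimulus
    if (!is.null(condition)) keep <- keep & al$trials$condition == condition
    if (!any(keep)) stopf("no trials for stimulus '%s'", stimulus)
    m <- apply(al$tensor[, keep, , drop = FALSE], c(1, 3), mean)
    m - rowMeans(m[, base_idx, drop = FALSE])
  }
  d <- mean_psth(aligned_c2, condition_c2) - mean_psth(aligned_c1, condition_c1)
  structure(list(matrix = d, offsets = aligned_c1$offsets,
                 stimulus = stimulus, frame_rate = aligned_c1$frame_rate),
            class = "difference_psth")
}

#' PCA of difference-PSTH shapes
#'
#' Principal-component analysis of the cells x frames difference-PSTH matrix
#' restricted to the analysis window (default 0-1 s). The matrix is
#' mean-centered across cells but not variance-normalized, so component
#' weights keep raw-amplitude meaning. Each component's sign is canonicalized
#' so that its projection onto the mean difference-PSTH is non-negative
#' (falling back to a positive largest-magnitude element when that projection
#' is zero), making the decomposition deterministic across runs.
#'
#' @param dpsth a [difference_psth()] object.
#' @param window analysis window in seconds (default `c(0, 1)`).
#' @return list with `components` (frames x n_comp orthonormal time
#'   profiles), `variance_explained` (percent, sums to 100), `weights`
#'   (per-cell scores), `center`, `window_offsets`.
#' @export
pca_difference_psths <- function(dpsth, window = c(0, 1)) {
  idx <- match(win_to_offsets(window, dpsth$frame_rate), dpsth$offsets)
  if (anyNA(idx)) stopf("analysis window outside the peri-stimulus grid")
  X <- dpsth$matrix[, idx, drop = FALSE]
  if (all(X == 0)) stopf("all-zero difference-PSTH matrix: no variance to decompose")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  mu <- colMeans(X)
  rot <- pc$rotation
  sc <- pc$x
  for (k in seq_len(ncol(rot))) {
    s <- sum(rot[, k] * mu)
    if (abs(s) < 1e-12) s <- rot[which.max(abs(rot[, k])), k]
    if (s < 0) { rot[, k] <- -rot[, k]; sc[, k] <- -sc[, k] }
  }
  list(components = rot, variance_explained = ve, weights = sc,
       center = pc$center, window_offsets = dpsth$offsets[idx])
}

class_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Pairwise noise correlations
#'
#' For one stimulus and condition, subtracts each cell's across-trial mean
#' evoked response and computes the Pearson correlation of the residuals for
#' every cell pair, aggregated by (unordered) class pair.
#'
#' @param aligned an `aligned` object.
#' @param stimulus,condition trial selectors.
#' @param responsive_mask optional logical vector per cell (e.g. from the
#'   signed-rank responsiveness test); only masked-in cells enter the table.
#' @return list with `pairs` (data.frame: cell_i, cell_j, class_i, class_j,
#'   condition, stimulus, NC), `summary` (per class pair: mean, SEM,
#'   n_pairs), and `nc_matrix`. Zero-variance cells are dropped with a
#'   message.
#' @export
noise_correlations <- function(aligned, stimulus, condition,
                               responsive_mask = NULL) {
  keep <- aligned$trials$stimulus == stimulus &
    aligned$trials$condition == condition
  if (sum(keep) < 3L) stopf("need >= 3 trials for noise correlations")
  resp <- aligned$evoked[, keep, drop = FALSE]
  cells <- aligned$cells
  use <- rep(TRUE, nrow(cells))
  if (!is.null(responsive_mask)) use <- use & responsive_mask
  v <- apply(resp, 1L, stats::var)
  if (any(use & v == 0)) {
    message(sprintf("dropping %d zero-variance cell(s)", sum(use & v == 0)))
    use <- use & v > 0
  }
  idx <- which(use)
  resid <- resp[idx, , drop = FALSE] - rowMeans(resp[idx, , drop = FALSE])
  ncm <- stats::cor(t(resid))
  pr <- which(upper.tri(ncm), arr.ind = TRUE)
  pairs <- data.frame(
    cell_i = cells$cell_id[idx[pr[, 1L]]],
    cell_j = cells$cell_id[idx[pr[, 2L]]],
    class_i = cells$class[idx[pr[, 1L]]],
    class_j = cells$class[idx[pr[, 2L]]],
    condition = condition, stimulus = stimulus,
    NC = ncm[pr], stringsAsFactors = FALSE)
  pairs$class_pair <- class_pair_key(pairs$class_i, pairs$class_j)
  agg <- do.call(rbind, lapply(split(pairs$NC, pairs$class_pair), function(x) {
    data.frame(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
               n_pairs = length(x))
  }))
  agg$class_pair <- rownames(agg)
  rownames(agg) <- NULL
  dimnames(ncm) <- list(cells$cell_id[idx], cells$cell_id[idx])
  list(pairs = pairs, summary = agg[, c("class_pair", "mean", "sem", "n_pairs")],
       nc_matrix = ncm)
}

#' Change in noise correlations between conditions
#'
#' Pairs the two tables by cell pair, takes NC differences (condition 2
#' minus condition 1), and tests each class-pair family with a two-sided
#' sign test (zeros dropped), Bonferroni-corrected over the class-pair
#' families.
#'
#' @param tab_c1,tab_c2 outputs of [noise_correlations()] for the two
#'   conditions.
#' @param n_families Bonferroni family count (default 10, the number of
#'   unordered class pairs of 4 classes).
#' @return data.frame per class pair: `class_pair`, `mean_delta`, `n_pairs`,
#'   `p_sign`, `p_bonf`.
#' @export
compare_noise_correlations <- function(tab_c1, tab_c2, n_families = 10) {
  key1 <- paste(tab_c1$pairs$cell_i, tab_c1$pairs$cell_j)
  key2 <- paste(tab_c2$pairs$cell_i, tab_c2$pairs$cell_j)
  common <- intersect(key1, key2)
  if (!length(common)) stopf("no matched cell pairs between conditions")
  d <- tab_c2$pairs$NC[match(common, key2)] - tab_c1$pairs$NC[match(common, key1)]
  cp <- tab_c1$pairs$class_pair[match(common, key1)]
  out <- do.call(rbind, lapply(split(d, cp), function(x) {
    nz <- x[x != 0]
    p <- if (length(nz) == 0L) 1 else
      stats::binom.test(sum(nz > 0), length(nz))$p.value
    data.frame(mean_delta = mean(x), n_pairs = length(x), p_sign = p)
  }))
  out$class_pair <- rownames(out)
  rownames(out) <- NULL
  out$p_bonf <- pmin(1, n_families * out$p_sign)
  out[, c("class_pair", "mean_delta", "n_pairs", "p_sign", "p_bonf")]
}

#' Running-speed-matched trial subset
#'
#' Bins trial running speeds into `n_bins` equal-width bins over the pooled
#' range and, per bin, keeps the same number of trials from each condition
#' (the minimum of the two counts, drawn without replacement under the
#' seed). Removes condition differences in the running-speed distribution by
#' construction.
#'
#' @param trial_table data.frame with columns `condition`, `stimulus` and
#'   `speed` (per-trial mean running speed over the response window).
#' @param condition_pair length-2 character vector of conditions to match.
#' @param stimulus stimulus to restrict to.
#' @param n_bins number of equal-width speed bins (default 10).
#' @param seed integer seed for the within-bin draw.
#' @return integer vector of row indices into `trial_table` (the matched
#'   subset, both conditions).
#' @export
stratify_by_running <- function(trial_table, condition_pair, stimulus,
                                n_bins = 10, seed = 1) {
  sel <- which(trial_table$stimulus == stimulus &
                 trial_table$condition %in% condition_pair)
  if (!length(sel)) stopf("no trials for stimulus '%s'", stimulus)
  sp <- trial_table$speed[sel]
  br <- seq(min(sp), max(sp), length.out = n_bins + 1L)
  br[1L] <- br[1L] - 1e-9
  bin <- cut(sp, br, labels = FALSE)
  keep <- integer(0)
  any_overlap <- FALSE
  with_seed(seed, {
    for (b in seq_len(n_bins)) {
      i1 <- sel[bin == b & trial_table$condition[sel] == condition_pair[1L]]
      i2 <- sel[bin == b & trial_table$condition[sel] == condition_pair[2L]]
      k <- min(length(i1), length(i2))
      if (k > 0L) {
        any_overlap <- TRUE
        keep <- c(keep,
                  if (length(i1) == k) i1 else sample(i1, k),
                  if (length(i2) == k) i2 else sample(i2, k))
      }
    }
  })
  if (!any_overlap) stopf("running-speed distributions do not overlap in any bin")
  sort(keep)
}

#' Per-trial mean running speed over a window
#'
#' @param session a `session` object with per-frame `running_speed`.
#' @param window window in seconds relative to grating onset (default 0-1 s).
#' @return numeric vector, one mean speed per trial.
#' @export
trial_speeds <- function(session, window = c(0, 1)) {
  offs <- win_to_offsets(window, session$frame_rate)
  vapply(session$trials$onset_frame, function(on) {
    mean(session$running_speed[on + offs])
  }, numeric(1))
}

#' Exclude trials with licks in the analysis window
#'
#' Removes trials with at least one lick within `window` (half-open
#' `[start, end)`) of grating onset; a lick at exactly the window end is
#' kept.
#'
#' @param trial_table data.frame with `onset_frame` and a `lick_frames`
#'   list-column of absolute lick frames.
#' @param window window in seconds relative to onset (default `c(0, 1)`).
#' @param frame_rate acquisition rate in Hz.
#' @return integer vector of retained row indices; warns if empty.
#' @export
exclude_lick_trials <- function(trial_table, window = c(0, 1), frame_rate = 8) {
  offs <- win_to_offsets(window, frame_rate)
  lo <- offs[1L]; hi <- offs[length(offs)]
  licked <- vapply(seq_len(nrow(trial_table)), function(t) {
    lf <- trial_table$lick_frames[[t]]
    if (!length(lf)) return(FALSE)
    rel <- lf - trial_table$onset_frame[t]
    any(rel >= lo & rel <= hi)
  }, logical(1))
  keep <- which(!licked)
  if (!length(keep)) warnf("all trials contain licks in the window")
  keep
}
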