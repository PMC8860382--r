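#' Pooled standard deviation of two response samples
#'
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' @param a,b numeric vectors of per-trial responses.
#' @keywords internal
pooled_sd <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
}

#' Stimulus selectivity index of one cell
#'
#' SI = (mean response to the vertical grating - mean response to the angled
#' grating) / pooled SD, positive for vertical-preferring cells and negative
#' for angled-preferring cells.
#'
#' @param resp_V per-trial evoked responses to the vertical grating.
#' @param resp_A per-trial evoked responses to the angled grating.
#' @return list with `SI`, `s_pooled`, `sP`/`sN` (SDs for vertical/angled),
#'   `mean_V`, `mean_A`, `n_V`, `n_A`.
#' @export
selectivity_index <- function(resp_V, resp_A) {
  if (length(resp_V) < 2L || length(resp_A) < 2L) {
    stopf("need >= 2 trials per stimulus (got %d, %d)",
          length(resp_V), length(resp_A))
  }
  sp <- pooled_sd(resp_V, resp_A)
  if (sp == 0) stopf("zero pooled SD: selectivity index undefined")
  list(SI = (mean(resp_V) - mean(resp_A)) / sp,
       s_pooled = sp, sP = stats::sd(resp_V), sN = stats::sd(resp_A),
       mean_V = mean(resp_V), mean_A = mean(resp_A),
       n_V = length(resp_V), n_A = length(resp_A))
}

#' Significance of stimulus selectivity (rank-sum test)
#'
#' Two-sided Wilcoxon rank-sum test between the per-trial responses to the
#' two gratings. All-tied inputs give p = 1 (not selective).
#'
#' @inheritParams selectivity_index
#' @param alpha significance level (default 0.05).
#' @return list with `p`, `is_selective`, and `preference`
#'   (`"vertical"`, `"angled"` or `"none"`).
#' @export
classify_selective <- function(resp_V, resp_A, alpha = 0.05) {
  if (length(resp_V) < 2L || length(resp_A) < 2L) {
    stopf("need >= 2 trials per stimulus")
  }
  if (length(unique(c(resp_V, resp_A))) == 1L) {
    return(list(p = 1, is_selective = FALSE, preference = "none"))
  }
  p <- suppressWarnings(
    stats::wilcox.test(resp_V, resp_A, alternative = "two.sided")$p.value
  )
  sel <- p < alpha
  pref <- if (!sel) "none" else if (mean(resp_V) >= mean(resp_A)) "vertical" else "angled"
  list(p = p, is_selective = sel, preference = pref)
}

#' Significance of stimulus responsiveness (signed-rank test)
#'
#' Two-sided Wilcoxon signed-rank test of the paired difference between
#' evoked (0-1 s) and pre-stimulus baseline (-0.5-0 s) responses.
#'
#' @param evoked per-trial evoked responses.
#' @param baseline per-trial baseline responses (paired, same length).
#' @param alpha significance level.
#' @return list with `p`, `is_responsive`, and `direction` (+1 increased,
#'   -1 decreased, 0 none).
#' @export
classify_responsive <- function(evoked, baseline, alpha = 0.05) {
  if (length(evoked) != length(baseline)) stopf("evoked/baseline length mismatch")
  d <- evoked - baseline
  if (all(d == 0)) return(list(p = 1, is_responsive = FALSE, direction = 0))
  p <- suppressWarnings(
    stats::wilcox.test(evoked, baseline, paired = TRUE,
                       alternative = "two.sided")$p.value
  )
  list(p = p, is_responsive = p < alpha,
       direction = if (p < alpha) sign(stats::median(d)) else 0)
}

#' Per-cell selectivity records for one condition
#'
#' Runs [selectivity_index()], [classify_selective()] and
#' [classify_responsive()] for every cell of an aligned-response object,
#' restricted to trials of the given condition.
#'
#' @param aligned an `aligned` object from [align_to_trials()].
#' @param condition condition label to select trials by.
#' @param alpha significance level.
#' @return data.frame with one row per cell: `cell_id`, `class`, `condition`,
#'   `SI`, `s_pooled`, `p_selective`, `is_selective`, `preference`,
#'   `p_responsive_vertical`, `p_responsive_angled`, `n_V`, `n_A`.
#' @export
selectivity_records <- function(aligned, condition, alpha = 0.05) {
  tr <- aligned$trials
  iV <- which(tr$condition == condition & tr$stimulus == "vertical")
  iA <- which(tr$condition == condition & tr$stimulus == "angled")
  if (length(iV) < 2L || length(iA) < 2L) {
    stopf("condition '%s': fewer than 2 trials of a stimulus", condition)
  }
  n_cells <- dim(aligned$tensor)[1L]
  out <- lapply(seq_len(n_cells), function(i) {
    rV <- aligned$evoked[i, iV]; rA <- aligned$evoked[i, iA]
    si <- selectivity_index(rV, rA)
    cs <- classify_selective(rV, rA, alpha)
    pv <- classify_responsive(aligned$evoked[i, iV] + aligned$baseline[i, iV],
                              aligned$baseline[i, iV], alpha)
    pa <- classify_responsive(aligned$evoked[i, iA] + aligned$baseline[i, iA],
                              aligned$baseline[i, iA], alpha)
    data.frame(cell_id = aligned$cells$cell_id[i],
               class = aligned$cells$class[i],
               condition = condition,
               SI = si$SI, s_pooled = si$s_pooled,
               p_selective = cs$p, is_selective = cs$is_selective,
               preference = cs$preference,
               p_responsive_vertical = pv$p, p_responsive_angled = pa$p,
               is_responsive = pv$is_responsive || pa$is_responsive,
               n_V = si$n_V, n_A = si$n_A,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Recruited cells between two conditions
#'
#' Cells that are non-selective in the first condition and significantly
#' selective in the second, partitioned by second-condition preference.
#'
#' @param records_c1,records_c2 per-cell record data.frames from
#'   [selectivity_records()], matched by `cell_id`.
#' @return list with `vertical` and `angled` character vectors of cell ids.
#' @export
recruited_cells <- function(records_c1, records_c2) {
  unmatched <- c(setdiff(records_c1$cell_id, records_c2$cell_id),
                 setdiff(records_c2$cell_id, records_c1$cell_id))
  if (length(unmatched)) {
    stopf("unmatched cell ids: %s", paste(unmatched, collapse = ", "))
  }
  r2 <- records_c2[match(records_c1$cell_id, records_c2$cell_id), ]
  rec <- !records_c1$is_selective & r2$is_selective
  list(vertical = r2$cell_id[rec & r2$preference == "vertical"],
       angled = r2$cell_id[rec & r2$preference == "angled"])
}

#' Change in selectivity toward the preferred stimulus
#'
#' Delta SI = sign(SI_c2) * (SI_c2 - SI_c1): positive values mean the cell
#' became more selective for its condition-2 preferred stimulus regardless of
#' which grating that is. A cell with SI_c2 exactly 0 uses sign +1.
#'
#' @inheritParams recruited_cells
#' @return data.frame with `cell_id`, `class`, `SI_c1`, `SI_c2`, `dSI`.
#' @export
delta_selectivity <- function(records_c1, records_c2) {
  r2 <- records_c2[match(records_c1$cell_id, records_c2$cell_id), ]
  if (anyNA(r2$cell_id)) stopf("records not matched by cell_id")
  s <- sign(r2$SI)
  s[s == 0] <- 1
  data.frame(cell_id = records_c1$cell_id, class = records_c1$class,
             SI_c1 = records_c1$SI, SI_c2 = r2$SI,
             dSI = s * (r2$SI - records_c1$SI),
             stringsAsFactors = FALSE)
}

#' Behavioral d-prime of a go/no-go session
#'
#' `bd' = qnorm(H) - qnorm(F)` with hit rate H and false-alarm rate F. Rates
#' are clipped to `[1/(2n), 1 - 1/(2n)]` (n = trial count of that type) so
#' perfect sessions give a finite d-prime.
#'
#' @param n_hit,n_miss go-trial outcome counts.
#' @param n_fa,n_cr no-go-trial outcome counts.
#' @return list with `H`, `F`, `bd`, `n_go`, `n_nogo`.
#' @export
behavioral_dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  n_go <- n_hit + n_miss
  n_nogo <- n_fa + n_cr
  if (n_go < 1L || n_nogo < 1L) stopf("need at least one go and one no-go trial")
  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  H <- clip(n_hit / n_go, n_go)
  F_ <- clip(n_fa / n_nogo, n_nogo)
  list(H = H, F = F_, bd = stats::qnorm(H) - stats::qnorm(F_),
       n_go = n_go, n_nogo = n_nogo)
}

#' Local PYR-population selectivity around PV cells
#'
#' For each PV cell, averages the per-trial responses of all PYR cells within
#' `radius_um` (closed ball, 2-D within-plane Euclidean distance) and
#' computes the selectivity index of that neighborhood-averaged response.
#' Pairs each PV cell's own SI (x) with its local PYR SI (y).
#'
#' @param aligned an `aligned` object.
#' @param condition condition label.
#' @param radius_um neighborhood radius in micrometers (default 100).
#' @return data.frame with `pv_cell_id`, `x` (PV SI), `y` (local PYR SI),
#'   `n_neighbors`. PV cells without PYR neighbors are excluded.
#' @export
local_population_selectivity <- function(aligned, condition, radius_um = 100) {
  cells <- aligned$cells
  tr <- aligned$trials
  iV <- which(tr$condition == condition & tr$stimulus == "vertical")
  iA <- which(tr$condition == condition & tr$stimulus == "angled")
  pv <- which(cells$class == "PV")
  pyr <- which(cells$class == "PYR")
  rows <- list()
  dropped <- 0L
  for (p in pv) {
    d <- sqrt((cells$x_um[pyr] - cells$x_um[p])^2 +
              (cells$y_um[pyr] - cells$y_um[p])^2)
    nb <- pyr[d <= radius_um]
    if (!length(nb)) { dropped <- dropped + 1L; next }
    pooled_V <- colMeans(aligned$evoked[nb, iV, drop = FALSE])
    pooled_A <- colMeans(aligned$evoked[nb, iA, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      pv_cell_id = cells$cell_id[p],
      x = selectivity_index(aligned$evoked[p, iV], aligned$evoked[p, iA])$SI,
      y = selectivity_index(pooled_V, pooled_A)$SI,
      n_neighbors = length(nb), stringsAsFactors = FALSE)
  }
  if (dropped) message(sprintf("%d PV cell(s) had no PYR neighbor and were excluded", dropped))
  if (!length(rows)) return(data.frame(pv_cell_id = character(), x = numeric(),
                                       y = numeric(), n_neighbors = integer()))
  do.call(rbind, rows)
}

#' Bootstrap confidence interval and test for a regression slope
#'
#' Least-squares slope of y on x with a cell-resampling bootstrap: pairs are
#' resampled with replacement `n_boot` times to obtain the 2.5 and 97.5
#' percentile CI. Against a comparison slope, the two-sided p-value is twice
#' the fraction of bootstrap slopes lower than the comparison slope
#' (a one-sided slope-reduction probability, doubled).
#'
#' @param x,y numeric vectors (e.g. PV SI and local PYR SI).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the resampling.
#' @param comparison_slope optional slope to test against.
#' @return list with `slope`, `ci` (length-2), `boot_slopes`, and `p`
#'   (NA unless `comparison_slope` given).
#' @export
bootstrap_slope <- function(x, y, n_boot = 10000, seed = 1,
                            comparison_slope = NULL) {
  n <- length(x)
  if (n < 3L) stopf("need >= 3 points")
  if (stats::sd(x) == 0) stopf("x is constant; slope undefined")
  slope_of <- function(xx, yy) stats::cov(xx, yy) / stats::var(xx)
  est <- slope_of(x, y)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
    X <- matrix(x[idx], nrow = n_boot)
    Y <- matrix(y[idx], nrow = n_boot)
    mx <- rowMeans(X); my <- rowMeans(Y)
    vx <- rowMeans(X * X) - mx^2
    sl <- (rowMeans(X * Y) - mx * my) / vx
    bad <- which(!is.finite(sl))
    for (b in bad) {   # constant-x resample: redraw
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[i]) > 0) { sl[b] <- slope_of(x[i], y[i]); break }
      }
    }
    if (length(bad)) message(sprintf("redrew %d degenerate resample(s)", length(bad)))
    sl
  })
  p <- NA_real_
  if (!is.null(comparison_slope)) {
    p <- min(1, 2 * mean(boots < comparison_slope))
  }
  list(slope = est,
       ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
       boot_slopes = boots, p = p)
}
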