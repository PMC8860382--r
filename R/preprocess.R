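#' Neuropil correction of ROI fluorescence
#'
#' Subtracts a scaled, median-subtracted neuropil trace from the ROI trace:
#' `F_roi - factor * (F_np - median(F_np))`. The median subtraction keeps the
#' overall fluorescence level (and hence the baseline used for dF/F) at the
#' ROI's own level while removing the shared out-of-focus fluctuations.
#'
#' @param F_roi numeric vector, raw ROI fluorescence per frame.
#' @param F_np numeric vector, neuropil-mask fluorescence, same length.
#' @param factor contamination factor in `[0, 1]` (default 0.7).
#' @return numeric vector of corrected fluorescence.
#' @export
neuropil_correct <- function(F_roi, F_np, factor = 0.7) {
  if (length(F_roi) != length(F_np)) {
    stopf("F_roi and F_np differ in length (%d vs %d)",
          length(F_roi), length(F_np))
  }
  if (factor < 0 || factor > 1) stopf("factor must be in [0, 1], got %g", factor)
  F_roi - factor * (F_np - stats::median(F_np))
}

#' Running-minimum baseline of a fluorescence trace
#'
#' Applies a causal moving average of `smooth_s` seconds, then takes for each
#' time point the minimum of the smoothed trace over the preceding
#' `lookback_s` seconds (inclusive of the current sample). Early time points
#' use the available prefix; the causal average shrinks at the trace start
#' rather than padding.
#'
#' @param F numeric vector of fluorescence per frame.
#' @param frame_rate acquisition rate in Hz.
#' @param smooth_s causal smoothing window in seconds (default 0.375).
#' @param lookback_s running-minimum lookback in seconds (default 600).
#' @return numeric vector `F0` of the same length.
#' @export
compute_baseline <- function(F, frame_rate, smooth_s = 0.375, lookback_s = 600) {
  if (length(F) == 0L) stopf("empty trace")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  k <- max(1L, as.integer(round(smooth_s * frame_rate)))
  sm <- causal_moving_average(F, k)
  w <- max(1L, as.integer(round(lookback_s * frame_rate)))
  running_min(sm, w)
}

# causal moving average with a shrinking window at the trace start
causal_moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 1L) return(x)
  cs <- cumsum(x)
  out <- cs / seq_len(n)
  if (n > k) {
    idx <- (k + 1L):n
    out[idx] <- (cs[idx] - cs[idx - k]) / k
  }
  out
}

# sliding-window minimum (window = preceding w samples, inclusive), via the
# block prefix/suffix cummin decomposition; O(n)
running_min <- function(x, w) {
  n <- length(x)
  if (w >= n) return(cummin(x))
  nb <- ceiling(n / w)
  xp <- c(x, rep(Inf, nb * w - n))
  m <- matrix(xp, nrow = w)
  left <- as.vector(apply(m, 2L, cummin))[seq_len(n)]
  right <- as.vector(apply(m[w:1, , drop = FALSE], 2L, cummin)[w:1, , drop = FALSE])
  j <- seq_len(n) - w + 1L
  out <- left
  has_prev <- j > 1L
  out[has_prev] <- pmin(right[j[has_prev]], left[has_prev])
  out
}

#' Fractional fluorescence change dF/F
#'
#' @param F numeric vector, neuropil-corrected fluorescence.
#' @param F0 numeric vector, baseline fluorescence (strictly positive).
#' @return `(F - F0) / F0`, element-wise.
#' @export
compute_dff <- function(F, F0) {
  if (length(F) != length(F0)) stopf("F and F0 differ in length")
  if (any(F0 <= 0)) {
    stopf("non-positive baseline at %d frame(s); pathological F0", sum(F0 <= 0))
  }
  (F - F0) / F0
}

#' Align traces to stimulus onsets
#'
#' Cuts a peri-stimulus window around every grating onset and computes the
#' per-trial evoked response scalar: mean dF/F over the response window minus
#' mean over the pre-stimulus baseline window. Windows in seconds are mapped
#' to frame offsets by flooring the start and ceiling the end on a grid where
#' frame 0 contains the onset; membership is half-open `[start, end)`.
#'
#' @param session a `session` object (see [generate_session()]), or any list
#'   with elements `traces` (cells x frames matrix), `trials` (data.frame with
#'   an `onset_frame` column) and `frame_rate`.
#' @param window peri-stimulus window in seconds, default `c(-0.5, 3)`.
#' @param response_win evoked-response window, default `c(0, 1)`.
#' @param baseline_win pre-stimulus baseline window, default `c(-0.5, 0)`.
#' @return an object of class `aligned`: list with `tensor`
#'   (cells x trials x frames), `offsets` (frame offsets relative to onset),
#'   `evoked` and `baseline` (cells x trials), `trials` (the retained trial
#'   table), `cells`, `frame_rate` and the windows used. Trials whose window
#'   exceeds the trace bounds are dropped with a warning.
#' @export
align_to_trials <- function(session, window = c(-0.5, 3),
                            response_win = c(0, 1),
                            baseline_win = c(-0.5, 0)) {
  traces <- session$traces
  trials <- session$trials
  fr <- session$frame_rate
  offsets <- win_to_offsets(window, fr)
  n_frames <- ncol(traces)
  lo <- trials$onset_frame + offsets[1L]
  hi <- trials$onset_frame + offsets[length(offsets)]
  keep <- lo >= 1L & hi <= n_frames
  if (!all(keep)) {
    warnf("dropping %d trial(s) whose peri-stimulus window exceeds the trace",
          sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }
  n_cells <- nrow(traces)
  n_trials <- nrow(trials)
  tensor <- array(NA_real_, dim = c(n_cells, n_trials, length(offsets)))
  for (t in seq_len(n_trials)) {
    tensor[, t, ] <- traces[, trials$onset_frame[t] + offsets, drop = FALSE]
  }
  resp_idx <- match(win_to_offsets(response_win, fr), offsets)
  base_idx <- match(win_to_offsets(baseline_win, fr), offsets)
  if (anyNA(resp_idx) || anyNA(base_idx)) {
    stopf("response/baseline windows fall outside the peri-stimulus window")
  }
  resp_mean <- apply(tensor[, , resp_idx, drop = FALSE], c(1, 2), mean)
  base_mean <- apply(tensor[, , base_idx, drop = FALSE], c(1, 2), mean)
  structure(list(
    tensor = tensor, offsets = offsets,
    evoked = resp_mean - base_mean, baseline = base_mean,
    trials = trials, cells = session$cells, frame_rate = fr,
    window = window, response_win = response_win, baseline_win = baseline_win
  ), class = "aligned")
}

# seconds -> frame offsets relative to the onset frame; [start, end) half-open
win_to_offsets <- function(win, frame_rate) {
  f0 <- as.integer(floor(win[1] * frame_rate))
  f1 <- as.integer(ceiling(win[2] * frame_rate))
  if (f1 <= f0) stopf("degenerate window [%g, %g)", win[1], win[2])
  f0:(f1 - 1L)
}

#' @export
print.aligned <- function(x, ...) {
  cat(sprintf("aligned responses: %d cells x %d trials x %d frames (%g Hz)\n",
              dim(x$tensor)[1], dim(x$tensor)[2], dim(x$tensor)[3],
              x$frame_rate))
  invisible(x)
}
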