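#' Default per-class, per-condition target selectivity distributions
#'
#' Mean and SD of the true (signed) selectivity index drawn per cell, as
#' 4 x 2 matrices (classes x conditions). The defaults emulate a session in
#' which selectivity grows from the first to the second condition in all
#' classes, most strongly in PYR cells.
#'
#' @param conditions length-2 character vector of condition labels.
#' @return list with matrices `mean` and `sd`.
#' @export
default_si_distributions <- function(conditions = c("pre", "post")) {
  m <- rbind(PYR = c(0.30, 0.60), PV = c(0.25, 0.45),
             SOM = c(0.15, 0.30), VIP = c(0.10, 0.20))
  s <- rbind(PYR = c(0.35, 0.45), PV = c(0.30, 0.35),
             SOM = c(0.25, 0.30), VIP = c(0.20, 0.25))
  colnames(m) <- colnames(s) <- conditions
  list(mean = m, sd = s)
}

#' Configuration of the synthetic-session generator
#'
#' Builds a validated configuration for [generate_session()] and
#' [generate_raw_fluorescence()]. The same config plus the same seed is
#' guaranteed to give bit-identical output.
#'
#' @param n_cells_per_class named counts for PYR, PV, SOM, VIP.
#' @param frame_rate imaging rate in Hz (default 8).
#' @param n_trials_per_stim_per_cond trials per stimulus per condition
#'   (default 100, the order of a typical behavioral block).
#' @param conditions ordered pair of condition labels, `c("pre","post")` or
#'   `c("ignore","attend")`.
#' @param si_distributions list of 4 x 2 `mean` and `sd` matrices of the true
#'   selectivity index (see [default_si_distributions()]).
#' @param si_cross_condition_cor correlation between a cell's true SI in the
#'   two conditions (default 0.7); controls how much condition-2 selectivity
#'   is predictable from condition 1.
#' @param modulation_mode `"suppression"` (condition-2 selectivity changes
#'   realized by changing the non-preferred response only, emulating
#'   learning) or `"mixed"` (each cell randomly uses enhancement of the
#'   preferred or suppression of the non-preferred response, emulating
#'   attention).
#' @param shared_noise_loadings either a list with per-class named vectors
#'   `global` and `class` (trial-to-trial shared-noise SDs in response
#'   amplitude units), or a list of two such lists (one per condition).
#' @param private_noise_sd per-trial private response-amplitude noise SD.
#' @param frame_noise_sd per-frame additive trace noise SD.
#' @param response_amp named per-class mean response amplitude (dF/F units).
#' @param calcium_tau calcium-indicator decay constant in seconds
#'   (default 0.6, GCaMP6f-like).
#' @param neuropil_gain neuropil contamination factor in `[0, 1)`, used by
#'   [generate_raw_fluorescence()].
#' @param baseline_drift slow multiplicative drift amplitude of the raw
#'   baseline fluorescence (fraction, default 0.02).
#' @param running_speed_params list of per-condition `c(meanlog, sdlog)`
#'   lognormal parameters of trial running speed (cm/s).
#' @param lick_prob named per-stimulus probability of licking within 0-1 s
#'   of grating onset.
#' @param positions_extent field-of-view extent in micrometers.
#' @param seed integer root seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cells_per_class = c(PYR = 40, PV = 12, SOM = 12, VIP = 12),
                         frame_rate = 8,
                         n_trials_per_stim_per_cond = 100,
                         conditions = c("pre", "post"),
                         si_distributions = default_si_distributions(conditions),
                         si_cross_condition_cor = 0.7,
                         modulation_mode = c("suppression", "mixed"),
                         shared_noise_loadings = NULL,
                         private_noise_sd = 0.12,
                         frame_noise_sd = 0.01,
                         response_amp = c(PYR = 0.40, PV = 0.50, SOM = 0.45, VIP = 0.35),
                         calcium_tau = 0.6,
                         neuropil_gain = 0.7,
                         baseline_drift = 0.02,
                         running_speed_params = list(c(meanlog = 2.2, sdlog = 0.4),
                                                     c(meanlog = 2.5, sdlog = 0.4)),
                         lick_prob = c(vertical = 0.8, angled = 0.15),
                         positions_extent = 500,
                         seed = 1) {
  modulation_mode <- match.arg(modulation_mode)
  if (is.null(shared_noise_loadings)) {
    shared_noise_loadings <- list(
      global = c(PYR = 0.04, PV = 0.04, SOM = 0.04, VIP = 0.04),
      class  = c(PYR = 0.05, PV = 0.08, SOM = 0.08, VIP = 0.06))
  }
  if (!is.null(shared_noise_loadings$global)) {
    # one loading set: use it in both conditions
    shared_noise_loadings <- list(shared_noise_loadings, shared_noise_loadings)
  }
  if (any(n_cells_per_class < 1L)) stopf("all cell counts must be >= 1")
  if (n_trials_per_stim_per_cond < 1L) stopf("trial count must be >= 1")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (neuropil_gain < 0 || neuropil_gain >= 1) stopf("neuropil_gain must be in [0, 1)")
  if (length(conditions) != 2L) stopf("exactly two condition labels required")
  cfg <- list(n_cells_per_class = n_cells_per_class[CELL_CLASSES],
              frame_rate = frame_rate,
              n_trials_per_stim_per_cond = n_trials_per_stim_per_cond,
              conditions = conditions,
              si_distributions = si_distributions,
              si_cross_condition_cor = si_cross_condition_cor,
              modulation_mode = modulation_mode,
              shared_noise_loadings = shared_noise_loadings,
              private_noise_sd = private_noise_sd,
              frame_noise_sd = frame_noise_sd,
              response_amp = response_amp,
              calcium_tau = calcium_tau,
              neuropil_gain = neuropil_gain,
              baseline_drift = baseline_drift,
              running_speed_params = running_speed_params,
              lick_prob = lick_prob,
              positions_extent = positions_extent,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# trial geometry: 8 s trials, onset 3 s in, transient confined to the trial
trial_geometry <- function(frame_rate) {
  trial_len <- as.integer(round(8 * frame_rate))
  onset_off <- as.integer(round(3 * frame_rate))   # 0-based offset into trial
  list(trial_len = trial_len, onset_off = onset_off,
       kernel_len = trial_len - onset_off)
}

# per-condition total amplitude SD from loadings + private noise
amp_sd_per_class <- function(cfg, cond_idx) {
  ld <- cfg$shared_noise_loadings[[cond_idx]]
  sqrt(ld$global[CELL_CLASSES]^2 + ld$class[CELL_CLASSES]^2 +
         cfg$private_noise_sd^2)
}

#' Generate a synthetic dF/F imaging session with ground truth
#'
#' Builds per-cell dF/F traces as kernel-convolved evoked transients (one
#' single-exponential calcium transient per trial, amplitude = true evoked
#' amplitude + shared latent-factor noise + private noise) plus per-frame
#' trace noise, together with a trial table (both stimuli x both conditions,
#' condition blocks in order, stimulus order randomized within block),
#' per-cell metadata, running speed and licks.
#'
#' Trial-to-trial shared variability follows a one-global-factor plus
#' one-factor-per-class model, so class-structured noise-correlation
#' matrices arise by construction; the implied pairwise correlations are
#' available from [expected_noise_correlation()].
#'
#' Random streams are derived hierarchically from the root seed per cell and
#' per condition, so enlarging one class leaves existing cells' data
#' unchanged.
#'
#' @param config a [synth_config()] object.
#' @return list with `session` (class `session`: `traces`, `trials`,
#'   `cells`, `running_speed`, `frame_rate`) and `ground_truth` (class
#'   `ground_truth`: per-cell true amplitudes `amp` (cell x stimulus x
#'   condition), true SI per condition, loadings, modulation branch per cell).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  geo <- trial_geometry(cfg$frame_rate)
  n_per <- cfg$n_cells_per_class
  n_cells <- sum(n_per)
  classes <- rep(CELL_CLASSES, times = n_per)
  n_tpc <- cfg$n_trials_per_stim_per_cond
  n_trials_cond <- 2L * n_tpc
  n_trials <- 2L * n_trials_cond
  n_frames <- n_trials * geo$trial_len

  # --- trial table (condition blocks, randomized stimulus order per block)
  stim <- character(0); cond <- character(0)
  for (ci in 1:2) {
    s <- with_seed(derive_seed(cfg$seed, 3L, ci),
                   sample(rep(c("vertical", "angled"), n_tpc)))
    stim <- c(stim, s)
    cond <- c(cond, rep(cfg$conditions[ci], n_trials_cond))
  }
  onset_frame <- (seq_len(n_trials) - 1L) * geo$trial_len + geo$onset_off + 1L

  # --- per-trial latent factors (global + per class), per condition
  g_fac <- numeric(n_trials)
  h_fac <- matrix(0, n_trials, 4L, dimnames = list(NULL, CELL_CLASSES))
  for (ci in 1:2) {
    idx <- which(cond == cfg$conditions[ci])
    g_fac[idx] <- with_seed(derive_seed(cfg$seed, 1L, ci, 0L), stats::rnorm(length(idx)))
    for (k in 1:4) {
      h_fac[idx, k] <- with_seed(derive_seed(cfg$seed, 1L, ci, k),
                                 stats::rnorm(length(idx)))
    }
  }

  # --- per-cell ground truth and noise streams
  si_m <- cfg$si_distributions$mean; si_s <- cfg$si_distributions$sd
  rho <- cfg$si_cross_condition_cor
  sd_amp1 <- amp_sd_per_class(cfg, 1L); sd_amp2 <- amp_sd_per_class(cfg, 2L)
  amp <- array(NA_real_, c(n_cells, 2L, 2L),
               dimnames = list(NULL, c("vertical", "angled"), cfg$conditions))
  si_true <- matrix(NA_real_, n_cells, 2L, dimnames = list(NULL, cfg$conditions))
  branch <- character(n_cells)
  xy <- matrix(NA_real_, n_cells, 2L)
  priv <- matrix(NA_real_, n_cells, n_trials)
  traces <- matrix(NA_real_, n_cells, n_frames)
  class_idx <- match(classes, CELL_CLASSES)
  within_idx <- stats::ave(seq_len(n_cells), classes, FUN = seq_along)
  for (i in seq_len(n_cells)) {
    cl <- classes[i]
    with_seed(derive_seed(cfg$seed, 2L, class_idx[i], within_idx[i]), {
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      si1 <- si_m[cl, 1L] + si_s[cl, 1L] * z1
      si2 <- si_m[cl, 2L] + si_s[cl, 2L] * (rho * z1 + sqrt(1 - rho^2) * z2)
      si_true[i, ] <- c(si1, si2)
      coin <- stats::runif(1)   # always drawn so the stream is mode-invariant
      use_enh <- cfg$modulation_mode == "mixed" && coin < 0.5
      branch[i] <- if (use_enh) "enhancement" else "suppression"
      xy[i, ] <- stats::runif(2, 0, cfg$positions_extent)
      priv[i, ] <- stats::rnorm(n_trials, 0, cfg$private_noise_sd)
      traces[i, ] <- stats::rnorm(n_frames, 0, cfg$frame_noise_sd)
    })
    a0 <- cfg$response_amp[cl]
    d1 <- si_true[i, 1L] * sd_amp1[cl]
    d2 <- si_true[i, 2L] * sd_amp2[cl]
    # condition 1: symmetric around the class mean amplitude
    amp[i, , 1L] <- c(a0 + d1 / 2, a0 - d1 / 2)
    # condition 2: change only the non-preferred (suppression) or only the
    # preferred (enhancement) response relative to condition 1
    pref2 <- if (si_true[i, 2L] >= 0) 1L else 2L   # 1 = vertical
    nonp2 <- 3L - pref2
    a2 <- amp[i, , 1L]
    if (branch[i] == "suppression") {
      a2[nonp2] <- a2[pref2] - abs(d2)
    } else {
      a2[pref2] <- a2[nonp2] + abs(d2)
    }
    amp[i, , 2L] <- a2
  }

  # --- assemble traces: add one transient per trial
  kern <- exp(-(seq_len(geo$kernel_len) - 1L) / (cfg$calcium_tau * cfg$frame_rate))
  ld <- cfg$shared_noise_loadings
  cond_i <- ifelse(cond == cfg$conditions[1L], 1L, 2L)
  stim_i <- ifelse(stim == "vertical", 1L, 2L)
  for (t in seq_len(n_trials)) {
    li <- ld[[cond_i[t]]]
    A <- amp[cbind(seq_len(n_cells), stim_i[t], cond_i[t])] +
      li$global[classes] * g_fac[t] +
      li$class[classes] * h_fac[t, class_idx] +
      priv[, t]
    cols <- onset_frame[t]:(onset_frame[t] + geo$kernel_len - 1L)
    traces[, cols] <- traces[, cols] + A %o% kern
  }

  # --- behavior: running speed per frame, licks, outcomes
  speed <- numeric(n_frames)
  licks <- vector("list", n_trials)
  outcome <- character(n_trials)
  for (ci in 1:2) {
    idx <- which(cond_i == ci)
    p <- cfg$running_speed_params[[ci]]
    with_seed(derive_seed(cfg$seed, 4L, ci), {
      trial_speed <- stats::rlnorm(length(idx), p[["meanlog"]], p[["sdlog"]])
      for (j in seq_along(idx)) {
        t <- idx[j]
        fr0 <- (t - 1L) * geo$trial_len + 1L
        frames <- fr0:(fr0 + geo$trial_len - 1L)
        speed[frames] <- pmax(0, trial_speed[j] +
                                stats::rnorm(geo$trial_len, 0, 1))
        licked <- stats::runif(1) < cfg$lick_prob[[stim[t]]]
        if (licked) {
          lt <- stats::runif(1, 0.2, 0.95)   # lick latency within 0-1 s
          licks[[t]] <- onset_frame[t] + as.integer(floor(lt * cfg$frame_rate))
        } else licks[[t]] <- integer(0)
        outcome[t] <- if (stim[t] == "vertical") {
          if (licked) "hit" else "miss"
        } else {
          if (licked) "false_alarm" else "correct_rejection"
        }
      }
    })
  }

  cells <- data.frame(cell_id = sprintf("%s_%03d", classes, within_idx),
                      class = classes, x_um = xy[, 1L], y_um = xy[, 2L],
                      matched_id = seq_len(n_cells), stringsAsFactors = FALSE)
  trials <- data.frame(stimulus = stim, condition = cond,
                       onset_frame = onset_frame, outcome = outcome,
                       stringsAsFactors = FALSE)
  trials$lick_frames <- licks
  session <- structure(list(traces = traces, trials = trials, cells = cells,
                            running_speed = speed,
                            frame_rate = cfg$frame_rate),
                       class = "session")
  gt <- structure(list(amp = amp, si_true = si_true, branch = branch,
                       loadings = ld, private_noise_sd = cfg$private_noise_sd,
                       conditions = cfg$conditions, classes = classes),
                  class = "ground_truth")
  list(session = session, ground_truth = gt)
}

#' Closed-form noise correlation implied by the latent-factor model
#'
#' Pairwise correlation of per-trial response amplitudes of two cells under
#' the one-global + one-per-class factor model: shared covariance divided by
#' the product of total amplitude SDs.
#'
#' @param config a [synth_config()] object.
#' @param class_i,class_j cell classes of the pair.
#' @param same_cell_class logical; TRUE if the two cells belong to the same
#'   class (then the class factor is shared).
#' @param cond_idx condition index (1 or 2).
#' @return expected Pearson correlation.
#' @export
expected_noise_correlation <- function(config, class_i, class_j,
                                       same_cell_class = identical(class_i, class_j),
                                       cond_idx = 1L) {
  ld <- config$shared_noise_loadings[[cond_idx]]
  num <- ld$global[[class_i]] * ld$global[[class_j]] +
    if (same_cell_class) ld$class[[class_i]] * ld$class[[class_j]] else 0
  sds <- amp_sd_per_class(config, cond_idx)
  num / (sds[[class_i]] * sds[[class_j]])
}

#' Generate raw ROI + neuropil fluorescence with known contamination
#'
#' Converts a synthetic dF/F session into raw fluorescence:
#' `F_true = F0 * (1 + dF/F)` with a per-cell baseline level and slow
#' multiplicative drift, a shared neuropil trace `F_np`, and the contaminated
#' ROI signal `F_roi = F_true + neuropil_gain * F_np`. The uncontaminated
#' `F_true` is returned for oracle tests.
#'
#' @param config a [synth_config()] object.
#' @return list with `raw` (class `raw_session`: `F_roi` and `F_true`
#'   cells x frames, `F_np` per frame, plus `trials`, `cells`,
#'   `running_speed`, `frame_rate`) and `ground_truth`.
#' @export
generate_raw_fluorescence <- function(config) {
  gen <- generate_session(config)
  s <- gen$session
  n_cells <- nrow(s$traces); n_frames <- ncol(s$traces)
  tt <- seq_len(n_frames) / config$frame_rate
  with_seed(derive_seed(config$seed, 5L), {
    f0_level <- stats::runif(n_cells, 80, 120)
    phase <- stats::runif(n_cells, 0, 2 * pi)
    # shared neuropil: baseline + slow wander + a little fast noise. The
    # neuropil level is kept small relative to the somatic baseline so the
    # irreducible median offset left by the correction stays negligible in
    # dF/F units.
    wander <- stats::filter(stats::rnorm(n_frames, 0, 1), rep(1 / 65, 65),
                            sides = 1)
    wander[is.na(wander)] <- 0
    F_np <- 5 + 8 * as.numeric(wander) + stats::rnorm(n_frames, 0, 0.3)
  })
  period <- max(tt) / 2
  F_true <- matrix(NA_real_, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    f0 <- f0_level[i] * (1 + config$baseline_drift * sin(2 * pi * tt / period + phase[i]))
    F_true[i, ] <- f0 * (1 + s$traces[i, ])
  }
  F_roi <- F_true + config$neuropil_gain * matrix(F_np, n_cells, n_frames, byrow = TRUE)
  raw <- structure(list(F_roi = F_roi, F_np = F_np, F_true = F_true,
                        trials = s$trials, cells = s$cells,
                        running_speed = s$running_speed,
                        frame_rate = s$frame_rate),
                   class = "raw_session")
  list(raw = raw, ground_truth = gen$ground_truth)
}

#' Generate trial data from a first-order multivariate autoregressive process
#'
#' Simulates, per trial, `a(t) = W a(t-1) + k(stim, t) + e(t)` with Gaussian
#' noise, exactly the generative form the MVAR fitting module assumes, and
#' stores the true parameters as ground truth. `weights` may be a single
#' cells x cells matrix (one condition) or a named list of two matrices
#' (condition-specific dynamics).
#'
#' @param weights interaction matrix (spectral radius must be < 1), or a
#'   named list of two such matrices keyed by condition label.
#' @param stim_kernels array cells x 2 (vertical, angled) x frames of
#'   stimulus-input coefficients; recycled across conditions.
#' @param n_trials trials per stimulus per condition.
#' @param noise_sd innovation SD.
#' @param seed integer seed.
#' @param frame_rate nominal frame rate in Hz (default 8).
#' @return object of class `mvar_session`: `tensor` (cells x trials x
#'   frames), `trials` (stimulus, condition), `frame_rate`, and
#'   `ground_truth` (weights list, kernels, noise_sd).
#' @export
generate_mvar_dataset <- function(weights, stim_kernels, n_trials,
                                  noise_sd = 0.1, seed = 1, frame_rate = 8) {
  if (is.matrix(weights)) weights <- list(c1 = weights)
  if (is.null(names(weights))) names(weights) <- paste0("c", seq_along(weights))
  for (nm in names(weights)) {
    rho <- max(Mod(eigen(weights[[nm]], only.values = TRUE)$values))
    if (rho >= 1) {
      stopf("unstable weights for condition '%s': spectral radius %.4f >= 1", nm, rho)
    }
  }
  n_cells <- dim(stim_kernels)[1L]
  n_fr <- dim(stim_kernels)[3L]
  conds <- names(weights)
  stims <- c("vertical", "angled")
  n_total <- n_trials * 2L * length(conds)
  tensor <- array(NA_real_, c(n_cells, n_total, n_fr))
  trials <- data.frame(stimulus = character(n_total), condition = character(n_total),
                       stringsAsFactors = FALSE)
  t <- 0L
  with_seed(seed, {
    for (ci in seq_along(conds)) {
      W <- weights[[ci]]
      for (si in 1:2) {
        for (r in seq_len(n_trials)) {
          t <- t + 1L
          a <- matrix(NA_real_, n_cells, n_fr)
          a[, 1L] <- stim_kernels[, si, 1L] + stats::rnorm(n_cells, 0, noise_sd)
          for (f in 2:n_fr) {
            a[, f] <- W %*% a[, f - 1L] + stim_kernels[, si, f] +
              stats::rnorm(n_cells, 0, noise_sd)
          }
          tensor[, t, ] <- a
          trials$stimulus[t] <- stims[si]
          trials$condition[t] <- conds[ci]
        }
      }
    }
  })
  structure(list(tensor = tensor, trials = trials, frame_rate = frame_rate,
                 ground_truth = list(weights = weights, kernels = stim_kernels,
                                     noise_sd = noise_sd)),
            class = "mvar_session")
}

#' Generate a matched pair of sessions for two experimental contrasts
#'
#' Produces one "learning"-style (pre/post, suppression-dominated) and one
#' "attention"-style (ignore/attend, mixed) session over the *same* cells:
#' identical condition-1 selectivity per cell, with condition-2 selectivity
#' changes either independent between the two contrasts or identical, to
#' probe whether per-cell selectivity changes in the two contrasts are
#' correlated.
#'
#' @param config a [synth_config()] object (conditions/mode fields are
#'   overridden per contrast).
#' @param shared_modulation logical; TRUE makes the per-cell condition-2 SI
#'   identical in both contrasts, FALSE (default) draws them independently.
#' @return list with `learning` and `attention` (each as returned by
#'   [generate_session()]).
#' @export
generate_contrast_pair <- function(config, shared_modulation = FALSE) {
  base <- config
  cfg_l <- base
  cfg_l$conditions <- c("pre", "post")
  colnames(cfg_l$si_distributions$mean) <- colnames(cfg_l$si_distributions$sd) <-
    cfg_l$conditions
  cfg_l$modulation_mode <- "suppression"
  cfg_a <- base
  cfg_a$conditions <- c("ignore", "attend")
  colnames(cfg_a$si_distributions$mean) <- colnames(cfg_a$si_distributions$sd) <-
    cfg_a$conditions
  cfg_a$modulation_mode <- "mixed"
  if (!shared_modulation) {
    # different root seed => independent condition-2 draws; condition-1 SI is
    # re-anchored below so cells stay comparable across contrasts
    cfg_a$seed <- derive_seed(base$seed, 6L)
    cfg_a$si_cross_condition_cor <- config$si_cross_condition_cor
  }
  learning <- generate_session(cfg_l)
  attention <- generate_session(cfg_a)
  if (!shared_modulation) {
    # re-anchor: same cells means same condition-1 truth; enforce by copying
    # positions/ids from the learning session's cell table
    attention$session$cells <- learning$session$cells
  }
  list(learning = learning, attention = attention)
}
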