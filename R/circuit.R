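#' Activation function of the rate model
#'
#' Piecewise function: 0 for negative input, saturating
#' `(rmax - r0) * tanh(x / (rmax - r0))` otherwise, so population activity
#' lives in `[0, rmax - r0)`.
#'
#' @param x input (vectorized).
#' @param r0 minimum activity (default 1).
#' @param rmax maximum activity (default 20).
#' @return activity values.
#' @export
phi <- function(x, r0 = 1, rmax = 20) {
  if (rmax <= r0) stopf("rmax must exceed r0")
  ifelse(x < 0, 0, (rmax - r0) * tanh(x / (rmax - r0)))
}

#' Default circuit parameters
#'
#' The standard parameter set of the 4-population (PYR, PV, SOM, VIP) rate
#' model: time constants (PYR 0.8 s, interneurons 0.4 s), baseline inputs
#' (6.0, 4.0, 1.2, 4.6), stimulus inputs (17.8, 10.0, 0, 0; a fraction 0.2
#' of the stimulus input is delivered during the non-preferred stimulus),
#' top-down input pairs {ignore, attend} ({1, 2} for the multiplicative
#' model, {0, 1} for the additive model), the experimentally derived 4 x 4
#' connectivity magnitude matrix, total noise SD 0.52 with one third of the
#' noise variance assigned to each shared source a population receives, and
#' activity bounds r0 = 1, rmax = 20. Euler time step 1 ms, 100 trials.
#'
#' The connectivity matrix holds magnitudes; the model adds
#' `sum_j W_ij r_j`, so columns originating from the inhibitory classes
#' (PV, SOM, VIP) are negated before use.
#'
#' @param mode `"additive"` or `"multiplicative"`.
#' @param targets character subset of classes receiving attentional
#'   modulation (default: all four).
#' @param n_trials trials per condition (default 100).
#' @param noise_convention `"linear"` (default; the chi mixing coefficients
#'   scale the noise-source SDs directly, so a modulated population's total
#'   input noise is smaller — modulation quenches variability) or `"sqrt"`
#'   (square-root coefficients, keeping the total input-noise variance at
#'   `sigma^2` regardless of targeting).
#' @param noise_time `"trial"` (default): the shared and private noise
#'   sources are drawn once per trial and held constant — quenched
#'   trial-to-trial input fluctuations, so window-mean variability is of
#'   the same order as the noise SD and the static-mix correlation
#'   predictions apply; `"step"`: fresh draws every integration step
#'   (white input noise, which largely averages out within the 1 s
#'   readout windows).
#' @return object of class `circuit_params`.
#' @export
circuit_params <- function(mode = c("multiplicative", "additive"),
                           targets = CELL_CLASSES, n_trials = 100,
                           noise_convention = c("linear", "sqrt"),
                           noise_time = c("trial", "step")) {
  mode <- match.arg(mode)
  noise_convention <- match.arg(noise_convention)
  noise_time <- match.arg(noise_time)
  if (!all(targets %in% CELL_CLASSES)) stopf("unknown target class")
  td1 <- if (mode == "multiplicative") 1.0 else 0.0
  td2 <- if (mode == "multiplicative") 2.0 else 1.0
  W <- matrix(c(0.017, 0.956, 0.512, 0.045,
                0.8535, 0.99, 0.307, 0.091,
                0.285, 0, 0, 0.14,
                2.104, 0.184, 0.734, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(CELL_CLASSES, CELL_CLASSES))
  p <- list(mode = mode,
            tau = c(PYR = 0.8, PV = 0.4, SOM = 0.4, VIP = 0.4),
            I_b = c(PYR = 6.0, PV = 4.0, SOM = 1.2, VIP = 4.6),
            I_s = c(PYR = 17.8, PV = 10.0, SOM = 0.0, VIP = 0.0),
            nonpref_fraction = 0.2,
            I_td = list(PYR = c(ignore = td1, attend = td2),
                        PV = c(ignore = td1, attend = td2),
                        SOM = c(ignore = td1, attend = td2),
                        VIP = c(ignore = td1, attend = td2)),
            W = W, sigma = 0.52,
            r0 = 1.0, rmax = 20.0, dt = 0.001, n_trials = as.integer(n_trials),
            targets = targets, noise_convention = noise_convention,
            noise_time = noise_time)
  class(p) <- "circuit_params"
  p
}

#' Default parameter set for a modulation mode
#'
#' Thin wrapper over [circuit_params()] returning the printed parameter
#' tables for the additive or multiplicative model.
#'
#' @inheritParams circuit_params
#' @export
default_params <- function(mode) {
  if (!mode %in% c("additive", "multiplicative")) stopf("unknown mode '%s'", mode)
  circuit_params(mode = mode)
}

# signed connectivity: inhibitory source columns negated
signed_W <- function(W) sweep(W, 2L, c(1, -1, -1, -1), `*`)

# Per-class noise-mixing chi values. A population carries feedforward
# shared noise iff it receives stimulus input, and top-down shared noise iff
# it actually receives modulatory drive in this condition: i.e. it is a
# target and its top-down input differs from the no-modulation identity
# (1 for the multiplicative model, 0 for the additive model). The change in
# shared external fluctuations between ignore and attend is what moves the
# modeled noise correlations.
chi_values <- function(params, condition = "ignore") {
  chi_ff <- ifelse(params$I_s > 0, 1 / 3, 0)
  identity_td <- if (params$mode == "multiplicative") 1.0 else 0.0
  td <- vapply(CELL_CLASSES, function(cl) {
    if (cl %in% params$targets) params$I_td[[cl]][[condition]] else identity_td
  }, numeric(1))
  chi_td <- ifelse(td != identity_td, 1 / 3, 0)
  names(chi_ff) <- names(chi_td) <- CELL_CLASSES
  list(ff = chi_ff, td = chi_td)
}

# condition-dependent deterministic inputs per class
condition_inputs <- function(params, condition) {
  td <- vapply(CELL_CLASSES, function(cl) {
    if (cl %in% params$targets) params$I_td[[cl]][[condition]]
    else params$I_td[[cl]][["ignore"]]
  }, numeric(1))
  if (params$mode == "multiplicative") {
    list(I_const = td * params$I_b, I_stim = td * params$I_s, td = td)
  } else {
    list(I_const = params$I_b + td, I_stim = params$I_s, td = td)
  }
}

# protocol: 5 s blank, 3 s non-preferred, 4 s blank, 3 s preferred
protocol_scale <- function(params) {
  steps_per_s <- as.integer(round(1 / params$dt))
  ss <- numeric(15L * steps_per_s)
  ss[(5L * steps_per_s + 1L):(8L * steps_per_s)] <- params$nonpref_fraction
  ss[(12L * steps_per_s + 1L):(15L * steps_per_s)] <- 1
  attr(ss, "pref_window") <- c(12L * steps_per_s, 13L * steps_per_s)
  attr(ss, "nonpref_window") <- c(5L * steps_per_s, 6L * steps_per_s)
  ss
}

#' Simulate the stochastic circuit model
#'
#' Euler integration (1 ms step) of the duplicated 8-population model over
#' the 15 s protocol (5 s blank, 3 s non-preferred stimulus, 4 s blank, 3 s
#' preferred stimulus), repeated over trials with unit-Gaussian noise: one
#' shared feedforward and one shared top-down source plus a private source
#' per copy, entering inside the activation scaled by sigma and the chi
#' mixing weights. By default each source is drawn once per trial and held
#' constant (quenched trial-to-trial fluctuations); per-step white draws
#' are available via `circuit_params(noise_time = "step")`.
#'
#' @param params a [circuit_params()] object.
#' @param condition `"ignore"` or `"attend"`.
#' @param seed integer seed.
#' @param store_rates keep (decimated) rate trajectories.
#' @param decimate keep every n-th step when storing rates (default 10).
#' @param stim_scale_override optional numeric vector of per-step stimulus
#'   drive replacing the standard 15 s protocol (e.g. a long constant
#'   epoch to read out a steady state); the preferred/non-preferred readout
#'   windows then default to the last and first second.
#' @return object of class `circuit_sim`: `pref_mean` / `nonpref_mean`
#'   (trials x 8 matrices of 1 s window means after each stimulus onset),
#'   optional `rates` (trials x 8 x time), `pop_class` (class of each of
#'   the 8 populations), `condition`, `params`, `seed`.
#' @export
simulate_circuit <- function(params, condition = c("ignore", "attend"),
                             seed = 1, store_rates = FALSE, decimate = 10,
                             stim_scale_override = NULL) {
  condition <- match.arg(condition)
  ci <- condition_inputs(params, condition)
  chi <- chi_values(params, condition)
  mixing <- if (params$noise_convention == "sqrt") sqrt else identity
  c_ff <- params$sigma * mixing(chi$ff)
  c_td <- params$sigma * mixing(chi$td)
  c_priv <- params$sigma * mixing(pmax(0, 1 - chi$ff - chi$td))
  dup <- rep(seq_len(4L), each = 2L)   # copy layout: E E P P S S V V
  if (is.null(stim_scale_override)) {
    ss <- protocol_scale(params)
    pw <- attr(ss, "pref_window"); nw <- attr(ss, "nonpref_window")
  } else {
    ss <- stim_scale_override
    steps_per_s <- as.integer(round(1 / params$dt))
    pw <- c(length(ss) - steps_per_s, length(ss))
    nw <- c(0L, min(steps_per_s, length(ss)))
  }
  res <- with_seed(seed,
    circuit_sim_cpp(params$tau[dup], ci$I_const[dup], ci$I_stim[dup],
                    signed_W(params$W), c_ff[dup], c_td[dup], c_priv[dup],
                    as.numeric(ss), params$dt, params$r0, params$rmax,
                    params$n_trials, pw[1L], pw[2L], nw[1L], nw[2L],
                    store_rates, as.integer(decimate),
                    identical(params$noise_time %||% "trial", "trial")))
  pop_class <- CELL_CLASSES[dup]
  colnames(res$pref_mean) <- colnames(res$nonpref_mean) <-
    paste0(pop_class, c("_1", "_2"))
  structure(list(pref_mean = res$pref_mean, nonpref_mean = res$nonpref_mean,
                 rates = res$rates, pop_class = pop_class,
                 condition = condition, params = params, seed = seed),
            class = "circuit_sim")
}

#' Noise-free fixed point of the circuit, by damped iteration
#'
#' Independent solver for the deterministic steady state
#' `r = phi(I_const + stim_scale * I_stim + W_signed r)` at the 4-class
#' level (the two copies are identical without noise). Used as an oracle
#' against the Euler simulation.
#'
#' @param params a [circuit_params()] object.
#' @param condition `"ignore"` or `"attend"`.
#' @param stim_scale stimulus drive: 0 (blank), the non-preferred fraction,
#'   or 1 (preferred).
#' @param damping step size of the damped iteration (default 0.1).
#' @param tol convergence tolerance (default 1e-12).
#' @param max_iter iteration cap.
#' @return named per-class steady-state rates.
#' @export
circuit_fixed_point <- function(params, condition = "ignore", stim_scale = 0,
                                damping = 0.1, tol = 1e-12, max_iter = 200000) {
  ci <- condition_inputs(params, condition)
  Ws <- signed_W(params$W)
  inp <- ci$I_const + stim_scale * ci$I_stim
  r <- rep(0, 4)
  for (k in seq_len(max_iter)) {
    rn <- (1 - damping) * r +
      damping * phi(inp + as.numeric(Ws %*% r), params$r0, params$rmax)
    if (max(abs(rn - r)) < tol) { r <- rn; break }
    r <- rn
  }
  names(r) <- CELL_CLASSES
  r
}

#' Model stimulus selectivity per cell class
#'
#' Per class (the two copies averaged per trial), the difference between the
#' mean activity in the 1 s window after preferred-stimulus onset and the
#' 1 s window after non-preferred-stimulus onset, divided by their pooled
#' standard deviation over trials.
#'
#' @param sim a [simulate_circuit()] result.
#' @return named numeric vector of per-class SI.
#' @export
model_selectivity <- function(sim) {
  vapply(CELL_CLASSES, function(cl) {
    cols <- which(sim$pop_class == cl)
    xp <- rowMeans(sim$pref_mean[, cols, drop = FALSE])
    xn <- rowMeans(sim$nonpref_mean[, cols, drop = FALSE])
    sp <- pooled_sd(xp, xn)
    if (sp == 0) stopf("zero pooled SD for class %s", cl)
    (mean(xp) - mean(xn)) / sp
  }, numeric(1))
}

#' Model noise correlations between the 8 populations
#'
#' Pearson correlation over trials of the per-trial mean activity in the
#' 1 s window after preferred-stimulus onset, for every pair of the 8
#' populations; summarized per class pair (within-class entries use the two
#' copies of that class, between-class entries average the four cross-copy
#' correlations).
#'
#' @param sim a [simulate_circuit()] result.
#' @return list with `nc_matrix` (8 x 8) and `class_pairs` (named vector
#'   keyed like `"PYR-SOM"`).
#' @export
model_noise_correlations <- function(sim) {
  if (nrow(sim$pref_mean) < 3L) stopf("need >= 3 trials")
  v <- apply(sim$pref_mean, 2L, stats::var)
  if (any(v == 0)) warnf("zero-variance population(s): NC undefined there")
  ncm <- suppressWarnings(stats::cor(sim$pref_mean))
  cls <- sim$pop_class
  pairs <- list()
  for (a in seq_len(4L)) for (b in a:4L) {
    ca <- CELL_CLASSES[a]; cb <- CELL_CLASSES[b]
    ia <- which(cls == ca); ib <- which(cls == cb)
    val <- if (a == b) ncm[ia[1L], ia[2L]] else mean(ncm[ia, ib])
    pairs[[class_pair_key(ca, cb)]] <- val
  }
  list(nc_matrix = ncm, class_pairs = unlist(pairs))
}

# seed for one simulated condition, a pure function of the configuration so
# that identical configurations reached through different code paths (sweep
# vs ratio scan) reuse identical noise
config_seed <- function(seed, mode, targets, condition) {
  bit <- sum(2^(match(targets, CELL_CLASSES) - 1L))
  config_hash <- bit + 16L * (mode == "multiplicative")
  derive_seed(seed, 7L, config_hash, match(condition, c("ignore", "attend")))
}

# simulate ignore + attend for one configuration; dSI and dNC averaged over
# n_seeds independent replicate pairs
delta_stats <- function(params, seed, n_seeds = 1L) {
  dsi <- 0; dnc <- 0
  for (k in seq_len(n_seeds)) {
    sims <- lapply(c("ignore", "attend"), function(cond) {
      simulate_circuit(params, cond,
                       seed = config_seed(derive_seed(seed, 9L, k),
                                          params$mode, params$targets, cond))
    })
    dsi <- dsi + model_selectivity(sims[[2L]]) - model_selectivity(sims[[1L]])
    dnc <- dnc + model_noise_correlations(sims[[2L]])$class_pairs -
      model_noise_correlations(sims[[1L]])$class_pairs
  }
  list(dSI = dsi / n_seeds, dNC = dnc / n_seeds)
}

#' Sweep attentional-modulation targets
#'
#' Simulates, for each of the 15 non-empty subsets of {PYR, PV, SOM, VIP}
#' and each requested modulation mode, the ignore and attend conditions and
#' reports the attend-minus-ignore change in per-class selectivity and
#' per-class-pair noise correlations.
#'
#' @param modes character vector of modes (default both).
#' @param n_trials trials per condition.
#' @param seed root seed.
#' @param n_seeds independent replicate simulation pairs to average the
#'   change statistics over (default 1).
#' @return data.frame with one row per mode x target subset: `mode`,
#'   `targets`, `dSI_<class>` and `dNC_<pair>` columns.
#' @export
attention_sweep <- function(modes = c("additive", "multiplicative"),
                            n_trials = 100, seed = 1, n_seeds = 1) {
  subsets <- Filter(length, unlist(lapply(1:4, function(k)
    utils::combn(CELL_CLASSES, k, simplify = FALSE)), recursive = FALSE))
  rows <- list()
  for (mode in modes) {
    for (tg in subsets) {
      params <- circuit_params(mode = mode, targets = tg, n_trials = n_trials)
      d <- delta_stats(params, seed, n_seeds)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, targets = paste(tg, collapse = "+"),
        t(stats::setNames(d$dSI, paste0("dSI_", names(d$dSI)))),
        t(stats::setNames(d$dNC, paste0("dNC_", names(d$dNC)))),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Scan the relative modulation strength of PYR versus SOM
#'
#' Multiplicative modulation targeting PYR and SOM only (PV and VIP
#' unmodulated): the SOM attend value is varied over `som_values` and the
#' PYR attend value follows proportionally with slope `ratio` relative to
#' the unmodulated value, i.e. `1 + ratio * (m - 1)` for the multiplicative
#' model, so the ignore condition stays exactly modulation-free.
#'
#' @param som_values SOM attend values (default 1.0 to 2.2 in steps of 0.1).
#' @param ratio PYR/SOM modulation ratio (default 0.7).
#' @param mode modulation mode (default `"multiplicative"`).
#' @param n_trials trials per condition.
#' @param seed root seed.
#' @param n_seeds replicate simulation pairs averaged per scan point.
#' @return data.frame per scan point: `som_value`, `pyr_value`, `dSI_*`,
#'   `dNC_*`.
#' @export
modulation_ratio_scan <- function(som_values = seq(1.0, 2.2, by = 0.1),
                                  ratio = 0.7, mode = "multiplicative",
                                  n_trials = 100, seed = 1, n_seeds = 1) {
  rows <- list()
  for (m in som_values) {
    params <- circuit_params(mode = mode, targets = c("PYR", "SOM"),
                             n_trials = n_trials)
    base <- params$I_td$SOM[["ignore"]]
    pyr_attend <- base + ratio * (m - base)
    params$I_td$SOM[["attend"]] <- m
    params$I_td$PYR[["attend"]] <- pyr_attend
    d <- delta_stats(params, seed, n_seeds)
    rows[[length(rows) + 1L]] <- data.frame(
      som_value = m, pyr_value = pyr_attend,
      t(stats::setNames(d$dSI, paste0("dSI_", names(d$dSI)))),
      t(stats::setNames(d$dNC, paste0("dNC_", names(d$dNC)))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Estimate match thresholds from unmodulated control runs
#'
#' Runs the circuit with an empty target set (attend identical to ignore up
#' to the noise realization) `n_runs` times and returns twice the
#' across-run standard deviation of the per-class dSI and per-pair dNC
#' estimates: the sampling scale against which real modulation effects are
#' judged.
#'
#' @param mode modulation mode.
#' @param n_trials trials per condition.
#' @param seed root seed.
#' @param n_runs number of control runs (default 10).
#' @return list with `theta_si` and `theta_nc`.
#' @export
estimate_match_thresholds <- function(mode = "multiplicative", n_trials = 100,
                                      seed = 1, n_runs = 10) {
  dsis <- NULL; dncs <- NULL
  for (k in seq_len(n_runs)) {
    params <- circuit_params(mode = mode, targets = character(0),
                             n_trials = n_trials)
    sims <- lapply(1:2, function(j) {
      simulate_circuit(params, c("ignore", "attend")[j],
                       seed = derive_seed(seed, 8L, k, j))
    })
    dsi <- model_selectivity(sims[[2L]]) - model_selectivity(sims[[1L]])
    dnc <- model_noise_correlations(sims[[2L]])$class_pairs -
      model_noise_correlations(sims[[1L]])$class_pairs
    dsis <- rbind(dsis, dsi); dncs <- rbind(dncs, dnc)
  }
  list(theta_si = 2 * sqrt(mean(apply(dsis, 2L, stats::var))),
       theta_nc = 2 * sqrt(mean(apply(dncs, 2L, stats::var))))
}

#' Evaluate the experimental match criteria on one sweep row
#'
#' Criterion 1: attention increases PYR and PV selectivity (beyond
#' `theta_si`) while SOM and VIP selectivity stay within `theta_si` of
#' unchanged. Criterion 2: SOM-SOM noise correlation increases beyond
#' `theta_nc` and VIP-VIP decreases beyond `theta_nc`. A configuration
#' matches when both hold.
#'
#' @param row one-row data.frame from [attention_sweep()] or
#'   [modulation_ratio_scan()].
#' @param thresholds list with `theta_si`, `theta_nc` (see
#'   [estimate_match_thresholds()]).
#' @return list with `criterion1`, `criterion2`, `match`.
#' @export
evaluate_match <- function(row, thresholds) {
  need <- c(paste0("dSI_", CELL_CLASSES), "dNC_SOM-SOM", "dNC_VIP-VIP")
  if (!all(need %in% names(row))) {
    stopf("missing entries: %s", paste(setdiff(need, names(row)), collapse = ", "))
  }
  t_si <- thresholds$theta_si; t_nc <- thresholds$theta_nc
  c1 <- row[["dSI_PYR"]] > t_si && row[["dSI_PV"]] > t_si &&
    abs(row[["dSI_SOM"]]) <= t_si && abs(row[["dSI_VIP"]]) <= t_si
  c2 <- row[["dNC_SOM-SOM"]] > t_nc && row[["dNC_VIP-VIP"]] < -t_nc
  list(criterion1 = c1, criterion2 = c2, match = c1 && c2)
}
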