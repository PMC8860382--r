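#' Specification of the multivariate autoregressive model
#'
#' First-order (by default) linear dynamical system over simultaneously
#' imaged cells at frame resolution:
#' `a(t) = sum_l W_l a(t-l) + s(cell, stimulus, condition, peri-stimulus bin)
#' + e(t)`, fit by least squares over within-trial transitions only. The
#' per-bin stimulus kernels absorb the intercept (every transition carries
#' exactly one kernel indicator). Interaction weights can be shared across
#' conditions or condition-specific; stimulus kernels are always
#' condition-specific, so the shared/free comparison isolates the
#' interaction weights.
#'
#' @param lag_order autoregressive order (default 1).
#' @param weight_mode `"shared"` or `"per_condition"`.
#' @param include_running include per-frame running speed as a regressor
#'   (requires a `speed` trials x frames matrix on the data object; never
#'   used during cross-validation).
#' @param ridge_penalty L2 penalty on all coefficients (default 0 = plain
#'   least squares).
#' @return object of class `mvar_spec`.
#' @export
mvar_spec <- function(lag_order = 1, weight_mode = c("shared", "per_condition"),
                      include_running = FALSE, ridge_penalty = 0) {
  weight_mode <- match.arg(weight_mode)
  if (lag_order < 1) stopf("lag_order must be >= 1")
  if (ridge_penalty < 0) stopf("ridge_penalty must be >= 0")
  structure(list(lag_order = as.integer(lag_order), weight_mode = weight_mode,
                 include_running = include_running,
                 ridge_penalty = ridge_penalty), class = "mvar_spec")
}

# Build the transition design matrix. `data` needs $tensor (cells x trials x
# frames) and $trials (stimulus, condition). Rows = within-trial transitions.
build_mvar_design <- function(data, spec, trial_subset = NULL) {
  tensor <- data$tensor
  trials <- data$trials
  if (!is.null(trial_subset)) {
    tensor <- tensor[, trial_subset, , drop = FALSE]
    trials <- trials[trial_subset, , drop = FALSE]
  }
  n_cells <- dim(tensor)[1L]
  n_trials <- dim(tensor)[2L]
  n_fr <- dim(tensor)[3L]
  L <- spec$lag_order
  if (n_fr <= L) stopf("trials too short for lag order %d", L)
  frames_to <- (L + 1L):n_fr
  n_per_trial <- length(frames_to)
  n_rows <- n_trials * n_per_trial
  conds <- sort(unique(data$trials$condition))
  stims <- sort(unique(data$trials$stimulus))
  per_cond <- spec$weight_mode == "per_condition" && length(conds) > 1L

  # response: a(t)
  Y <- matrix(NA_real_, n_rows, n_cells)
  lag_cols <- n_cells * L * (if (per_cond) length(conds) else 1L)
  kern_levels <- expand.grid(frame = frames_to, stimulus = stims,
                             condition = conds, stringsAsFactors = FALSE)
  X <- matrix(0, n_rows, lag_cols + nrow(kern_levels))
  kern_key <- paste(kern_levels$condition, kern_levels$stimulus, kern_levels$frame)
  row <- 0L
  for (tr in seq_len(n_trials)) {
    ci <- match(trials$condition[tr], conds)
    rows <- row + seq_len(n_per_trial)
    Y[rows, ] <- t(tensor[, tr, frames_to, drop = FALSE][, 1L, ])
    for (l in seq_len(L)) {
      block0 <- if (per_cond) ((ci - 1L) * L + (l - 1L)) * n_cells else (l - 1L) * n_cells
      X[rows, block0 + seq_len(n_cells)] <- t(tensor[, tr, frames_to - l, drop = FALSE][, 1L, ])
    }
    kcols <- lag_cols + match(paste(trials$condition[tr], trials$stimulus[tr], frames_to),
                              kern_key)
    X[cbind(rows, kcols)] <- 1
    row <- row + n_per_trial
  }
  if (spec$include_running) {
    if (is.null(data$speed)) stopf("include_running requires a 'speed' trials x frames matrix")
    sp <- data$speed
    if (!is.null(trial_subset)) sp <- sp[trial_subset, , drop = FALSE]
    X <- cbind(X, as.vector(t(sp[, frames_to, drop = FALSE])))
  }
  list(X = X, Y = Y, lag_cols = lag_cols, kern_levels = kern_levels,
       conds = conds, stims = stims, per_cond = per_cond, n_cells = n_cells,
       frames_to = frames_to,
       trial_of_row = rep(seq_len(n_trials), each = n_per_trial))
}

# least-squares / ridge solve; returns coefficients and per-column SEs
solve_mvar <- function(X, Y, penalty) {
  p <- ncol(X)
  if (penalty > 0) {
    XtX <- crossprod(X) + diag(penalty, p)
    cf <- solve(XtX, crossprod(X, Y))
    XtXinv <- solve(XtX)
  } else {
    qrx <- qr(X)
    if (qrx$rank < p) {
      stopf("design matrix rank-deficient (%d < %d); set ridge_penalty > 0",
            qrx$rank, p)
    }
    cf <- qr.coef(qrx, Y)
    XtXinv <- chol2inv(qr.R(qrx))
  }
  resid <- Y - X %*% cf
  df <- max(1L, nrow(X) - p)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtXinv), sigma2))
  list(coef = cf, se = se, resid = resid)
}

#' Fit the MVAR interaction model
#'
#' @param data object with `tensor` (cells x trials x frames) and `trials`
#'   (columns `stimulus`, `condition`): an [align_to_trials()] result or a
#'   [generate_mvar_dataset()] output.
#' @param spec an [mvar_spec()].
#' @return object of class `mvar_fit`: `W` (named list per condition;
#'   identical entries in shared mode) each cells x cells (x lag if
#'   `lag_order > 1`), `W_se` (matching standard errors), `kernels`
#'   (data.frame of per-cell stimulus-input coefficients), `spec`, plus the
#'   design metadata needed for prediction.
#' @export
fit_mvar <- function(data, spec = mvar_spec()) {
  if (dim(data$tensor)[1L] < 2L) stopf("need >= 2 cells")
  des <- build_mvar_design(data, spec)
  fit <- solve_mvar(des$X, des$Y, spec$ridge_penalty)
  n <- des$n_cells
  L <- spec$lag_order
  Wof <- function(block0) {
    w <- array(NA_real_, c(n, n, L))
    ws <- array(NA_real_, c(n, n, L))
    for (l in seq_len(L)) {
      cols <- block0 + (l - 1L) * n + seq_len(n)
      w[, , l] <- t(fit$coef[cols, , drop = FALSE])
      ws[, , l] <- t(fit$se[cols, , drop = FALSE])
    }
    if (L == 1L) list(W = w[, , 1L], se = ws[, , 1L]) else list(W = w, se = ws)
  }
  conds <- des$conds
  W <- list(); W_se <- list()
  if (des$per_cond) {
    for (ci in seq_along(conds)) {
      b <- Wof(((ci - 1L) * L) * n)
      W[[conds[ci]]] <- b$W; W_se[[conds[ci]]] <- b$se
    }
  } else {
    b <- Wof(0L)
    for (ci in seq_along(conds)) { W[[conds[ci]]] <- b$W; W_se[[conds[ci]]] <- b$se }
  }
  kern <- des$kern_levels
  # cells x kernel-level matrix of stimulus-input coefficients
  kern_coef <- t(fit$coef[des$lag_cols + seq_len(nrow(des$kern_levels)), ,
                          drop = FALSE])
  structure(list(W = W, W_se = W_se, kernels = kern, kernel_coef = kern_coef,
                 spec = spec, conds = conds, stims = des$stims,
                 n_cells = des$n_cells), class = "mvar_fit")
}

# one-step-ahead predictions for given rows of a design built with the same
# spec/levels as the fit
predict_rows <- function(fit_coef, X) X %*% fit_coef

#' Leave-one-out cross-validation of the MVAR model
#'
#' Holds out each vertical-grating trial of the second condition in turn,
#' fits the model on all remaining trials, and predicts the held-out trial
#' one-step-ahead from its observed previous-frame activity (teacher
#' forcing). Per cell, errors are pooled over all held-out trials and turned
#' into an R-squared relative to a baseline model that predicts the
#' trial-averaged response profile of the training trials:
#' `R2 = 1 - SSE_mvar / SSE_trial_average`. Train R-squared is the same
#' quantity computed in-sample on the training vertical trials, averaged
#' over folds. Running speed is never included here.
#'
#' @param data as in [fit_mvar()].
#' @param spec an [mvar_spec()]; `include_running` is forced off.
#' @param holdout_condition condition whose vertical trials are held out
#'   (default: last condition label present).
#' @param max_folds cap on the number of leave-one-out folds; when the
#'   condition has more vertical trials, only the first `max_folds` are held
#'   out in turn (deterministic).
#' @return list with `test_R2`, `train_R2` (per cell; NA where the baseline
#'   SSE is zero), `overfit` (mean over cells of train - test), `n_folds`.
#' @export
crossvalidate_mvar <- function(data, spec = mvar_spec(),
                               holdout_condition = NULL, max_folds = Inf) {
  spec$include_running <- FALSE
  trials <- data$trials
  conds <- sort(unique(trials$condition))
  if (is.null(holdout_condition)) holdout_condition <- conds[length(conds)]
  fold_trials <- which(trials$stimulus == "vertical" &
                         trials$condition == holdout_condition)
  if (length(fold_trials) < 3L) stopf("need >= 3 vertical trials in '%s'",
                                      holdout_condition)
  all_vert <- fold_trials
  if (length(fold_trials) > max_folds) fold_trials <- fold_trials[seq_len(max_folds)]
  full <- build_mvar_design(data, spec)
  n_cells <- full$n_cells
  frames_to <- full$frames_to
  sse_test <- sse_test_base <- matrix(0, n_cells, 1L)
  train_r2 <- matrix(NA_real_, n_cells, length(fold_trials))
  for (f in seq_along(fold_trials)) {
    ho <- fold_trials[f]
    test_rows <- which(full$trial_of_row == ho)
    train_rows <- setdiff(seq_len(nrow(full$X)), test_rows)
    fit <- solve_mvar(full$X[train_rows, , drop = FALSE],
                      full$Y[train_rows, , drop = FALSE], spec$ridge_penalty)
    # baseline: trial-averaged profile of training vertical/holdout trials
    tr_same <- setdiff(all_vert, ho)
    psth <- apply(data$tensor[, tr_same, frames_to, drop = FALSE], c(1, 3), mean)
    pred <- full$X[test_rows, , drop = FALSE] %*% fit$coef
    err <- t(full$Y[test_rows, , drop = FALSE]) - t(pred)       # cells x frames
    errb <- t(full$Y[test_rows, , drop = FALSE]) - psth
    sse_test <- sse_test + rowSums(err^2)
    sse_test_base <- sse_test_base + rowSums(errb^2)
    # in-sample R2 on the training vertical/holdout trials
    tr_rows <- which(full$trial_of_row %in% tr_same)
    predt <- full$X[tr_rows, , drop = FALSE] %*% fit$coef
    sse_tr <- colSums((full$Y[tr_rows, , drop = FALSE] - predt)^2)
    base_tr <- full$Y[tr_rows, , drop = FALSE] -
      t(psth[, rep(seq_along(frames_to), times = length(tr_same)), drop = FALSE])
    # rows are ordered trial-major, frames within trial, matching psth tiling
    sse_trb <- colSums(base_tr^2)
    train_r2[, f] <- ifelse(sse_trb > 0, 1 - sse_tr / sse_trb, NA_real_)
  }
  test_R2 <- ifelse(sse_test_base > 0, 1 - sse_test / sse_test_base, NA_real_)
  if (anyNA(test_R2)) warnf("%d cell(s) skipped: zero baseline SSE", sum(is.na(test_R2)))
  train_R2 <- rowMeans(train_r2)
  list(test_R2 = as.numeric(test_R2), train_R2 = train_R2,
       overfit = mean(train_R2 - test_R2, na.rm = TRUE),
       n_folds = length(fold_trials))
}

#' Per-session overfitting estimate
#'
#' Mean over cells of (train R-squared minus test R-squared).
#'
#' @param train_R2,test_R2 per-cell R-squared vectors on the same cells.
#' @return scalar overfitting estimate.
#' @export
overfitting_estimate <- function(train_R2, test_R2) {
  if (length(train_R2) != length(test_R2)) stopf("R2 vectors differ in length")
  mean(train_R2 - test_R2, na.rm = TRUE)
}

#' Match overfitting distributions between two session groups
#'
#' Iteratively removes from group B the session whose overfitting estimate
#' is most extreme relative to group A's mean until a two-sample t test no
#' longer distinguishes the groups (p > alpha). Deterministic given the
#' inputs.
#'
#' @param overfits_A,overfits_B per-session overfitting estimates.
#' @param alpha t-test threshold to reach (default 0.05).
#' @return list with `retained` (indices into `overfits_B`), `removed`,
#'   and `p_final`.
#' @export
match_overfitting_distributions <- function(overfits_A, overfits_B, alpha = 0.05) {
  if (length(overfits_A) < 3L || length(overfits_B) < 3L) {
    stopf("need >= 3 sessions per group")
  }
  retained <- seq_along(overfits_B)
  repeat {
    p <- stats::t.test(overfits_A, overfits_B[retained])$p.value
    if (p > alpha) break
    if (length(retained) <= 3L) {
      stopf("cannot match distributions: group B reduced to 3 sessions (p = %.3g)", p)
    }
    worst <- retained[which.max(abs(overfits_B[retained] - mean(overfits_A)))]
    retained <- setdiff(retained, worst)
  }
  list(retained = retained, removed = setdiff(seq_along(overfits_B), retained),
       p_final = p)
}
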