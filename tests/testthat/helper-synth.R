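# small shared fixtures, built in code

small_config <- function(seed = 1, ...) {
  synth_config(n_cells_per_class = c(PYR = 12, PV = 4, SOM = 4, VIP = 4),
               n_trials_per_stim_per_cond = 30, seed = seed, ...)
}

# minimal aligned-like object for analyses that consume evoked responses
fake_aligned <- function(evoked, trials, classes = NULL, baseline = NULL,
                         x_um = NULL, y_um = NULL) {
  n_cells <- nrow(evoked)
  if (is.null(classes)) classes <- rep("PYR", n_cells)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
                      class = classes,
                      x_um = x_um %||% rep(0, n_cells),
                      y_um = y_um %||% rep(0, n_cells),
                      stringsAsFactors = FALSE)
  structure(list(
    tensor = array(0, c(n_cells, nrow(trials), 4)),
    offsets = -1:2,
    evoked = evoked,
    baseline = baseline %||% matrix(0, n_cells, nrow(trials)),
    trials = trials, cells = cells, frame_rate = 8,
    window = c(-0.125, 0.375), response_win = c(0, 0.25),
    baseline_win = c(-0.125, 0)
  ), class = "aligned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable random interaction matrix
stable_weights <- function(n, scale = 0.5, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * n, 0, scale / sqrt(n)), n)
}

# simple peri-stimulus input kernels, cells x 2 stimuli x frames
simple_kernels <- function(n, n_frames = 28, seed = 1) {
  set.seed(seed)
  K <- array(0, c(n, 2, n_frames))
  for (s in 1:2) for (f in 5:min(20, n_frames)) {
    K[, s, f] <- rnorm(n, ifelse(s == 1, 0.5, 0.2), 0.2)
  }
  K
}
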