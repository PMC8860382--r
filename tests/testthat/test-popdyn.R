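test_that("difference-PSTHs vanish for identical conditions and ignore offsets", {
  cfg <- small_config(seed = 51)
  s <- generate_session(cfg)$session
  al <- align_to_trials(s)
  d0 <- difference_psth(al, al, "vertical", "pre", "pre")
  expect_true(all(abs(d0$matrix) < 1e-12))
  # adding a constant to all traces leaves the difference unchanged
  s2 <- s
  s2$traces <- s$traces + 0.37
  al2 <- align_to_trials(s2)
  d1 <- difference_psth(al, al, "vertical", "pre", "post")
  d2 <- difference_psth(al2, al2, "vertical", "pre", "post")
  expect_equal(d2$matrix, d1$matrix, tolerance = 1e-10)
})

test_that("suppression-mode sessions give negative mean response differences", {
  # learning-style: condition-2 selectivity gains come from suppressing the
  # non-preferred response, so the angled-stimulus difference-PSTH is
  # negative on average over cells in the response window
  si <- default_si_distributions()
  si$mean["PYR", ] <- c(0.2, 0.8)
  cfg <- synth_config(n_cells_per_class = c(PYR = 40, PV = 4, SOM = 4, VIP = 4),
                      n_trials_per_stim_per_cond = 80, seed = 52,
                      modulation_mode = "suppression", si_distributions = si)
  s <- generate_session(cfg)$session
  al <- align_to_trials(s)
  d <- difference_psth(al, al, "angled", "pre", "post")
  win <- match(0:7, d$offsets)
  expect_lt(mean(d$matrix[, win]), 0)
})

test_that("PCA of difference-PSTHs recovers planted low-rank structure", {
  fr <- 8
  offsets <- -4:23
  # rank-1: every row a multiple of one profile
  u <- sin(seq(0, pi, length.out = 8))
  M <- matrix(0, 30, length(offsets))
  M[, match(0:7, offsets)] <- outer(rnorm(30, 1, 0.5), u)
  dp <- structure(list(matrix = M, offsets = offsets, stimulus = "vertical",
                       frame_rate = fr), class = "difference_psth")
  p <- pca_difference_psths(dp)
  expect_gt(p$variance_explained[1], 99.999)
  # two orthogonal factors with 9:1 variance ratio -> about 90/10 split
  v <- cos(seq(0, 2 * pi, length.out = 8)); v <- v - sum(v * u) * u / sum(u^2)
  set.seed(2)
  a <- rnorm(400, 0, 3); b <- rnorm(400, 0, 1)
  M2 <- matrix(0, 400, length(offsets))
  M2[, match(0:7, offsets)] <- outer(a, u / sqrt(sum(u^2))) +
    outer(b, v / sqrt(sum(v^2)))
  dp2 <- structure(list(matrix = M2, offsets = offsets, stimulus = "vertical",
                        frame_rate = fr), class = "difference_psth")
  p2 <- pca_difference_psths(dp2)
  expect_equal(p2$variance_explained[1:2], c(90, 10), tolerance = 2)
  # reconstruction from all components reproduces the windowed matrix
  X <- M2[, match(0:7, offsets)]
  Xc <- scale(X, center = p2$center, scale = FALSE)
  expect_equal(p2$weights %*% t(p2$components), unclass(Xc),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(diff(p2$variance_explained) <= 1e-9))
  expect_equal(sum(p2$variance_explained), 100)
  # deterministic sign canonicalization
  p3 <- pca_difference_psths(dp2)
  expect_identical(p2$components, p3$components)
  expect_error(pca_difference_psths(structure(list(matrix = M2 * 0,
    offsets = offsets, stimulus = "v", frame_rate = fr),
    class = "difference_psth")), "zero")
})

test_that("noise correlations reflect shared variability and nothing else", {
  n_tr <- 300
  trials <- data.frame(stimulus = "vertical", condition = "c1",
                       stringsAsFactors = FALSE)[rep(1, n_tr), ]
  set.seed(3)
  shared <- rnorm(n_tr)
  # two cells driven by the same factor only: NC near 1
  ev <- rbind(1 + shared, 2 + 3 * shared)
  al <- fake_aligned(ev, trials)
  nc <- noise_correlations(al, "vertical", "c1")
  expect_equal(nc$pairs$NC, 1, tolerance = 1e-12)
  # independent cells at large n: |NC| below the 2/sqrt(n) null bound
  set.seed(4)
  n_big <- 10000
  trials_big <- trials[rep(1, n_big), ]
  ev2 <- matrix(rnorm(4 * n_big), 4)
  al2 <- fake_aligned(ev2, trials_big)
  nc2 <- noise_correlations(al2, "vertical", "c1")
  expect_lt(max(abs(nc2$pairs$NC)), 0.03)
  # adding a fixed evoked mean to every trial changes nothing
  al3 <- fake_aligned(ev2 + 5, trials_big)
  expect_equal(noise_correlations(al3, "vertical", "c1")$pairs$NC, nc2$pairs$NC)
})

test_that("NC tables are symmetric, bounded and affine invariant", {
  cfg <- small_config(seed = 53)
  al <- align_to_trials(generate_session(cfg)$session)
  nc <- noise_correlations(al, "vertical", "pre")
  expect_true(all(abs(nc$pairs$NC) <= 1))
  expect_equal(nc$nc_matrix, t(nc$nc_matrix))
  expect_true(all(diag(nc$nc_matrix) == 1))
  # per-cell affine transform of responses leaves NC unchanged
  al2 <- al
  al2$evoked <- al$evoked * runif(nrow(al$evoked), 0.5, 2) + rnorm(nrow(al$evoked))
  nc2 <- noise_correlations(al2, "vertical", "pre")
  expect_equal(nc2$pairs$NC, nc$pairs$NC, tolerance = 1e-10)
})

test_that("condition comparisons detect planted loading changes", {
  # identical tables: all deltas zero, all p = 1
  cfg <- small_config(seed = 54)
  al <- align_to_trials(generate_session(cfg)$session)
  nc <- noise_correlations(al, "vertical", "pre")
  cmp0 <- compare_noise_correlations(nc, nc)
  expect_true(all(cmp0$mean_delta == 0))
  expect_true(all(cmp0$p_sign == 1))
  # Bonferroni with 10 families
  expect_equal(cmp0$p_bonf, pmin(1, 10 * cmp0$p_sign))
  # attention-style change: SOM class loading up, VIP loading down in
  # condition 2
  ld1 <- list(global = c(PYR = 0.04, PV = 0.04, SOM = 0.04, VIP = 0.04),
              class = c(PYR = 0.05, PV = 0.08, SOM = 0.06, VIP = 0.09))
  ld2 <- ld1
  ld2$class[["SOM"]] <- 0.12; ld2$class[["VIP"]] <- 0.02
  cfg2 <- synth_config(n_cells_per_class = c(PYR = 10, PV = 10, SOM = 14, VIP = 14),
                       n_trials_per_stim_per_cond = 150, seed = 55,
                       conditions = c("ignore", "attend"),
                       modulation_mode = "mixed",
                       shared_noise_loadings = list(ld1, ld2))
  al2 <- align_to_trials(generate_session(cfg2)$session)
  t1 <- noise_correlations(al2, "vertical", "ignore")
  t2 <- noise_correlations(al2, "vertical", "attend")
  cmp <- compare_noise_correlations(t1, t2)
  expect_gt(cmp$mean_delta[cmp$class_pair == "SOM-SOM"], 0)
  expect_lt(cmp$mean_delta[cmp$class_pair == "VIP-VIP"], 0)
  expect_lt(cmp$p_bonf[cmp$class_pair == "SOM-SOM"], 0.05)
})

test_that("running-speed stratification equalizes per-bin trial counts", {
  set.seed(5)
  tt <- data.frame(condition = rep(c("ignore", "attend"), each = 100),
                   stimulus = "vertical",
                   speed = c(rlnorm(100, 2.0, 0.4), rlnorm(100, 2.6, 0.4)),
                   stringsAsFactors = FALSE)
  idx <- stratify_by_running(tt, c("ignore", "attend"), "vertical", seed = 2)
  sub <- tt[idx, ]
  br <- seq(min(tt$speed), max(tt$speed), length.out = 11)
  br[1] <- br[1] - 1e-9
  counts <- table(cut(sub$speed, br), sub$condition)
  expect_true(all(counts[, 1] == counts[, 2]))
  # identical distributions: everything kept
  tt2 <- tt; tt2$speed <- rep(tt$speed[1:100], 2)
  idx2 <- stratify_by_running(tt2, c("ignore", "attend"), "vertical", seed = 2)
  expect_equal(length(idx2), 200L)
  # disjoint supports: error
  tt3 <- tt; tt3$speed <- c(rep(1, 100), rep(100, 100)) + runif(200, 0, 0.5)
  expect_error(stratify_by_running(tt3, c("ignore", "attend"), "vertical"),
               "overlap")
})

test_that("stratification removes a planted running-speed confound", {
  # responses depend on speed; the attend condition runs faster, inflating
  # the apparent selectivity difference; matching speeds removes most of it
  set.seed(6)
  n <- 400
  cond <- rep(c("ignore", "attend"), each = n)
  stim <- rep(rep(c("vertical", "angled"), n / 2), 2)
  speed <- ifelse(cond == "ignore", rlnorm(2 * n, 1.8, 0.35),
                  rlnorm(2 * n, 2.6, 0.35))
  # the preferred response grows with running speed; conditions differ only
  # through their speed distributions, so the speed-free SI difference is 0
  amp <- ifelse(stim == "vertical", 0.3 + 0.08 * speed, 0)
  ev <- matrix(amp + rnorm(2 * n), 1)
  trials <- data.frame(condition = cond, stimulus = stim, speed = speed,
                       stringsAsFactors = FALSE)
  si_of <- function(rows) {
    selectivity_index(ev[1, rows][trials$stimulus[rows] == "vertical"],
                      ev[1, rows][trials$stimulus[rows] == "angled"])$SI
  }
  si_ig <- si_of(which(cond == "ignore"))
  si_at <- si_of(which(cond == "attend"))
  expect_gt(si_at - si_ig, 0.3)   # the confound inflates the difference
  kv <- stratify_by_running(trials, c("ignore", "attend"), "vertical", seed = 3)
  ka <- stratify_by_running(trials, c("ignore", "attend"), "angled", seed = 3)
  keep <- sort(c(kv, ka))
  si_ig2 <- si_of(intersect(keep, which(cond == "ignore")))
  si_at2 <- si_of(intersect(keep, which(cond == "attend")))
  # matched speeds shrink the apparent difference toward the true value 0
  expect_lt(abs(si_at2 - si_ig2), 0.5 * (si_at - si_ig))
})

test_that("lick-trial exclusion uses the half-open response window", {
  fr <- 8
  tt <- data.frame(onset_frame = c(100, 200, 300, 400))
  tt$lick_frames <- list(integer(0),        # no licks: kept
                         200 + 3L,          # inside 0-1 s: removed
                         300 + 8L,          # exactly t = 1.0 s: kept
                         400 - 2L)          # before onset: kept
  keep <- exclude_lick_trials(tt, frame_rate = fr)
  expect_equal(keep, c(1L, 3L, 4L))
  # all trials licked: empty with warning
  tt2 <- data.frame(onset_frame = c(10, 20))
  tt2$lick_frames <- list(10L, 21L)
  expect_warning(k2 <- exclude_lick_trials(tt2, frame_rate = fr), "licks")
  expect_length(k2, 0)
})
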