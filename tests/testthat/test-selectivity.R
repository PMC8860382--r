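test_that("selectivity index matches hand evaluation and is antisymmetric", {
  # mean diff 1, sP = sN = sqrt(2), pooled SD sqrt(2)
  r <- selectivity_index(c(1, 3), c(0, 2))
  expect_equal(r$SI, 1 / sqrt(2))
  expect_equal(r$s_pooled, sqrt(2))
  # same samples: SI = 0
  expect_equal(selectivity_index(c(1, 2, 3), c(1, 2, 3))$SI, 0)
  # stimulus swap negates SI exactly
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_equal(selectivity_index(a, b)$SI, -selectivity_index(b, a)$SI)
  expect_error(selectivity_index(rep(1, 5), rep(1, 5)), "pooled")
  expect_error(selectivity_index(1, c(1, 2)), "trials")
})

test_that("SI is invariant under common affine scaling of all responses", {
  set.seed(2)
  a <- rnorm(30, 1); b <- rnorm(30, 0.4)
  si <- selectivity_index(a, b)$SI
  expect_equal(selectivity_index(2.7 * a + 5, 2.7 * b + 5)$SI, si)
})

test_that("rank-sum selectivity classification matches exact enumeration", {
  # complete separation at n = 4 vs 4: exact two-sided p = 2/70
  r <- classify_selective(c(5, 6, 7, 8), c(0, 1, 2, 3))
  expect_equal(r$p, 2 / 70, tolerance = 1e-12)
  expect_true(r$is_selective)
  expect_equal(r$preference, "vertical")
  # identical samples: not selective
  r0 <- classify_selective(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p, 1)
  expect_false(r0$is_selective)
  # rank statistic is invariant to trial order
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(classify_selective(a, b)$p,
               classify_selective(sample(a), sample(b))$p)
})

test_that("signed-rank responsiveness matches exact enumeration and symmetry", {
  set.seed(10)
  base <- rnorm(10)
  # 10 distinct positive differences: exact two-sided p = 2/1024
  d <- 1 + runif(10, 0, 0.5)
  r <- classify_responsive(base + d, base)
  expect_equal(r$p, 2 / 1024, tolerance = 1e-12)
  expect_equal(r$direction, 1)
  # no difference
  r0 <- classify_responsive(base, base)
  expect_equal(r0$p, 1)
  expect_equal(r0$direction, 0)
  # sign flip of all differences flips direction, keeps p
  r2 <- classify_responsive(base - d, base)
  expect_equal(r2$p, r$p)
  expect_equal(r2$direction, -1)
})

test_that("recruited cells are non-selective then selective, by preference", {
  rec <- function(id, sel, pref) {
    data.frame(cell_id = id, is_selective = sel, preference = pref,
               stringsAsFactors = FALSE)
  }
  r1 <- rec(c("a", "b", "c"), c(TRUE, FALSE, FALSE), c("vertical", "none", "none"))
  r2 <- rec(c("a", "b", "c"), c(TRUE, TRUE, FALSE), c("vertical", "vertical", "none"))
  out <- recruited_cells(r1, r2)
  expect_equal(out$vertical, "b")   # a selective in both is excluded
  expect_equal(out$angled, character(0))
  expect_error(recruited_cells(r1, r2[1:2, ]), "unmatched")
})

test_that("recruitment detection tracks generator ground truth", {
  # PYR cells built non-selective pre and strongly selective post; the
  # interneuron classes stay non-selective throughout, so the ground-truth
  # recruited set is exactly the PYR cells
  si <- default_si_distributions()
  si$mean[] <- 0; si$sd[] <- 0.01
  si$mean["PYR", 2] <- 0.9; si$sd["PYR", 2] <- 0.1
  cfg <- synth_config(n_cells_per_class = c(PYR = 30, PV = 6, SOM = 6, VIP = 6),
                      n_trials_per_stim_per_cond = 200, seed = 11,
                      si_distributions = si)
  g <- generate_session(cfg)
  al <- align_to_trials(g$session)
  r1 <- selectivity_records(al, "pre")
  r2 <- selectivity_records(al, "post")
  out <- recruited_cells(r1, r2)
  est <- sort(c(out$vertical, out$angled))
  gt <- g$session$cells$cell_id[g$session$cells$class == "PYR"]
  disagree <- length(union(setdiff(est, gt), setdiff(gt, est)))
  expect_lt(disagree / nrow(g$session$cells), 0.10)
})

test_that("delta selectivity follows the preference-signed convention", {
  rec <- function(id, si) data.frame(cell_id = id, class = "PYR", SI = si,
                                     stringsAsFactors = FALSE)
  expect_equal(delta_selectivity(rec("a", 0.1), rec("a", 0.4))$dSI, 0.3)
  expect_equal(delta_selectivity(rec("a", -0.1), rec("a", -0.4))$dSI, 0.3)
  expect_equal(delta_selectivity(rec("a", 0.25), rec("a", 0.25))$dSI, 0)
  # SI_c2 = 0 uses sign +1
  expect_equal(delta_selectivity(rec("a", 0.2), rec("a", 0))$dSI, -0.2)
})

test_that("behavioral d-prime matches the inverse-normal formula", {
  expect_equal(behavioral_dprime(10, 10, 10, 10)$bd, 0)
  # H and F one SD from chance: bd ~ 2
  b <- behavioral_dprime(84134, 15866, 15866, 84134)
  expect_equal(b$bd, 2, tolerance = 1e-3)
  # perfect session: clipped rates, bd = 2 * qnorm(39/40)
  b2 <- behavioral_dprime(20, 0, 0, 20)
  expect_equal(b2$bd, 2 * qnorm(39 / 40), tolerance = 1e-12)
  expect_error(behavioral_dprime(0, 0, 1, 1), "trial")
})

test_that("d-prime is increasing in hits and decreasing in false alarms", {
  bds <- sapply(5:15, function(h) behavioral_dprime(h, 20 - h, 5, 15)$bd)
  expect_true(all(diff(bds) > 0))
  bds <- sapply(2:12, function(f) behavioral_dprime(15, 5, f, 20 - f)$bd)
  expect_true(all(diff(bds) < 0))
})

test_that("local PYR-population selectivity uses a closed 100 um ball", {
  # one PV cell at origin; PYR neighbors at 50, exactly 100, and 150 um
  set.seed(4)
  n_tr <- 40
  trials <- data.frame(stimulus = rep(c("vertical", "angled"), each = n_tr),
                       condition = "c1", stringsAsFactors = FALSE)
  ev <- rbind(c(rnorm(n_tr, 1), rnorm(n_tr, 0)),     # PV
              c(rnorm(n_tr, 2), rnorm(n_tr, 0.5)),   # PYR at 50 um
              c(rnorm(n_tr, -1), rnorm(n_tr, 1)),    # PYR at exactly 100 um
              c(rnorm(n_tr, 9), rnorm(n_tr, 0)))     # PYR at 150 um, excluded
  al <- fake_aligned(ev, trials, classes = c("PV", "PYR", "PYR", "PYR"),
                     x_um = c(0, 50, 100, 150), y_um = c(0, 0, 0, 0))
  out <- local_population_selectivity(al, "c1")
  expect_equal(out$n_neighbors, 2L)   # the 100 um cell is inside (closed ball)
  pooled_V <- colMeans(ev[2:3, trials$stimulus == "vertical"])
  pooled_A <- colMeans(ev[2:3, trials$stimulus == "angled"])
  expect_equal(out$y, selectivity_index(pooled_V, pooled_A)$SI)
  # single neighbor: y equals that cell's SI
  al2 <- fake_aligned(ev[1:2, ], trials, classes = c("PV", "PYR"),
                      x_um = c(0, 50), y_um = c(0, 0))
  out2 <- local_population_selectivity(al2, "c1")
  expect_equal(out2$y, selectivity_index(ev[2, trials$stimulus == "vertical"],
                                         ev[2, trials$stimulus == "angled"])$SI)
})

test_that("noise-free PV/PYR selectivity field gives slope one", {
  # construct pairs where local PYR SI equals PV SI by definition
  x <- seq(-1, 1, length.out = 50)
  y <- x
  b <- bootstrap_slope(x, y, n_boot = 500, seed = 1)
  expect_equal(b$slope, 1, tolerance = 1e-12)
  expect_lt(diff(b$ci), 1e-10)
})

test_that("bootstrap slope test behaves at the null and under exact fits", {
  set.seed(5)
  x <- rnorm(100); y <- 2 * x
  b <- bootstrap_slope(x, y, n_boot = 1000, seed = 2)
  expect_equal(b$slope, 2, tolerance = 1e-12)
  expect_lt(diff(b$ci), 1e-9)
  # comparison slope at the point estimate: p near 1
  set.seed(6)
  y2 <- 0.5 * x + rnorm(100, 0, 0.3)
  b2 <- bootstrap_slope(x, y2, n_boot = 4000, seed = 3,
                        comparison_slope = cov(x, y2) / var(x))
  expect_gt(b2$p, 0.5)
  expect_error(bootstrap_slope(1:2, 1:2), "points")
  expect_error(bootstrap_slope(rep(1, 5), rnorm(5)), "constant")
})

test_that("slope reduction between conditions is detected with power", {
  # two conditions with true slopes 0.2 vs 0.05; moderate noise, n = 200
  detected <- 0
  n_rep <- 25
  for (k in seq_len(n_rep)) {
    set.seed(100 + k)
    x1 <- rnorm(200); y1 <- 0.2 * x1 + rnorm(200, 0, 0.2)
    x2 <- rnorm(200); y2 <- 0.05 * x2 + rnorm(200, 0, 0.2)
    s2 <- cov(x2, y2) / var(x2)
    b <- bootstrap_slope(x1, y1, n_boot = 2000, seed = k, comparison_slope = s2)
    if (b$p < 0.05) detected <- detected + 1
  }
  expect_gte(detected / n_rep, 0.9)
})
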