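test_that("the activation function is rectified and saturating as printed", {
  expect_equal(phi(-5), 0)
  expect_equal(phi(0), 0)
  expect_equal(phi(6), 19 * tanh(6 / 19))
  expect_equal(phi(6), 5.80820, tolerance = 1e-5)
  expect_true(all(phi(seq(-10, 100, by = 0.5)) < 19))
  expect_error(phi(1, r0 = 2, rmax = 1), "rmax")
})

test_that("default parameter tables carry the printed values", {
  pm <- default_params("multiplicative")
  expect_equal(unname(pm$I_b), c(6.0, 4.0, 1.2, 4.6))
  expect_equal(unname(pm$I_s), c(17.8, 10.0, 0.0, 0.0))
  for (cl in c("PYR", "PV", "SOM", "VIP")) {
    expect_equal(unname(pm$I_td[[cl]]), c(1.0, 2.0))
  }
  pa <- default_params("additive")
  for (cl in c("PYR", "PV", "SOM", "VIP")) {
    expect_equal(unname(pa$I_td[[cl]]), c(0.0, 1.0))
  }
  expect_equal(pm$sigma, 0.52)
  expect_equal(unname(pm$tau), c(0.8, 0.4, 0.4, 0.4))
  expect_equal(pm$W["PYR", "PV"], 0.956)
  expect_equal(pm$W["VIP", "PYR"], 2.104)
  expect_error(default_params("divisive"), "mode")
})

test_that("noise-free simulations reach the independent fixed point", {
  p <- circuit_params("multiplicative", targets = c("PYR", "SOM"), n_trials = 1)
  p$sigma <- 0
  sim <- simulate_circuit(p, "ignore", seed = 1, store_rates = TRUE,
                          decimate = 1, stim_scale_override = rep(0, 30000))
  fp <- circuit_fixed_point(p, "ignore", 0)
  expect_lt(max(abs(sim$rates[1, , 30000] - fp[rep(1:4, each = 2)])), 1e-6)
  # isolated unit: phi of its own input
  p2 <- circuit_params("additive", targets = character(0), n_trials = 1)
  p2$sigma <- 0; p2$W[] <- 0
  sim2 <- simulate_circuit(p2, "ignore", seed = 1, store_rates = TRUE,
                           decimate = 1, stim_scale_override = rep(0, 30000))
  expect_equal(sim2$rates[1, 1, 30000], 19 * tanh(6 / 19), tolerance = 1e-6)
  # noise-free runs are seed independent
  sim3 <- simulate_circuit(p2, "ignore", seed = 99, store_rates = TRUE,
                           decimate = 1, stim_scale_override = rep(0, 30000))
  expect_identical(sim2$rates, sim3$rates)
})

test_that("noise-free duplicated copies stay identical and rates stay bounded", {
  p <- circuit_params("multiplicative", n_trials = 2)
  p$sigma <- 0
  sim <- simulate_circuit(p, "attend", seed = 1, store_rates = TRUE)
  for (c in 1:4) {
    expect_identical(sim$rates[, 2 * c - 1, ], sim$rates[, 2 * c, ])
  }
  # stochastic run: activity bounded by the activation range
  p2 <- circuit_params("multiplicative", n_trials = 5)
  sim2 <- simulate_circuit(p2, "attend", seed = 2, store_rates = TRUE)
  expect_true(all(sim2$rates >= 0))
  expect_true(all(sim2$rates <= p2$rmax - p2$r0))
})

test_that("simulation reruns are reproducible from the seed", {
  p <- circuit_params("multiplicative", targets = "SOM", n_trials = 5)
  s1 <- simulate_circuit(p, "attend", seed = 7)
  s2 <- simulate_circuit(p, "attend", seed = 7)
  expect_identical(s1$pref_mean, s2$pref_mean)
  s3 <- simulate_circuit(p, "attend", seed = 8)
  expect_false(identical(s1$pref_mean, s3$pref_mean))
})

test_that("model selectivity is null without stimulus input and stable with it", {
  # no stimulus drive anywhere: SI within the sampling bound
  p <- circuit_params("multiplicative", targets = character(0), n_trials = 100)
  p$I_s[] <- 0
  sim <- simulate_circuit(p, "ignore", seed = 3)
  si <- model_selectivity(sim)
  expect_true(all(abs(si) < 3 / sqrt(100) * 1.5))
  # default drive: PYR positively selective, stable across seeds
  p2 <- circuit_params("multiplicative", targets = character(0), n_trials = 100)
  sis <- sapply(1:10, function(k) {
    model_selectivity(simulate_circuit(p2, "ignore", seed = 400 + k))[["PYR"]]
  })
  expect_true(all(sis > 0))
  expect_lt(sd(sis), 0.2 * mean(sis))
  # a zero-variance population is an error
  p3 <- circuit_params("additive", targets = character(0), n_trials = 5)
  p3$sigma <- 0
  sim3 <- simulate_circuit(p3, "ignore", seed = 1)
  expect_error(model_selectivity(sim3), "pooled")
})

test_that("model noise correlations reflect the static noise mix", {
  # isolated populations (W = 0) sharing only feedforward noise; at a
  # near-linear operating point the within-class correlation equals the
  # feedforward variance share: 1/3 under sqrt mixing, 1/5 under linear
  ss <- rep(1, 3000)
  for (case in list(c("sqrt", 1 / 3), c("linear", 1 / 5))) {
    p <- circuit_params("multiplicative", targets = character(0),
                        n_trials = 6000, noise_convention = case[[1]])
    p$W[] <- 0
    p$I_b[] <- 2; p$I_s[] <- 1   # keeps chi_ff = 1/3 and phi nearly linear
    sim <- simulate_circuit(p, "ignore", seed = 5, stim_scale_override = ss)
    nc <- model_noise_correlations(sim)
    expect_lt(abs(nc$class_pairs[["PYR-PYR"]] - as.numeric(case[[2]])), 0.04)
    # no shared sources at all: within-class NC near zero
    p0 <- p
    p0$I_s[] <- 0   # removes feedforward noise (chi_ff = 0)
    sim0 <- simulate_circuit(p0, "ignore", seed = 6, stim_scale_override = ss)
    nc0 <- model_noise_correlations(sim0)
    expect_lt(abs(nc0$class_pairs[["PYR-PYR"]]), 0.04)
  }
  # NC matrix is symmetric with unit diagonal
  p <- circuit_params("multiplicative", n_trials = 50)
  nc <- model_noise_correlations(simulate_circuit(p, "attend", seed = 7))
  expect_equal(nc$nc_matrix, t(nc$nc_matrix))
  expect_equal(unname(diag(nc$nc_matrix)), rep(1, 8))
})

test_that("window-mean statistics are sampling consistent across trial counts", {
  p1 <- circuit_params("multiplicative", targets = c("PYR", "SOM"), n_trials = 100)
  p2 <- circuit_params("multiplicative", targets = c("PYR", "SOM"), n_trials = 1000)
  s100 <- simulate_circuit(p1, "attend", seed = 8)
  s1k <- simulate_circuit(p2, "attend", seed = 9)
  si100 <- model_selectivity(s100); si1k <- model_selectivity(s1k)
  # SE of the 100-trial SI estimate, per class, from its sampling theory
  se <- abs(si100) / sqrt(2 * 99) * sqrt(2) + sqrt(2 / 100) * 2
  expect_true(all(abs(si100 - si1k) < 3 * (se + 0.05)))
})

test_that("the sweep covers all target subsets and modes", {
  tab <- attention_sweep(n_trials = 5, seed = 1)
  expect_equal(nrow(tab), 30L)
  expect_equal(length(unique(tab$targets)), 15L)
  expect_true(all(c("dSI_PYR", "dNC_SOM-SOM", "dNC_VIP-VIP") %in% names(tab)))
})

test_that("the ratio scan is consistent with the sweep and null at unity", {
  # ratio 1 at SOM value 2.0 is exactly the multiplicative {PYR,SOM} sweep
  # configuration under the same seed scheme
  sc <- modulation_ratio_scan(som_values = 2.0, ratio = 1, n_trials = 20, seed = 3)
  sw <- attention_sweep(modes = "multiplicative", n_trials = 20, seed = 3)
  row <- sw[sw$targets == "PYR+SOM", ]
  expect_equal(sc$dSI_PYR, row$dSI_PYR)
  expect_equal(sc[["dNC_SOM-SOM"]], row[["dNC_SOM-SOM"]])
  expect_equal(sc$pyr_value, 2.0)
  # no modulation at the lower endpoint: deltas are pure sampling noise
  sc0 <- modulation_ratio_scan(som_values = 1.0, ratio = 0.7, n_trials = 100,
                               seed = 4, n_seeds = 4)
  expect_lt(abs(sc0$dSI_SOM), 0.5)
  expect_lt(abs(sc0[["dNC_SOM-SOM"]]), 0.2)
  expect_equal(sc0$pyr_value, 1.0)
})

test_that("match evaluation applies both criteria literally", {
  thr <- list(theta_si = 0.5, theta_nc = 0.05)
  row <- data.frame(dSI_PYR = 2, dSI_PV = 1, dSI_SOM = 0.1, dSI_VIP = -0.2,
                    `dNC_SOM-SOM` = 0.2, `dNC_VIP-VIP` = -0.2,
                    check.names = FALSE)
  m <- evaluate_match(row, thr)
  expect_true(m$criterion1); expect_true(m$criterion2); expect_true(m$match)
  # all-zero row: no match
  row0 <- row; row0[] <- 0
  expect_false(evaluate_match(row0, thr)$match)
  # large SOM selectivity change defeats criterion 1 regardless of the rest
  row2 <- row; row2$dSI_SOM <- 3
  m2 <- evaluate_match(row2, thr)
  expect_false(m2$criterion1); expect_true(m2$criterion2); expect_false(m2$match)
  expect_error(evaluate_match(row[, 1:3], thr), "missing")
})
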