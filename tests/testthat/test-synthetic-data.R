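test_that("trajectories are deterministic, in-bounds, and well-mixed", {
  cfg <- trajectory_config(duration = 1200, seed = 7)
  tr1 <- simulate_trajectory(cfg)
  tr2 <- simulate_trajectory(cfg)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$x >= 0 & tr1$x <= 100 & tr1$y >= 0 & tr1$y <= 100))
  # >= 80% of 3-cm bins visited in 20 min
  bins <- unique(floor(tr1$x / 3) * 100 + floor(tr1$y / 3))
  expect_gt(length(bins) / ceiling(100 / 3)^2, 0.8)
})

test_that("empirical mean speed matches the configured foraging speed", {
  tr <- simulate_trajectory(trajectory_config(mean_speed = 11.6,
                                              duration = 2520, seed = 8))
  v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / 0.02
  expect_gt(mean(v), 10.4)
  expect_lt(mean(v), 12.8)
})

test_that("a zero-speed configuration yields a stationary path", {
  tr <- simulate_trajectory(trajectory_config(mean_speed = 0, speed_sd = 0,
                                              duration = 10, seed = 1))
  expect_equal(stats::sd(tr$x), 0)
  expect_equal(stats::sd(tr$y), 0)
})

test_that("rate functions reproduce their closed forms", {
  g <- grid_spec(spacing = 42, orientation = 0, phase = c(0, 0),
                 peak_rate = 5, baseline_rate = 0.1)
  expect_equal(rate_function(g, x = 0, y = 0), 5.1, tolerance = 1e-6)
  h0 <- hd_spec(kappa = 1e-10, peak_rate = 3, baseline_rate = 0)
  expect_equal(rate_function(h0, hd = seq(0, 6, by = 0.5)),
               rep(3, 13), tolerance = 1e-6)
  s <- speed_spec(intercept = 2, slope = 0.5)
  expect_equal(rate_function(s, speed = 10), 7)
  s2 <- speed_spec(intercept = 2, slope = -0.5)
  expect_equal(rate_function(s2, speed = 10), 0)  # clipped at zero
  th <- theta_rhythm_spec(f = 8, mod_depth = 0.5, base_rate = 4)
  expect_equal(rate_function(th, theta_phase = 0), 6)
  expect_equal(rate_function(th, theta_phase = pi), 2)
})

test_that("simulated spike counts obey the programmed rate", {
  tr <- tibble::tibble(t = seq(0, 1000, by = 0.02), x = 50, y = 50, hd = 0)
  st <- simulate_spikes(speed_spec(intercept = 5, slope = 0), tr, seed = 9)
  expect_lt(abs(length(st) - 5000), 3 * sqrt(5000))
  st0 <- simulate_spikes(speed_spec(intercept = 0, slope = 0,
                                    baseline_rate = 0), tr, seed = 9)
  expect_length(st0, 0)
  expect_identical(simulate_spikes(speed_spec(5, 0), tr, seed = 2),
                   simulate_spikes(speed_spec(5, 0), tr, seed = 2))
})

test_that("binned empirical tuning of simulated trains matches the spec", {
  tr <- quick_trajectory(duration = 1200, seed = 10)
  spec <- hd_spec(mu = pi, kappa = 2, peak_rate = 6, baseline_rate = 0.2)
  st <- simulate_spikes(spec, tr, seed = 11)
  tun <- hd_tuning(st, tr)
  truth <- rate_function(spec, hd = tun$curve$hd)
  # chi-square GOF of binned counts vs expected under the true curve
  occ <- tun$curve$occupancy
  expected <- truth * occ
  observed <- tun$curve$rate * occ
  sel <- expected > 5
  chi2 <- sum((observed[sel] - expected[sel])^2 / expected[sel])
  p <- stats::pchisq(chi2, df = sum(sel) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("the simulated LFP carries the programmed instantaneous frequency", {
  tr <- tibble::tibble(t = seq(0, 120, by = 0.02), x = 50, y = 50, hd = 0)
  ep <- tibble::tibble(start = 0, end = 121, condition = "light")
  spec <- lfp_spec(intercept = c(light = 8, dark = 8),
                   slope = c(light = 0, dark = 0), noise_sd = 0)
  sim <- simulate_lfp(spec, tr, ep, seed = 3)
  th <- theta_signal(list(samples = sim$samples, fs = 600, t0 = 0), c(6, 10))
  interior <- 3000:69000
  expect_lt(max(abs(th$frequency[interior] - 8)), 0.05)
  expect_identical(simulate_lfp(spec, tr, ep, seed = 4)$samples,
                   simulate_lfp(spec, tr, ep, seed = 4)$samples)
  bad <- lfp_spec(intercept = c(light = 0.2, dark = 0.2),
                  slope = c(light = 0, dark = 0))
  expect_error(simulate_lfp(bad, tr, ep, seed = 3), "frequency")
})

test_that("make_session assembles a valid, fully provenanced session", {
  ses <- make_session(trajectory_config(duration = 2520, seed = 12),
                      cell_specs = list(g = grid_spec(),
                                        s = speed_spec()),
                      epoch_length = 180, first_condition = "light",
                      seed = 12)
  expect_s3_class(ses, "mec_session")
  expect_equal(nrow(ses$epochs), 14)
  expect_equal(ses$epochs$condition[1], "light")
  expect_no_error(validate_session(ses))
  expect_named(ses$metadata$ground_truth, c("cells", "lfp", "trajectory"))
  expect_setequal(unique(ses$spikes$unit_id), c("g", "s"))
})
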