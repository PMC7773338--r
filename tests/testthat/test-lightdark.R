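test_that("epoch modulation detects and directs rate steps", {
  # the canonical example: light rates {4.0, 4.1, 3.9}, dark {2.0, 2.1, 1.9}
  ep <- alternating_epochs(7 * 180, 180, first = "light")
  st <- regular_epoch_train(ep, c(4.0, 2.0, 4.1, 2.1, 3.9, 1.9, 4.0))
  m <- epoch_modulation(st, ep)
  expect_true(m$included)
  expect_true(m$modulated)
  expect_equal(m$direction, "darkness-negative")
  expect_equal(m$dark_to_light_ratio, 0.5, tolerance = 0.01)

  # identical epoch rates: not modulated
  st2 <- regular_epoch_train(ep, rep(3, 7))
  m2 <- epoch_modulation(st2, ep)
  expect_false(m2$modulated)

  # only two pairs of one type: excluded
  ep4 <- alternating_epochs(5 * 180, 180, first = "light")
  st3 <- regular_epoch_train(ep4, c(4, 2, 4, 2, 4))
  m3 <- epoch_modulation(st3, ep4)
  expect_false(m3$included)
  expect_true(is.na(m3$p_value))
})

test_that("the paired test is calibrated and sensitive on Poisson units", {
  ep <- alternating_epochs(2520, 180)
  sim_unit <- function(rl, rd, seed) {
    set.seed(seed)
    unlist(lapply(seq_len(nrow(ep)), function(i) {
      r <- if (ep$condition[i] == "light") rl else rd
      sort(stats::runif(stats::rpois(1, r * 180), ep$start[i], ep$end[i]))
    }))
  }
  det <- vapply(1:40, function(s)
    epoch_modulation(sim_unit(2, 1, s), ep)$modulated, logical(1))
  fp <- vapply(1:40, function(s)
    epoch_modulation(sim_unit(1.5, 1.5, 500 + s), ep)$modulated, logical(1))
  expect_gte(mean(det), 0.95)
  expect_lte(mean(fp), 0.15)
})

test_that("transition PSTHs localize steps and center at zero", {
  ep <- alternating_epochs(2520, 180)
  t_grid <- seq(0, 2520 - 0.02, by = 0.02)
  set.seed(51)
  rates <- dplyr::bind_rows(lapply(1:5, function(u) {
    lam <- ifelse(in_epochs_vec(t_grid, ep, "light"), 6, 2)
    tibble::tibble(unit_id = paste0("u", u), t = t_grid,
                   rate = stats::rpois(length(t_grid), lam * 0.02) / 0.02)
  }))
  psth <- transition_psth(rates, ep, "light_to_dark", bin = 5, n_side = 4)
  pre <- mean(psth$mean_z[psth$offset < 0])
  post <- mean(psth$mean_z[psth$offset >= 0])
  expect_gt(pre - post, 0.2)
  # the step is complete within one bin of the transition
  expect_lt(psth$mean_z[psth$offset == 0] - post, 0.2)
  # z-scoring: session-wide mean of each unit's z-rate is ~0
  z <- rates |>
    dplyr::group_by(unit_id) |>
    dplyr::summarise(m = mean((rate - mean(rate)) / stats::sd(rate)))
  expect_true(all(abs(z$m) < 1e-10))
  # unmodulated units: flat PSTH
  set.seed(52)
  flat <- tibble::tibble(unit_id = "f", t = t_grid,
                         rate = stats::rpois(length(t_grid), 0.08) / 0.02)
  pf <- transition_psth(flat, ep, "light_to_dark", bin = 5, n_side = 4)
  expect_lt(max(abs(pf$mean_z)), 0.25)
})

test_that("theta-speed regression recovers programmed slopes", {
  tr <- quick_trajectory(duration = 900, seed = 53)
  ep <- tibble::tibble(start = 0, end = 901, condition = "light")
  spec <- lfp_spec(intercept = c(light = 7.2, dark = 7.2),
                   slope = c(light = 0.04, dark = 0.04), noise_sd = 0.2)
  sim <- simulate_lfp(spec, tr, ep, seed = 54)
  ses <- mec_session(tr, tibble::tibble(unit_id = character(),
                                        t = numeric()),
                     epochs = ep, lfp = list(samples = sim$samples,
                                             fs = 600, t0 = 0),
                     validate = FALSE)
  sig <- derive_signals(ses, band = c(6, 10))
  res <- theta_speed_regression(sig)
  expect_gt(res$slope, 0.035); expect_lt(res$slope, 0.045)
  expect_gt(res$y_intercept, 7.0); expect_lt(res$y_intercept, 7.4)
  # same op with acceleration as the predictor
  resa <- theta_speed_regression(sig, predictor = "accel")
  expect_true(is.finite(resa$slope))
  # constant-frequency LFP: slope CI includes zero
  spec0 <- lfp_spec(intercept = c(light = 8, dark = 8),
                    slope = c(light = 0, dark = 0), noise_sd = 0.2)
  sim0 <- simulate_lfp(spec0, tr, ep, seed = 55)
  ses0 <- ses; ses0$lfp$samples <- sim0$samples
  sig0 <- derive_signals(ses0, band = c(6, 10))
  res0 <- theta_speed_regression(sig0)
  expect_lt(abs(res0$slope), 3 * 0.002)
  expect_error(theta_speed_regression(sig[1:50, ]), "valid samples")
})

test_that("time courses are flat for stationary processes and pool correctly", {
  tr <- quick_trajectory(duration = 2520, seed = 56)
  ep <- alternating_epochs(2520, 180)
  spec <- lfp_spec(slope = c(light = 0.04, dark = 0.04), noise_sd = 0.2)
  sim <- simulate_lfp(spec, tr, ep, seed = 57)
  ses <- mec_session(tr, tibble::tibble(unit_id = character(),
                                        t = numeric()),
                     epochs = ep, lfp = list(samples = sim$samples,
                                             fs = 600, t0 = 0),
                     validate = FALSE)
  sig <- derive_signals(ses, band = c(6, 10))
  tc <- timecourse(sig, ep, "light", extract_theta_slope, bin = 10,
                   n_bins = 18)
  expect_equal(nrow(tc), 18)
  expect_lt(diff(range(tc$slope)), 0.01)
  expect_lt(abs(mean(tc$slope) - 0.04), 0.005)
  # pooling consistency: n-weighted bin slopes reproduce the pooled slope
  mask <- in_epochs_vec(sig$t, ep, "light")
  pooled <- theta_speed_regression(sig[mask, ])
  wmean <- sum(tc$slope * tc$n) / sum(tc$n)
  expect_equal(wmean, pooled$slope, tolerance = 0.004)
})

test_that("time-course correlation matches affine and null expectations", {
  tA <- tibble::tibble(offset = rep(seq(0, 170, 10), 2),
                       condition = rep(c("light", "dark"), each = 18),
                       slope = stats::rnorm(36))
  tB <- dplyr::mutate(tA, stability = 2 * slope + 1)
  tB <- dplyr::select(tB, offset, condition, stability)
  cc <- timecourse_correlation(tA, tB, "slope", "stability")
  expect_equal(cc$r[cc$scope == "pooled"], 1, tolerance = 1e-12)
  # independent tables: mostly weak correlation
  set.seed(58)
  hits <- vapply(1:40, function(i) {
    a <- dplyr::mutate(tA, slope = stats::rnorm(36))
    b <- dplyr::mutate(tB, stability = stats::rnorm(36))
    abs(timecourse_correlation(a, b, "slope",
                               "stability")$r[1]) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(timecourse_correlation(tA[1:2, ], tB[1:2, ],
                                      "slope", "stability"), "matched bins")
})
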