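test_that("lag collection respects the window, segments, and minimum", {
  ls <- collect_lags(c(1.0, 1.1))
  expect_equal(ls$lags, 0.1, tolerance = 1e-12)
  # regular 8 Hz train: lags cluster at multiples of 125 ms
  st <- seq(0, 10, by = 0.125)
  lr <- collect_lags(st)
  expect_true(all(abs(lr$lags / 0.125 - round(lr$lags / 0.125)) < 1e-9))
  # segments split pairs
  seg <- tibble::tibble(start = c(0, 10), end = c(5, 15))
  lc <- collect_lags(c(4.9, 5.1, 10.2), segments = seg)
  expect_equal(lc$count, 0)  # 4.9 and 5.1 fall in different/excluded spans
  # refusal below 100 lags names the rule
  few <- seq(0, 9.8, by = 0.2)  # 49 lags within 0.6 s window? enough spikes
  ls_few <- collect_lags(few[1:30])
  expect_lt(ls_few$count, 100)
  expect_error(fit_rhythmicity(ls_few), "100")
  # probability-normalized lag histogram sums to one
  h <- graphics::hist(lr$lags, breaks = seq(0, 0.6, by = 0.01),
                      plot = FALSE)
  expect_equal(sum(h$counts / lr$count), 1)
})

test_that("the fitted lag density is normalized and properly nested", {
  st <- sim_rhythmic_train(6, 8, 0.5, 300, 40)
  fit <- fit_rhythmicity(collect_lags(st))
  int <- stats::integrate(function(t) rhythm_density(fit$model, t),
                          1e-9, 0.6, rel.tol = 1e-10, subdivisions = 2000)
  expect_lt(abs(int$value - 1), 1e-6)
  expect_gte(fit$loglik_full, fit$loglik_null)
  expect_gte(fit$deviance, 0)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
})

test_that("rhythmic trains are detected with accurate frequency", {
  st <- sim_rhythmic_train(5, 8, 0.5, 600, 41)
  fit <- fit_rhythmicity(collect_lags(st))
  expect_gt(fit$model[["f"]], 7.75)
  expect_lt(fit$model[["f"]], 8.25)
  expect_lt(fit$p_value, 0.001)
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "tau", "r", "upsilon", "f"))
  expect_equal(glance(fit)$deviance, fit$deviance)
})

test_that("a constant-speed session fills exactly one speed bin", {
  st <- sim_rhythmic_train(8, 8, 0.6, 120, 42)
  sp <- tibble::tibble(t = seq(0, 120, by = 0.02), speed = 12.3)
  sb <- speed_binned_rhythmicity(st, sp)
  expect_equal(sum(sb$n_lags > 0), 1)
  expect_equal(sb$speed[sb$n_lags > 0], 12)  # 1-cm/s bin center
  expect_true(sb$fitted[sb$n_lags > 0])
})

test_that("speed-dependent rhythmic frequency regresses to its slope", {
  tr <- quick_trajectory(duration = 1200, seed = 41)
  v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / 0.02
  v <- c(v[1], v)
  t_hi <- seq(0, 1200, by = 0.001)
  vi <- stats::approx(tr$t, v, t_hi, rule = 2)$y
  set.seed(42)
  ph <- cumsum(2 * pi * (7 + 0.05 * vi) * 0.001)
  st <- t_hi[stats::runif(length(t_hi)) < 8 * (1 + 0.6 * cos(ph)) * 0.001]
  ks <- kalman_speed(tr)
  sb <- speed_binned_rhythmicity(st, tibble::tibble(t = tr$t,
                                                    speed = ks$speed))
  sel <- sb$fitted & sb$p_value < 0.05 & sb$f >= 5 & sb$f <= 11
  fit <- stats::lm(f ~ speed, data = sb[sel, ], weights = sb$n_lags[sel])
  expect_lt(abs(unname(stats::coef(fit)[2]) - 0.05), 0.01)
})

test_that("population time courses read frequency off the mean model curve", {
  ep <- alternating_epochs(1440, 180)
  spk <- dplyr::bind_rows(
    tibble::tibble(unit_id = "a", t = sim_rhythmic_train(10, 8, 0.8, 1440, 1)),
    tibble::tibble(unit_id = "b", t = sim_rhythmic_train(10, 8, 0.8, 1440, 2)))
  tb <- timebinned_rhythmicity(spk, ep, "light", bin = 30, n_bins = 3)
  expect_true(all(abs(tb$frequency - 8) <= 0.1))
  expect_true(all(tb$n_units == 2))
  # units at 7 and 9 Hz: first peak of the mean curve between the two
  spk2 <- dplyr::bind_rows(
    tibble::tibble(unit_id = "a", t = sim_rhythmic_train(10, 7, 0.8, 1440, 3)),
    tibble::tibble(unit_id = "b", t = sim_rhythmic_train(10, 9, 0.8, 1440, 4)))
  tb2 <- timebinned_rhythmicity(spk2, ep, "light", bin = 180, n_bins = 1)
  expect_gt(1 / tb2$frequency, 0.111)
  expect_lt(1 / tb2$frequency, 0.143)
})

test_that("phase locking measures concentration on the theta cycle", {
  dur <- 600
  theta <- tibble::tibble(t = seq(0, dur, by = 1 / 600))
  # gently wandering frequency so the 50 Hz grid strobes all phases
  finst <- 8 + 0.4 * sin(2 * pi * theta$t / 7)
  theta$phase_unwrapped <- cumsum(2 * pi * finst / 600)
  theta$phase <- theta$phase_unwrapped %% (2 * pi)
  sp_sig <- tibble::tibble(t = seq(0, dur, by = 0.02), speed = 10)
  # spikes exactly at phase zero (phase-crossing times)
  wraps <- which(diff(theta$phase_unwrapped %/% (2 * pi)) == 1)
  st0 <- theta$t[wraps]
  pl0 <- phase_locking(st0, theta, sp_sig)
  expect_gt(pl0$mrl, 0.9)
  expect_lt(min(abs(pl0$preferred), 2 * pi - abs(pl0$preferred)), 0.25)
  # uniform-phase Poisson cell
  stu <- sim_poisson_train(5, dur, 43)
  plu <- phase_locking(stu, theta, sp_sig)
  expect_lt(plu$mrl, 0.05)
  # below the spike minimum, the unit is flagged excluded
  expect_true(phase_locking(st0[1:20], theta, sp_sig)$excluded)
  # speed masking removes slow-running spikes
  sp2 <- sp_sig
  sp2$speed[sp2$t < dur / 2] <- 0
  pl2 <- phase_locking(st0, theta, sp2)
  expect_lt(pl2$n_spikes, length(st0) * 0.6)
})
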