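test_that("rate maps conserve occupancy and localize spikes", {
  tr <- quick_trajectory(duration = 600, seed = 15)
  st <- simulate_spikes(speed_spec(intercept = 5, slope = 0), tr, seed = 16)
  m <- rate_map(st, tr)
  expect_equal(sum(m$occupancy), 600, tolerance = 0.03)
  expect_true(all(m$rates[m$visited] >= 0))
  # uniform 5 Hz cell: visited-bin rates scatter around 5
  expect_equal(mean(m$rates[m$visited & m$occupancy > 1]), 5,
               tolerance = 0.4)
  # all spikes in one bin, unsmoothed
  tr2 <- tibble::tibble(t = seq(0, 60, by = 0.02), x = 50, y = 50, hd = 0)
  m2 <- rate_map(c(10, 20, 30), tr2, smooth_sd = 0)
  expect_equal(sum(m2$rates_raw > 0, na.rm = TRUE), 1)
  expect_error(rate_map(numeric(0), tr2[0, ]), "valid positions")
})

test_that("the autocorrelogram is unity at zero lag and point-symmetric", {
  tr <- quick_trajectory(duration = 600, seed = 17)
  st <- simulate_spikes(grid_spec(spacing = 42, peak_rate = 6), tr,
                        seed = 18)
  ac <- autocorr2d(rate_map(st, tr))
  n <- nrow(ac)
  ctr <- (n + 1) / 2
  expect_equal(ac[ctr, ctr], 1, tolerance = 1e-9)
  expect_equal(ac, ac[n:1, n:1], tolerance = 1e-9)
  # hexagonal structure: inner peaks sit near one spacing from center
  pk <- gridtheta:::local_maxima(ac, 0.1)
  m <- rate_map(st, tr)
  d <- sqrt((pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2) * m$bin_size
  inner <- sort(d[d > 6])[1:6]
  expect_true(all(abs(inner - 42) < 9))
})

test_that("grid scores separate hexagonal maps from noise", {
  tr <- quick_trajectory(duration = 1200, seed = 19)
  st <- simulate_spikes(grid_spec(spacing = 42, peak_rate = 6), tr,
                        seed = 20)
  g <- grid_score(rate_map(st, tr))
  expect_gte(g$score, 0.19)
  expect_lte(g$score, 1)
  # smoothed white noise maps: low or undefined scores (rare
  # pseudo-hexagonal constellations are tolerated at a low rate)
  low <- vapply(1:10, function(s) {
    set.seed(400 + s)
    noise <- matrix(stats::rnorm(34^2), 34, 34)
    gn <- grid_score(structure(list(rates = gridtheta:::smooth_map(noise, 1),
                                    visited = matrix(TRUE, 34, 34),
                                    bin_size = 3),
                               class = "mec_ratemap"))
    is.na(gn$score) || gn$score < 0.19
  }, logical(1))
  expect_gte(sum(low), 9)
  # degenerate map: no peaks -> undefined with a reason
  flat <- structure(list(rates = matrix(1, 20, 20), bin_size = 3,
                         visited = matrix(TRUE, 20, 20)),
                    class = "mec_ratemap")
  gf <- grid_score(flat)
  expect_true(is.na(gf$score))
  expect_match(gf$reason, "peaks")
})

test_that("rotation correlation matches a brute-force Pearson oracle", {
  set.seed(22)
  toy <- gridtheta:::smooth_map(matrix(stats::rnorm(21^2), 21, 21), 1.2)
  angles <- seq(0, 357, by = 3)
  got <- rotation_correlation(toy, inner = 3, outer = 9,
                              angles_deg = angles)
  # oracle: per-angle Pearson over annulus bins, interpolating rotated
  # coordinates directly, written without the package machinery
  ctr <- 11
  oracle <- sapply(angles, function(a) {
    th <- a * pi / 180
    v0 <- c(); v1 <- c()
    for (i in 1:21) for (j in 1:21) {
      d <- sqrt((i - ctr)^2 + (j - ctr)^2)
      if (d < 3 || d > 9) next
      rx <- cos(th) * (i - ctr) - sin(th) * (j - ctr) + ctr
      ry <- sin(th) * (i - ctr) + cos(th) * (j - ctr) + ctr
      i0 <- floor(rx); j0 <- floor(ry)
      if (i0 < 1 || j0 < 1 || i0 + 1 > 21 || j0 + 1 > 21) next
      fx <- rx - i0; fy <- ry - j0
      val <- (1 - fx) * (1 - fy) * toy[i0, j0] +
        fx * (1 - fy) * toy[i0 + 1, j0] +
        (1 - fx) * fy * toy[i0, j0 + 1] + fx * fy * toy[i0 + 1, j0 + 1]
      v0 <- c(v0, toy[i, j]); v1 <- c(v1, val)
    }
    stats::cor(v0, v1)
  })
  expect_lt(max(abs(got$r - oracle)), 1e-9)
})

test_that("spatial information equals its closed-form values", {
  cnt <- matrix(1, 32, 32)
  expect_equal(spatial_information(counts = cnt)$delta_h, 0)
  cnt2 <- matrix(0, 32, 32); cnt2[5, 7] <- 117
  expect_equal(spatial_information(counts = cnt2)$delta_h, 10)
  cnt3 <- matrix(NA_real_, 4, 4); cnt3[1, 1:4] <- c(6, 6, 0, 0)
  expect_equal(spatial_information(counts = cnt3)$delta_h, 1)
  expect_error(spatial_information(counts = matrix(0, 4, 4)), "spike")
})

test_that("spatial correlation is symmetric with exact endpoints", {
  tr <- quick_trajectory(duration = 600, seed = 23)
  st <- simulate_spikes(grid_spec(spacing = 42, peak_rate = 6), tr,
                        seed = 24)
  m <- rate_map(st, tr)
  expect_equal(spatial_correlation(m, m), 1)
  neg <- m
  neg$rates <- max(m$rates, na.rm = TRUE) - m$rates
  expect_equal(spatial_correlation(m, neg), -1)
  st2 <- simulate_spikes(grid_spec(spacing = 42, peak_rate = 6), tr,
                         seed = 25)
  m2 <- rate_map(st2, tr)
  expect_equal(spatial_correlation(m, m2), spatial_correlation(m2, m))
  # same underlying map, independent noise: strong but imperfect
  expect_gt(spatial_correlation(m, m2), 0.5)
  small <- structure(list(rates = matrix(c(1, 2, NA, NA), 2, 2),
                          visited = matrix(c(TRUE, TRUE, FALSE, FALSE), 2)),
                     class = "mec_ratemap")
  expect_warning(expect_true(is.na(spatial_correlation(small, small))),
                 "common visited")
})

test_that("spatiotemporal correlation grades map-consistent firing", {
  tr <- quick_trajectory(duration = 900, seed = 26)
  spec <- grid_spec(spacing = 42, peak_rate = 6)
  st <- simulate_spikes(spec, tr, seed = 27)
  ref <- rate_map(st, tr)
  rate <- instantaneous_rate(st, tr$t)
  r_obs <- spatiotemporal_correlation(rate, tr, ref)
  expect_gt(r_obs, 0.2)
  # observed == expected -> exactly 1
  nb <- nrow(ref$rates)
  bx <- pmin(pmax(floor(tr$x / ref$bin_size), 0), nb - 1) + 1
  by <- pmin(pmax(floor(tr$y / ref$bin_size), 0), nb - 1) + 1
  exact <- tibble::tibble(t = tr$t, rate = ref$rates[cbind(bx, by)])
  expect_equal(spatiotemporal_correlation(exact, tr, ref), 1,
               tolerance = 1e-9)
  # time-shuffled observed rate -> near zero
  set.seed(28)
  shuf <- rate
  shuf$rate <- sample(shuf$rate)
  expect_lt(abs(spatiotemporal_correlation(shuf, tr, ref)), 0.02)
})

test_that("spike-triggered maps are translation invariant with flat nulls", {
  tr <- quick_trajectory(duration = 900, seed = 29)
  st <- simulate_spikes(grid_spec(spacing = 42, peak_rate = 6), tr,
                        seed = 30)
  m1 <- spike_triggered_map(st, tr)
  sh <- tr  # shifts are whole multiples of the 3 cm relative bin
  sh$x <- sh$x + 402
  sh$y <- sh$y + 150
  m2 <- spike_triggered_map(st, sh)
  expect_equal(m1$map, m2$map, tolerance = 1e-9)
  expect_equal(m1$spacing, m2$spacing)
  expect_equal(m1$spacing, 42, tolerance = 3)
  # spatially uniform cell: profile flat, no spacing peak
  stu <- simulate_spikes(speed_spec(intercept = 4, slope = 0), tr,
                         seed = 31)
  mu_ <- suppressWarnings(spike_triggered_map(stu, tr))
  prof <- mu_$profile$rate[mu_$profile$radius <= 60]
  expect_lt((max(prof, na.rm = TRUE) - min(prof, na.rm = TRUE)) /
              mean(prof, na.rm = TRUE), 0.25)
})

test_that("border scores rank wall-hugging above central fields", {
  tr <- quick_trajectory(duration = 900, seed = 32)
  stw <- simulate_spikes(border_spec(wall = "W", depth = 3, rate = 8,
                                     baseline_rate = 0.05), tr, seed = 33)
  bw <- border_score(rate_map(stw, tr))
  expect_gt(bw$score, 0.68)
  # central Gaussian field
  ctr_spec <- grid_spec(spacing = 90, phase = c(50, 50), peak_rate = 8,
                        field_sd = 10, baseline_rate = 0.02)
  stc <- simulate_spikes(ctr_spec, tr, seed = 34)
  bc <- border_score(rate_map(stc, tr))
  expect_lt(bc$score, 0)
  # invariance under the arena symmetries
  m <- rate_map(stw, tr)
  for (f in list(function(z) z[nrow(z):1, ], function(z) z[, ncol(z):1],
                 function(z) t(z))) {
    mm <- m
    mm$rates <- f(m$rates)
    mm$visited <- f(m$visited)
    expect_equal(border_score(mm)$score, bw$score, tolerance = 1e-9)
  }
})

test_that("head-direction tuning recovers von Mises structure", {
  tr <- quick_trajectory(duration = 1200, seed = 35)
  spec <- hd_spec(mu = pi / 2, kappa = 4, peak_rate = 6, baseline_rate = 0)
  st <- simulate_spikes(spec, tr, seed = 36)
  tun <- hd_tuning(st, tr)
  expect_equal(tun$preferred, pi / 2, tolerance = 6 * pi / 180)
  expect_equal(tun$mrl, besselI(4, 1) / besselI(4, 0), tolerance = 0.05)
  expect_lt(tun$rayleigh_p, 0.001)
  # direction-independent cell
  stu <- simulate_spikes(speed_spec(intercept = 4, slope = 0), tr,
                         seed = 37)
  expect_lt(hd_tuning(stu, tr)$mrl, 0.05)
  # all spikes at one bin
  trc <- tibble::tibble(t = seq(0, 60, by = 0.02), x = 50, y = 50,
                        hd = 1.0)
  one <- hd_tuning(seq(1, 50, by = 0.5), trc)
  expect_gt(one$mrl, 0.99)
  expect_true(hd_tuning(c(1, 2), trc)$excluded)
})
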