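test_that("waveform width and rate classify putative cell types", {
  expect_equal(classify_pn_in(0.25, 3), "IN")
  expect_equal(classify_pn_in(0.40, 12), "IN")
  expect_equal(classify_pn_in(0.40, 5), "PN")
  expect_equal(classify_pn_in(c(0.25, 0.4), c(3, 5)), c("IN", "PN"))
})

test_that("the stability screen enforces rate and between-half ratio", {
  st <- seq(0, 600, by = 0.2)  # 5 Hz constant
  expect_true(stability_screen(st, 0, 600)$pass)
  expect_false(stability_screen(seq(0, 600, by = 2), 0, 600)$pass) # 0.5 Hz
  st2 <- c(seq(0, 300, by = 0.5), seq(300, 600, by = 0.2))  # 2 vs 5 Hz
  scr <- stability_screen(st2, 0, 600)
  expect_false(scr$pass)
  expect_gt(scr$ratio, 2)
})

test_that("speed scores match an independent streaming correlation", {
  x <- tibble::tibble(t = 1:1000, rate = stats::runif(1000, 0, 20))
  expect_equal(speed_score(x, tibble::tibble(t = 1:1000, speed = x$rate)), 1)
  expect_error(speed_score(tibble::tibble(t = 1:10, rate = rep(1, 10)),
                           tibble::tibble(t = 1:10, speed = rep(2, 10))),
               "zero-variance")
  # rate = 2 + 0.5 speed + Poisson frame noise, vs a streaming oracle
  tr <- quick_trajectory(duration = 1200, seed = 44)
  ks <- kalman_speed(tr)
  set.seed(45)
  counts <- stats::rpois(nrow(tr), (2 + 0.5 * ks$speed) * 0.02)
  rate <- tibble::tibble(t = tr$t, rate = counts / 0.02)
  got <- speed_score(rate, tibble::tibble(t = tr$t, speed = ks$speed))
  # streaming-sum Pearson, written independently
  n <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(nrow(tr))) {
    if (is.na(ks$speed[i])) next
    xv <- rate$rate[i]; yv <- ks$speed[i]
    n <- n + 1; sx <- sx + xv; sy <- sy + yv
    sxx <- sxx + xv^2; syy <- syy + yv^2; sxy <- sxy + xv * yv
  }
  oracle <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  expect_gt(got, 0)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("speed tuning curves and adjusted ratios compose correctly", {
  v <- seq(1, 29, by = 2)
  cl <- tibble::tibble(speed = v, rate = 2 + 0.5 * v,
                       occupancy = rep(10, 15), reliable = TRUE)
  cd <- cl
  expect_equal(speed_adjusted_ratio(cl, cd)$adjusted_ratio, 1)
  cd2 <- dplyr::mutate(cl, rate = rate * 0.5)
  # halving the curve halves the ratio regardless of occupancy change
  cd2$occupancy <- rev(cl$occupancy) + 5
  expect_equal(speed_adjusted_ratio(cl, cd2)$adjusted_ratio, 0.5)
  # identical tuning + slower dark occupancy: adjusted 1, raw below 1
  occ_slow <- stats::dnorm(v, 8, 5)
  occ_fast <- stats::dnorm(v, 10, 5)
  cl3 <- tibble::tibble(speed = v, rate = 2 + 0.5 * v,
                        occupancy = occ_fast, reliable = TRUE)
  cd3 <- tibble::tibble(speed = v, rate = 2 + 0.5 * v,
                        occupancy = occ_slow, reliable = TRUE)
  r3 <- speed_adjusted_ratio(cl3, cd3)
  expect_equal(r3$adjusted_ratio, 1, tolerance = 1e-9)
  expect_lt(r3$raw_ratio, 1)
})

test_that("LN forward selection identifies a speed cell quickly", {
  tr <- quick_trajectory(duration = 400, seed = 46)
  st <- simulate_spikes(speed_spec(intercept = 2, slope = 0.5), tr,
                        seed = 47)
  ks <- kalman_speed(tr)
  sig <- tibble::tibble(t = tr$t, speed = ks$speed,
                        theta_phase = NA_real_)
  fit <- fit_ln_model(st, tr, sig, covariates = c("hd", "speed"))
  expect_true("speed" %in% fit$selected)
  # held-out gain of the selected model is positive in most folds
  expect_gt(mean(fit$fold_ll > 0), 0.5)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_covariates, length(fit$selected))
})

test_that("response-curve normalization modes behave by definition", {
  tr <- quick_trajectory(duration = 600, seed = 48)
  st <- simulate_spikes(speed_spec(intercept = 2, slope = 0.5), tr,
                        seed = 49)
  ks <- kalman_speed(tr)
  sig <- tibble::tibble(t = tr$t, speed = ks$speed, theta_phase = NA_real_)
  fit <- fit_ln_model(st, tr, sig, covariates = "speed")
  win <- speed_response_curve(fit, "within")
  expect_equal(max(win$response), 1)
  raw <- speed_response_curve(fit, "none")
  acr <- speed_response_curve(fit, "across", reference = raw)
  expect_equal(max(acr$response), 1, tolerance = 1e-9)
  # a fit without speed gives a flat curve at 1 under within-normalization
  flat_fit <- fit
  flat_fit$selected <- character(0)
  flat <- speed_response_curve(flat_fit, "within")
  expect_true(all(flat$response == 1))
  expect_error(speed_response_curve(fit, "across"), "reference")
})

test_that("hierarchical clustering splits monotone response curves by sign", {
  v <- seq(1, 29, by = 2)
  set.seed(50)
  up <- lapply(1:10, function(i)
    tibble::tibble(speed = v, response = (0.3 + 0.7 * v / 29) +
                     stats::rnorm(15, 0, 0.02)))
  dn <- lapply(1:10, function(i)
    tibble::tibble(speed = v, response = (1 - 0.7 * v / 29) +
                     stats::rnorm(15, 0, 0.02)))
  curves <- c(up, dn)
  names(curves) <- paste0("u", 1:20)
  cl <- cluster_speed_cells(curves)
  expect_equal(unname(cl$sign[1:10]), rep("positive", 10))
  expect_equal(unname(cl$sign[11:20]), rep("negative", 10))
  # permutation invariance of the assignment
  perm <- sample(20)
  cl2 <- cluster_speed_cells(curves[perm])
  expect_equal(cl2$sign[match(cl$unit_id, cl2$unit_id)], cl$sign)
  # degenerate case: all increasing
  cl3 <- cluster_speed_cells(c(up, up)[1:20])
  expect_gte(sum(cl3$sign == "positive"), 18)
})

test_that("cell classification applies either-condition threshold logic", {
  m <- tibble::tibble(
    unit_id = rep(c("g", "b", "h", "n"), each = 2),
    condition = rep(c("light", "dark"), 4),
    grid_score = c(0.25, 0.05, 0.1, 0.1, 0.05, 0.02, 0.1, 0.1),
    n_spikes = c(500, 400, 400, 350, 350, 400, 400, 400),
    border_score = c(0.1, 0.2, 0.3, 0.70, 0.2, 0.1, 0.3, 0.2),
    hd_inv_circ_sd = c(0.5, 0.4, 0.6, 0.5, 1.2, 0.9, 0.8, 0.7),
    hd_rayleigh_p = c(0.5, 0.5, 0.4, 0.3, 1e-4, 0.002, 0.2, 0.4),
    hd_peak_rate = c(3, 3, 2, 2, 2, 1.5, 2, 2),
    spike_width_ms = rep(c(0.4, 0.4, 0.45, 0.2), each = 2),
    mean_rate = c(4, 4, 3, 3, 2, 2, 12, 11))
  lab <- classify_cells(m)
  lab <- lab[match(c("g", "b", "h", "n"), lab$unit_id), ]
  expect_equal(lab$is_grid, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lab$is_border, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(lab$is_hd, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(lab$putative_class, c("PN", "PN", "PN", "IN"))
  # classification is a pure function: identical on rerun
  expect_identical(classify_cells(m), classify_cells(m))
  # missing metric -> undetermined, not FALSE
  m2 <- m[m$unit_id == "g", c("unit_id", "condition", "border_score")]
  lab2 <- classify_cells(m2)
  expect_true(is.na(lab2$is_grid))
})
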