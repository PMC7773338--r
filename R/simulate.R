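#' Trajectory configuration for synthetic foraging sessions
#'
#' The generator emulates a mouse foraging in a square arena: running
#' speed follows a truncated Ornstein-Uhlenbeck process around the mean
#' reported for illuminated foraging (11.6 cm/s), heading turns with
#' smoothly varying angular velocity, and walls reflect the path.
#'
#' @param arena_side Arena side, cm.
#' @param duration Session length, s (default 2520 = 42 min).
#' @param mean_speed Stationary mean running speed, cm/s.
#' @param speed_sd Stationary speed SD, cm/s.
#' @param speed_tau Speed process time constant, s.
#' @param turn_sd Stationary angular-velocity SD, rad/s.
#' @param turn_tau Angular-velocity time constant, s.
#' @param hd_jitter_kappa von Mises concentration of head direction about
#'   the movement heading.
#' @param dt Tracking step, s (50 Hz).
#' @param seed Integer seed.
#' @return A `trajectory_config` list.
#' @export
trajectory_config <- function(arena_side = 100, duration = 2520,
                              mean_speed = 11.6, speed_sd = 5,
                              speed_tau = 2, turn_sd = 2, turn_tau = 0.5,
                              hd_jitter_kappa = 50, dt = 0.02, seed = NULL) {
  assert_that(duration > 0, "duration must be positive")
  structure(list(arena_side = arena_side, duration = duration,
                 mean_speed = mean_speed, speed_sd = speed_sd,
                 speed_tau = speed_tau, turn_sd = turn_sd,
                 turn_tau = turn_tau, hd_jitter_kappa = hd_jitter_kappa,
                 dt = dt, seed = seed),
            class = "trajectory_config")
}

#' Simulate a foraging trajectory
#'
#' @param cfg A [trajectory_config()].
#' @return Tibble `t, x, y, hd` on the uniform `dt` grid (a tracking
#'   table for [mec_session()]).
#' @export
simulate_trajectory <- function(cfg) {
  assert_that(inherits(cfg, "trajectory_config"), "cfg must be a trajectory_config")
  with_seed(cfg$seed, {
    n <- floor(cfg$duration / cfg$dt)
    dt <- cfg$dt
    phi_v <- exp(-dt / cfg$speed_tau)
    phi_w <- exp(-dt / cfg$turn_tau)
    sig_v <- cfg$speed_sd * sqrt(1 - phi_v^2)
    sig_w <- cfg$turn_sd * sqrt(1 - phi_w^2)
    x <- y <- th <- v <- numeric(n)
    x[1] <- cfg$arena_side / 2; y[1] <- cfg$arena_side / 2
    th[1] <- stats::runif(1, 0, 2 * pi)
    v[1] <- max(0, cfg$mean_speed)
    w <- 0
    ev <- stats::rnorm(n); ew <- stats::rnorm(n)
    side <- cfg$arena_side
    for (i in seq_len(n - 1)) {
      v[i + 1] <- abs(cfg$mean_speed + phi_v * (v[i] - cfg$mean_speed) +
                        sig_v * ev[i])
      w <- phi_w * w + sig_w * ew[i]
      th[i + 1] <- th[i] + w * dt
      xi <- x[i] + v[i + 1] * cos(th[i + 1]) * dt
      yi <- y[i] + v[i + 1] * sin(th[i + 1]) * dt
      # reflect at walls, flipping the corresponding heading component
      if (xi < 0) { xi <- -xi; th[i + 1] <- pi - th[i + 1] }
      if (xi > side) { xi <- 2 * side - xi; th[i + 1] <- pi - th[i + 1] }
      if (yi < 0) { yi <- -yi; th[i + 1] <- -th[i + 1] }
      if (yi > side) { yi <- 2 * side - yi; th[i + 1] <- -th[i + 1] }
      x[i + 1] <- xi; y[i + 1] <- yi
    }
    jit <- rvonmises(n, 0, cfg$hd_jitter_kappa)
    jit <- ((jit + pi) %% (2 * pi)) - pi  # center on 0
    hd <- wrap_2pi(th + jit)
    tibble::tibble(t = (seq_len(n) - 1) * dt, x = x, y = y, hd = hd)
  })
}

# Running speed straight from tracking displacements (generator-side
# truth; analyses use the Kalman estimate instead).
trajectory_speed <- function(tracking) {
  dt <- stats::median(diff(tracking$t))
  d <- sqrt(diff(tracking$x)^2 + diff(tracking$y)^2) / dt
  c(d[1], d)
}

# --- cell specs ---------------------------------------------------------

#' Tuning-curve specifications for simulated units
#'
#' Each constructor returns a spec consumed by [rate_function()] and
#' [simulate_spikes()].  `conjunctive_spec()` composes several tunings
#' multiplicatively: each factor is normalized to mean 1 along the
#' trajectory, matching the exponential-additive structure of the LN
#' model in log rate.
#'
#' @param spacing Grid spacing (distance between neighboring field
#'   centers), cm.
#' @param orientation Grid orientation, rad.
#' @param phase Grid spatial phase offset, cm (length 2).
#' @param peak_rate Peak firing rate contribution, Hz.
#' @param field_sd Gaussian field SD, cm.
#' @param baseline_rate Additive baseline, Hz.
#' @return A cell-spec object.
#' @export
grid_spec <- function(spacing = 42, orientation = 0, phase = c(0, 0),
                      peak_rate = 5, field_sd = spacing / 7,
                      baseline_rate = 0.1) {
  assert_that(spacing > 2 * field_sd, "grid spacing must exceed 2 * field_sd")
  structure(list(spacing = spacing, orientation = orientation, phase = phase,
                 peak_rate = peak_rate, field_sd = field_sd,
                 baseline_rate = baseline_rate),
            class = c("grid_spec", "cell_spec"))
}

#' @rdname grid_spec
#' @param wall One of `"W"`, `"E"`, `"S"`, `"N"`.
#' @param depth Field depth from the wall, cm.
#' @param rate In-field rate, Hz.
#' @param arena_side Arena side, cm (locates the E/N walls).
#' @export
border_spec <- function(wall = "W", depth = 8, rate = 5, baseline_rate = 0.1,
                        arena_side = 100) {
  structure(list(wall = wall, depth = depth, rate = rate,
                 baseline_rate = baseline_rate, arena_side = arena_side),
            class = c("border_spec", "cell_spec"))
}

#' @rdname grid_spec
#' @param mu Preferred head direction, rad.
#' @param kappa von Mises concentration.
#' @export
hd_spec <- function(mu = 0, kappa = 4, peak_rate = 5, baseline_rate = 0.1) {
  structure(list(mu = mu, kappa = kappa, peak_rate = peak_rate,
                 baseline_rate = baseline_rate),
            class = c("hd_spec", "cell_spec"))
}

#' @rdname grid_spec
#' @param intercept Rate at speed 0, Hz.
#' @param slope Hz per cm/s (linear/saturating forms) or peak rate gain
#'   above the intercept, Hz (bell form).
#' @param shape `"linear"`, `"saturating"`, or `"bell"` (cells with an
#'   interior preferred speed).
#' @param v_sat Saturation constant for the saturating form, cm/s.
#' @param v_pref,v_width Preferred speed and tuning width for the bell
#'   form, cm/s.
#' @export
speed_spec <- function(intercept = 2, slope = 0.3, shape = "linear",
                       v_sat = 15, v_pref = 10, v_width = 8,
                       baseline_rate = 0) {
  structure(list(intercept = intercept, slope = slope, shape = shape,
                 v_sat = v_sat, v_pref = v_pref, v_width = v_width,
                 baseline_rate = baseline_rate),
            class = c("speed_spec", "cell_spec"))
}

#' @rdname grid_spec
#' @param f Rhythm frequency, Hz (theta band 4-12).
#' @param mod_depth Modulation depth in `[0, 1]`.
#' @param base_rate Mean rate, Hz.
#' @export
theta_rhythm_spec <- function(f = 8, mod_depth = 0.5, base_rate = 5,
                              baseline_rate = 0) {
  assert_that(mod_depth >= 0 && mod_depth <= 1, "mod_depth must be in [0,1]")
  structure(list(f = f, mod_depth = mod_depth, base_rate = base_rate,
                 baseline_rate = baseline_rate),
            class = c("theta_rhythm_spec", "cell_spec"))
}

#' @rdname grid_spec
#' @param ... Component cell specs.
#' @param mean_rate Target trajectory-averaged rate of the composed cell,
#'   Hz.
#' @export
conjunctive_spec <- function(..., mean_rate = 5) {
  parts <- list(...)
  assert_that(all(vapply(parts, inherits, TRUE, "cell_spec")),
              "components must be cell specs")
  structure(list(parts = parts, mean_rate = mean_rate),
            class = c("conjunctive_spec", "cell_spec"))
}

# hexagonal-lattice gain in [0, 1]: sum of unit Gaussians at lattice nodes
hex_gain <- function(spec, x, y) {
  s <- spec$spacing
  a1 <- s * c(cos(spec$orientation), sin(spec$orientation))
  a2 <- s * c(cos(spec$orientation + pi / 3), sin(spec$orientation + pi / 3))
  B <- cbind(a1, a2)
  Binv <- solve(B)
  px <- x - spec$phase[1]; py <- y - spec$phase[2]
  u <- Binv[1, 1] * px + Binv[1, 2] * py
  w <- Binv[2, 1] * px + Binv[2, 2] * py
  g <- numeric(length(x))
  for (di in -1:1) for (dj in -1:1) {
    ni <- round(u) + di; nj <- round(w) + dj
    cx <- B[1, 1] * ni + B[1, 2] * nj
    cy <- B[2, 1] * ni + B[2, 2] * nj
    g <- g + exp(-((px - cx)^2 + (py - cy)^2) / (2 * spec$field_sd^2))
  }
  unname(pmin(g, 1))
}

#' Evaluate a cell spec's firing rate
#'
#' Total function of the behavioral covariates; any covariate a spec does
#' not use may be missing.
#'
#' @param spec A cell spec.
#' @param x,y Position, cm.
#' @param hd Head direction, rad.
#' @param speed Running speed, cm/s.
#' @param theta_phase LFP theta phase, rad.
#' @return Rate, Hz (vectorized, always `>= 0`).
#' @export
rate_function <- function(spec, x = NULL, y = NULL, hd = NULL, speed = NULL,
                          theta_phase = NULL) {
  UseMethod("rate_function")
}

#' @export
rate_function.grid_spec <- function(spec, x = NULL, y = NULL, hd = NULL,
                                    speed = NULL, theta_phase = NULL) {
  spec$baseline_rate + spec$peak_rate * hex_gain(spec, x, y)
}

#' @export
rate_function.border_spec <- function(spec, x = NULL, y = NULL, hd = NULL,
                                      speed = NULL, theta_phase = NULL) {
  d <- switch(spec$wall, W = x, S = y,
              E = spec$arena_side - x, N = spec$arena_side - y)
  spec$baseline_rate + spec$rate * as.numeric(d <= spec$depth)
}

#' @export
rate_function.hd_spec <- function(spec, x = NULL, y = NULL, hd = NULL,
                                  speed = NULL, theta_phase = NULL) {
  spec$baseline_rate +
    spec$peak_rate * exp(spec$kappa * (cos(hd - spec$mu) - 1))
}

#' @export
rate_function.speed_spec <- function(spec, x = NULL, y = NULL, hd = NULL,
                                     speed = NULL, theta_phase = NULL) {
  r <- switch(spec$shape,
    linear = spec$intercept + spec$slope * speed,
    saturating = spec$intercept +
      spec$slope * spec$v_sat * (1 - exp(-speed / spec$v_sat)),
    bell = spec$intercept +
      spec$slope * exp(-(speed - spec$v_pref)^2 / (2 * spec$v_width^2)))
  spec$baseline_rate + pmax(0, r)
}

#' @export
rate_function.theta_rhythm_spec <- function(spec, x = NULL, y = NULL,
                                            hd = NULL, speed = NULL,
                                            theta_phase = NULL) {
  spec$baseline_rate +
    spec$base_rate * (1 + spec$mod_depth * cos(theta_phase))
}

#' @export
rate_function.conjunctive_spec <- function(spec, x = NULL, y = NULL,
                                           hd = NULL, speed = NULL,
                                           theta_phase = NULL) {
  g <- rep(1, max(length(x), length(hd), length(speed), length(theta_phase), 1))
  for (p in spec$parts) {
    f <- rate_function(p, x = x, y = y, hd = hd, speed = speed,
                       theta_phase = theta_phase)
    m <- mean(f, na.rm = TRUE)
    if (m > 0) g <- g * (f / m)
  }
  spec$mean_rate * g
}

#' Simulate a Poisson spike train from a cell spec along a trajectory
#'
#' Inhomogeneous Poisson thinning at 1 ms resolution of the spec's rate
#' evaluated on interpolated behavioral covariates.
#'
#' @param spec A cell spec.
#' @param tracking Tracking tibble (`t, x, y, hd`).
#' @param theta Optional theta phase carrier: a list with `t` and `phase`
#'   (unwrapped radians); required only by theta-rhythmic specs riding on
#'   an LFP.  When absent, a theta-rhythmic spec uses its own constant-`f`
#'   oscillator.
#' @param seed Integer seed.
#' @param dt_thin Thinning resolution, s.
#' @return Numeric vector of spike times, s.
#' @export
simulate_spikes <- function(spec, tracking, theta = NULL, seed = NULL,
                            dt_thin = 0.001) {
  with_seed(seed, {
    t_hi <- seq(tracking$t[1], tracking$t[nrow(tracking)], by = dt_thin)
    x <- interp_at(tracking$t, tracking$x, t_hi)
    y <- interp_at(tracking$t, tracking$y, t_hi)
    hd_c <- interp_at(tracking$t, cos(tracking$hd), t_hi)
    hd_s <- interp_at(tracking$t, sin(tracking$hd), t_hi)
    hd <- wrap_2pi(atan2(hd_s, hd_c))
    sp <- trajectory_speed(tracking)
    speed <- interp_at(tracking$t, sp, t_hi)
    phase <- if (!is.null(theta)) {
      interp_at(theta$t, theta$phase, t_hi)
    } else if (inherits(spec, "theta_rhythm_spec")) {
      2 * pi * spec$f * t_hi
    } else if (inherits(spec, "conjunctive_spec") &&
                 any(vapply(spec$parts, inherits, TRUE, "theta_rhythm_spec"))) {
      f0 <- spec$parts[[which(vapply(spec$parts, inherits, TRUE,
                                     "theta_rhythm_spec"))[1]]]$f
      2 * pi * f0 * t_hi
    } else NULL
    lam <- rate_function(spec, x = x, y = y, hd = hd, speed = speed,
                         theta_phase = phase)
    lam[is.na(lam)] <- 0
    assert_that(all(lam >= 0), "rate function returned negative rates")
    keep <- stats::runif(length(t_hi)) < lam * dt_thin
    t_hi[keep]
  })
}

#' LFP specification: theta carrier with speed-coupled frequency
#'
#' Instantaneous theta frequency is linear in running speed with
#' condition-specific slope and intercept; phase is integrated
#' continuously across epoch boundaries.
#'
#' @param intercept Named vector of intercepts, Hz, for `light` and
#'   `dark`.
#' @param slope Named vector of slopes, Hz per cm/s.
#' @param amplitude Carrier amplitude (arbitrary units).
#' @param noise_sd Additive white noise SD.
#' @param slope_ramp Optional within-epoch slope dynamics: a list with
#'   `delta` (named vector, Hz per cm/s) and `tau` (s); the effective
#'   slope at time `t` after an epoch start is
#'   `slope + delta * (1 - exp(-t / tau))`, emulating the slow
#'   saturating drift of the theta-frequency speed slope after
#'   illumination changes.
#' @return An `lfp_spec`.
#' @export
lfp_spec <- function(intercept = c(light = 7.2, dark = 7.2),
                     slope = c(light = 0.05, dark = 0.02),
                     amplitude = 1, noise_sd = 0.3, slope_ramp = NULL) {
  structure(list(intercept = intercept, slope = slope,
                 amplitude = amplitude, noise_sd = noise_sd,
                 slope_ramp = slope_ramp),
            class = "lfp_spec")
}

#' Simulate the LFP trace for a session
#'
#' @param spec An [lfp_spec()].
#' @param tracking Tracking tibble (speed is derived from it).
#' @param epochs Epoch table assigning each instant a condition.
#' @param fs Sample rate, Hz.
#' @param seed Integer seed.
#' @return List with `samples`, `fs`, `t0`, plus the unwrapped `phase`
#'   and instantaneous `freq` used (at `fs`), for reuse as a spike-train
#'   theta carrier.
#' @export
simulate_lfp <- function(spec, tracking, epochs, fs = 600, seed = NULL) {
  with_seed(seed, {
    t_hi <- seq(tracking$t[1], tracking$t[nrow(tracking)], by = 1 / fs)
    speed <- interp_at(tracking$t, trajectory_speed(tracking), t_hi)
    cond <- rep("light", length(t_hi))
    offset <- rep(0, length(t_hi))
    for (i in seq_len(nrow(epochs))) {
      sel <- t_hi >= epochs$start[i] & t_hi < epochs$end[i]
      cond[sel] <- epochs$condition[i]
      offset[sel] <- t_hi[sel] - epochs$start[i]
    }
    m <- unname(spec$slope[cond])
    if (!is.null(spec$slope_ramp)) {
      m <- m + unname(spec$slope_ramp$delta[cond]) *
        (1 - exp(-offset / spec$slope_ramp$tau))
    }
    f <- unname(spec$intercept[cond] + m * speed)
    assert_that(all(f > 0.5 & f < 20),
                "instantaneous frequency left (0.5, 20) Hz; adjust lfp_spec")
    phase <- cumsum(2 * pi * f / fs)
    samples <- spec$amplitude * cos(phase) +
      stats::rnorm(length(t_hi), 0, spec$noise_sd)
    list(samples = samples, fs = fs, t0 = t_hi[1], phase = phase, freq = f)
  })
}

#' Assemble a complete synthetic session
#'
#' Generates trajectory, epochs, LFP, and one Poisson spike train per
#' cell spec; embeds all specs and seeds in the session metadata as
#' ground truth.
#'
#' @param traj_cfg A [trajectory_config()].
#' @param cell_specs Named list of cell specs (names become unit ids).
#' @param lfp A [lfp_spec()] or `NULL` for no LFP.
#' @param epoch_length Epoch length, s.
#' @param first_condition Condition of the first epoch.
#' @param spike_widths Optional named numeric vector of waveform widths,
#'   ms (default 0.45, a putative principal neuron).
#' @param seed Master seed; per-component seeds are derived from it.
#' @return An `mec_session`.
#' @export
make_session <- function(traj_cfg = trajectory_config(),
                         cell_specs = list(),
                         lfp = lfp_spec(),
                         epoch_length = 180, first_condition = "light",
                         spike_widths = NULL, seed = 1) {
  traj_cfg$seed <- traj_cfg$seed %||% (seed * 1000L %% 2147483647L)
  tracking <- simulate_trajectory(traj_cfg)
  epochs <- alternating_epochs(traj_cfg$duration, epoch_length,
                               first = first_condition)
  lfp_out <- NULL; theta <- NULL
  if (!is.null(lfp)) {
    sim <- simulate_lfp(lfp, tracking, epochs, seed = seed * 1000L + 1L)
    lfp_out <- list(samples = sim$samples, fs = sim$fs, t0 = sim$t0)
    theta <- list(t = seq(tracking$t[1], by = 1 / sim$fs,
                          length.out = length(sim$samples)),
                  phase = sim$phase)
  }
  spikes <- tibble::tibble(unit_id = character(), t = numeric())
  for (i in seq_along(cell_specs)) {
    id <- names(cell_specs)[i] %||% paste0("u", i)
    st <- simulate_spikes(cell_specs[[i]], tracking, theta = theta,
                          seed = seed * 1000L + 1L + i)
    spikes <- dplyr::bind_rows(spikes,
                               tibble::tibble(unit_id = id, t = st))
  }
  ids <- names(cell_specs) %||% paste0("u", seq_along(cell_specs))
  widths <- rep(0.45, length(ids))
  if (!is.null(spike_widths)) widths[match(names(spike_widths), ids)] <-
    spike_widths
  units <- tibble::tibble(unit_id = ids, spike_width_ms = widths,
                          label = NA_character_)
  mec_session(tracking = tracking, spikes = spikes, units = units,
              epochs = epochs, lfp = lfp_out,
              arena_side = traj_cfg$arena_side,
              metadata = list(seed = seed,
                              ground_truth = list(cells = cell_specs,
                                                  lfp = lfp,
                                                  trajectory = traj_cfg)))
}
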