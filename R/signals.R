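#' Running speed and acceleration from tracking via a Kalman filter
#'
#' Filters the 50 Hz positional data with a 2D constant-velocity Kalman
#' filter (state `[x, y, vx, vy]`, white-acceleration process noise).
#' Speed is the Euclidean norm of the velocity estimate; acceleration is
#' the centered finite difference of speed, smoothed with the same 125 ms
#' Gaussian used for firing rates.  Missing tracking samples are bridged
#' by prediction-only steps but flagged `NA` in the output.
#'
#' @param tracking Tracking tibble (`t, x, y, hd`).
#' @param process_noise White-acceleration spectral density,
#'   (cm/s^2)^2 per s.
#' @param measurement_noise Position measurement SD, cm.
#' @return Tibble `t, speed, accel` (cm/s, cm/s^2) on the tracking grid.
#' @export
kalman_speed <- function(tracking, process_noise = 10,
                         measurement_noise = 0.5) {
  n <- nrow(tracking)
  ok <- !is.na(tracking$x) & !is.na(tracking$y)
  assert_that(sum(ok) >= 3, "need at least 3 valid tracking samples")
  dt <- stats::median(diff(tracking$t))
  # the x and y axes decouple into identical 2-state [pos, vel] filters;
  # the Riccati recursion is iterated to its steady-state gain first,
  # then the (fast, scalar) state recursion is run over the samples
  q <- process_noise
  r2 <- measurement_noise^2
  p11 <- 1; p12 <- 0; p22 <- 100
  k1 <- k2 <- 0
  for (it in 1:500) {
    a11 <- p11 + 2 * dt * p12 + dt^2 * p22 + q * dt^3 / 3
    a12 <- p12 + dt * p22 + q * dt^2 / 2
    a22 <- p22 + q * dt
    S <- a11 + r2
    k1n <- a11 / S; k2n <- a12 / S
    p11 <- (1 - k1n) * a11
    p12 <- (1 - k1n) * a12
    p22 <- a22 - k2n * a12
    if (abs(k1n - k1) < 1e-12 && abs(k2n - k2) < 1e-12) {
      k1 <- k1n; k2 <- k2n; break
    }
    k1 <- k1n; k2 <- k2n
  }
  first <- which(ok)[1]
  px <- tracking$x[first]; vx_ <- 0
  py <- tracking$y[first]; vy_ <- 0
  vx <- vy <- rep(NA_real_, n)
  xs <- tracking$x; ys <- tracking$y
  for (i in first:n) {
    if (i > first) {
      px <- px + vx_ * dt
      py <- py + vy_ * dt
    }
    if (ok[i]) {
      ix <- xs[i] - px; iy <- ys[i] - py
      px <- px + k1 * ix; vx_ <- vx_ + k2 * ix
      py <- py + k1 * iy; vy_ <- vy_ + k2 * iy
      vx[i] <- vx_; vy[i] <- vy_
    }
  }
  speed <- sqrt(vx^2 + vy^2)
  sd_samp <- 0.125 / dt
  ds <- c(NA, (speed[-(1:2)] - speed[1:(n - 2)]) / (2 * dt), NA)
  accel <- gauss_smooth(ds, sd_samp)
  tibble::tibble(t = tracking$t, speed = speed, accel = accel)
}

#' Instantaneous firing rate on the behavioral grid
#'
#' Counts spikes per 20 ms video frame, divides by the frame period, and
#' (optionally) smooths with a 125 ms Gaussian.  Before smoothing the
#' rate integral equals the in-range spike count exactly.
#'
#' @param spike_times Numeric spike times, s.
#' @param t_grid Frame-start times, s, uniform 20 ms grid.
#' @param smooth_sd Gaussian SD, s (`0` for raw counts).
#' @return Tibble `t, rate` (Hz).
#' @export
instantaneous_rate <- function(spike_times, t_grid, smooth_sd = 0.125) {
  dt <- stats::median(diff(t_grid))
  edges <- c(t_grid, t_grid[length(t_grid)] + dt)
  counts <- graphics::hist(spike_times[spike_times >= edges[1] &
                                         spike_times < edges[length(edges)]],
                           breaks = edges, plot = FALSE)$counts
  rate <- counts / dt
  if (smooth_sd > 0) rate <- gauss_smooth(rate, smooth_sd / dt)
  tibble::tibble(t = t_grid, rate = rate)
}

#' Locate the session's theta band from the LFP power spectrum
#'
#' Welch-style smoothed periodogram; the band is the largest local peak
#' in 4-12 Hz plus/minus `half_width`, clipped to `[4, 12]`.  If no peak
#' rises above 1.5x the local background the fixed 6-10 Hz band is
#' returned with a warning.
#'
#' @param lfp LFP list (`samples`, `fs`, `t0`).
#' @param half_width Band half width, Hz.
#' @return Numeric `c(lo, hi)`, Hz.
#' @export
detect_theta_band <- function(lfp, half_width = 2) {
  assert_that(length(lfp$samples) / lfp$fs >= 60,
              "need at least 60 s of LFP")
  sp <- stats::spec.pgram(stats::ts(lfp$samples, frequency = lfp$fs),
                          spans = c(51, 51), taper = 0.1, plot = FALSE,
                          detrend = TRUE)
  sel <- sp$freq >= 2 & sp$freq <= 20
  f <- sp$freq[sel]; p <- sp$spec[sel]
  in_theta <- f >= 4 & f <= 12
  pk_i <- which(in_theta)[which.max(p[in_theta])]
  background <- stats::median(p)
  if (!length(pk_i) || p[pk_i] < 1.5 * background) {
    warning("no theta peak above background; falling back to 6-10 Hz")
    return(c(6, 10))
  }
  pk <- f[pk_i]
  c(max(4, pk - half_width), min(12, pk + half_width))
}

#' Theta phase, frequency, and amplitude from the LFP
#'
#' Zero-phase third-order Butterworth band-pass, then the Hilbert
#' analytic signal.  Instantaneous frequency is the unwrapped phase
#' derivative, clipped to 0.5-20 Hz to suppress edge artifacts.
#'
#' @param lfp LFP list at 600 Hz.
#' @param band Numeric `c(lo, hi)`, Hz (e.g. from
#'   [detect_theta_band()]).
#' @return Tibble `t, phase, phase_unwrapped, frequency, amplitude` at
#'   the LFP rate.
#' @export
theta_signal <- function(lfp, band = c(6, 10)) {
  fs <- lfp$fs
  assert_that(band[1] > 0 && band[2] < fs / 2, "band outside (0, fs/2)")
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp$samples)
  z <- analytic_signal(filt)
  phase <- Arg(z)
  amp <- Mod(z)
  pu <- unwrap_phase(phase)
  n <- length(pu)
  freq <- c(NA, (pu[-(1:2)] - pu[1:(n - 2)]) / (2 / fs), NA) / (2 * pi)
  freq <- pmin(pmax(freq, 0.5), 20)
  tibble::tibble(t = lfp$t0 + (seq_len(n) - 1) / fs,
                 phase = phase, phase_unwrapped = pu,
                 frequency = freq, amplitude = amp)
}

#' Align theta measures to the 50 Hz behavioral grid
#'
#' Nearest-sample alignment of the 600 Hz theta signal to the tracking
#' grid, with the first and last `edge_exclude` seconds of every epoch
#' masked (Hilbert edge artifacts and transition smear).
#'
#' @param theta Output of [theta_signal()].
#' @param t_grid 50 Hz time grid, s.
#' @param epochs Optional epoch table driving the edge mask.
#' @param edge_exclude Seconds masked at each epoch edge.
#' @return Tibble `t, phase, frequency, amplitude`.
#' @export
align_theta <- function(theta, t_grid, epochs = NULL, edge_exclude = 0.5) {
  idx <- round((t_grid - theta$t[1]) / (theta$t[2] - theta$t[1])) + 1
  idx[idx < 1 | idx > nrow(theta)] <- NA
  out <- tibble::tibble(t = t_grid,
                        phase = theta$phase[idx],
                        frequency = theta$frequency[idx],
                        amplitude = theta$amplitude[idx])
  if (!is.null(epochs)) {
    keep <- rep(FALSE, length(t_grid))
    for (i in seq_len(nrow(epochs))) {
      keep <- keep | (t_grid >= epochs$start[i] + edge_exclude &
                        t_grid < epochs$end[i] - edge_exclude)
    }
    out$frequency[!keep] <- NA
    out$amplitude[!keep] <- NA
  }
  out
}

#' Mask samples by near-zero acceleration
#'
#' Keeps samples with `|accel| <= window`, the restriction used to show
#' that theta-frequency speed tuning is not an acceleration artifact.
#'
#' @param signals Tibble containing an `accel` column.
#' @param window Threshold, cm/s^2.
#' @return `signals` filtered to the masked rows.
#' @export
restrict_by_acceleration <- function(signals, window = 5) {
  out <- dplyr::filter(signals, !is.na(.data$accel),
                       abs(.data$accel) <= window)
  assert_that(nrow(out) > 0,
              sprintf("no samples with |accel| <= %g cm/s^2", window))
  out
}

#' Derive the full 50 Hz signal set for a session
#'
#' Convenience wrapper: Kalman speed/acceleration plus (when an LFP is
#' present) theta phase, frequency, and amplitude aligned to the
#' behavioral grid with epoch-edge exclusion.
#'
#' @param session An `mec_session`.
#' @param band Theta band, or `NULL` to detect it from the PSD.
#' @param edge_exclude Epoch-edge exclusion, s.
#' @return Tibble `t, speed, accel, theta_phase, theta_freq, theta_amp`.
#' @export
derive_signals <- function(session, band = NULL, edge_exclude = 0.5) {
  ks <- kalman_speed(session$tracking)
  out <- tibble::tibble(t = ks$t, speed = ks$speed, accel = ks$accel,
                        theta_phase = NA_real_, theta_freq = NA_real_,
                        theta_amp = NA_real_)
  if (!is.null(session$lfp)) {
    if (is.null(band)) band <- detect_theta_band(session$lfp)
    th <- theta_signal(session$lfp, band)
    al <- align_theta(th, out$t, session$epochs, edge_exclude)
    out$theta_phase <- al$phase
    out$theta_freq <- al$frequency
    out$theta_amp <- al$amplitude
  }
  out
}
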