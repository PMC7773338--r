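# Internal numerical helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian smoothing of a regularly sampled signal; kernel truncated at
# +/- 4 SD and renormalized within the window so edges are not damped.
# NA samples are excluded from the local normalization.
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- stats::filter(c(rep(0, half), x0, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), as.numeric(ok), rep(0, half)), k, sides = 2)
  out <- as.numeric(num / den)[(half + 1):(half + length(x))]
  out[!ok] <- NA_real_
  out
}

# Analytic signal by the frequency-domain construction: doubles positive
# frequencies, zeroes negative ones.  Input must be real and finite.
# Zero-pads to a highly composite length so the FFT stays O(n log n),
# then truncates; the pad only perturbs the extreme edges, which all
# downstream statistics already exclude.
analytic_signal <- function(x) {
  n0 <- length(x)
  np <- stats::nextn(n0, c(2, 3, 5))
  if (np > n0) {
    z <- analytic_signal_core(c(x, rep(0, np - n0)))
    return(z[seq_len(n0)])
  }
  analytic_signal_core(x)
}

analytic_signal_core <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Phase unwrapping (adds multiples of 2*pi so jumps never exceed pi).
unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

wrap_2pi <- function(a) a %% (2 * pi)

# --- circular statistics -----------------------------------------------

# Mean resultant length and mean direction of angles, optionally weighted.
circ_resultant <- function(angles, w = NULL) {
  if (is.null(w)) w <- rep(1, length(angles))
  keep <- !is.na(angles) & !is.na(w)
  angles <- angles[keep]; w <- w[keep]
  if (!length(angles) || sum(w) <= 0) {
    return(list(mrl = NA_real_, mean = NA_real_, n = 0L))
  }
  C <- sum(w * cos(angles)) / sum(w)
  S <- sum(w * sin(angles)) / sum(w)
  list(mrl = sqrt(C^2 + S^2), mean = wrap_2pi(atan2(S, C)), n = length(angles))
}

# Rayleigh test of circular uniformity (Zar's approximation).
rayleigh_test <- function(angles) {
  res <- circ_resultant(angles)
  n <- res$n
  if (n < 2) return(list(statistic = NA_real_, p_value = NA_real_, n = n))
  R <- n * res$mrl
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(statistic = z, p_value = min(1, p), n = n)
}

# von Mises sampler (Best & Fisher 1979 rejection method).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- wrap_2pi(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

# --- interpolation ------------------------------------------------------

# Bilinear interpolation of a matrix at arbitrary (row, col) coordinates
# given in bin units (1-based, bin centers at integers).  Coordinates
# falling outside the grid, or touching an NA corner, give NA.
bilinear <- function(mat, ri, ci) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # clamp exact upper edge
  edge_r <- ri == nr & c0 >= 1 & c0 + 1 <= nc
  edge_c <- ci == nc & r0 >= 1 & r0 + 1 <= nr
  out <- rep(NA_real_, length(ri))
  idx <- which(ok)
  if (length(idx)) {
    i00 <- cbind(r0[idx], c0[idx]); i10 <- cbind(r0[idx] + 1, c0[idx])
    i01 <- cbind(r0[idx], c0[idx] + 1); i11 <- cbind(r0[idx] + 1, c0[idx] + 1)
    v <- (1 - fr[idx]) * (1 - fc[idx]) * mat[i00] +
      fr[idx] * (1 - fc[idx]) * mat[i10] +
      (1 - fr[idx]) * fc[idx] * mat[i01] +
      fr[idx] * fc[idx] * mat[i11]
    out[idx] <- v
  }
  # points exactly on the top/right boundary
  ib <- which(!ok & (edge_r | edge_c) & ri <= nr & ci <= nc & ri >= 1 & ci >= 1)
  if (length(ib)) {
    out[ib] <- mat[cbind(pmin(round(ri[ib]), nr), pmin(round(ci[ib]), nc))]
  }
  out
}

# Linear interpolation helper that tolerates NA runs at the edges.
interp_at <- function(t, y, t_out) {
  ok <- !is.na(y)
  if (sum(ok) < 2) return(rep(NA_real_, length(t_out)))
  stats::approx(t[ok], y[ok], xout = t_out, rule = 2)$y
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
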