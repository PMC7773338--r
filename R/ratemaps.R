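#' Occupancy-normalized spatial firing rate map
#'
#' Divides the arena into square bins, computes per-bin spike count over
#' per-bin occupancy time, and smooths the rate surface with a 2D
#' Gaussian kernel restricted to visited bins (unvisited bins are
#' excluded from the kernel normalization, not filled).
#'
#' @param spike_times Spike times, s.
#' @param tracking Tracking tibble (`t, x, y, hd`); `NA` positions are
#'   excluded from occupancy.
#' @param arena_side Arena side, cm.
#' @param bin_size Bin side, cm (default 3).
#' @param smooth_sd Gaussian SD, cm (default 3; `0` disables smoothing).
#' @return An object of class `mec_ratemap`: smoothed `rates`, raw
#'   `rates_raw`, `spike_counts`, `occupancy` (s), logical `visited`,
#'   and the geometry.
#' @export
rate_map <- function(spike_times, tracking, arena_side = 100, bin_size = 3,
                     smooth_sd = 3) {
  # partition the arena exactly: the effective bin side is the nearest
  # divisor of the arena side, so the grid never overhangs the walls
  nb <- max(2L, round(arena_side / bin_size))
  bin_size <- arena_side / nb
  dt <- stats::median(diff(tracking$t))
  ok <- !is.na(tracking$x) & !is.na(tracking$y)
  assert_that(any(ok), "tracking has no valid positions")
  bx <- pmin(pmax(floor(tracking$x[ok] / bin_size), 0), nb - 1) + 1
  by <- pmin(pmax(floor(tracking$y[ok] / bin_size), 0), nb - 1) + 1
  occ <- matrix(0, nb, nb)
  tab <- table(factor(bx, levels = 1:nb), factor(by, levels = 1:nb))
  occ <- matrix(as.numeric(tab), nb, nb) * dt
  sx <- interp_at(tracking$t[ok], tracking$x[ok], spike_times)
  sy <- interp_at(tracking$t[ok], tracking$y[ok], spike_times)
  keep <- !is.na(sx) & !is.na(sy)
  sbx <- pmin(pmax(floor(sx[keep] / bin_size), 0), nb - 1) + 1
  sby <- pmin(pmax(floor(sy[keep] / bin_size), 0), nb - 1) + 1
  cnt <- matrix(as.numeric(table(factor(sbx, levels = 1:nb),
                                 factor(sby, levels = 1:nb))), nb, nb)
  visited <- occ > 0
  assert_that(any(visited), "zero occupancy everywhere")
  raw <- matrix(NA_real_, nb, nb)
  raw[visited] <- cnt[visited] / occ[visited]
  rates <- if (smooth_sd > 0) smooth_map(raw, smooth_sd / bin_size) else raw
  structure(list(rates = rates, rates_raw = raw, spike_counts = cnt,
                 occupancy = occ, visited = visited, bin_size = bin_size,
                 smoothing_sd = smooth_sd, arena_side = arena_side),
            class = "mec_ratemap")
}

# 2D Gaussian smoothing over visited (non-NA) bins with mask-renormalized
# kernel weights.
smooth_map <- function(m, sd_bins) {
  half <- max(1L, ceiling(3 * sd_bins))
  k1 <- stats::dnorm(seq(-half, half), sd = sd_bins)
  K <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  ok <- !is.na(m)
  m0 <- ifelse(ok, m, 0)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (di in -half:half) {
    ri_src <- max(1, 1 - di):min(nr, nr - di)
    ri_dst <- ri_src + di
    for (dj in -half:half) {
      cj_src <- max(1, 1 - dj):min(nc, nc - dj)
      cj_dst <- cj_src + dj
      w <- K[di + half + 1, dj + half + 1]
      num[ri_dst, cj_dst] <- num[ri_dst, cj_dst] + w * m0[ri_src, cj_src]
      den[ri_dst, cj_dst] <- den[ri_dst, cj_dst] + w * ok[ri_src, cj_src]
    }
  }
  out <- num / den
  out[!ok] <- NA_real_
  out
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every integer spatial
#' lag, using pairwise-complete visited bins.  The result is
#' point-symmetric with value 1 at zero lag.
#'
#' @param map An `mec_ratemap` (or a plain numeric matrix with `NA`
#'   marking unvisited bins).
#' @param min_overlap Minimum overlapping bins for a defined lag.
#' @return `(2n-1) x (2n-1)` matrix of correlations (`NA` where the
#'   overlap is too small).
#' @export
autocorr2d <- function(map, min_overlap = 20) {
  m <- if (inherits(map, "mec_ratemap")) map$rates else map
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, 2 * nr - 1, 2 * nc - 1)
  for (di in -(nr - 1):(nr - 1)) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    for (dj in -(nc - 1):(nc - 1)) {
      cj <- max(1, 1 - dj):min(nc, nc - dj)
      a <- m[ri, cj, drop = FALSE]
      b <- m[ri + di, cj + dj, drop = FALSE]
      v <- !is.na(a) & !is.na(b)
      nv <- sum(v)
      if (nv >= min_overlap) {
        av <- a[v]; bv <- b[v]
        sa <- stats::sd(av); sb <- stats::sd(bv)
        if (sa > 0 && sb > 0) {
          out[di + nr, dj + nc] <-
            sum((av - mean(av)) * (bv - mean(bv))) / ((nv - 1) * sa * sb)
        }
      }
    }
  }
  out
}

# Local maxima of a matrix by strict 8-neighborhood dominance.
local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- !is.na(m) & m >= threshold
  res <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (!ok[i, j]) next
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (sum(!is.na(nb)) < 2) next
    if (m[i, j] >= max(nb, na.rm = TRUE) &&
          sum(nb == m[i, j], na.rm = TRUE) == 1) {
      res <- rbind(res, c(i, j, m[i, j]))
    }
  }
  res
}

# Autocorrelogram fields: connected regions above threshold, excluding
# the central (zero-lag) field, with a minimum area so isolated noisy
# bins do not masquerade as grid peaks.  Returns peak locations (field
# maxima) as rows of (i, j, value).
autocorr_fields <- function(ac, threshold = 0.1, min_bins = 6) {
  mask <- !is.na(ac) & ac >= threshold
  if (!any(mask)) return(NULL)
  lab <- label_components(mask)
  ctr <- (nrow(ac) + 1) / 2
  central <- lab[ctr, ctr]
  res <- NULL
  for (id in seq_len(max(lab))) {
    if (id == central) next
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_bins) next
    k <- which.max(ac[idx])
    res <- rbind(res, c(idx[k, 1], idx[k, 2], ac[idx[k, 1], idx[k, 2]]))
  }
  res
}

# Least-squares central conic fit x'Ax = 1 through points (centered
# coordinates); returns the 2x2 matrix A or NULL when not elliptical.
fit_ellipse <- function(px, py) {
  M <- cbind(px^2, px * py, py^2)
  beta <- tryCatch(solve(crossprod(M), crossprod(M, rep(1, length(px)))),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  A <- matrix(c(beta[1], beta[2] / 2, beta[2] / 2, beta[3]), 2, 2)
  ev <- eigen(A, symmetric = TRUE)
  if (any(ev$values <= 0)) return(NULL)
  list(A = A, values = ev$values, vectors = ev$vectors)
}

#' Rotation-correlation curve of an annulus
#'
#' For each rotation angle, correlates the values of bins whose center
#' lies inside the annulus with the bilinear interpolation of the matrix
#' at the rotated bin centers (pairwise-complete).  The curve of a
#' hexagonally symmetric autocorrelogram peaks at multiples of 60
#' degrees.
#'
#' @param mat Square matrix (an autocorrelogram) with the rotation
#'   center at the middle element.
#' @param inner,outer Annulus radii, in bins.
#' @param angles_deg Rotation angles, degrees.
#' @return Tibble `angle, r`.
#' @export
rotation_correlation <- function(mat, inner, outer,
                                 angles_deg = seq(0, 357, by = 3)) {
  nr <- nrow(mat); nc <- ncol(mat)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  coords <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  dx <- coords$i - cr; dy <- coords$j - cc
  d <- sqrt(dx^2 + dy^2)
  sel <- d >= inner & d <= outer
  dx <- dx[sel]; dy <- dy[sel]
  v0 <- mat[cbind(coords$i[sel], coords$j[sel])]
  r <- vapply(angles_deg, function(a) {
    th <- a * pi / 180
    rx <- cos(th) * dx - sin(th) * dy
    ry <- sin(th) * dx + cos(th) * dy
    v1 <- bilinear(mat, rx + cr, ry + cc)
    ok <- !is.na(v0) & !is.na(v1)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(v0[ok], v1[ok])
  }, numeric(1))
  tibble::tibble(angle = angles_deg, r = r)
}

#' Grid score of a rate map
#'
#' Measures hexagonal symmetry in `[0, 1]`: (1) the six autocorrelogram
#' peaks closest to the center are detected; (2) an ellipse fitted
#' through them defines an affine eccentricity correction that maps the
#' ellipse to a circle; (3) an annulus enclosing the six peaks is
#' correlated with rotated versions of itself; (4) the score is the
#' power of the 6-cycles-per-rotation component of that curve divided by
#' the total power over components 1-10.
#'
#' @param map An `mec_ratemap`.
#' @param inner_factor Annulus inner radius as a multiple of the minimum
#'   peak distance.
#' @param outer_factor Annulus outer radius as a multiple of the maximum
#'   peak distance.
#' @param angle_step Rotation step, degrees.
#' @param peak_threshold Minimum autocorrelation of a detected peak.
#' @param n_components Power-spectrum components in the normalization.
#' @return List of class `mec_gridscore`: `score` (`NA` with a `reason`
#'   when fewer than six peaks exist), the rotation-correlation `curve`,
#'   peak coordinates, and the ellipse/annulus parameters used.
#' @export
grid_score <- function(map, inner_factor = 0.5, outer_factor = 1.25,
                       angle_step = 3, peak_threshold = 0.1,
                       n_components = 10) {
  ac <- autocorr2d(map)
  n <- nrow(ac)
  ctr <- (n + 1) / 2
  pk <- autocorr_fields(ac, peak_threshold)
  fail <- function(reason) {
    structure(list(score = NA_real_, reason = reason, curve = NULL,
                   peaks = NULL, ellipse = NULL, annulus = NULL),
              class = "mec_gridscore")
  }
  if (is.null(pk) || nrow(pk) < 6) {
    return(fail("fewer than six autocorrelogram peaks"))
  }
  d <- sqrt((pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2)
  ord <- order(d)[1:6]
  six <- pk[ord, , drop = FALSE]
  d6 <- d[ord]
  # six peaks of a (possibly elliptical) grid lie at comparable radii;
  # wildly inconsistent distances mean there is no grid to score
  if (max(d6) / min(d6) > 1.3) {
    return(fail("peak distances inconsistent with a hexagonal lattice"))
  }
  px <- six[, 1] - ctr; py <- six[, 2] - ctr
  # eccentricity correction: map the fitted ellipse to the circle with
  # the same geometric-mean radius
  ell <- fit_ellipse(px, py)
  mat <- ac
  if (!is.null(ell)) {
    rm_ <- (ell$values[1] * ell$values[2])^(-1 / 4)
    Tm <- rm_ * diag(sqrt(ell$values)) %*% t(ell$vectors)
    Tinv <- solve(Tm)
    coords <- expand.grid(i = seq_len(n), j = seq_len(n))
    src <- Tinv %*% rbind(coords$i - ctr, coords$j - ctr)
    mat <- matrix(bilinear(ac, src[1, ] + ctr, src[2, ] + ctr), n, n)
    tp <- Tm %*% rbind(px, py)
    px <- tp[1, ]; py <- tp[2, ]
  }
  # a hexagonal arrangement has adjacent peak angles ~60 degrees apart
  # (checked after eccentricity correction); arbitrary six-blob
  # constellations - e.g. from noisy maps - are rejected, not scored
  ang <- sort(atan2(py, px) %% (2 * pi)) * 180 / pi
  gaps <- diff(c(ang, ang[1] + 360))
  if (max(abs(gaps - 60)) > 15) {
    return(fail("peak angles inconsistent with a hexagonal lattice"))
  }
  pd <- sqrt(px^2 + py^2)
  inner <- inner_factor * min(pd)
  outer <- min(outer_factor * max(pd), ctr - 1)
  curve <- rotation_correlation(mat, inner, outer,
                                angles_deg = seq(0, 360 - angle_step,
                                                 by = angle_step))
  cc <- curve$r
  cc[is.na(cc)] <- mean(cc, na.rm = TRUE)
  sp <- Mod(stats::fft(cc))^2
  pow <- sp[2:(n_components + 1)]
  score <- pow[6] / sum(pow)
  structure(list(score = score, reason = NULL, curve = curve,
                 peaks = six, ellipse = ell,
                 annulus = c(inner = inner, outer = outer)),
            class = "mec_gridscore")
}

#' @export
print.mec_gridscore <- function(x, ...) {
  if (is.na(x$score)) {
    cat("<mec_gridscore> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<mec_gridscore> G = %.3f (annulus %.1f-%.1f bins)\n",
                x$score, x$annulus["inner"], x$annulus["outer"]))
  }
  invisible(x)
}

#' Spatial information as delta entropy
#'
#' `delta_H = H_max - H`, where `H_max = log2(n)` is the entropy of a
#' uniform spike-location distribution over the `n` visited bins and `H`
#' the observed entropy of per-bin spike-location probabilities
#' (`0 * log 0 := 0`).
#'
#' @param spike_times Spike times, s (with `tracking`), or `NULL` when
#'   `counts` is given.
#' @param tracking Tracking tibble (ignored when `counts` is given).
#' @param counts Optional per-bin spike-count matrix (visited bins =
#'   non-`NA` entries).
#' @param arena_side,bin_size Map geometry.
#' @return Tibble with `delta_h`, `h`, `h_max`, `n_bins`, `n_spikes`
#'   (bits).
#' @export
spatial_information <- function(spike_times = NULL, tracking = NULL,
                                counts = NULL, arena_side = 100,
                                bin_size = 3) {
  if (is.null(counts)) {
    m <- rate_map(spike_times, tracking, arena_side, bin_size, smooth_sd = 0)
    counts <- m$spike_counts
    counts[!m$visited] <- NA
  }
  cn <- counts[!is.na(counts)]
  n <- length(cn)
  total <- sum(cn)
  assert_that(total > 0, "spatial information needs at least one spike")
  assert_that(n >= 2, "need at least two visited bins")
  p <- cn / total
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  hmax <- log2(n)
  tibble::tibble(delta_h = hmax - h, h = h, h_max = hmax,
                 n_bins = n, n_spikes = total)
}

#' Pearson correlation between two rate maps
#'
#' Vectorizes both maps and correlates over bins visited in both.
#'
#' @param map_a,map_b `mec_ratemap`s (or matrices) on the same geometry.
#' @param min_common Minimum number of common visited bins.
#' @return Pearson r (NA with a warning if too few common bins).
#' @export
spatial_correlation <- function(map_a, map_b, min_common = 10) {
  a <- if (inherits(map_a, "mec_ratemap")) map_a$rates else map_a
  b <- if (inherits(map_b, "mec_ratemap")) map_b$rates else map_b
  assert_that(all(dim(a) == dim(b)), "maps must share geometry")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_common) {
    warning("fewer than ", min_common, " common visited bins")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}

#' Spatiotemporal correlation of observed and map-predicted rate
#'
#' The expected rate at each 20 ms sample is the reference map's value
#' at the animal's current bin; the statistic is the Pearson correlation
#' between the observed instantaneous rate and this expectation.
#'
#' @param rate_signal Tibble `t, rate` (50 Hz grid).
#' @param tracking Tracking tibble aligned with `rate_signal`.
#' @param ref_map Reference `mec_ratemap` (typically the light-condition
#'   map).
#' @return Pearson r (`NA` if the expected signal is constant).
#' @export
spatiotemporal_correlation <- function(rate_signal, tracking, ref_map) {
  nb <- nrow(ref_map$rates)
  bs <- ref_map$bin_size
  ok <- !is.na(tracking$x) & !is.na(tracking$y)
  bx <- pmin(pmax(floor(tracking$x / bs), 0), nb - 1) + 1
  by <- pmin(pmax(floor(tracking$y / bs), 0), nb - 1) + 1
  expected <- rep(NA_real_, nrow(tracking))
  expected[ok] <- ref_map$rates[cbind(bx[ok], by[ok])]
  obs <- rate_signal$rate[match(round(tracking$t, 6),
                                round(rate_signal$t, 6))]
  keep <- !is.na(expected) & !is.na(obs)
  if (sum(keep) < 3 || stats::sd(expected[keep]) == 0) {
    warning("expected rate signal is constant or empty")
    return(NA_real_)
  }
  stats::cor(obs[keep], expected[keep])
}

#' Spike-triggered firing rate map and grid spacing
#'
#' Accumulates occupancy and spikes over the 10 s following every spike
#' in coordinates relative to the bin occupied at the spike, normalizes,
#' and smooths.  The radial profile averages the map over circle
#' circumferences of increasing radius; the radius of its first local
#' maximum after the central field estimates the grid spacing,
#' insensitive to slow drift of the map.
#'
#' @param spike_times Spike times, s.
#' @param tracking Tracking tibble.
#' @param window Forward accumulation window, s.
#' @param bin_size Bin side, cm.
#' @param max_radius Largest profile radius, cm.
#' @param smooth_sd Gaussian smoothing SD, cm.
#' @return List of class `mec_stmap`: relative-coordinate `map`,
#'   `profile` (tibble `radius, rate`), `spacing` (cm, `NA` when no
#'   local maximum exists).
#' @export
spike_triggered_map <- function(spike_times, tracking, window = 10,
                                bin_size = 3, max_radius = 95,
                                smooth_sd = 3) {
  if (length(spike_times) < 100) {
    warning("fewer than 100 spikes; spike-triggered map will be noisy")
  }
  dt <- stats::median(diff(tracking$t))
  nb_rel <- ceiling(max_radius / bin_size)
  dim_rel <- 2 * nb_rel + 1
  ok <- !is.na(tracking$x) & !is.na(tracking$y)
  tt <- tracking$t[ok]; xx <- tracking$x[ok]; yy <- tracking$y[ok]
  bx <- floor(xx / bin_size); by <- floor(yy / bin_size)
  si <- findInterval(spike_times, tt)
  si <- si[si >= 1 & si <= length(tt)]
  w_samp <- round(window / dt)
  occ <- matrix(0, dim_rel, dim_rel)
  cnt <- matrix(0, dim_rel, dim_rel)
  n_tr <- length(tt)
  # occupancy: forward window of every trigger spike, relative bins
  starts <- si
  ends <- pmin(si + w_samp, n_tr)
  lens <- ends - starts + 1
  idx <- sequence(lens) - 1 + rep(starts, lens)
  trig <- rep(seq_along(starts), lens)
  rel_i <- bx[idx] - bx[starts][trig] + nb_rel + 1
  rel_j <- by[idx] - by[starts][trig] + nb_rel + 1
  keep <- rel_i >= 1 & rel_i <= dim_rel & rel_j >= 1 & rel_j <= dim_rel
  oc <- table(factor(rel_i[keep], levels = 1:dim_rel),
              factor(rel_j[keep], levels = 1:dim_rel))
  occ <- matrix(as.numeric(oc), dim_rel, dim_rel) * dt
  # spikes: subsequent spikes of the same train within the window,
  # accumulated as (trigger, follower) pairs in one pass
  st <- tt[si]
  sp_sorted <- sort(spike_times)
  lo <- findInterval(st, sp_sorted) + 1          # first spike strictly later
  hi <- findInterval(st + window, sp_sorted)     # last spike inside window
  has <- hi >= lo
  if (any(has)) {
    lens <- hi[has] - lo[has] + 1
    fol <- sequence(lens) - 1 + rep(lo[has], lens)
    trg <- rep(which(has), lens)
    li <- findInterval(sp_sorted[fol], tt)
    good <- li >= 1
    ri <- bx[li[good]] - bx[si[trg[good]]] + nb_rel + 1
    rj <- by[li[good]] - by[si[trg[good]]] + nb_rel + 1
    kp <- ri >= 1 & ri <= dim_rel & rj >= 1 & rj <= dim_rel
    if (any(kp)) {
      tb <- table(factor(ri[kp], levels = 1:dim_rel),
                  factor(rj[kp], levels = 1:dim_rel))
      cnt <- matrix(as.numeric(tb), dim_rel, dim_rel)
    }
  }
  visited <- occ > 0
  raw <- matrix(NA_real_, dim_rel, dim_rel)
  raw[visited] <- cnt[visited] / occ[visited]
  sm <- smooth_map(raw, smooth_sd / bin_size)
  ctr <- nb_rel + 1
  coords <- expand.grid(i = 1:dim_rel, j = 1:dim_rel)
  dcm <- sqrt((coords$i - ctr)^2 + (coords$j - ctr)^2) * bin_size
  radii <- seq(0, max_radius, by = 1)
  vals <- sm[cbind(coords$i, coords$j)]
  prof <- vapply(radii, function(r) {
    sel <- abs(dcm - r) <= bin_size / 2
    mean(vals[sel], na.rm = TRUE)
  }, numeric(1))
  spacing <- st_first_peak(radii, gauss_smooth(prof, 2))
  structure(list(map = sm, profile = tibble::tibble(radius = radii,
                                                    rate = prof),
                 spacing = spacing, bin_size = bin_size),
            class = "mec_stmap")
}

# First local maximum of the radial profile after the central field:
# find the first local minimum, then the first local maximum beyond it
# that rises above the minimum by a minimal prominence (a fraction of
# the profile range), so sampling wiggles are not read as the ring.
st_first_peak <- function(radii, prof, prominence = 0.05) {
  ok <- which(!is.na(prof))
  r <- radii[ok]; p <- prof[ok]
  n <- length(p)
  if (n < 5) return(NA_real_)
  prom <- prominence * (max(p) - min(p))
  dmin <- NA
  for (i in 2:(n - 1)) {
    if (p[i] <= p[i - 1] && p[i] < p[i + 1]) { dmin <- i; break }
  }
  if (is.na(dmin)) return(NA_real_)
  floor_ <- p[dmin]
  run_max <- -Inf; run_pos <- NA
  for (i in (dmin + 1):n) {
    floor_ <- min(floor_, p[i])
    if (p[i] > run_max) { run_max <- p[i]; run_pos <- i }
    # hill ends once the profile has risen by >= prom and dropped back
    if (run_max - p[dmin] >= prom && p[i] <= run_max - prom) {
      # parabolic refinement of the hill top to sub-grid resolution
      if (run_pos > 1 && run_pos < n) {
        y1 <- p[run_pos - 1]; y2 <- p[run_pos]; y3 <- p[run_pos + 1]
        den <- y1 - 2 * y2 + y3
        if (den < 0) {
          off <- 0.5 * (y1 - y3) / den
          return(r[run_pos] + off * (r[2] - r[1]))
        }
      }
      return(r[run_pos])
    }
  }
  NA_real_
}

# Connected components (8-neighborhood) of a logical matrix; returns an
# integer label matrix (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1, 2)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Border score of a rate map
#'
#' `(cM - dm) / (cM + dm)`, where `cM` is the maximal fraction of any
#' single wall covered by a single firing field and `dm` the
#' rate-weighted mean distance of field bins to their nearest wall,
#' normalized by half the arena side.  Ranges from -1 (central field) to
#' +1 (field hugging an entire wall).
#'
#' @param map An `mec_ratemap`.
#' @param field_threshold Field bins exceed this fraction of the peak
#'   rate.
#' @param min_field_area Minimum field area, cm^2.
#' @return List with `score`, `cm`, `dm`, `n_fields` (`score = NA` with
#'   a `reason` when no field qualifies).
#' @export
border_score <- function(map, field_threshold = 0.3, min_field_area = 200) {
  r <- map$rates
  nb <- nrow(r)
  peak <- max(r, na.rm = TRUE)
  mask <- !is.na(r) & r > field_threshold * peak
  lab <- label_components(mask)
  min_bins <- ceiling(min_field_area / map$bin_size^2)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_bins)
  if (!length(keep_ids)) {
    return(list(score = NA_real_, reason = "no firing field of sufficient area",
                cm = NA_real_, dm = NA_real_, n_fields = 0L))
  }
  # wall coverage: fraction of each wall's adjacent bin row covered by a
  # single field
  walls <- list(W = cbind(1, 1:nb), E = cbind(nb, 1:nb),
                S = cbind(1:nb, 1), N = cbind(1:nb, nb))
  cm <- 0
  for (w in walls) {
    wl <- lab[w]
    for (id in keep_ids) cm <- max(cm, sum(wl == id) / nb)
  }
  # rate-weighted mean distance of field bins to the nearest wall
  infield <- lab > 0 & matrix(lab %in% keep_ids, nb, nb)
  idx <- which(infield, arr.ind = TRUE)
  cx <- (idx[, 1] - 0.5) * map$bin_size
  cy <- (idx[, 2] - 0.5) * map$bin_size
  dwall <- pmin(cx, cy, map$arena_side - cx, map$arena_side - cy)
  wts <- r[idx]
  dm <- sum(wts * dwall) / sum(wts) / (map$arena_side / 2)
  list(score = (cm - dm) / (cm + dm), reason = NULL, cm = cm, dm = dm,
       n_fields = length(keep_ids))
}

#' Head-direction tuning curve and circular statistics
#'
#' Occupancy-normalized firing rate over 60 six-degree bins, with the
#' mean resultant length (MRL) and preferred direction of the
#' rate-weighted resultant, the circular SD derived from the MRL, and a
#' Rayleigh test of the spike head directions.
#'
#' @param spike_times Spike times, s.
#' @param tracking Tracking tibble with `hd` (radians).
#' @param bin_deg Bin width, degrees.
#' @param min_spikes Units with fewer spikes are flagged excluded.
#' @return List of class `mec_hdtuning`: `curve` (tibble
#'   `hd, rate, occupancy`), `mrl`, `preferred`, `circ_sd`, `peak_rate`,
#'   `rayleigh_p`, `n_spikes`, `excluded`.
#' @export
hd_tuning <- function(spike_times, tracking, bin_deg = 6, min_spikes = 10) {
  nbin <- round(360 / bin_deg)
  dt <- stats::median(diff(tracking$t))
  ok <- !is.na(tracking$hd)
  occ_bin <- floor(tracking$hd[ok] / (2 * pi) * nbin) %% nbin + 1
  occ <- as.numeric(table(factor(occ_bin, levels = 1:nbin))) * dt
  hd_sp <- spike_hd(spike_times, tracking)
  hd_sp <- hd_sp[!is.na(hd_sp)]
  sp_bin <- floor(hd_sp / (2 * pi) * nbin) %% nbin + 1
  cnt <- as.numeric(table(factor(sp_bin, levels = 1:nbin)))
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  centers <- (seq_len(nbin) - 0.5) * 2 * pi / nbin
  res <- circ_resultant(centers, w = ifelse(is.na(rate), 0, rate))
  ray <- rayleigh_test(hd_sp)
  excluded <- length(hd_sp) < min_spikes
  structure(list(curve = tibble::tibble(hd = centers, rate = rate,
                                        occupancy = occ),
                 mrl = res$mrl, preferred = res$mean,
                 circ_sd = sqrt(-2 * log(pmax(res$mrl, 1e-12))),
                 peak_rate = suppressWarnings(max(rate, na.rm = TRUE)),
                 rayleigh_p = ray$p_value, n_spikes = length(hd_sp),
                 excluded = excluded),
            class = "mec_hdtuning")
}

# head direction at spike times (nearest tracking sample)
spike_hd <- function(spike_times, tracking) {
  idx <- findInterval(spike_times, tracking$t)
  idx[idx < 1] <- 1
  tracking$hd[idx]
}
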