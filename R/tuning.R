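#' Putative principal neuron / interneuron classification
#'
#' Narrow waveforms or high rates mark putative interneurons: `IN` iff
#' spike width < 0.29 ms or mean rate > 10 Hz, else `PN`.
#'
#' @param spike_width_ms Waveform peak-to-trough width, ms.
#' @param mean_rate_hz Session mean firing rate, Hz.
#' @return Character vector of `"PN"` / `"IN"`.
#' @export
classify_pn_in <- function(spike_width_ms, mean_rate_hz) {
  ifelse(spike_width_ms < 0.29 | mean_rate_hz > 10, "IN", "PN")
}

#' Firing-stability screen
#'
#' Fails units whose session mean rate is below 1 Hz or whose mean rates
#' differ by more than a factor of two between the first and second
#' session halves.
#'
#' @param spike_times Spike times, s.
#' @param t_start,t_end Session span, s.
#' @param min_rate Minimum mean rate, Hz.
#' @param max_ratio Maximum between-half rate ratio.
#' @return List `pass`, `mean_rate`, `ratio`.
#' @export
stability_screen <- function(spike_times, t_start, t_end, min_rate = 1,
                             max_ratio = 2) {
  dur <- t_end - t_start
  assert_that(dur >= 120, "session too short for a stability screen")
  mid <- t_start + dur / 2
  r_all <- length(spike_times) / dur
  r1 <- sum(spike_times >= t_start & spike_times < mid) / (dur / 2)
  r2 <- sum(spike_times >= mid & spike_times < t_end) / (dur / 2)
  ratio <- if (min(r1, r2) == 0) Inf else max(r1, r2) / min(r1, r2)
  list(pass = r_all >= min_rate && ratio <= max_ratio,
       mean_rate = r_all, ratio = ratio)
}

#' Binned speed tuning curve
#'
#' Mean instantaneous firing rate per running-speed bin, with per-bin
#' occupancy; bins with under 1 s of occupancy are flagged.
#'
#' @param rate_signal Tibble `t, rate` (50 Hz).
#' @param speed_signal Tibble `t, speed` aligned with it.
#' @param breaks Speed-bin edges, cm/s (2 cm/s bins over 0-30).
#' @param min_occupancy Flagging threshold, s.
#' @return Tibble `speed, rate, occupancy, reliable`.
#' @export
speed_tuning_curve <- function(rate_signal, speed_signal,
                               breaks = seq(0, 30, by = 2),
                               min_occupancy = 1) {
  dt <- stats::median(diff(speed_signal$t))
  v <- pmin(speed_signal$speed, max(breaks) - 1e-9)
  ok <- !is.na(v) & !is.na(rate_signal$rate)
  b <- cut(v[ok], breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  occ <- as.numeric(table(factor(b, levels = seq_along(centers)))) * dt
  mean_r <- tapply(rate_signal$rate[ok], factor(b, levels = seq_along(centers)),
                   mean)
  tibble::tibble(speed = centers, rate = as.numeric(mean_r),
                 occupancy = occ, reliable = occ >= min_occupancy)
}

#' Speed score
#'
#' Pearson product-moment correlation between the instantaneous firing
#' rate and running speed on the 50 Hz grid.
#'
#' @param rate_signal Tibble `t, rate`.
#' @param speed_signal Tibble `t, speed`.
#' @return Pearson r.
#' @export
speed_score <- function(rate_signal, speed_signal) {
  ok <- !is.na(rate_signal$rate) & !is.na(speed_signal$speed)
  assert_that(sum(ok) > 2, "too few valid samples")
  r <- rate_signal$rate[ok]; v <- speed_signal$speed[ok]
  assert_that(stats::sd(r) > 0 && stats::sd(v) > 0,
              "zero-variance input: speed score undefined")
  stats::cor(r, v)
}

# --- LN Poisson model ---------------------------------------------------

# Penalty-pair list for one covariate's weight vector.
ln_adjacency <- function(type, nb) {
  if (type == "position") {
    side <- sqrt(nb)
    idx <- matrix(seq_len(nb), side, side)
    pairs <- rbind(cbind(as.vector(idx[-side, ]), as.vector(idx[-1, ])),
                   cbind(as.vector(idx[, -side]), as.vector(idx[, -1])))
  } else if (type %in% c("hd", "phase")) {
    pairs <- cbind(seq_len(nb), c(2:nb, 1))
  } else {
    pairs <- cbind(seq_len(nb - 1), 2:nb)
  }
  pairs
}

# Fit one penalized Poisson LN model; returns weights and train LL.
ln_fit_once <- function(counts, bins, nbins, pairs, dt, beta = 5,
                        init = NULL, maxit = 150) {
  covs <- names(bins)
  nbins <- unlist(nbins)
  offs <- c(0, cumsum(nbins))[seq_along(covs)]
  names(offs) <- covs
  npar <- sum(nbins)
  w0 <- init %||% rep(log(max(mean(counts) / dt, 1e-3)) / length(covs), npar)
  obj <- function(w) {
    eta <- rep(0, length(counts))
    for (c_ in covs) eta <- eta + w[offs[c_] + bins[[c_]]]
    mu <- exp(eta) * dt
    pen <- 0
    for (c_ in covs) {
      wc <- w[offs[c_] + seq_len(nbins[[c_]])]
      pr <- pairs[[c_]]
      pen <- pen + beta * sum((wc[pr[, 1]] - wc[pr[, 2]])^2)
    }
    sum(mu) - sum(counts * eta) + pen
  }
  grad <- function(w) {
    eta <- rep(0, length(counts))
    for (c_ in covs) eta <- eta + w[offs[c_] + bins[[c_]]]
    resid <- exp(eta) * dt - counts
    g <- numeric(length(w))
    for (c_ in covs) {
      nb <- nbins[[c_]]
      gk <- numeric(nb)
      rs <- rowsum(resid, bins[[c_]])
      gk[as.integer(rownames(rs))] <- rs[, 1]
      wc <- w[offs[c_] + seq_len(nb)]
      pr <- pairs[[c_]]
      dd <- 2 * beta * (wc[pr[, 1]] - wc[pr[, 2]])
      dpen <- numeric(nb)
      rs1 <- rowsum(dd, pr[, 1])
      dpen[as.integer(rownames(rs1))] <- rs1[, 1]
      rs2 <- rowsum(dd, pr[, 2])
      dpen[as.integer(rownames(rs2))] <-
        dpen[as.integer(rownames(rs2))] - rs2[, 1]
      g[offs[c_] + seq_len(nb)] <- gk + dpen
    }
    g
  }
  o <- stats::optim(w0, obj, grad, method = "L-BFGS-B",
                    control = list(maxit = maxit))
  eta <- rep(0, length(counts))
  for (c_ in covs) eta <- eta + o$par[offs[c_] + bins[[c_]]]
  mu <- exp(eta) * dt
  ll <- sum(counts * log(mu) - mu - lgamma(counts + 1))
  list(w = o$par, offs = offs, loglik = ll)
}

# Held-out Poisson LL of a fitted LN model on test frames.
ln_test_ll <- function(fit, counts, bins, dt) {
  eta <- rep(0, length(counts))
  for (c_ in names(bins)) eta <- eta + fit$w[fit$offs[c_] + bins[[c_]]]
  mu <- exp(eta) * dt
  sum(counts * log(mu) - mu - lgamma(counts + 1))
}

#' Fit the linear-nonlinear Poisson conjunctive tuning model
#'
#' Binned one-hot covariates (position 10x10, head direction 18,
#' theta phase 18, speed 15 over 0-30 cm/s), Poisson log link additive
#' in the covariate weight vectors, quadratic roughness penalty on
#' adjacent weights (circular for angular covariates), 10-fold blocked
#' cross-validation, and forward covariate selection: starting from the
#' best single covariate, covariates are added while the held-out
#' log-likelihood increase across folds is significant by a one-sided
#' signed-rank test.  A unit whose best model does not beat the
#' mean-rate model is labeled unmodulated — a valid outcome, not an
#' error.
#'
#' @param spike_times Spike times, s.
#' @param tracking Tracking tibble.
#' @param signals Output of [derive_signals()] (speed and theta phase).
#' @param arena_side Arena side, cm.
#' @param covariates Candidate covariates.
#' @param n_pos_bins,n_hd_bins,n_phase_bins,n_speed_bins Bin counts.
#' @param speed_max Speed clip, cm/s.
#' @param beta Roughness penalty weight.
#' @param n_folds Cross-validation folds (blocked, interleaved chunks).
#' @param alpha Selection significance level.
#' @return Object of class `mec_lnfit`: `selected` covariates (may be
#'   empty = unmodulated), per-covariate `weights`, `fold_ll` matrix of
#'   held-out log-likelihood increases over the mean-rate model,
#'   `mean_rate`, `speed_bins`, selection `path`.
#' @export
fit_ln_model <- function(spike_times, tracking, signals, arena_side = 100,
                         covariates = c("position", "hd", "phase", "speed"),
                         n_pos_bins = 100, n_hd_bins = 18, n_phase_bins = 18,
                         n_speed_bins = 15, speed_max = 30, beta = 5,
                         n_folds = 10, alpha = 0.05) {
  dt <- stats::median(diff(tracking$t))
  n <- nrow(tracking)
  edges <- c(tracking$t, tracking$t[n] + dt)
  counts <- graphics::hist(spike_times[spike_times >= edges[1] &
                                         spike_times < edges[n + 1]],
                           breaks = edges, plot = FALSE)$counts
  side <- sqrt(n_pos_bins)
  bins_all <- list()
  if ("position" %in% covariates) {
    bx <- pmin(pmax(floor(tracking$x / arena_side * side), 0), side - 1)
    by <- pmin(pmax(floor(tracking$y / arena_side * side), 0), side - 1)
    bins_all$position <- as.integer(bx * side + by + 1)
  }
  if ("hd" %in% covariates) {
    bins_all$hd <- as.integer(floor(tracking$hd / (2 * pi) * n_hd_bins) %%
                                n_hd_bins + 1)
  }
  if ("phase" %in% covariates && !all(is.na(signals$theta_phase))) {
    bins_all$phase <- as.integer(
      floor(wrap_2pi(signals$theta_phase) / (2 * pi) * n_phase_bins) %%
        n_phase_bins + 1)
  }
  if ("speed" %in% covariates) {
    v <- pmin(pmax(signals$speed, 0), speed_max - 1e-9)
    bins_all$speed <- as.integer(floor(v / speed_max * n_speed_bins) + 1)
  }
  nbins_all <- list(position = n_pos_bins, hd = n_hd_bins,
                    phase = n_phase_bins, speed = n_speed_bins)
  valid <- rep(TRUE, n)
  for (b in bins_all) valid <- valid & !is.na(b)
  counts <- counts[valid]
  bins_all <- lapply(bins_all, function(b) b[valid])
  nv <- length(counts)
  pairs_all <- lapply(names(bins_all), function(c_)
    ln_adjacency(c_, nbins_all[[c_]]))
  names(pairs_all) <- names(bins_all)
  # blocked folds: 5 chunks per fold, interleaved
  n_chunks <- n_folds * 5
  chunk <- pmin(floor((seq_len(nv) - 1) / ceiling(nv / n_chunks)),
                n_chunks - 1)
  fold <- chunk %% n_folds + 1
  mean_rate <- sum(counts) / (nv * dt)

  cv_ll <- function(sel) {
    b <- bins_all[sel]; nb <- nbins_all[sel]; pr <- pairs_all[sel]
    warm <- ln_fit_once(counts, b, nb, pr, dt, beta)
    inc <- numeric(n_folds)
    for (k in seq_len(n_folds)) {
      tr <- fold != k; te <- fold == k
      fit <- ln_fit_once(counts[tr], lapply(b, `[`, tr), nb, pr, dt, beta,
                         init = warm$w, maxit = 60)
      ll_m <- ln_test_ll(fit, counts[te], lapply(b, `[`, te), dt)
      mu0 <- max(sum(counts[tr]) / (sum(tr) * dt), 1e-6) * dt
      ll_0 <- sum(counts[te] * log(mu0) - mu0 - lgamma(counts[te] + 1))
      inc[k] <- ll_m - ll_0
    }
    list(inc = inc, warm = warm)
  }

  cands <- names(bins_all)
  results <- list()
  for (c_ in cands) results[[c_]] <- cv_ll(c_)
  means <- vapply(results, function(r) mean(r$inc), numeric(1))
  best <- cands[which.max(means)]
  path <- list()
  sel <- character(0)
  cur_inc <- rep(0, n_folds)
  # accept the best single covariate only if it beats the mean-rate model
  p0 <- stats::wilcox.test(results[[best]]$inc, alternative = "greater",
                           exact = FALSE)$p.value
  path[[1]] <- tibble::tibble(step = 1, candidate = best,
                              mean_increase = means[best], p = p0,
                              accepted = p0 < alpha)
  if (p0 < alpha) {
    sel <- best
    cur_inc <- results[[best]]$inc
    remaining <- setdiff(cands, sel)
    step <- 2
    while (length(remaining)) {
      trial <- lapply(remaining, function(c_) cv_ll(c(sel, c_)))
      names(trial) <- remaining
      tm <- vapply(trial, function(r) mean(r$inc), numeric(1))
      cb <- remaining[which.max(tm)]
      pv <- stats::wilcox.test(trial[[cb]]$inc, cur_inc, paired = TRUE,
                               alternative = "greater",
                               exact = FALSE)$p.value
      path[[step]] <- tibble::tibble(step = step, candidate = cb,
                                     mean_increase = tm[cb], p = pv,
                                     accepted = pv < alpha)
      if (pv < alpha) {
        sel <- c(sel, cb)
        cur_inc <- trial[[cb]]$inc
        remaining <- setdiff(remaining, cb)
        step <- step + 1
      } else break
    }
  }
  weights <- NULL; final <- NULL
  if (length(sel)) {
    final <- ln_fit_once(counts, bins_all[sel], nbins_all[sel],
                         pairs_all[sel], dt, beta)
    weights <- lapply(sel, function(c_)
      final$w[final$offs[c_] + seq_len(nbins_all[[c_]])])
    names(weights) <- sel
  }
  structure(list(selected = sel, weights = weights,
                 fold_ll = cur_inc, mean_rate = mean_rate,
                 dt = dt,
                 speed_bins = seq(speed_max / n_speed_bins / 2,
                                  speed_max, by = speed_max / n_speed_bins),
                 speed_occupancy_bins =
                   if ("speed" %in% names(bins_all))
                     tabulate(bins_all$speed, n_speed_bins) * dt else NULL,
                 path = dplyr::bind_rows(path)),
            class = "mec_lnfit")
}

#' @export
print.mec_lnfit <- function(x, ...) {
  cat(sprintf("<mec_lnfit> selected: %s (mean CV LL gain %.1f)\n",
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "none (unmodulated)",
              mean(x$fold_ll)))
  invisible(x)
}

#' Model-derived speed response curve
#'
#' The speed contribution of an LN fit: the exponentiated speed weight
#' vector scaled to the model's mean rate, so conjunctive covariate
#' effects are factored out of the speed tuning.  `within`
#' normalization divides the curve by its own maximum; `across` divides
#' by the maximum of a reference (light-condition) curve so that
#' condition-wide gain changes remain visible.
#'
#' @param fit An `mec_lnfit`.
#' @param normalization `"within"`, `"across"`, or `"none"` (Hz).
#' @param reference Reference curve (tibble from this function with
#'   `normalization = "none"`) required for `"across"`.
#' @param min_occupancy Speed bins with less occupancy (s) are dropped;
#'   their weights are dominated by noise.
#' @return Tibble `speed, response`.
#' @export
speed_response_curve <- function(fit, normalization = c("within", "across",
                                                        "none"),
                                 reference = NULL, min_occupancy = 10) {
  normalization <- match.arg(normalization)
  v <- fit$speed_bins
  occ <- fit$speed_occupancy_bins %||% rep(Inf, length(v))
  if (!("speed" %in% fit$selected)) {
    resp <- rep(fit$mean_rate, length(v))
  } else {
    g <- exp(fit$weights$speed)
    wmean <- sum(g * occ) / sum(occ)
    resp <- g / wmean * fit$mean_rate
  }
  keep <- occ >= min_occupancy
  out <- tibble::tibble(speed = v[keep], response = resp[keep])
  if (normalization == "within") {
    out$response <- out$response / max(out$response)
  } else if (normalization == "across") {
    assert_that(!is.null(reference), "across-normalization needs a reference")
    refmax <- max(reference$response)
    assert_that(refmax > 0, "reference maximum is zero")
    out$response <- out$response / refmax
  }
  out
}

#' Cluster speed-modulated units into positive and negative groups
#'
#' Fits a quadratic polynomial to each within-normalized speed response
#' curve and clusters the fitted curves (Ward linkage, Euclidean
#' distance) into two groups; each group's sign is the sign of its
#' centroid's mean finite-difference slope.
#'
#' @param curves Named list (or tibble list-column) of response-curve
#'   tibbles (`speed, response`), one per unit.
#' @return Tibble `unit_id, cluster, sign`.
#' @export
cluster_speed_cells <- function(curves) {
  assert_that(length(curves) >= 2, "need at least two speed-modulated units")
  ids <- names(curves) %||% as.character(seq_along(curves))
  fitted <- t(vapply(curves, function(cu) {
    fit <- stats::lm(response ~ stats::poly(speed, 2), data = cu)
    stats::predict(fit)
  }, numeric(nrow(curves[[1]]))))
  if (max(stats::dist(fitted)) < 1e-10) {
    warning("all curves identical; single-cluster fallback")
    sgn <- if (mean(diff(fitted[1, ])) >= 0) "positive" else "negative"
    return(tibble::tibble(unit_id = ids, cluster = 1L, sign = sgn))
  }
  hc <- stats::hclust(stats::dist(fitted), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  sgn <- vapply(1:2, function(k) {
    centroid <- colMeans(fitted[cl == k, , drop = FALSE])
    if (mean(diff(centroid)) >= 0) "positive" else "negative"
  }, character(1))
  tibble::tibble(unit_id = ids, cluster = as.integer(cl), sign = sgn[cl])
}

#' Apply functional cell-type classification criteria
#'
#' Either-condition logic with configurable thresholds (defaults are the
#' standard criteria): grid cells need a grid score at or above
#' `grid_score_min` plus `grid_min_spikes` spikes in either condition;
#' border cells a border score above `border_score_min` in either
#' condition; head direction cells at least `hd_min_spikes` spikes in
#' each condition and, in either condition, inverse circular SD above 1,
#' Rayleigh p below 0.001, and peak rate above 1 Hz.  Missing metrics
#' leave the label `NA` (undetermined), never `FALSE`.
#'
#' @param metrics Tibble with one row per `unit_id` and `condition`
#'   (`"light"`/`"dark"`), and columns among `grid_score`, `n_spikes`,
#'   `border_score`, `hd_inv_circ_sd`, `hd_rayleigh_p`, `hd_peak_rate`,
#'   `speed_selected`, `speed_sign`, `spike_width_ms`, `mean_rate`.
#' @param grid_score_min,grid_min_spikes,border_score_min,hd_min_spikes
#'   Classification thresholds.
#' @return Tibble `unit_id, is_grid, is_border, is_hd, is_speed_mod,
#'   speed_sign, putative_class`.
#' @export
classify_cells <- function(metrics, grid_score_min = 0.19,
                           grid_min_spikes = 300, border_score_min = 0.68,
                           hd_min_spikes = 10) {
  col_or_na <- function(df, nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_real_, nrow(df))
  either <- function(x) if (all(is.na(x))) NA else any(x, na.rm = TRUE)
  per_unit <- function(df) {
    g <- either(col_or_na(df, "grid_score") >= grid_score_min &
                  col_or_na(df, "n_spikes") >= grid_min_spikes)
    b <- either(col_or_na(df, "border_score") > border_score_min)
    hd_counts_ok <- all(col_or_na(df, "n_spikes") >= hd_min_spikes) &&
      all(c("light", "dark") %in% df$condition)
    h <- if (!isTRUE(hd_counts_ok)) FALSE else {
      isTRUE(either(col_or_na(df, "hd_inv_circ_sd") > 1)) &&
        isTRUE(either(col_or_na(df, "hd_rayleigh_p") < 0.001)) &&
        isTRUE(either(col_or_na(df, "hd_peak_rate") > 1))
    }
    if (all(is.na(col_or_na(df, "hd_inv_circ_sd")))) h <- NA
    sp <- if ("speed_selected" %in% names(df)) {
      either(as.logical(df$speed_selected))
    } else NA
    sgn <- if ("speed_sign" %in% names(df)) {
      s <- stats::na.omit(df$speed_sign)
      if (length(s)) s[1] else NA_character_
    } else NA_character_
    pc <- if (all(c("spike_width_ms", "mean_rate") %in% names(df))) {
      classify_pn_in(df$spike_width_ms[1], max(df$mean_rate, na.rm = TRUE))
    } else NA_character_
    tibble::tibble(is_grid = g, is_border = b, is_hd = h,
                   is_speed_mod = sp, speed_sign = sgn, putative_class = pc)
  }
  metrics |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(~ per_unit(.x)) |>
    dplyr::ungroup()
}
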