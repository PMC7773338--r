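#' Epoch-wise firing-rate modulation by illumination
#'
#' Computes each epoch's mean firing rate and applies Student's paired
#' t-test to the disjoint (light epoch, following dark epoch) pairs, so
#' each epoch enters the statistic once and the nominal level is
#' honest.  Units without spiking activity across at least three
#' light-to-dark and three dark-to-light epoch pairs are excluded
#' (flagged, not dropped silently).
#'
#' @param spike_times Spike times, s.
#' @param epochs Epoch table.
#' @param alpha Significance level.
#' @param min_pairs Minimum pairs of each transition type.
#' @return One-row tibble: `included`, `n_pairs_ld`, `n_pairs_dl`,
#'   `t_stat`, `df`, `p_value`, `modulated`, `direction`
#'   (`darkness-negative` = lower rate in dark), `dark_to_light_ratio`.
#' @export
epoch_modulation <- function(spike_times, epochs, alpha = 0.05,
                             min_pairs = 3) {
  ne <- nrow(epochs)
  rates <- vapply(seq_len(ne), function(i) {
    sum(spike_times >= epochs$start[i] & spike_times < epochs$end[i]) /
      (epochs$end[i] - epochs$start[i])
  }, numeric(1))
  first <- epochs$condition[-ne]
  active <- vapply(seq_len(ne - 1), function(i) {
    rates[i] > 0 || rates[i + 1] > 0
  }, logical(1))
  is_ld <- first == "light" & active
  is_dl <- first == "dark" & active
  n_ld <- sum(is_ld); n_dl <- sum(is_dl)
  included <- n_ld >= min_pairs && n_dl >= min_pairs
  out <- tibble::tibble(included = included, n_pairs_ld = n_ld,
                        n_pairs_dl = n_dl, t_stat = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        modulated = NA, direction = NA_character_,
                        dark_to_light_ratio = NA_real_)
  if (!included) return(out)
  pair_idx <- which(is_ld)   # disjoint: each epoch in at most one pair
  light_r <- rates[pair_idx]
  dark_r <- rates[pair_idx + 1]
  diffs <- light_r - dark_r
  if (stats::sd(diffs) < 1e-9) {
    # degenerate paired t: identical rates are not modulated; an exactly
    # constant nonzero difference is modulation with certainty
    out$modulated <- mean(diffs) != 0
    out$p_value <- if (mean(diffs) != 0) 0 else 1
    out$t_stat <- if (mean(diffs) != 0) Inf * sign(mean(diffs)) else 0
  } else {
    tt <- stats::t.test(light_r, dark_r, paired = TRUE)
    out$t_stat <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
    out$modulated <- tt$p.value < alpha
  }
  out$direction <- if (mean(dark_r) < mean(light_r)) "darkness-negative"
  else "darkness-positive"
  ml <- mean(rates[epochs$condition == "light"])
  md <- mean(rates[epochs$condition == "dark"])
  out$dark_to_light_ratio <- if (ml > 0) md / ml else NA_real_
  out
}

#' Speed-occupancy-adjusted dark-to-light rate ratio
#'
#' Expected rate per condition is the speed tuning curve integrated
#' against a common reference speed-occupancy distribution (the
#' light-condition occupancy for both conditions), which isolates
#' tuning-curve change from the slight behavioral slowing in darkness.
#' The raw ratio uses each condition's own occupancy.
#'
#' @param curve_light,curve_dark [speed_tuning_curve()] outputs on
#'   common bins.
#' @return Tibble `adjusted_ratio, raw_ratio`.
#' @export
speed_adjusted_ratio <- function(curve_light, curve_dark) {
  ok <- !is.na(curve_light$rate) & !is.na(curve_dark$rate)
  assert_that(any(ok), "no common occupied speed bins")
  p_ref <- curve_light$occupancy[ok] / sum(curve_light$occupancy[ok])
  p_d <- curve_dark$occupancy[ok] / sum(curve_dark$occupancy[ok])
  e_light <- sum(p_ref * curve_light$rate[ok])
  e_dark <- sum(p_ref * curve_dark$rate[ok])
  raw_l <- sum(p_ref * curve_light$rate[ok])
  raw_d <- sum(p_d * curve_dark$rate[ok])
  assert_that(e_light > 0, "light-condition expected rate is zero")
  tibble::tibble(adjusted_ratio = e_dark / e_light,
                 raw_ratio = raw_d / raw_l)
}

#' Population PSTH around light/dark transitions
#'
#' Each unit's instantaneous rate is z-scored over the whole session,
#' binned at 5 s around every transition of the requested type, averaged
#' over transitions, and then averaged across units.
#'
#' @param rates Tibble `unit_id, t, rate` of 50 Hz instantaneous rates.
#' @param epochs Epoch table.
#' @param transition `"light_to_dark"` or `"dark_to_light"`.
#' @param bin Bin width, s.
#' @param n_side Bins on each side of the transition.
#' @return Tibble `offset` (bin start relative to transition, s),
#'   `mean_z`, `sd_z`, `n_units`.
#' @export
transition_psth <- function(rates, epochs, transition = "light_to_dark",
                            bin = 5, n_side = 6) {
  ne <- nrow(epochs)
  from <- if (transition == "light_to_dark") "light" else "dark"
  tpts <- epochs$end[-ne][epochs$condition[-ne] == from]
  tpts <- tpts[abs(tpts - epochs$start[-1][epochs$condition[-ne] == from]) <
                 1e-6]
  assert_that(length(tpts) > 0, "no transitions of the requested type")
  offsets <- (seq_len(2 * n_side) - n_side - 1) * bin
  per_unit <- rates |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(function(df, key) {
      s <- stats::sd(df$rate, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        warning("zero-variance unit excluded from PSTH: ", key$unit_id)
        return(tibble::tibble(offset = numeric(), z = numeric()))
      }
      z <- (df$rate - mean(df$rate, na.rm = TRUE)) / s
      rows <- lapply(offsets, function(o) {
        vals <- unlist(lapply(tpts, function(tp) {
          z[df$t >= tp + o & df$t < tp + o + bin]
        }))
        tibble::tibble(offset = o, z = mean(vals, na.rm = TRUE))
      })
      dplyr::bind_rows(rows)
    }) |>
    dplyr::ungroup()
  per_unit |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(mean_z = mean(.data$z, na.rm = TRUE),
                     sd_z = stats::sd(.data$z, na.rm = TRUE),
                     n_units = sum(!is.na(.data$z)), .groups = "drop")
}

#' Linear regression of a theta measure on running speed
#'
#' Ordinary least squares of 50 Hz theta frequency (or amplitude, or any
#' other sample-aligned value) on running speed, restricted to a speed
#' range that removes immobility artifacts.
#'
#' @param signals Tibble with `speed` and the value column.
#' @param value Name of the value column (default `theta_freq`; pass
#'   e.g. `theta_amp`, or swap `speed` for acceleration via `predictor`).
#' @param predictor Name of the predictor column.
#' @param speed_range Regression sample restriction, cm/s (applied to
#'   the `speed` column).
#' @param min_n Minimum valid samples.
#' @return One-row tibble `slope, y_intercept, r, p_value, n`.
#' @export
theta_speed_regression <- function(signals, value = "theta_freq",
                                   predictor = "speed",
                                   speed_range = c(2, 30), min_n = 100) {
  y <- signals[[value]]
  x <- signals[[predictor]]
  sel <- !is.na(y) & !is.na(x) & !is.na(signals$speed) &
    signals$speed >= speed_range[1] & signals$speed <= speed_range[2]
  n <- sum(sel)
  assert_that(n >= min_n,
              sprintf("only %d valid samples (need %d)", n, min_n))
  fit <- stats::lm(y[sel] ~ x[sel])
  ct <- stats::cor.test(x[sel], y[sel])
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 y_intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Metric time course over 10 s bins within or around epochs
#'
#' Pools 50 Hz samples across all epochs of a condition by offset bin
#' (`from_epoch_start`: offsets 0 ... `n_bins * bin`;
#' `around_transition`: bins straddling each transition into the
#' condition) and applies a metric extractor to each pooled bin.
#'
#' @param data Tibble of per-sample rows containing `t` plus whatever
#'   the extractor consumes.
#' @param epochs Epoch table.
#' @param condition Condition whose epochs (or incoming transitions) are
#'   analyzed.
#' @param extractor Function of a pooled-row tibble returning a named
#'   numeric vector (or a one-row data frame); `NULL` entries are
#'   allowed for undefined bins.
#' @param bin Bin width, s.
#' @param n_bins Bins after the epoch start (or per side around a
#'   transition).
#' @param mode `"from_epoch_start"` or `"around_transition"`.
#' @return Tibble `offset, condition, n`, plus the extractor's fields.
#' @export
timecourse <- function(data, epochs, condition, extractor, bin = 10,
                       n_bins = 18,
                       mode = c("from_epoch_start", "around_transition")) {
  mode <- match.arg(mode)
  ep <- epochs[epochs$condition == condition, ]
  assert_that(nrow(ep) > 0, "condition absent from epochs")
  offsets <- if (mode == "from_epoch_start") {
    (seq_len(n_bins) - 1) * bin
  } else {
    (seq_len(2 * n_bins) - n_bins - 1) * bin
  }
  anchors <- if (mode == "from_epoch_start") ep$start else ep$start
  rows <- lapply(offsets, function(o) {
    sel <- rep(FALSE, nrow(data))
    for (a in anchors) {
      lo <- a + o; hi <- a + o + bin
      if (mode == "from_epoch_start") hi <- min(hi, ep$end[ep$start == a])
      sel <- sel | (data$t >= lo & data$t < hi)
    }
    base <- tibble::tibble(offset = o, condition = condition, n = sum(sel))
    met <- if (any(sel)) extractor(data[sel, ]) else NULL
    if (is.null(met)) return(base)
    dplyr::bind_cols(base, tibble::as_tibble(as.list(met)))
  })
  dplyr::bind_rows(rows)
}

#' Extractors for [timecourse()]
#'
#' `extract_theta_slope()` regresses theta frequency on speed in the
#' pooled bin; `make_extract_spatial_corr(ref_map)` builds 3 cm rate
#' maps from pooled frames (summing spikes and occupancy across epochs
#' before scoring) and correlates them with a reference map;
#' `make_extract_grid_score()` scores the pooled-bin map.  Frame tables
#' need columns `x, y, spike_count` for the spatial extractors and
#' `speed, theta_freq` for the regression extractor.
#'
#' @param rows Pooled-bin rows (passed by [timecourse()]).
#' @return Named numeric vector of metrics, or `NULL` when undefined.
#' @export
extract_theta_slope <- function(rows) {
  res <- tryCatch(theta_speed_regression(rows, min_n = 50),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  c(slope = res$slope, y_intercept = res$y_intercept)
}

# rate map from pooled 50 Hz frames carrying per-frame spike counts
map_from_frames <- function(rows, arena_side = 100, bin_size = 3,
                            smooth_sd = 3, min_occupancy = 0.1,
                            dt = 0.02) {
  nb <- max(2L, round(arena_side / bin_size))
  bin_size <- arena_side / nb
  ok <- !is.na(rows$x) & !is.na(rows$y)
  bx <- pmin(pmax(floor(rows$x[ok] / bin_size), 0), nb - 1) + 1
  by <- pmin(pmax(floor(rows$y[ok] / bin_size), 0), nb - 1) + 1
  occ <- matrix(as.numeric(table(factor(bx, levels = 1:nb),
                                 factor(by, levels = 1:nb))), nb, nb) * dt
  cnt <- matrix(0, nb, nb)
  sc <- rows$spike_count[ok]
  has <- sc > 0
  if (any(has)) {
    tb <- stats::xtabs(sc[has] ~ factor(bx[has], levels = 1:nb) +
                         factor(by[has], levels = 1:nb))
    cnt <- matrix(as.numeric(tb), nb, nb)
  }
  visited <- occ >= min_occupancy
  raw <- matrix(NA_real_, nb, nb)
  raw[visited] <- cnt[visited] / occ[visited]
  rates <- smooth_map(raw, smooth_sd / bin_size)
  structure(list(rates = rates, rates_raw = raw, spike_counts = cnt,
                 occupancy = occ, visited = visited, bin_size = bin_size,
                 smoothing_sd = smooth_sd, arena_side = arena_side),
            class = "mec_ratemap")
}

#' @rdname extract_theta_slope
#' @param ref_map Reference `mec_ratemap` (e.g. the whole-light map).
#' @param arena_side,bin_size Map geometry for the pooled-bin maps.
#' @export
make_extract_spatial_corr <- function(ref_map, arena_side = 100,
                                      bin_size = 3) {
  function(rows) {
    m <- map_from_frames(rows, arena_side, bin_size)
    r <- suppressWarnings(spatial_correlation(m, ref_map))
    if (is.na(r)) NULL else c(spatial_corr = r)
  }
}

#' @rdname extract_theta_slope
#' @export
make_extract_grid_score <- function(arena_side = 100, bin_size = 3) {
  function(rows) {
    m <- map_from_frames(rows, arena_side, bin_size)
    g <- grid_score(m)
    if (is.na(g$score)) NULL else c(grid_score = g$score)
  }
}

#' Correlation between two metric time courses
#'
#' Pearson correlation across matched (offset, condition) bins, pooled
#' over conditions and within each condition.
#'
#' @param table_a,table_b [timecourse()] outputs.
#' @param metric_a,metric_b Metric column names.
#' @return Tibble `scope, r, p_value, n` with rows `pooled` and one per
#'   condition.
#' @export
timecourse_correlation <- function(table_a, table_b,
                                   metric_a = setdiff(names(table_a),
                                                      c("offset", "condition",
                                                        "n"))[1],
                                   metric_b = setdiff(names(table_b),
                                                      c("offset", "condition",
                                                        "n"))[1]) {
  j <- dplyr::inner_join(
    dplyr::select(table_a, "offset", "condition", a = dplyr::all_of(metric_a)),
    dplyr::select(table_b, "offset", "condition", b = dplyr::all_of(metric_b)),
    by = c("offset", "condition"))
  j <- j[!is.na(j$a) & !is.na(j$b), ]
  assert_that(nrow(j) >= 3, "fewer than 3 matched bins")
  one <- function(df, scope) {
    if (nrow(df) < 3) {
      return(tibble::tibble(scope = scope, r = NA_real_,
                            p_value = NA_real_, n = nrow(df)))
    }
    ct <- stats::cor.test(df$a, df$b)
    tibble::tibble(scope = scope, r = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(df))
  }
  out <- list(one(j, "pooled"))
  for (cond in unique(j$condition)) {
    out[[length(out) + 1]] <- one(j[j$condition == cond, ], cond)
  }
  dplyr::bind_rows(out)
}

#' Fit a saturating-exponential summary to a time course
#'
#' Least-squares fit of `a + b * (1 - exp(-t / tau))` to a metric's
#' offset profile; descriptive only.
#'
#' @param tc A [timecourse()] table.
#' @param metric Metric column name.
#' @return Tibble `a, b, tau`.
#' @export
fit_exponential_timecourse <- function(tc, metric) {
  t <- tc$offset; y <- tc[[metric]]
  ok <- !is.na(y)
  t <- t[ok]; y <- y[ok]
  assert_that(length(y) >= 4, "too few bins for an exponential fit")
  fit <- stats::nls(y ~ a + b * (1 - exp(-t / tau)),
                    start = list(a = y[1], b = y[length(y)] - y[1],
                                 tau = max(t) / 3),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  co <- stats::coef(fit)
  tibble::tibble(a = co[["a"]], b = co[["b"]], tau = co[["tau"]])
}
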