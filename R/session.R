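#' Construct an open-field recording session
#'
#' A session bundles everything one recording contributes to the pipeline:
#' positional tracking on a uniform 50 Hz grid, per-unit spike times with
#' waveform widths, an optional LFP trace, and the table of alternating
#' light/dark epochs.  All angles are radians internally; degrees appear
#' only in files.
#'
#' @param tracking Data frame with columns `t` (s, uniform 50 Hz grid),
#'   `x`, `y` (cm, arena frame with the origin at one corner) and `hd`
#'   (head direction, radians in `[0, 2*pi)`; `NA` marks lost tracking).
#' @param spikes Data frame with columns `unit_id` (character) and `t`
#'   (spike times, s, sorted within unit).
#' @param units Data frame with columns `unit_id`, `spike_width_ms`
#'   (waveform peak-to-trough, ms) and optionally `label`.
#' @param epochs Data frame with columns `start`, `end` (s) and
#'   `condition` (`"light"` or `"dark"`); intervals are half-open
#'   `[start, end)`, non-overlapping, sorted, and conditions alternate.
#' @param lfp `NULL`, or a list with `samples` (numeric), `fs` (Hz; 600
#'   after [resample_lfp()]) and `t0` (s).
#' @param arena_side Arena side length, cm (default 100, a 1 m square box).
#' @param metadata Free-form list kept with the session (provenance,
#'   simulation ground truth, seeds).
#' @param validate Run [validate_session()] on the result (default `TRUE`).
#'
#' @return An object of class `mec_session`.
#' @export
mec_session <- function(tracking, spikes, units = NULL, epochs, lfp = NULL,
                        arena_side = 100, metadata = list(), validate = TRUE) {
  tracking <- tibble::as_tibble(tracking)
  spikes <- tibble::as_tibble(spikes)
  spikes$unit_id <- as.character(spikes$unit_id)
  if (is.null(units)) {
    units <- tibble::tibble(unit_id = unique(spikes$unit_id),
                            spike_width_ms = NA_real_, label = NA_character_)
  }
  units <- tibble::as_tibble(units)
  units$unit_id <- as.character(units$unit_id)
  if (is.null(units$label)) units$label <- NA_character_
  epochs <- tibble::as_tibble(epochs)
  s <- structure(
    list(arena_side = arena_side, tracking = tracking, spikes = spikes,
         units = units, lfp = lfp, epochs = epochs, metadata = metadata),
    class = "mec_session")
  if (validate) validate_session(s)
  s
}

#' @export
print.mec_session <- function(x, ...) {
  dur <- diff(range(x$tracking$t))
  cat(sprintf("<mec_session> %.0f cm arena, %.1f min, %d units, %d epochs (%s)\n",
              x$arena_side, dur / 60, nrow(x$units), nrow(x$epochs),
              if (is.null(x$lfp)) "no LFP" else sprintf("LFP @ %g Hz", x$lfp$fs)))
  invisible(x)
}

#' Validate session invariants
#'
#' Checks the uniform tracking grid, coordinate bounds, spike ordering,
#' epoch structure (half-open, sorted, non-overlapping, alternating
#' conditions), and time-range consistency.  Violations raise an error
#' naming the offending rows.
#'
#' @param session An `mec_session`.
#' @param dt Expected tracking step, s.
#' @param tol Numeric tolerance on the tracking step.
#' @return The session, invisibly.
#' @export
validate_session <- function(session, dt = 0.02, tol = 1e-6) {
  tr <- session$tracking
  assert_that(all(c("t", "x", "y", "hd") %in% names(tr)),
              "tracking must have columns t, x, y, hd")
  if (nrow(tr) > 1) {
    steps <- diff(tr$t)
    bad <- which(abs(steps - dt) > tol)
    assert_that(length(bad) == 0, sprintf(
      "tracking time grid is not uniform at %g s: first bad step at row %d",
      dt, bad[1]))
  }
  ok <- !is.na(tr$x)
  assert_that(all(tr$x[ok] >= -tol & tr$x[ok] <= session$arena_side + tol &
                    tr$y[ok] >= -tol & tr$y[ok] <= session$arena_side + tol),
              "tracking positions fall outside the arena")
  hd_ok <- is.na(tr$hd) | (tr$hd >= 0 & tr$hd < 2 * pi + tol)
  assert_that(all(hd_ok), "head direction must be in [0, 2*pi) or NA")
  ep <- session$epochs
  assert_that(all(c("start", "end", "condition") %in% names(ep)),
              "epochs must have columns start, end, condition")
  assert_that(all(ep$condition %in% c("light", "dark")),
              "epoch condition must be 'light' or 'dark'")
  bad <- which(ep$start >= ep$end)
  assert_that(length(bad) == 0,
              sprintf("epoch rows with start >= end: %s",
                      paste(bad, collapse = ", ")))
  if (nrow(ep) > 1) {
    assert_that(!is.unsorted(ep$start), "epochs must be sorted by start")
    ov <- which(ep$start[-1] < ep$end[-nrow(ep)] - 1e-9)
    assert_that(length(ov) == 0,
                sprintf("overlapping epochs at rows: %s",
                        paste(ov + 1, collapse = ", ")))
    same <- which(ep$condition[-1] == ep$condition[-nrow(ep)])
    assert_that(length(same) == 0,
                sprintf("conditions must alternate; repeated at rows: %s",
                        paste(same + 1, collapse = ", ")))
  }
  sp <- session$spikes
  if (nrow(sp)) {
    assert_that(all(sp$t >= 0), "spike times must be non-negative")
    srt <- tapply(sp$t, sp$unit_id, function(v) !is.unsorted(v))
    assert_that(all(srt), "spike times must be sorted within unit")
    t_max <- max(tr$t[nrow(tr)], ep$end[nrow(ep)]) + 1
    assert_that(all(sp$t <= t_max), "spike times exceed session duration")
  }
  un <- session$units
  w <- un$spike_width_ms
  assert_that(all(is.na(w) | w > 0), "spike widths must be positive")
  if (!is.null(session$lfp)) {
    assert_that(is.numeric(session$lfp$samples) && session$lfp$fs > 0,
                "lfp must have numeric samples and positive fs")
    assert_that(all(is.finite(session$lfp$samples)),
                "lfp samples must be finite")
  }
  assert_that(session$arena_side > 0, "arena_side must be positive")
  invisible(session)
}

#' Build an alternating light/dark epoch table
#'
#' @param duration Total covered time, s.
#' @param epoch_length Length of each epoch, s (default 180, the common
#'   3-min alternation).
#' @param first Condition of the first epoch.
#' @param t0 Start time, s.
#' @return Tibble with `start`, `end`, `condition`.
#' @export
alternating_epochs <- function(duration, epoch_length = 180, first = "light",
                               t0 = 0) {
  n <- floor((duration + 1e-9) / epoch_length)
  assert_that(n >= 1, "duration shorter than one epoch")
  starts <- t0 + (seq_len(n) - 1) * epoch_length
  conds <- rep(c(first, setdiff(c("light", "dark"), first)), length.out = n)
  tibble::tibble(start = starts, end = starts + epoch_length, condition = conds)
}

#' Read a session from its on-disk directory
#'
#' Expects `tracking.csv` (t,x,y,hd_deg), `spikes.csv` (unit_id,t),
#' `units.csv` (unit_id,spike_width_ms\[,label\]), `epochs.csv`
#' (start,end,condition), `session.json`, and optionally `lfp.csv` (v).
#'
#' @param path Session directory.
#' @return An `mec_session`.
#' @export
read_session <- function(path) {
  need <- c("tracking.csv", "spikes.csv", "epochs.csv", "session.json")
  for (f in need) {
    assert_that(file.exists(file.path(path, f)),
                sprintf("session directory is missing %s", f))
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  tr <- readr::read_csv(file.path(path, "tracking.csv"),
                        show_col_types = FALSE)
  tracking <- tibble::tibble(t = tr$t, x = tr$x, y = tr$y,
                             hd = wrap_2pi(tr$hd_deg * pi / 180))
  tracking$hd[is.na(tr$hd_deg)] <- NA_real_
  spikes <- readr::read_csv(file.path(path, "spikes.csv"),
                            col_types = readr::cols(
                              unit_id = readr::col_character(),
                              t = readr::col_double()))
  units <- NULL
  if (file.exists(file.path(path, "units.csv"))) {
    units <- readr::read_csv(file.path(path, "units.csv"),
                             show_col_types = FALSE)
    units$unit_id <- as.character(units$unit_id)
  }
  epochs <- readr::read_csv(file.path(path, "epochs.csv"),
                            show_col_types = FALSE)
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.csv"))) {
    v <- readr::read_csv(file.path(path, "lfp.csv"), show_col_types = FALSE)$v
    lfp <- list(samples = v, fs = meta$lfp_fs_hz %||% 600,
                t0 = meta$lfp_t0 %||% 0)
  }
  mec_session(tracking = tracking, spikes = spikes, units = units,
              epochs = epochs, lfp = lfp,
              arena_side = meta$arena_side_cm %||% 100,
              metadata = meta$metadata %||% list())
}

#' Write a session to a directory
#'
#' Inverse of [read_session()]; times are written with sub-microsecond
#' precision so the round trip is the identity within 1e-6 s.
#'
#' @param session An `mec_session`.
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- session$tracking
  readr::write_csv(tibble::tibble(
    t = round(tr$t, 7), x = round(tr$x, 4), y = round(tr$y, 4),
    hd_deg = round(tr$hd * 180 / pi, 4)), file.path(path, "tracking.csv"))
  readr::write_csv(tibble::tibble(unit_id = session$spikes$unit_id,
                                  t = round(session$spikes$t, 7)),
                   file.path(path, "spikes.csv"))
  readr::write_csv(session$units, file.path(path, "units.csv"))
  readr::write_csv(session$epochs, file.path(path, "epochs.csv"))
  meta <- list(arena_side_cm = session$arena_side,
               created_by = "gridtheta",
               metadata = strip_classes(session$metadata))
  if (!is.null(session$lfp)) {
    meta$lfp_fs_hz <- session$lfp$fs
    meta$lfp_t0 <- session$lfp$t0
    readr::write_csv(tibble::tibble(v = round(session$lfp$samples, 6)),
                     file.path(path, "lfp.csv"))
  }
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Down-sample an LFP trace to the working rate
#'
#' Decimates (with an anti-alias low-pass when the ratio is integral) to
#' the 600 Hz rate all theta analyses assume.
#'
#' @param lfp List with `samples`, `fs`, `t0`.
#' @param fs_out Target rate, Hz (default 600).
#' @return An LFP list at `fs_out`.
#' @export
resample_lfp <- function(lfp, fs_out = 600) {
  if (lfp$fs == fs_out) return(lfp)
  ratio <- lfp$fs / fs_out
  assert_that(ratio > 1, "resample_lfp only down-samples")
  bf <- signal::butter(4, 0.8 / ratio, type = "low")
  sm <- signal::filtfilt(bf, lfp$samples)
  idx <- seq(1, length(sm), by = ratio)
  list(samples = sm[round(idx)], fs = fs_out, t0 = lfp$t0)
}

# Recursively drop S3 classes so provenance objects (cell specs etc.)
# serialize as plain JSON lists.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attr(x, "class") <- NULL
  }
  x
}

# Half-open [start, end) membership of times in a set of epochs.
in_epochs <- function(t, epochs) {
  if (!nrow(epochs)) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(epochs))) {
    hit <- hit | (t >= epochs$start[i] & t < epochs$end[i])
  }
  hit
}

#' Restrict a session to one illumination condition
#'
#' Pools all epochs of the requested condition (the standard move before
#' computing condition-wise rate maps).  Tracking and spikes are
#' restricted to the half-open union of the condition's epochs; the raw
#' LFP trace is kept whole (theta signals are masked after the transform,
#' where slicing cannot distort the filter) and the condition's epoch rows
#' are carried along for paired statistics.
#'
#' @param session An `mec_session`.
#' @param condition `"light"` or `"dark"`.
#' @return An `mec_session` view for that condition.
#' @export
slice_by_condition <- function(session, condition) {
  ep <- dplyr::filter(session$epochs, .data$condition == !!condition)
  assert_that(nrow(ep) > 0,
              sprintf("condition '%s' absent from epoch table", condition))
  tracking <- session$tracking[in_epochs(session$tracking$t, ep), ]
  spikes <- session$spikes[in_epochs(session$spikes$t, ep), ]
  meta <- session$metadata
  meta$condition_view <- condition
  out <- mec_session(tracking = tracking, spikes = spikes,
                     units = session$units, epochs = ep, lfp = session$lfp,
                     arena_side = session$arena_side, metadata = meta,
                     validate = FALSE)
  out
}

#' Membership mask of time points in a condition's epochs
#'
#' Half-open `[start, end)` membership of each time point in the union
#' of the epochs of one condition (or of all epochs).
#'
#' @param t Time points, s.
#' @param epochs Epoch table.
#' @param condition Optional condition filter.
#' @return Logical vector along `t`.
#' @export
epoch_mask <- function(t, epochs, condition = NULL) {
  if (!is.null(condition)) {
    epochs <- epochs[epochs$condition == condition, ]
  }
  in_epochs(t, epochs)
}

#' Total time covered by a session's epoch table
#' @param session An `mec_session`.
#' @return Seconds.
#' @export
epoch_duration <- function(session) {
  sum(session$epochs$end - session$epochs$start)
}
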