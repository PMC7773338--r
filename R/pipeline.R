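#' Run the condition-contrast analysis pipeline on a session
#'
#' Computes, per unit and per condition, the spatial metrics (grid
#' score, spatial information, border score, head-direction statistics,
#' spike counts), the speed score, the epoch-modulation test, and (when
#' an LFP is present) the per-condition theta-frequency vs speed
#' regression.  Stages can be selected; the LN model stage is opt-in
#' because it dominates run time.
#'
#' @param session An `mec_session`.
#' @param stages Any of `"spatial"`, `"modulation"`, `"theta"`, `"ln"`.
#' @param band Theta band (`NULL` = detect).
#' @return List of tibbles: `spatial_metrics`, `modulation`,
#'   `theta_speed`, `labels`, plus `ln_fits` when requested.
#' @export
run_session <- function(session,
                        stages = c("spatial", "modulation", "theta"),
                        band = NULL) {
  sig <- derive_signals(session, band = band)
  units <- session$units$unit_id
  out <- list()
  views <- list(light = slice_by_condition(session, "light"),
                dark = slice_by_condition(session, "dark"))
  if ("spatial" %in% stages) {
    rows <- list()
    for (u in units) {
      for (cond in names(views)) {
        v <- views[[cond]]
        st <- v$spikes$t[v$spikes$unit_id == u]
        dur <- epoch_duration(v)
        row <- tibble::tibble(unit_id = u, condition = cond,
                              n_spikes = length(st),
                              mean_rate = length(st) / dur,
                              grid_score = NA_real_, delta_h = NA_real_,
                              border_score = NA_real_, spacing = NA_real_,
                              hd_mrl = NA_real_, hd_inv_circ_sd = NA_real_,
                              hd_rayleigh_p = NA_real_,
                              hd_peak_rate = NA_real_,
                              speed_score = NA_real_)
        if (length(st) >= 10) {
          m <- rate_map(st, v$tracking, session$arena_side)
          g <- grid_score(m)
          row$grid_score <- g$score
          row$delta_h <- spatial_information(st, v$tracking,
                                             arena_side =
                                               session$arena_side)$delta_h
          b <- border_score(m)
          row$border_score <- b$score
          stm <- suppressWarnings(spike_triggered_map(st, v$tracking))
          row$spacing <- stm$spacing
          hd <- hd_tuning(st, v$tracking)
          row$hd_mrl <- hd$mrl
          row$hd_inv_circ_sd <- 1 / hd$circ_sd
          row$hd_rayleigh_p <- hd$rayleigh_p
          row$hd_peak_rate <- hd$peak_rate
          rs <- instantaneous_rate(st, v$tracking$t)
          sp <- sig[match(round(v$tracking$t, 6), round(sig$t, 6)), ]
          row$speed_score <- tryCatch(
            speed_score(rs, tibble::tibble(t = sp$t, speed = sp$speed)),
            error = function(e) NA_real_)
        }
        rows[[length(rows) + 1]] <- row
      }
    }
    out$spatial_metrics <- dplyr::bind_rows(rows)
    width <- session$units$spike_width_ms[match(units, session$units$unit_id)]
    met <- dplyr::left_join(out$spatial_metrics,
                            tibble::tibble(unit_id = units,
                                           spike_width_ms = width),
                            by = "unit_id")
    out$labels <- classify_cells(met)
  }
  if ("modulation" %in% stages) {
    out$modulation <- dplyr::bind_rows(lapply(units, function(u) {
      st <- session$spikes$t[session$spikes$unit_id == u]
      dplyr::bind_cols(tibble::tibble(unit_id = u),
                       epoch_modulation(st, session$epochs))
    }))
  }
  if ("theta" %in% stages && !is.null(session$lfp)) {
    out$theta_speed <- dplyr::bind_rows(lapply(c("light", "dark"),
                                               function(cond) {
      mask <- in_epochs(sig$t, session$epochs[session$epochs$condition ==
                                                cond, ])
      res <- tryCatch(theta_speed_regression(sig[mask, ]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(condition = cond), res)
    }))
  }
  if ("ln" %in% stages) {
    out$ln_fits <- dplyr::bind_rows(lapply(units, function(u) {
      st <- session$spikes$t[session$spikes$unit_id == u]
      scr <- stability_screen(st, session$tracking$t[1],
                              session$tracking$t[nrow(session$tracking)])
      if (!scr$pass) {
        return(tibble::tibble(unit_id = u, screened_out = TRUE,
                              selected = NA_character_))
      }
      fit <- fit_ln_model(st, session$tracking, sig,
                          arena_side = session$arena_side)
      tibble::tibble(unit_id = u, screened_out = FALSE,
                     selected = paste(fit$selected, collapse = "+"))
    }))
  }
  out
}

#' Write pipeline results as TSV tables
#'
#' Deterministic plain-text serialization (fixed significant digits) so
#' repeated runs of the same seeded session are byte-identical.
#'
#' @param results [run_session()] output.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results)) {
    df <- results[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    readr::write_tsv(df, file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}
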