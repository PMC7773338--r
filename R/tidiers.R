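# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rhythmicity fit
#'
#' @param x An `mec_rhythmfit`.
#' @param ... Unused.
#' @return Tibble with one row per model parameter.
#' @export
tidy.mec_rhythmfit <- function(x, ...) {
  tibble::tibble(term = names(x$model), estimate = unname(x$model))
}

#' @rdname tidy.mec_rhythmfit
#' @export
glance.mec_rhythmfit <- function(x, ...) {
  tibble::tibble(loglik_full = x$loglik_full, loglik_null = x$loglik_null,
                 deviance = x$deviance, p_value = x$p_value,
                 n_lags = x$n_lags)
}

#' Tidy an LN model fit
#'
#' @param x An `mec_lnfit`.
#' @param ... Unused.
#' @return Tibble with one row per covariate bin weight.
#' @export
tidy.mec_lnfit <- function(x, ...) {
  if (!length(x$selected)) {
    return(tibble::tibble(covariate = character(), bin = integer(),
                          weight = numeric()))
  }
  dplyr::bind_rows(lapply(x$selected, function(c_) {
    tibble::tibble(covariate = c_, bin = seq_along(x$weights[[c_]]),
                   weight = x$weights[[c_]])
  }))
}

#' @rdname tidy.mec_lnfit
#' @export
glance.mec_lnfit <- function(x, ...) {
  tibble::tibble(selected = paste(x$selected, collapse = "+"),
                 n_covariates = length(x$selected),
                 mean_cv_ll_increase = mean(x$fold_ll),
                 mean_rate = x$mean_rate)
}
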