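#' Tidy a Gompertz water-soaking fit
#'
#' @param x A [fit_gompertz()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy gompertz_fit
#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble::tibble(term = c("asymptote", "lag", "rate"),
                 estimate = c(x$asymptote, x$lag, x$rate))
}

#' Glance at a Gompertz water-soaking fit
#'
#' @param x A [fit_gompertz()] object.
#' @param ... Unused.
#' @return One-row tibble with fit diagnostics.
#' @method glance gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_obs = x$n_obs, converged = x$converged,
                 status = x$status, scale_max = x$scale_max)
}

#' Tidy the water-soaking / log-permeance regression
#'
#' @param x A [regress_ws_on_log_permeance()] object.
#' @param ... Passed to the `lm` tidier.
#' @return Coefficient-level tibble (intercept and log10-permeance slope).
#' @method tidy ws_permeance_fit
#' @export
tidy.ws_permeance_fit <- function(x, ...) {
  out <- tidy(x$fit, ...)
  out$term[out$term == "logp"] <- "log10_permeance"
  out
}

#' Glance at the water-soaking / log-permeance regression
#'
#' @param x A [regress_ws_on_log_permeance()] object.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `r_squared_pct`, `slope`,
#'   `intercept`, `p_value`, `n`.
#' @method glance ws_permeance_fit
#' @export
glance.ws_permeance_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, r_squared_pct = x$r_squared_pct,
                 slope = x$slope, intercept = x$intercept,
                 p_value = x$p_value, n = x$n)
}
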