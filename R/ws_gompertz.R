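#' Lag-parameterised Gompertz curve
#'
#' Sigmoid time course of water soaking in the lag parameterisation
#' \deqn{y(t) = A \exp\left(-\exp\left(\frac{U e}{A}(\lambda - t) + 1\right)\right)}
#' whose parameters are directly the quantities of interest: `asymptote`
#' (\eqn{A}) is the plateau score, `rate` (\eqn{U}) is the maximum slope of
#' the curve (score per hour), and `lag` (\eqn{\lambda}) is the time lag —
#' the point where the tangent at the inflection crosses zero, i.e. the
#' incubation time until first symptoms. At \eqn{t = \lambda} the curve
#' value is \eqn{A e^{-e} \approx 0.066 A}; the inflection sits later, at
#' \eqn{t = \lambda + A/(U e)}, with value \eqn{A/e}.
#'
#' @param t Time, hours; vectorised.
#' @param asymptote Plateau \eqn{A} (> 0), in rating units (or percent).
#' @param lag Time lag \eqn{\lambda} (>= 0), hours.
#' @param rate Maximum rate \eqn{U} (>= 0), rating units per hour.
#' @return Curve value at `t`, same units as `asymptote`.
#' @examples
#' gompertz_value(0:6, asymptote = 4, lag = 1.1, rate = 1.2)
#' @export
gompertz_value <- function(t, asymptote, lag, rate) {
  if (any(asymptote <= 0)) abort("Gompertz asymptote must be > 0.")
  if (any(rate < 0)) abort("Gompertz rate U must be >= 0.")
  if (any(lag < 0)) abort("Gompertz time lag must be >= 0.")
  asymptote * exp(-exp(rate * exp(1) / asymptote * (lag - t) + 1))
}

#' Fit the lag-parameterised Gompertz curve to a water-soaking time course
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt via
#' [minpack.lm::nls.lm()]) of the three-parameter lag Gompertz to observed
#' scores, with five deterministic multi-starts; the best (lowest residual
#' sum of squares) converged fit is kept. Ratings are treated as numeric —
#' the ordinal score and the continuous water-soaked area are near-linearly
#' related. For integer-valued (ordinal) courses the end categories are
#' censored rather than exact: a score of `scale_max` only says the course
#' is above the top bin edge and a score of 0 that it is below the first,
#' so those residuals are one-sided (hinge at half a score from the
#' category value). This prevents top-coded plateau scores from dragging
#' the fitted rate upward.
#'
#' Bounds: `0 <= lag <= max(t) + 4` (the lag may exceed the last
#' observation when symptoms have barely started by assay end),
#' `0 <= rate <= 5 * scale_max / 4`, and
#' `0.025 * scale_max <= asymptote <= scale_max`. If the last two
#' observations are equal and are the course maximum, the plateau is taken
#' as reached and `asymptote` is pinned there before fitting the remaining
#' two parameters.
#'
#' An all-zero course admits no fit and returns a censored result:
#' `lag = max(t)`, `rate = 0`, `status = "no_symptoms"`. A course that
#' jumps to its plateau between two consecutive observations (typical for
#' ordinal scores: e.g. 0, 1, 3, 3) admits exact fits of unbounded
#' steepness — the data bound the rate only from below, the least-squares
#' rate runs to the box bound, and neither rate nor lag is identified.
#' Such fits are returned with `status = "saturated"` and are excluded
#' from parameter averaging by [fit_ws_courses()] (their `lag_h` and
#' `rate_per_h` are set to `NA`; the water-soaking index, which is
#' observed, is unaffected).
#'
#' @param time_h Observation times, hours, strictly increasing, length >= 4.
#' @param rating Observed scores (0..`scale_max`), same length; may be
#'   fractional; need not be monotone.
#' @param scale_max Top of the measurement scale: 4 for the ordinal rating
#'   scale (default), 100 for percent area.
#' @return An object of class `gompertz_fit`: a list with `asymptote`,
#'   `lag`, `rate`, `rss`, `converged`, `status`, `n_obs`, `scale_max`, and
#'   the `data` fitted to. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' t <- c(0, 2, 4, 6)
#' y <- gompertz_value(t, 4, 1.1, 1.2)
#' fit_gompertz(t, y)
#' @export
fit_gompertz <- function(time_h, rating, scale_max = 4) {
  if (length(time_h) != length(rating)) abort("time_h and rating differ in length.")
  keep <- complete.cases(time_h, rating)
  time_h <- time_h[keep]; rating <- rating[keep]
  if (length(time_h) < 4L) abort("A Gompertz fit needs at least 4 observation times.")
  if (any(diff(time_h) <= 0)) abort("Observation times must be strictly increasing.")
  if (any(rating < 0 | rating > scale_max)) abort("Ratings must lie within the scale bounds.")

  data <- tibble::tibble(time_h = time_h, rating = rating)
  span <- max(time_h)
  if (all(rating == 0)) {
    return(new_gompertz_fit(asymptote = 0, lag = span, rate = 0, rss = 0,
                            converged = TRUE, status = "no_symptoms",
                            data = data, scale_max = scale_max))
  }

  lower <- c(asym = 0.025 * scale_max, lag = 0, rate = 0)
  upper <- c(asym = scale_max, lag = span + 4, rate = 5 * scale_max / 4)
  n <- length(rating)
  # integer scores are ordinal: the end categories are censored (a score
  # of scale_max means "above the top bin edge", 0 means "below the first
  # edge"), so end-category residuals are one-sided hinge residuals at
  # half a score from the category value; interior scores are two-sided
  ordinal <- all(rating %% 1 == 0)
  resid_fun <- function(p) {
    y <- gompertz_value(time_h, p[1], p[2], p[3])
    r <- y - rating
    if (ordinal) {
      top <- rating == scale_max
      bot <- rating == 0
      r[top] <- pmin(0, y[top] - (scale_max - 0.5))
      r[bot] <- pmax(0, y[bot] - 0.5)
    }
    r
  }
  pin_asym <- !ordinal && rating[n] == rating[n - 1L] &&
    rating[n] == max(rating) && rating[n] > 0

  a0 <- min(max(max(rating), lower[["asym"]]), upper[["asym"]])
  first_pos <- time_h[match(TRUE, rating > 0)]
  slope0 <- max(diff(rating) / diff(time_h), 0.05)
  starts <- list(
    c(asym = a0, lag = max(first_pos - 0.5, 0), rate = slope0),
    c(asym = a0, lag = 0, rate = slope0),
    c(asym = a0, lag = span / 2, rate = slope0 / 2),
    c(asym = min(a0 * 1.25, upper[["asym"]]), lag = max(first_pos - 1, 0), rate = slope0 * 1.5),
    c(asym = upper[["asym"]], lag = span / 4, rate = max(rating) / span)
  )

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12, ptol = 1e-12)
  for (st in starts) {
    fit <- if (pin_asym) {
      a_pin <- rating[n]
      try(suppressWarnings(minpack.lm::nls.lm(
        par = pmin(pmax(st[c("lag", "rate")], lower[c("lag", "rate")]),
                   upper[c("lag", "rate")]),
        fn = function(p) resid_fun(c(a_pin, p)),
        lower = lower[c("lag", "rate")], upper = upper[c("lag", "rate")],
        control = ctrl)), silent = TRUE)
    } else {
      try(suppressWarnings(minpack.lm::nls.lm(
        par = pmin(pmax(st, lower), upper), fn = resid_fun,
        lower = lower, upper = upper, control = ctrl)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      cf <- fit$par
      best <- if (pin_asym) {
        list(asymptote = rating[n], lag = unname(cf[["lag"]]),
             rate = unname(cf[["rate"]]), rss = rss)
      } else {
        list(asymptote = unname(cf[["asym"]]), lag = unname(cf[["lag"]]),
             rate = unname(cf[["rate"]]), rss = rss)
      }
    }
    if (!is.null(best) && best$rss < 1e-10) break # essentially exact fit
  }

  if (is.null(best)) {
    # fall back to direct bounded minimisation of the RSS
    obj <- function(p) sum(resid_fun(p)^2)
    op <- stats::optim(c(a0, max(first_pos - 0.5, 0), slope0), obj,
                       method = "L-BFGS-B", lower = lower, upper = upper)
    return(new_gompertz_fit(asymptote = op$par[1], lag = op$par[2],
                            rate = op$par[3], rss = op$value,
                            converged = op$convergence == 0,
                            status = "fallback", data = data,
                            scale_max = scale_max))
  }
  status <- "ok"
  if (best$rate > 0.98 * upper[["rate"]]) {
    # the course jumps to its plateau between two consecutive observations:
    # the data bound the rate only from below, so the least-squares rate
    # runs to the box bound and neither rate nor lag is identified
    status <- "saturated"
  }
  new_gompertz_fit(asymptote = best$asymptote, lag = best$lag, rate = best$rate,
                   rss = best$rss, converged = status == "ok", status = status,
                   data = data, scale_max = scale_max)
}

new_gompertz_fit <- function(asymptote, lag, rate, rss, converged, status,
                             data, scale_max) {
  structure(list(asymptote = asymptote, lag = lag, rate = rate, rss = rss,
                 converged = converged, status = status, n_obs = nrow(data),
                 scale_max = scale_max, data = data),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Lag-parameterised Gompertz fit (", x$status, ")\n", sep = "")
  cat(sprintf("  asymptote A = %.4g   time lag = %.4g h   rate U = %.4g /h   rss = %.3g\n",
              x$asymptote, x$lag, x$rate, x$rss))
  invisible(x)
}

#' Water-soaking score at a given incubation time
#'
#' Returns the observed score if the queried time matches a scheduled
#' observation (the study default: the score observed after 4 h), and the
#' fitted curve value otherwise. Querying outside the observed range of a
#' censored (unfitted) course is an error.
#'
#' @param fit A [fit_gompertz()] object.
#' @param t Query time, hours. Default 4 h, the standard index time.
#' @return A score in the fitted scale.
#' @export
ws_at_time <- function(fit, t = 4) {
  stopifnot(inherits(fit, "gompertz_fit"))
  hit <- which(abs(fit$data$time_h - t) < 1e-8)
  if (length(hit)) return(fit$data$rating[hit[1L]])
  if (fit$status == "no_symptoms") {
    if (t < min(fit$data$time_h) || t > max(fit$data$time_h)) {
      abort("Query time is outside the observed range of an unfitted (all-zero) course.")
    }
    return(0)
  }
  gompertz_value(t, fit$asymptote, fit$lag, fit$rate)
}

#' Fit Gompertz water-soaking kinetics for every fruit in a long table
#'
#' Maps [fit_gompertz()] over a long-format observation table and collects
#' the per-fruit parameters. Courses with fewer than 4 observations are not
#' fitted and are returned flagged (`status = "too_few_points"`).
#'
#' @param ws Long table with columns `fruit_id`, `time_h`, `rating`.
#' @param scale_max Scale top, see [fit_gompertz()].
#' @param index_time_h Time at which the water-soaking index is read
#'   (default 4 h).
#' @return A tibble with one row per fruit: `fruit_id`, `asymptote`,
#'   `lag_h`, `rate_per_h`, `rss`, `converged`, `status`, `ws_index`,
#'   `n_obs`.
#' @export
fit_ws_courses <- function(ws, scale_max = 4, index_time_h = 4) {
  miss <- setdiff(c("fruit_id", "time_h", "rating"), names(ws))
  if (length(miss)) abort(paste0("ws table is missing column(s): ", paste(miss, collapse = ", ")))
  ws |>
    dplyr::arrange(.data$fruit_id, .data$time_h) |>
    dplyr::group_by(.data$fruit_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 4L) {
        return(tibble::tibble(asymptote = NA_real_, lag_h = NA_real_,
                              rate_per_h = NA_real_, rss = NA_real_,
                              converged = FALSE, status = "too_few_points",
                              ws_index = NA_real_, n_obs = nrow(d)))
      }
      f <- fit_gompertz(d$time_h, d$rating, scale_max = scale_max)
      ident <- f$status != "saturated"
      tibble::tibble(asymptote = f$asymptote,
                     lag_h = if (ident) f$lag else NA_real_,
                     rate_per_h = if (ident) f$rate else NA_real_,
                     rss = f$rss, converged = f$converged, status = f$status,
                     ws_index = ws_at_time(f, index_time_h), n_obs = f$n_obs)
    }) |>
    dplyr::ungroup()
}
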