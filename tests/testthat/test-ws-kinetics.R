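test_that("area-percentage scores follow the five-point scale and its inverse", {
  expect_identical(rating_from_area_pct(c(0, 50, 70, 10)), c(0L, 3L, 4L, 2L))
  expect_identical(rating_from_area_pct(c(5, 34.99, 35, 60, 60.01)),
                   c(1L, 2L, 3L, 3L, 4L))

  # brute-force oracle: walk the printed bin definitions point by point
  oracle <- function(p) {
    if (p == 0) return(0L)
    if (p < 10) return(1L)
    if (p < 35) return(2L)
    if (p <= 60) return(3L)
    4L
  }
  grid <- seq(0, 100, by = 0.01)
  expect_identical(rating_from_area_pct(grid),
                   vapply(grid, oracle, integer(1)))

  expect_identical(area_midpoint_from_rating(0:4), c(0, 5, 22.5, 47.5, 80))
  expect_identical(rating_from_area_pct(area_midpoint_from_rating(0:4)), 0:4)

  expect_error(rating_from_area_pct(101))
  expect_error(rating_from_area_pct(-0.1))
  expect_error(area_midpoint_from_rating(2.5))
})

test_that("the lag-Gompertz closed form has its defining tangent geometry", {
  # degenerate rate: flat curve at A exp(-e)
  expect_equal(gompertz_value(c(0, 3, 10), 4, 1, 0), rep(4 * exp(-exp(1)), 3))
  # value at the lag itself
  for (a in c(1.5, 4)) {
    expect_equal(gompertz_value(2, a, 2, 1.1), a * exp(-exp(1)))
  }

  # tangent property checked against numerical differentiation: the
  # inflection sits at t* = lag + A/(U e), carries slope U, and its
  # tangent crosses zero exactly at the lag
  set.seed(5)
  for (k in 1:20) {
    a <- runif(1, 1, 4); l <- runif(1, 0, 3); u <- runif(1, 0.3, 2)
    t_star <- l + a / (u * exp(1))
    h <- 1e-6
    slope <- (gompertz_value(t_star + h, a, l, u) -
                gompertz_value(t_star - h, a, l, u)) / (2 * h)
    expect_equal(slope, u, tolerance = 1e-6)
    expect_equal(gompertz_value(t_star, a, l, u), a / exp(1), tolerance = 1e-12)
    x_intercept <- t_star - gompertz_value(t_star, a, l, u) / slope
    expect_equal(x_intercept, l, tolerance = 1e-5)
  }

  # monotone in time and in rate
  tg <- seq(0, 8, by = 0.25)
  expect_true(all(diff(gompertz_value(tg, 4, 1, 1.2)) > 0))
  ug <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(gompertz_value(3, 4, 1, ug)) > 0))

  expect_error(gompertz_value(1, -1, 1, 1))
  expect_error(gompertz_value(1, 4, -1, 1))
  expect_error(gompertz_value(1, 4, 1, -1))
})

test_that("noiseless model courses round-trip through the fitter", {
  t <- c(0, 2, 4, 6)
  cases <- list(c(4, 1.0, 1.2), c(3, 0.5, 0.8), c(2.5, 2.0, 0.6), c(4, 1.8, 1.6))
  for (p in cases) {
    f <- fit_gompertz(t, gompertz_value(t, p[1], p[2], p[3]))
    expect_lt(abs(f$asymptote - p[1]) / p[1], 1e-6)
    expect_lt(abs(f$lag - p[2]) / max(p[2], 1), 1e-6)
    expect_lt(abs(f$rate - p[3]) / p[3], 1e-6)
    expect_true(f$converged)
  }
})

test_that("fit_gompertz handles censored and degenerate courses", {
  f0 <- fit_gompertz(c(0, 2, 4, 6), c(0, 0, 0, 0))
  expect_identical(f0$status, "no_symptoms")
  expect_equal(f0$lag, 6)
  expect_equal(f0$rate, 0)

  # plateau-jump ordinal course: rate unidentified, flagged saturated
  fs <- fit_gompertz(c(0, 2, 4, 6), c(0, 1, 3, 3))
  expect_identical(fs$status, "saturated")
  expect_false(fs$converged)

  expect_error(fit_gompertz(c(0, 2, 4), c(0, 1, 2)), "at least 4")
  expect_error(fit_gompertz(c(0, 2, 2, 6), c(0, 1, 2, 3)), "strictly increasing")
  expect_error(fit_gompertz(c(0, 2, 4, 6), c(0, 1, 2, 5)), "scale bounds")
})

test_that("fits are translation-consistent in time", {
  t <- c(0, 2, 4, 6)
  y <- gompertz_value(t, 3.6, 0.9, 1.1)
  f0 <- fit_gompertz(t, y)
  for (shift in c(1, 2)) {
    f1 <- fit_gompertz(t + shift, y)
    expect_equal(f1$lag, f0$lag + shift, tolerance = 1e-5)
    expect_equal(f1$rate, f0$rate, tolerance = 1e-5)
    expect_equal(f1$asymptote, f0$asymptote, tolerance = 1e-5)
  }
})

test_that("ws_at_time prefers observed scores and falls back to the curve", {
  t <- c(0, 2, 4, 6)
  f <- fit_gompertz(t, c(0, 1, 2, 3))
  expect_equal(ws_at_time(f, 4), 2) # exact lookup wins
  # between scheduled points the fitted curve interpolates monotonically
  v3 <- ws_at_time(f, 3)
  expect_gt(v3, ws_at_time(f, 2.2))
  expect_lt(v3, ws_at_time(f, 3.8))

  y <- gompertz_value(t, 4, 1.0, 1.2)
  fc <- fit_gompertz(t, y)
  expect_equal(ws_at_time(fc, 3.3), gompertz_value(3.3, 4, 1.0, 1.2),
               tolerance = 1e-5)

  f0 <- fit_gompertz(t, c(0, 0, 0, 0))
  expect_equal(ws_at_time(f0, 3), 0)
  expect_error(ws_at_time(f0, 10), "outside")
})

test_that("fit_ws_courses maps fits over fruit and flags short courses", {
  ws <- dplyr::bind_rows(
    tibble::tibble(fruit_id = "a", time_h = c(0, 2, 4, 6),
                   rating = c(0, 1, 2, 3)),
    tibble::tibble(fruit_id = "b", time_h = c(0, 2, 4), rating = c(0, 1, 2))
  )
  k <- fit_ws_courses(ws)
  expect_identical(nrow(k), 2L)
  expect_identical(k$status[k$fruit_id == "b"], "too_few_points")
  expect_equal(k$ws_index[k$fruit_id == "a"], 2)
})

test_that("panel-level water-soaking metrics reproduce the expected correlation signs", {
  panel <- generate_panel(small_panel_config(seed = 9))
  st <- suppressMessages(run_study(panel))
  cm <- correlation_matrix(st$trait_means, c("ws_index", "lag_h", "rate_per_h"))
  r_lag <- cm$r[cm$trait_x == "ws_index" & cm$trait_y == "lag_h"]
  r_rate <- cm$r[cm$trait_x == "ws_index" & cm$trait_y == "rate_per_h"]
  r_lag_rate <- cm$r[cm$trait_x == "lag_h" & cm$trait_y == "rate_per_h"]
  expect_lt(r_lag, 0)   # more soaking, shorter lag
  expect_gt(r_rate, 0)  # more soaking, faster increase
  expect_lt(r_lag_rate, 0)
})

test_that("gompertz fit tidiers and plots expose the parameters", {
  t <- c(0, 2, 4, 6)
  f <- fit_gompertz(t, gompertz_value(t, 4, 1.0, 1.2))
  td <- tidy(f)
  expect_identical(td$term, c("asymptote", "lag", "rate"))
  expect_equal(td$estimate[2], 1.0, tolerance = 1e-5)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
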