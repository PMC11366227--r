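#' Default collection layout for a synthetic genotype panel
#'
#' Three greenhouse collections sampled in 2022 — 64 cultivars/breeding
#' clones, a segregating F2 of 76 individuals, and 32 wild *Fragaria*
#' accessions — optionally extended by a 31-genotype resampling of the
#' cultivar collection in a second (cooler-response) season. Latent
#' log10-permeance means are set so cultivars sit near 2e-6 m/s, the F2
#' lowest and the wild species highest, matching the observed ordering;
#' wild species get small, highly variable fruit and more variable juice
#' TSS.
#'
#' @param include_second_season Add the 31-genotype cultivar resample
#'   (season 2023) to the three 2022 collections.
#' @return A tibble with one row per collection x season.
#' @export
default_collections <- function(include_second_season = FALSE) {
  base <- tibble::tribble(
    ~collection, ~season, ~n_genotypes, ~fruit_per_genotype,
    ~log10_perm_mean, ~log10_perm_sd, ~mass_mean_g, ~mass_cv,
    ~tss_mean_brix, ~tss_sd,
    "cultivar", "2022", 64L, 10L, -5.74, 0.28, 15, 0.30, 8, 1.0,
    "f2",       "2022", 76L, 10L, -5.86, 0.28, 10, 0.35, 8, 1.0,
    "species",  "2022", 32L, 10L, -5.57, 0.28,  3, 0.80, 9, 2.0
  )
  if (include_second_season) {
    base <- dplyr::bind_rows(base, tibble::tibble(
      collection = "cultivar", season = "2023", n_genotypes = 31L,
      fruit_per_genotype = 10L, log10_perm_mean = -6.02, log10_perm_sd = 0.28,
      mass_mean_g = 15, mass_cv = 0.30, tss_mean_brix = 8, tss_sd = 1.0
    ))
  }
  base
}

#' Configuration for the synthetic genotype-panel generator
#'
#' Defines the latent statistical structure the pipeline assumes: per
#' collection a lognormal latent skin permeance, a lognormal fruit-mass
#' distribution with power-law surface-area allometry, normal juice TSS;
#' across the pooled panel a latent water-soaking severity coupled to
#' log10-permeance at correlation `ws_coupling`; and a monotone link from
#' severity to the Gompertz kinetics (higher severity: shorter time lag,
#' larger maximum rate).
#'
#' By default `ws_coupling` is `NULL` and the coupling is calibrated with
#' [calibrated_coupling()] so that the *pipeline-estimated* genotype-level
#' R-squared of the water-soaking index on log10-permeance equals
#' `target_r2` (default 0.46): the latent coupling is inflated by an
#' analytic correction for the attenuation caused by within-genotype
#' permeance sampling noise and by within-genotype water-soaking noise
#' plus ordinal discretisation.
#'
#' @param collections Collection layout, see [default_collections()].
#' @param ws_coupling Latent correlation between genotype log10-permeance
#'   and water-soaking severity, in \[-1, 1\]; `NULL` to calibrate from
#'   `target_r2`.
#' @param target_r2 Pipeline-level R-squared target used when
#'   `ws_coupling` is `NULL`.
#' @param severity_mean,severity_sd Pooled mean and SD of the latent
#'   severity, in water-soaking rating units at the index time.
#' @param between_frac Share of total log10-permeance variance that lies
#'   between genotypes (the rest is within-genotype, between fruit).
#' @param rate0,rate_slope Severity-to-rate link:
#'   `rate = max(0.05, rate0 + rate_slope * severity)` (rating/h). The
#'   time lag is not a free link: with the plateau at the scale top
#'   (complete soaking), the genotype lag is solved in closed form so the
#'   curve passes through the severity value at the index time
#'   ([solve_gompertz_lag()]), which makes the lag fall and the rate rise
#'   with severity.
#' @param lag_jitter_h,rate_jitter Fruit-level SD of the time lag (h) and
#'   rate (rating/h) around the genotype values.
#' @param mass_within_cv,tss_within_sd Within-genotype fruit-to-fruit
#'   variation of mass (CV) and TSS (degrees Brix).
#' @param weighing_noise_mg SD of i.i.d. weighing noise added to each
#'   gravimetric reading, mg.
#' @param discretize Round simulated water-soaking scores to the 0..4
#'   ordinal scale (the assay's observation process).
#' @param schedule_h Assay schedule (weighing and scoring times), hours,
#'   strictly increasing.
#' @param index_time_h Time at which the water-soaking index is read.
#' @param constants A [physical_constants()] object.
#' @param seed Integer root seed; the generator is fully deterministic
#'   given the seed.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(collections = default_collections(),
                         ws_coupling = NULL, target_r2 = 0.46,
                         severity_mean = 2.0, severity_sd = 0.74,
                         between_frac = 0.6,
                         rate0 = 0.6, rate_slope = 0.3,
                         lag_jitter_h = 0.35, rate_jitter = 0.12,
                         mass_within_cv = 0.15, tss_within_sd = 0.5,
                         weighing_noise_mg = 5, discretize = TRUE,
                         schedule_h = c(0, 2, 4, 6), index_time_h = 4,
                         constants = physical_constants(), seed = 1L) {
  req <- c("collection", "season", "n_genotypes", "fruit_per_genotype",
           "log10_perm_mean", "log10_perm_sd", "mass_mean_g", "mass_cv",
           "tss_mean_brix", "tss_sd")
  miss <- setdiff(req, names(collections))
  if (length(miss)) abort(paste0("collections is missing column(s): ", paste(miss, collapse = ", ")))
  if (any(collections$n_genotypes < 1L) || any(collections$fruit_per_genotype < 1L)) {
    abort("Collection sizes must be >= 1.")
  }
  if (any(collections$log10_perm_sd < 0) || any(collections$tss_sd < 0)) {
    abort("Latent SDs must be >= 0.")
  }
  if (any(diff(schedule_h) <= 0)) abort("Assay schedule must be strictly increasing.")
  if (!is.null(ws_coupling) && abs(ws_coupling) > 1) {
    abort("ws_coupling must lie within [-1, 1].")
  }
  if (between_frac <= 0 || between_frac > 1) abort("between_frac must lie in (0, 1].")
  cfg <- list(collections = tibble::as_tibble(collections),
              ws_coupling = ws_coupling, target_r2 = target_r2,
              severity_mean = severity_mean, severity_sd = severity_sd,
              between_frac = between_frac,
              rate0 = rate0, rate_slope = rate_slope,
              lag_jitter_h = lag_jitter_h, rate_jitter = rate_jitter,
              mass_within_cv = mass_within_cv, tss_within_sd = tss_within_sd,
              weighing_noise_mg = weighing_noise_mg, discretize = discretize,
              schedule_h = schedule_h, index_time_h = index_time_h,
              constants = constants, seed = as.integer(seed))
  class(cfg) <- "panel_config"
  cfg
}

# pooled between-genotype variance of latent log10-permeance and its mean
pooled_latent_moments <- function(config) {
  cc <- config$collections
  w <- cc$n_genotypes / sum(cc$n_genotypes)
  mu_bar <- sum(w * cc$log10_perm_mean)
  v_between <- sum(w * (config$between_frac * cc$log10_perm_sd^2 +
                          (cc$log10_perm_mean - mu_bar)^2))
  list(mu_bar = mu_bar, v_between = v_between)
}

#' Latent coupling calibrated for an attenuation-corrected pipeline R-squared
#'
#' The pipeline estimates the water-soaking/log-permeance relationship
#' from noisy genotype means, which attenuates the latent correlation.
#' This returns the latent coupling \eqn{\rho} such that
#' \eqn{\rho^2 k_x k_y = } `target_r2`, with the two reliability factors
#' computed in closed form from the configured noise model:
#' \itemize{
#'   \item \eqn{k_x}: log10 of the mean of `m` per-fruit lognormal
#'     permeances carries sampling variance
#'     \eqn{(e^{(\sigma_w \ln 10)^2} - 1) / (m \ln^2 10)} against the
#'     between-genotype variance of latent log10-permeance;
#'   \item \eqn{k_y}: the genotype water-soaking index (mean of `m`
#'     fruit) carries variance from the fruit-level lag and rate jitter
#'     (propagated through the Gompertz slope at the index time) plus
#'     ordinal discretisation variance 1/12 per fruit, against the pooled
#'     severity variance.
#' }
#'
#' @param config A [panel_config()].
#' @return The calibrated latent correlation (positive scalar).
#' @export
calibrated_coupling <- function(config) {
  pm <- pooled_latent_moments(config)
  cc <- config$collections
  m <- stats::weighted.mean(cc$fruit_per_genotype, cc$n_genotypes)
  sigma_w <- sqrt(1 - config$between_frac) * stats::weighted.mean(cc$log10_perm_sd, cc$n_genotypes)
  ex <- (exp((sigma_w * log(10))^2) - 1) / (m * log(10)^2)
  kx <- pm$v_between / (pm$v_between + ex)

  # typical kinetics at the severity centre, for the delta-method y-noise
  s0 <- config$severity_mean
  u0 <- max(0.05, config$rate0 + config$rate_slope * s0)
  a0 <- 4
  l0 <- solve_gompertz_lag(s0, u0, t = config$index_time_h, asymptote = a0)
  tq <- config$index_time_h
  ee <- exp(u0 * exp(1) / a0 * (l0 - tq) + 1)
  y0 <- a0 * exp(-ee)
  dy_dlag <- -y0 * ee * u0 * exp(1) / a0
  dy_drate <- y0 * ee * exp(1) / a0 * (tq - l0)
  fruit_var <- (dy_dlag * config$lag_jitter_h)^2 +
    (dy_drate * config$rate_jitter)^2 +
    if (config$discretize) 1 / 12 else 0
  ky <- config$severity_sd^2 / (config$severity_sd^2 + fruit_var / m)

  rho <- sqrt(config$target_r2 / (kx * ky))
  if (!is.finite(rho) || rho > 1) {
    abort("Calibration infeasible: the requested R-squared cannot be reached under the configured noise; reduce target_r2 or the noise levels.")
  }
  rho
}

#' Solve the Gompertz asymptote that hits a target score at a given time
#'
#' Finds the plateau `A` such that the lag-Gompertz with the supplied lag
#' and rate passes through `target` at time `t`. When even the scale top
#' cannot reach the target (curve too slow), the asymptote is pinned at
#' `scale_max` and the lag is instead shortened in closed form:
#' \eqn{\lambda = t + (\ln\ln(A/w) - 1) A/(U e)} (floored at 0).
#'
#' @param target Target score at time `t` (0 < target < `scale_max`).
#' @param lag,rate Gompertz lag (h) and rate (per h); vectorised.
#' @param t Time at which the target applies, hours.
#' @param scale_max Upper bound for the asymptote.
#' @return A tibble with columns `asymptote` and `lag` (the possibly
#'   adjusted lag).
#' @export
solve_gompertz_asymptote <- function(target, lag, rate, t = 4, scale_max = 4) {
  n <- max(length(target), length(lag), length(rate))
  target <- rep_len(target, n); lag <- rep_len(lag, n); rate <- rep_len(rate, n)
  if (any(target <= 0 | target >= scale_max)) {
    abort("target must lie strictly inside (0, scale_max).")
  }
  asym <- numeric(n); lag_out <- lag
  for (i in seq_len(n)) {
    f <- function(a) gompertz_value(t, a, lag[i], rate[i]) - target[i]
    hi <- f(scale_max)
    if (hi >= 0) {
      lo_a <- target[i] * (1 + 1e-9)
      asym[i] <- if (f(lo_a) >= 0) lo_a else {
        uniroot(f, c(lo_a, scale_max), tol = 1e-12)$root
      }
    } else {
      # pin the plateau at the scale top and shorten the lag analytically
      asym[i] <- scale_max
      q <- log(log(scale_max / target[i]))
      lag_out[i] <- max(0, t + (q - 1) * scale_max / (rate[i] * exp(1)))
    }
  }
  tibble::tibble(asymptote = asym, lag = lag_out)
}

#' Solve the Gompertz lag that hits a target score at a given time
#'
#' Closed-form inverse of the lag-Gompertz in \eqn{\lambda}: for plateau
#' `A`, rate `U` and target value `w` at time `t`,
#' \deqn{\lambda = t + (\ln\ln(A/w) - 1)\, A/(U e),}
#' floored at `floor_h`. Used by the panel generator, where the plateau is
#' the scale top and genotype severity fixes the curve's value at the
#' index time.
#'
#' @param target Target score at `t`; strictly inside (0, `asymptote`).
#' @param rate Gompertz rate, per hour; > 0. Vectorised with `target`.
#' @param t Time, hours.
#' @param asymptote Plateau.
#' @param floor_h Lower floor for the returned lag.
#' @return Lag in hours.
#' @export
solve_gompertz_lag <- function(target, rate, t = 4, asymptote = 4,
                               floor_h = 0.05) {
  if (any(target <= 0 | target >= asymptote)) {
    abort("target must lie strictly inside (0, asymptote).")
  }
  if (any(rate <= 0)) abort("rate must be > 0.")
  q <- log(log(asymptote / target))
  pmax(floor_h, t + (q - 1) * asymptote / (rate * exp(1)))
}

#' Simulate a gravimetric uptake series from a known permeance
#'
#' Inverts the permeance relation: the flow rate is
#' \eqn{F_f = P_f A \Delta\Psi \rho \bar{V}_w / (RT)} and the cumulative
#' mass is linear, \eqn{m(t) = m_0 + F_f t}, plus i.i.d. Gaussian weighing
#' noise. With zero noise, [derive_uptake()] recovers the permeance
#' exactly.
#'
#' @param permeance_m_s True skin permeance, m/s (>= 0 or negative for a
#'   shrinking fruit).
#' @param mass_g Initial fruit mass, g.
#' @param tss_brix Juice TSS, degrees Brix (sets the driving force).
#' @param schedule_h Weighing times, hours.
#' @param noise_sd_mg SD of weighing noise, mg.
#' @param constants A [physical_constants()] object.
#' @param seed Optional seed for the noise draws.
#' @return A tibble with `time_h` and `mass_g`.
#' @export
generate_uptake_series <- function(permeance_m_s, mass_g, tss_brix,
                                   schedule_h = c(0, 2, 4, 6),
                                   noise_sd_mg = 0,
                                   constants = physical_constants(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  area_m2 <- surface_area_from_mass(mass_g) * 1e-4
  delta_psi_pa <- -osmotic_potential_from_tss(tss_brix) * 1e6
  flow_kg_s <- permeance_m_s * area_m2 * delta_psi_pa / constants$rt_over_rho_vw
  tibble::tibble(
    time_h = schedule_h,
    mass_g = mass_g + flow_kg_s * schedule_h * 3600 * 1000 +
      rnorm(length(schedule_h), 0, noise_sd_mg / 1000)
  )
}

#' Simulate a water-soaking time course from Gompertz parameters
#'
#' Samples the lag-Gompertz at the schedule times and, if `discretize`,
#' pushes the continuous score through the assay's observation process:
#' rounding to the nearest integer score, clamped to \[0, `scale_max`\].
#'
#' @param lag_h,rate_per_h,asymptote Gompertz parameters.
#' @param schedule_h Scoring times, hours.
#' @param discretize Apply ordinal discretisation.
#' @param scale_max Scale top (4 for the rating scale).
#' @param seed Unused when the course is deterministic; accepted for
#'   interface symmetry with the other generators.
#' @return A tibble with `time_h` and `rating`.
#' @export
generate_ws_course <- function(lag_h, rate_per_h, asymptote,
                               schedule_h = c(0, 2, 4, 6),
                               discretize = TRUE, scale_max = 4,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- if (rate_per_h == 0 && asymptote == 0) {
    rep(0, length(schedule_h))
  } else {
    gompertz_value(schedule_h, asymptote, lag_h, rate_per_h)
  }
  if (discretize) y <- pmin(scale_max, pmax(0, round(y)))
  tibble::tibble(time_h = schedule_h, rating = y)
}

#' Generate a synthetic multi-collection genotype panel
#'
#' Draws genotype latents (log10-permeance, coupled water-soaking
#' severity, linked Gompertz kinetics, mean mass and TSS), then fruit-level
#' records around them, and renders the raw assay tables the pipeline
#' consumes: a fruit table, a long gravimetric uptake table and a long
#' water-soaking score table. Fully deterministic given `config$seed`.
#'
#' The severity latent is
#' \eqn{s_g = \mu_s + \beta (x_g - \bar{x}) + e_g} with
#' \eqn{\beta = \rho \sigma_s / \sigma_x} and
#' \eqn{e_g \sim N(0, \sigma_s\sqrt{1-\rho^2})}, so the latent
#' correlation between genotype log10-permeance \eqn{x_g} and severity is
#' exactly \eqn{\rho}. Severity maps to kinetics through the configured
#' monotone link, and the genotype asymptote is solved so the noiseless
#' curve passes through the severity value at the index time.
#'
#' @param config A [panel_config()].
#' @return An object of class `ws_panel`: a list with tibbles `latents`
#'   (ground truth per genotype), `fruit`, `uptake`, `ws`, plus the
#'   `config`.
#' @examples
#' cfg <- panel_config(collections = default_collections()[1, ] |>
#'   dplyr::mutate(n_genotypes = 5L, fruit_per_genotype = 3L), seed = 7)
#' panel <- generate_panel(cfg)
#' head(panel$fruit)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  pm <- pooled_latent_moments(config)
  rho <- config$ws_coupling %||% calibrated_coupling(config)
  if (rho != 0 && pm$v_between < 1e-12) {
    abort("A nonzero ws_coupling is infeasible when the latent log10-permeance has zero between-genotype variance.")
  }

  cc <- config$collections
  geno <- purrr::pmap_dfr(cc, function(collection, season, n_genotypes,
                                       fruit_per_genotype, log10_perm_mean,
                                       log10_perm_sd, mass_mean_g, mass_cv,
                                       tss_mean_brix, tss_sd) {
    sigma_b <- sqrt(config$between_frac) * log10_perm_sd
    sdlog <- sqrt(log(1 + mass_cv^2))
    tibble::tibble(
      collection = collection, season = season,
      fruit_per_genotype = fruit_per_genotype,
      log10_permeance = rnorm(n_genotypes, log10_perm_mean, sigma_b),
      sigma_w = sqrt(1 - config$between_frac) * log10_perm_sd,
      mass_g = stats::rlnorm(n_genotypes, log(mass_mean_g) - sdlog^2 / 2, sdlog),
      tss_brix = pmax(1, rnorm(n_genotypes, tss_mean_brix, tss_sd))
    )
  })
  geno$genotype <- sprintf("%s%s_g%03d", substr(geno$collection, 1, 1),
                           geno$season, seq_len(nrow(geno)))

  beta <- if (pm$v_between >= 1e-12) rho * config$severity_sd / sqrt(pm$v_between) else 0
  geno$severity <- config$severity_mean +
    beta * (geno$log10_permeance - pm$mu_bar) +
    rnorm(nrow(geno), 0, config$severity_sd * sqrt(1 - rho^2))
  sev_c <- pmin(pmax(geno$severity, 0.05), 3.95)
  geno$rate_per_h <- pmax(0.05, config$rate0 + config$rate_slope * sev_c)
  geno$asymptote <- 4
  geno$lag_h <- solve_gompertz_lag(sev_c, geno$rate_per_h,
                                   t = config$index_time_h, asymptote = 4)

  latents <- geno |>
    dplyr::select("genotype", "collection", "season", "log10_permeance",
                  "severity", "lag_h", "rate_per_h", "asymptote",
                  "mass_g", "tss_brix")

  # fruit level
  fruit <- geno |>
    dplyr::select("genotype", "collection", "season", "fruit_per_genotype",
                  "log10_permeance", "sigma_w", "severity", "lag_h",
                  "rate_per_h", "asymptote", "mass_g", "tss_brix") |>
    tidyr::uncount(.data$fruit_per_genotype, .id = "fruit_no") |>
    dplyr::mutate(
      fruit_id = sprintf("%s_f%02d", .data$genotype, .data$fruit_no),
      log10_perm_fruit = .data$log10_permeance + rnorm(dplyr::n(), 0, .data$sigma_w),
      permeance_true = 10^.data$log10_perm_fruit,
      mass_fruit_g = .data$mass_g *
        stats::rlnorm(dplyr::n(), -log(1 + config$mass_within_cv^2) / 2,
                      sqrt(log(1 + config$mass_within_cv^2))),
      tss_fruit = pmax(1, .data$tss_brix + rnorm(dplyr::n(), 0, config$tss_within_sd)),
      lag_fruit = pmax(0, .data$lag_h + rnorm(dplyr::n(), 0, config$lag_jitter_h)),
      rate_fruit = pmax(0.05, .data$rate_per_h + rnorm(dplyr::n(), 0, config$rate_jitter)),
      sev_fruit = pmin(pmax(.data$severity, 0.05), 3.95),
      firmness_score = pmin(3, pmax(1, round(1 + 0.45 * .data$sev_fruit +
                                               rnorm(dplyr::n(), 0, 0.6)))),
      achene_score = sample(1:3, dplyr::n(), replace = TRUE)
    )

  constants <- config$constants
  sched <- config$schedule_h
  n_t <- length(sched)

  uptake <- fruit |>
    dplyr::select("fruit_id", "permeance_true", "mass_fruit_g", "tss_fruit") |>
    tidyr::crossing(time_h = sched) |>
    dplyr::mutate(
      area_m2 = surface_area_from_mass(.data$mass_fruit_g) * 1e-4,
      dpsi_pa = -osmotic_potential_from_tss(.data$tss_fruit) * 1e6,
      flow = .data$permeance_true * .data$area_m2 * .data$dpsi_pa / constants$rt_over_rho_vw,
      mass_g = .data$mass_fruit_g + .data$flow * .data$time_h * 3600 * 1000 +
        rnorm(dplyr::n(), 0, config$weighing_noise_mg / 1000)
    ) |>
    dplyr::select("fruit_id", "time_h", "mass_g") |>
    dplyr::arrange(.data$fruit_id, .data$time_h)

  ws <- fruit |>
    dplyr::select("fruit_id", "asymptote", "lag_fruit", "rate_fruit") |>
    tidyr::crossing(time_h = sched) |>
    dplyr::mutate(rating = gompertz_value(.data$time_h, .data$asymptote,
                                          .data$lag_fruit, .data$rate_fruit)) |>
    dplyr::mutate(rating = if (config$discretize) pmin(4, pmax(0, round(.data$rating))) else .data$rating) |>
    dplyr::select("fruit_id", "time_h", "rating") |>
    dplyr::arrange(.data$fruit_id, .data$time_h)

  fruit_tbl <- fruit |>
    dplyr::transmute(
      fruit_id = .data$fruit_id, genotype = .data$genotype,
      collection = .data$collection, season = .data$season,
      mass_g = .data$mass_fruit_g, tss_brix = .data$tss_fruit,
      firmness_score = .data$firmness_score,
      achene_score = .data$achene_score,
      permeance_true = .data$permeance_true,
      lag_true = .data$lag_fruit, rate_true = .data$rate_fruit,
      asymptote_true = .data$asymptote
    )

  structure(list(latents = latents, fruit = fruit_tbl, uptake = uptake,
                 ws = ws, config = config, ws_coupling_used = rho),
            class = "ws_panel")
}

#' @export
print.ws_panel <- function(x, ...) {
  cat("Synthetic water-soaking genotype panel\n")
  cat(sprintf("  %d genotypes, %d fruit, seed %d, latent coupling %.3f\n",
              nrow(x$latents), nrow(x$fruit), x$config$seed, x$ws_coupling_used))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
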