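#' Fruit surface area from fresh mass
#'
#' Allometric power law for strawberry: `area_cm2 = 5.0756 * mass_g^0.6547`.
#' The exponent is below 1, so area grows sublinearly with mass (doubling
#' the mass less than doubles the area).
#'
#' @param mass_g Fruit fresh mass in grams; vectorised, must be >= 0.
#' @param coef,exponent Allometric coefficients; defaults are the calibrated
#'   strawberry values.
#' @param fruit_id Optional identifier(s) used in error messages.
#' @return Surface area in cm\eqn{^2}.
#' @examples
#' surface_area_from_mass(10) # ~22.92 cm^2
#' @export
surface_area_from_mass <- function(mass_g, coef = 5.0756, exponent = 0.6547,
                                   fruit_id = NULL) {
  bad <- !is.na(mass_g) & mass_g < 0
  if (any(bad)) {
    id <- if (!is.null(fruit_id)) paste0(" (fruit ", paste(unique(fruit_id[bad]), collapse = ", "), ")") else ""
    abort(paste0("Fruit mass must be non-negative", id, "."))
  }
  coef * mass_g^exponent
}

#' Osmotic potential of expressed juice from total soluble solids
#'
#' Cubic calibration from refractometer reading (degrees Brix) to the
#' osmotic potential of expressed strawberry juice (MPa):
#' \eqn{\Psi_\pi = -0.3292 - 0.0400\,TSS - 0.0088\,TSS^2 + 0.0002\,TSS^3}.
#' The polynomial is strictly decreasing (and always negative) on the
#' calibration range 0--25 Brix; values outside that range trigger a warning
#' because the cubic is not monotone far outside it.
#'
#' @param tss Total soluble solids, degrees Brix; vectorised, must be >= 0.
#' @return Osmotic potential in MPa (negative).
#' @examples
#' osmotic_potential_from_tss(10) # -1.4092 MPa
#' @export
osmotic_potential_from_tss <- function(tss) {
  if (any(!is.na(tss) & tss < 0)) {
    abort("TSS (degrees Brix) must be non-negative.")
  }
  if (any(!is.na(tss) & tss > 25)) {
    warn("TSS above 25 Brix is outside the calibration range of the osmotic-potential polynomial.")
  }
  -0.3292 - 0.0400 * tss - 0.0088 * tss^2 + 0.0002 * tss^3
}

#' Osmotic water uptake flow rate from a gravimetric time series
#'
#' Ordinary-least-squares slope of cumulative fruit mass (kg) against
#' elapsed time (s), with a free intercept. All weighings enter, including
#' the pre-immersion mass at t = 0 (blotting losses shift the level of the
#' series, not its slope).
#'
#' @param time_s Elapsed times in seconds, strictly increasing, length >= 2.
#' @param mass_kg Cumulative fruit masses in kg, strictly positive.
#' @param fruit_id Optional identifier used in error messages.
#' @return A list with `flow_rate` (kg s\eqn{^{-1}}) and `fit_r2`. With
#'   exactly two points the slope is the two-point difference quotient and
#'   `fit_r2` is 1.
#' @examples
#' fit_flow_rate(c(0, 7200), c(10, 10.05) / 1000 * 1000 / 1000)
#' @export
fit_flow_rate <- function(time_s, mass_kg, fruit_id = NULL) {
  id <- if (!is.null(fruit_id)) paste0(" (fruit ", fruit_id, ")") else ""
  if (length(time_s) < 2L) abort(paste0("Uptake series needs at least 2 weighings", id, "."))
  if (length(time_s) != length(mass_kg)) abort(paste0("time and mass differ in length", id, "."))
  if (any(diff(time_s) <= 0)) abort(paste0("Uptake times must be strictly increasing", id, "."))
  if (any(mass_kg <= 0)) abort(paste0("Fruit masses must be strictly positive", id, "."))
  fit <- lm(mass_kg ~ time_s)
  r2 <- if (length(time_s) == 2L) 1 else {
    tss <- sum((mass_kg - mean(mass_kg))^2)
    if (tss == 0) 1 else 1 - sum(resid(fit)^2) / tss
  }
  list(flow_rate = unname(coef(fit)[2L]), fit_r2 = r2)
}

#' Skin permeance for osmotic water uptake
#'
#' \eqn{P_f = F_f / (A \cdot \Delta\Psi) \cdot RT/(\rho \bar{V}_w)}, the
#' filtration permeability of the fruit skin. Permeance is linear in the
#' flow rate and inversely proportional to surface area and driving force,
#' so it is independent of fruit size and of juice osmotic potential.
#'
#' @param flow_rate Water uptake rate \eqn{F_f}, kg s\eqn{^{-1}}; vectorised.
#' @param area_m2 Fruit surface area, m\eqn{^2}; must be > 0.
#' @param delta_psi_mpa Positive water-potential gradient
#'   \eqn{\Delta\Psi = \Psi_{water} - \Psi_{fruit}}, MPa; must be > 0.
#' @param constants A [physical_constants()] object.
#' @return Permeance in m s\eqn{^{-1}}.
#' @examples
#' permeance(6.944e-9, 2.292e-3, 1) # ~4.09e-7 m/s
#' @export
permeance <- function(flow_rate, area_m2, delta_psi_mpa,
                      constants = physical_constants()) {
  if (any(!is.na(area_m2) & area_m2 <= 0)) abort("Surface area must be strictly positive.")
  if (any(!is.na(delta_psi_mpa) & delta_psi_mpa <= 0)) {
    abort("The water-potential gradient delta_psi must be strictly positive (fruit water potentials are negative, so the gradient toward pure water is positive).")
  }
  flow_rate / (area_m2 * delta_psi_mpa * 1e6) * constants$rt_over_rho_vw
}

#' Derive per-fruit biophysical uptake traits
#'
#' End-to-end conversion of raw records into derived traits: fits the
#' mass-versus-time regression per fruit, estimates surface area from the
#' pre-immersion mass, converts TSS to osmotic potential, and combines them
#' into flux density and skin permeance. Fruit turgor is taken as zero, so
#' the fruit water potential equals the juice osmotic potential and the
#' driving force is \eqn{\Delta\Psi = 0 - \Psi_\pi}.
#'
#' Fruits whose mass series decreases net over the assay get a negative
#' flow rate and permeance; they are flagged (`uptake_flag = "negative"`),
#' not dropped — osmotic water loss is physically possible — and are
#' excluded from log-permeance analyses downstream.
#'
#' @param fruit A data frame with one row per fruit: columns `fruit_id`,
#'   `genotype`, `collection`, `season` (any of the last three may be
#'   absent), `mass_g` (pre-immersion fresh mass), `tss_brix`.
#' @param uptake Long-format gravimetric series: columns `fruit_id`,
#'   `time_h`, `mass_g` (cumulative mass at each weighing).
#' @param constants A [physical_constants()] object; recorded in the
#'   result's `"constants"` attribute.
#' @return A tibble with one row per fruit: identifiers plus `area_cm2`,
#'   `area_m2`, `psi_pi_mpa`, `delta_psi_mpa`, `flow_rate_kg_s`,
#'   `flow_rate_mg_h`, `flux_kg_m2_s`, `permeance_m_s`, `uptake_r2`,
#'   `uptake_n`, `uptake_flag`.
#' @examples
#' fruit <- tibble::tibble(fruit_id = "f1", genotype = "G1",
#'                         mass_g = 10, tss_brix = 8)
#' uptake <- tibble::tibble(fruit_id = "f1", time_h = c(0, 2, 4, 6),
#'                          mass_g = 10 + 0.05 * c(0, 2, 4, 6))
#' derive_uptake(fruit, uptake)
#' @export
derive_uptake <- function(fruit, uptake, constants = physical_constants()) {
  req_f <- c("fruit_id", "mass_g", "tss_brix")
  req_u <- c("fruit_id", "time_h", "mass_g")
  miss <- setdiff(req_f, names(fruit))
  if (length(miss)) abort(paste0("fruit table is missing column(s): ", paste(miss, collapse = ", ")))
  miss <- setdiff(req_u, names(uptake))
  if (length(miss)) abort(paste0("uptake table is missing column(s): ", paste(miss, collapse = ", ")))
  orphans <- setdiff(unique(uptake$fruit_id), fruit$fruit_id)
  if (length(orphans)) {
    abort(paste0("uptake series reference unknown fruit: ", paste(head(orphans, 5), collapse = ", ")))
  }

  # grouped closed-form OLS slope; algebraically identical to lm() per fruit
  slopes <- uptake |>
    dplyr::mutate(time_s = .data$time_h * 3600, mass_kg = .data$mass_g / 1000) |>
    dplyr::group_by(.data$fruit_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      uptake_n = dplyr::n(),
      .span = max(.data$time_s) - min(.data$time_s),
      .sxx = sum((.data$time_s - mean(.data$time_s))^2),
      .sxy = sum((.data$time_s - mean(.data$time_s)) * (.data$mass_kg - mean(.data$mass_kg))),
      .syy = sum((.data$mass_kg - mean(.data$mass_kg))^2),
      .groups = "drop"
    )
  if (any(slopes$uptake_n < 2L)) {
    abort(paste0("Uptake series with fewer than 2 weighings for fruit: ",
                 paste(slopes$fruit_id[slopes$uptake_n < 2L], collapse = ", ")))
  }
  if (any(slopes$.span <= 0)) {
    abort(paste0("Zero time span in uptake series for fruit: ",
                 paste(slopes$fruit_id[slopes$.span <= 0], collapse = ", ")))
  }
  slopes <- slopes |>
    dplyr::mutate(
      flow_rate_kg_s = .data$.sxy / .data$.sxx,
      uptake_r2 = dplyr::if_else(.data$uptake_n == 2L | .data$.syy == 0,
                                 1, .data$.sxy^2 / (.data$.sxx * .data$.syy))
    ) |>
    dplyr::select("fruit_id", "flow_rate_kg_s", "uptake_r2", "uptake_n")

  id_cols <- intersect(c("fruit_id", "genotype", "collection", "season"), names(fruit))
  out <- fruit |>
    dplyr::select(dplyr::all_of(id_cols), "mass_g", "tss_brix") |>
    dplyr::left_join(slopes, by = "fruit_id") |>
    dplyr::mutate(
      area_cm2 = surface_area_from_mass(.data$mass_g, fruit_id = .data$fruit_id),
      area_m2 = .data$area_cm2 * 1e-4,
      psi_pi_mpa = osmotic_potential_from_tss(.data$tss_brix),
      delta_psi_mpa = 0 - .data$psi_pi_mpa,
      flux_kg_m2_s = .data$flow_rate_kg_s / .data$area_m2,
      permeance_m_s = permeance(.data$flow_rate_kg_s, .data$area_m2,
                                .data$delta_psi_mpa, constants),
      flow_rate_mg_h = .data$flow_rate_kg_s * 1e6 * 3600,
      uptake_flag = dplyr::case_when(
        is.na(.data$flow_rate_kg_s) ~ "no_series",
        .data$flow_rate_kg_s < 0 ~ "negative",
        TRUE ~ "ok"
      )
    ) |>
    tibble::as_tibble()
  attr(out, "constants") <- constants
  out
}
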