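test_that("surface-area power law matches an independent evaluation and its frozen values", {
  # independent oracle: evaluate the allometry on the log scale
  oracle <- function(m) ifelse(m == 0, 0, exp(log(5.0756) + 0.6547 * log(m)))
  set.seed(1)
  m <- c(0, 1, 10, runif(25, 0.2, 60))
  expect_equal(surface_area_from_mass(m), oracle(m), tolerance = 1e-12)

  expect_equal(surface_area_from_mass(1), 5.0756)
  expect_equal(surface_area_from_mass(0), 0)
  expect_equal(surface_area_from_mass(10), 22.91856326, tolerance = 1e-9)

  # exponent < 1: strictly increasing but sublinear on a log grid
  grid <- 10^seq(-1, 2, length.out = 40)
  a <- surface_area_from_mass(grid)
  expect_true(all(diff(a) > 0))
  expect_true(all(surface_area_from_mass(2 * grid) < 2 * a))

  expect_error(surface_area_from_mass(-1, fruit_id = "f9"), "f9")
})

test_that("osmotic-potential cubic matches its printed coefficients and is decreasing", {
  expect_equal(osmotic_potential_from_tss(0), -0.3292)
  expect_equal(osmotic_potential_from_tss(10), -1.4092)
  expect_equal(osmotic_potential_from_tss(5), -0.7242)

  # independent oracle via polynomial evaluation with Horner's scheme
  horner <- function(x) ((0.0002 * x - 0.0088) * x - 0.0400) * x - 0.3292
  tss <- seq(0, 25, by = 0.5)
  expect_equal(osmotic_potential_from_tss(tss), horner(tss), tolerance = 1e-14)

  # strictly decreasing and negative over the whole calibration grid
  fine <- osmotic_potential_from_tss(seq(0, 25, by = 0.1))
  expect_true(all(diff(fine) < 0))
  expect_true(all(fine < 0))

  expect_error(osmotic_potential_from_tss(-1))
  expect_warning(osmotic_potential_from_tss(30), "calibration range")
})

test_that("physical constants carry the expected water-uptake factor", {
  k <- physical_constants()
  expect_equal(k$rt_over_rho_vw, 1.35e5, tolerance = 0.01)
  expect_error(physical_constants(T_K = -1))
})

test_that("flow-rate regression recovers known slopes", {
  t_s <- c(0, 3600, 7200, 10800)
  f <- fit_flow_rate(t_s, 0.01 + 2.5e-9 * t_s)
  expect_equal(f$flow_rate, 2.5e-9, tolerance = 1e-12)
  expect_equal(f$fit_r2, 1)

  two <- fit_flow_rate(c(0, 7200), c(10, 10.05) / 1000)
  expect_equal(two$flow_rate, 0.05e-3 / 7200, tolerance = 1e-12)
  expect_equal(two$fit_r2, 1)

  expect_error(fit_flow_rate(0, 0.01), "at least 2")
  expect_error(fit_flow_rate(c(0, 0), c(0.01, 0.011)), "strictly increasing")
})

test_that("noisy flow-rate estimates fall within three analytic standard errors", {
  t_s <- c(0, 2, 4, 6) * 3600
  slope <- 3e-9
  sigma <- 1e-6 # 1 mg in kg
  se <- sigma / sqrt(sum((t_s - mean(t_s))^2))
  set.seed(7)
  hits <- replicate(1000, {
    m <- 0.012 + slope * t_s + rnorm(4, 0, sigma)
    abs(fit_flow_rate(t_s, m)$flow_rate - slope) < 3 * se
  })
  expect_gte(mean(hits), 0.99)
})

test_that("permeance reproduces the worked unit-conversion example and is homogeneous", {
  p <- permeance(6.944e-9, 2.292e-3, 1,
                 constants = physical_constants(R = 8.3145, T_K = 293.15,
                                                rho = 998.2, Vw = 1.807e-5))
  expect_equal(p, 4.094e-7, tolerance = 5e-4)

  expect_equal(permeance(0, 1e-3, 1), 0)
  base <- permeance(5e-9, 2e-3, 1.2)
  expect_equal(permeance(5e-9, 4e-3, 1.2), base / 2)
  # joint rescaling of flow and area leaves permeance unchanged
  for (c_scale in c(0.1, 3, 42)) {
    expect_equal(permeance(c_scale * 5e-9, c_scale * 2e-3, 1.2), base)
  }
  expect_error(permeance(1e-9, 0, 1), "positive")
  expect_error(permeance(1e-9, 1e-3, -0.5), "positive")
})

test_that("derive_uptake composes the chain with exact flux identity and sign flags", {
  fruit <- tibble::tibble(fruit_id = c("a", "b"), genotype = "G",
                          mass_g = c(10, 12), tss_brix = c(8, 9))
  uptake <- dplyr::bind_rows(
    generate_uptake_series(2e-6, 10, 8) |> dplyr::mutate(fruit_id = "a"),
    generate_uptake_series(-5e-7, 12, 9) |> dplyr::mutate(fruit_id = "b")
  )
  d <- derive_uptake(fruit, uptake)
  expect_equal(d$flux_kg_m2_s, d$flow_rate_kg_s / d$area_m2)
  expect_equal(d$delta_psi_mpa, -d$psi_pi_mpa)
  expect_true(all(d$delta_psi_mpa > 0))
  expect_identical(d$uptake_flag, c("ok", "negative"))
  expect_lt(abs(d$permeance_m_s[1] - 2e-6) / 2e-6, 1e-10)
  expect_lt(abs(d$permeance_m_s[2] + 5e-7) / 5e-7, 1e-10)
})

test_that("the grouped closed-form slope agrees with per-fruit lm fits", {
  set.seed(11)
  fruit <- tibble::tibble(fruit_id = paste0("f", 1:6), genotype = "G",
                          mass_g = runif(6, 5, 20), tss_brix = runif(6, 6, 10))
  uptake <- purrr::map_dfr(seq_len(6), function(i) {
    generate_uptake_series(runif(1, 5e-7, 4e-6), fruit$mass_g[i],
                           fruit$tss_brix[i], noise_sd_mg = 4) |>
      dplyr::mutate(fruit_id = fruit$fruit_id[i])
  })
  d <- derive_uptake(fruit, uptake)
  for (i in seq_len(6)) {
    u <- uptake[uptake$fruit_id == fruit$fruit_id[i], ]
    ref <- fit_flow_rate(u$time_h * 3600, u$mass_g / 1000)
    expect_equal(d$flow_rate_kg_s[i], ref$flow_rate, tolerance = 1e-12)
    expect_equal(d$uptake_r2[i], ref$fit_r2, tolerance = 1e-10)
  }
})

test_that("derive_uptake validates its inputs naming the offender", {
  fruit <- tibble::tibble(fruit_id = "a", genotype = "G", mass_g = 10, tss_brix = 8)
  expect_error(derive_uptake(fruit, tibble::tibble(fruit_id = "zz", time_h = 0:1,
                                                   mass_g = c(10, 10.1))), "zz")
  expect_error(derive_uptake(dplyr::select(fruit, -"tss_brix"),
                             tibble::tibble(fruit_id = "a", time_h = 0:1,
                                            mass_g = c(10, 10.1))), "tss_brix")
  expect_error(derive_uptake(fruit, tibble::tibble(fruit_id = "a", time_h = 0,
                                                   mass_g = 10)), "fewer than 2")
})

test_that("flux density is uncorrelated with surface area when permeance is size-independent", {
  # within the generative model permeance carries no size dependence, so
  # on a panel without deliberate collection-level co-variation of size
  # and permeance the genotype-level flux-area correlation hovers near
  # zero (the default multi-collection panel couples the two through the
  # small-but-permeable wild species, mirroring the weak pooled area
  # correlations of real panels)
  cols <- default_collections()[1, ]
  cols$n_genotypes <- 172L
  cols$fruit_per_genotype <- 6L
  hits <- vapply(1:20, function(s) {
    panel <- generate_panel(panel_config(collections = cols, seed = 3000 + s))
    d <- derive_uptake(panel$fruit, panel$uptake)
    g <- d |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(flux = mean(.data$flux_kg_m2_s),
                       area = mean(.data$area_cm2), .groups = "drop")
    abs(cor(g$flux, g$area)) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
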