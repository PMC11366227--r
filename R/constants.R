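#' Physical constants for the osmotic-uptake permeance calculation
#'
#' Bundles the constants entering the permeance relation
#' \eqn{P_f = F_f / (A \cdot \Delta\Psi) \cdot RT/(\rho \bar{V}_w)}.
#' The derived factor \eqn{RT/(\rho \bar{V}_w)} has units J kg\eqn{^{-1}}
#' and is about 1.35e5 at 20 degrees C.
#'
#' @param R Universal gas constant, m\eqn{^3} Pa mol\eqn{^{-1}} K\eqn{^{-1}}.
#' @param T_K Absolute temperature, K. Defaults to 293.15 K (20 degrees C,
#'   conventional lab temperature; the assay temperature is configurable).
#' @param rho Density of water, kg m\eqn{^{-3}}.
#' @param Vw Molar volume of water, m\eqn{^3} mol\eqn{^{-1}}.
#'
#' @return An object of class `physical_constants`: a named list with the
#'   four constants plus `rt_over_rho_vw`, the precomputed factor
#'   \eqn{RT/(\rho \bar{V}_w)} (J kg\eqn{^{-1}}).
#' @examples
#' physical_constants()
#' physical_constants(T_K = 298.15) # assay run at 25 C
#' @export
physical_constants <- function(R = 8.3145, T_K = 293.15, rho = 998.2,
                               Vw = 1.807e-5) {
  vals <- c(R = R, T_K = T_K, rho = rho, Vw = Vw)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All physical constants must be finite and strictly positive.")
  }
  out <- list(R = R, T_K = T_K, rho = rho, Vw = Vw,
              rt_over_rho_vw = R * T_K / (rho * Vw))
  class(out) <- "physical_constants"
  out
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants for osmotic water uptake\n")
  cat(sprintf("  R   = %g m^3 Pa mol^-1 K^-1\n", x$R))
  cat(sprintf("  T   = %g K\n", x$T_K))
  cat(sprintf("  rho = %g kg m^-3\n", x$rho))
  cat(sprintf("  Vw  = %g m^3 mol^-1\n", x$Vw))
  cat(sprintf("  RT/(rho Vw) = %.4g J kg^-1\n", x$rt_over_rho_vw))
  invisible(x)
}
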