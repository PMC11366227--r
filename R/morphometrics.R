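#' Strain release of a cuticle disc upon isolation
#'
#' Fractional shrinkage of an excised skin disc when the cuticular membrane
#' is enzymatically isolated and relaxes:
#' \eqn{100 (A_i - A_{CM}) / A_{CM}}, a proxy for the elastic strain held
#' in vivo. Negative values (the membrane expanded on isolation) are
#' physically unusual and worth flagging by the caller, but are returned
#' as-is.
#'
#' @param area_excised_mm2 Area of the disc as excised, \eqn{A_i}
#'   (mm\eqn{^2}); by convention the projected cross-section of the biopsy
#'   punch.
#' @param area_relaxed_mm2 Area of the flattened isolated membrane,
#'   \eqn{A_{CM}} (mm\eqn{^2}).
#' @return Strain release in percent; scale-invariant in the pair of areas.
#' @examples
#' strain_release(13, 10) # 30%
#' @export
strain_release <- function(area_excised_mm2, area_relaxed_mm2) {
  if (any(!is.na(area_excised_mm2) & area_excised_mm2 <= 0) ||
      any(!is.na(area_relaxed_mm2) & area_relaxed_mm2 <= 0)) {
    abort("Disc areas must be strictly positive.")
  }
  (area_excised_mm2 - area_relaxed_mm2) / area_relaxed_mm2 * 100
}

#' Achene depression depth from a silicone cast
#'
#' Field-friendly phenotyping: the achene depression is cast in silicone
#' and the cast measured under the microscope; a zero-intercept calibration
#' (depth = 1.19 x cast depth, r^2 = 0.98) converts to the true depression
#' depth.
#'
#' @param cast_depth_mm Cast depth, mm; >= 0.
#' @param slope Calibration slope; default 1.19.
#' @return Achene depression depth, mm.
#' @examples
#' achene_depth_from_cast(1.0) # 1.19 mm
#' @export
achene_depth_from_cast <- function(cast_depth_mm, slope = 1.19) {
  if (any(!is.na(cast_depth_mm) & cast_depth_mm < 0)) {
    abort("Cast depth must be non-negative.")
  }
  slope * cast_depth_mm
}

#' Surface area of a truncated-cone skin disc
#'
#' Area of an excised disc modelled as a frustum whose top is the circular
#' biopsy-punch cross-section and whose base (at the bottom of the achene
#' depression) may be elliptical; the ellipse is replaced by its
#' equal-area circle of radius \eqn{\sqrt{ab}}. The returned area is the
#' frustum's slant (lateral) surface plus the base disc:
#' \deqn{\pi r_b^2 + \pi (r_t + r_b) \sqrt{(r_t - r_b)^2 + d^2}.}
#' At zero depth with equal diameters this reduces to the flat punch disc
#' \eqn{\pi r^2}; with base = top it is the cylinder wall plus base.
#'
#' @param top_diam_mm Punch (top) diameter, mm.
#' @param base_major_mm,base_minor_mm Major and minor diameters of the
#'   elliptical base, mm. `base_minor_mm` defaults to `base_major_mm`
#'   (circular base).
#' @param depth_mm Depth of the depression, mm; >= 0.
#' @return Surface area, mm\eqn{^2}; always >= the flat disc area of the
#'   larger of top and base, with equality only in the flat limit.
#' @examples
#' truncated_cone_area(4, 4, depth_mm = 0) # flat 4-mm punch: ~12.57 mm^2
#' @export
truncated_cone_area <- function(top_diam_mm, base_major_mm,
                                base_minor_mm = base_major_mm, depth_mm = 0) {
  dims <- c(top_diam_mm, base_major_mm, base_minor_mm, depth_mm)
  if (any(!is.na(dims) & dims < 0)) abort("All disc dimensions must be non-negative.")
  r_top <- top_diam_mm / 2
  r_base <- sqrt(base_major_mm * base_minor_mm) / 2
  lateral <- pi * (r_top + r_base) * sqrt((r_top - r_base)^2 + depth_mm^2)
  pi * r_base^2 + lateral
}

#' Microcrack infiltrated-area percentage from a binary mask
#'
#' Microcracking is indexed as the percentage of the microscope field of
#' view infiltrated by the fluorescent tracer acridine orange. The mask is
#' consumed pre-thresholded: `TRUE` (or 1) marks infiltrated pixels.
#'
#' @param mask Logical or 0/1 numeric matrix (or vector); must be
#'   non-empty and strictly two-valued.
#' @return Percentage of `TRUE` pixels.
#' @examples
#' m <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
#' infiltrated_area_pct(m) # 25%
#' @export
infiltrated_area_pct <- function(mask) {
  if (length(mask) == 0L) abort("Microcrack mask is empty.")
  if (is.logical(mask)) {
    v <- mask
  } else if (is.numeric(mask) && all(mask %in% c(0, 1))) {
    v <- mask == 1
  } else {
    abort("Microcrack mask must be logical or strictly 0/1.")
  }
  if (anyNA(v)) abort("Microcrack mask contains missing pixels.")
  100 * sum(v) / length(v)
}

#' Read a single-channel image as a binary microcrack mask
#'
#' Convenience reader for PNG/TIFF masks: loads the first channel and
#' thresholds it. Thresholding of raw fluorescence images is
#' instrument-dependent and not authoritative here; masks should normally
#' arrive already binarised.
#'
#' @param path Path to a PNG or TIFF file.
#' @param threshold Intensity in \[0, 1\] above which a pixel counts as
#'   infiltrated; default 0.5.
#' @return Logical matrix.
#' @export
read_mask <- function(path, threshold = 0.5) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) abort("Reading PNG masks requires the 'png' package.")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("Reading TIFF masks requires the 'tiff' package.")
      tiff::readTIFF(path)
    },
    abort("Unsupported mask format; use PNG or TIFF.")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > threshold
}

#' Cuticle mass per unit area
#'
#' Converts disc masses to mass per unit fruit surface area. The wax load
#' is the difference between the cuticular membrane (CM) and the dewaxed
#' membrane (DCM) after solvent extraction.
#'
#' @param cm_mass_mg Dry mass of the cuticular membrane disc, mg.
#' @param dcm_mass_mg Dry mass of the dewaxed membrane, mg; must not
#'   exceed `cm_mass_mg`.
#' @param area_mm2 Area of the excised disc, mm\eqn{^2}.
#' @return A tibble with `cm_g_m2`, `dcm_g_m2`, `wax_g_m2`
#'   (g m\eqn{^{-2}}; mg/mm\eqn{^2} x 1000).
#' @examples
#' cuticle_mass_per_area(0.0063, 0.004, pi * 2^2)
#' @export
cuticle_mass_per_area <- function(cm_mass_mg, dcm_mass_mg, area_mm2) {
  if (any(!is.na(area_mm2) & area_mm2 <= 0)) abort("Disc area must be strictly positive.")
  if (any(!is.na(cm_mass_mg) & !is.na(dcm_mass_mg) & dcm_mass_mg > cm_mass_mg)) {
    abort("Dewaxed membrane mass cannot exceed the whole-membrane mass.")
  }
  tibble::tibble(
    cm_g_m2 = cm_mass_mg / area_mm2 * 1000,
    dcm_g_m2 = dcm_mass_mg / area_mm2 * 1000,
    wax_g_m2 = (cm_mass_mg - dcm_mass_mg) / area_mm2 * 1000
  )
}
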