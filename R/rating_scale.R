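#' Water-soaking rating score from percent surface area affected
#'
#' Five-point ordinal scale: 0 = no water soaking; 1 = <10% of the surface
#' water-soaked; 2 = 10 to <35%; 3 = 35 to 60%; 4 = >60%.
#'
#' @param pct Percent of fruit surface area water-soaked, in \[0, 100\];
#'   vectorised.
#' @return Integer score in 0..4.
#' @examples
#' rating_from_area_pct(c(0, 5, 10, 50, 70))
#' @export
rating_from_area_pct <- function(pct) {
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) {
    abort("Water-soaked area percentage must lie within [0, 100].")
  }
  dplyr::case_when(
    is.na(pct) ~ NA_integer_,
    pct == 0 ~ 0L,
    pct < 10 ~ 1L,
    pct < 35 ~ 2L,
    pct <= 60 ~ 3L,
    TRUE ~ 4L
  )
}

#' Representative percent area for a water-soaking score
#'
#' Inverse of [rating_from_area_pct()] at the bin midpoints: 0 -> 0%,
#' 1 -> 5%, 2 -> 22.5%, 3 -> 47.5%, 4 -> 80%. Used by the simulator and
#' for linear score/area checks; the round trip
#' `rating_from_area_pct(area_midpoint_from_rating(s)) == s` holds for all
#' scores.
#'
#' @param score Integer water-soaking score in 0..4; vectorised.
#' @return Percent surface area.
#' @export
area_midpoint_from_rating <- function(score) {
  if (any(!is.na(score) & (score %% 1 != 0 | score < 0 | score > 4))) {
    abort("Water-soaking score must be an integer in 0..4.")
  }
  mid <- c(0, 5, 22.5, 47.5, 80)
  mid[as.integer(score) + 1L]
}
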