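#' Convert a deviation angle in degrees to prism diopters
#'
#' Uses the standard orthoptic definition: one prism diopter displaces a
#' ray by 1 cm at 1 m, so PD = 100 * tan(angle). The conversion is odd
#' and sign-preserving; no small-angle approximation is used.
#'
#' @param angle_deg deviation angle(s) in degrees, |angle| < 90.
#' @return prism diopters, same sign as the input.
#' @export
#' @examples
#' deg_to_pd(1)     # 1.7455
#' deg_to_pd(-7.42) # -13.02
deg_to_pd <- function(angle_deg) {
  if (any(!is.finite(angle_deg)) || any(abs(angle_deg) >= 90)) {
    stop("`angle_deg` must be finite with |angle| < 90 degrees", call. = FALSE)
  }
  100 * tan(angle_deg * pi / 180)
}

#' Convert prism diopters to degrees
#'
#' Exact inverse of [deg_to_pd()]: angle = atan(pd / 100).
#'
#' @param pd prism diopter value(s), finite.
#' @return angle in degrees.
#' @export
pd_to_deg <- function(pd) {
  if (any(!is.finite(pd))) stop("`pd` must be finite", call. = FALSE)
  atan(pd / 100) * 180 / pi
}
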