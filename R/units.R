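#' Scaled clinical units
#'
#' Geometry is computed in millimetres; results are reported in the scaled
#' units conventional for pulmonary-artery morphometry: cross-sectional
#' areas in 100 mm^2, diameters in 10 mm, volumes in 1000 mm^3. Angles stay
#' in degrees. The published risk-score weights assume these scales, so the
#' conversion lives at the reporting boundary and nowhere else.
#'
#' @param x numeric value(s) in base units (mm^2, mm, mm^3).
#' @return value(s) in scaled units.
#' @examples
#' scale_area(615.75)    # mm^2 -> 100 mm^2
#' scale_length(28)      # mm   -> 10 mm
#' scale_volume(9424.8)  # mm^3 -> 1000 mm^3
#' @name scaled-units
NULL

#' @rdname scaled-units
#' @export
scale_area <- function(x) x / 100

#' @rdname scaled-units
#' @export
scale_length <- function(x) x / 10

#' @rdname scaled-units
#' @export
scale_volume <- function(x) x / 1000
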