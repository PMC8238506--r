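# Membrane-area geometry behind the AIS/soma area ratio alpha.

#' Surface area of a prolate spheroid
#'
#' Soma shape model: an ellipsoid of revolution with polar axis `length` and
#' equatorial diameter `width` (`length > width`).
#' Area = `2*pi*b^2 * (1 + (a/(b*e)) * asin(e))` with semi-axes `a = length/2`,
#' `b = width/2` and eccentricity `e = sqrt(1 - b^2/a^2)`.
#'
#' @param length Polar-axis length (um).
#' @param width Equatorial diameter (um).
#' @return Surface area in um^2.
#' @export
prolate_spheroid_area <- function(length, width) {
  stopifnot(length > 0, width > 0)
  if (length <= width) stop("prolate spheroid requires length > width")
  a <- length / 2
  b <- width / 2
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

#' Lateral surface area of a cylinder
#'
#' AIS shape model: an unmyelinated cylinder; only the lateral surface
#' carries membrane (`pi * diameter * length`).
#'
#' @param length Cylinder length (um).
#' @param diameter Cylinder diameter (um).
#' @return Lateral area in um^2.
#' @export
cylinder_lateral_area <- function(length, diameter) {
  stopifnot(length > 0, diameter > 0)
  pi * diameter * length
}

#' AIS/soma membrane-area ratio
#'
#' The area ratio `alpha` between the AIS compartment (cylinder) and the
#' soma compartment (prolate spheroid).  With the anatomical defaults
#' (soma 20.4 x 9.5 um, AIS 20 x 1 um) this evaluates to 0.12 (two decimals).
#'
#' @param soma_length,soma_width Soma spheroid dimensions (um).
#' @param ais_length,ais_diameter AIS cylinder dimensions (um).
#' @return The unitless area ratio.
#' @examples
#' round(ais_soma_area_ratio(), 2)   # 0.12
#' @export
ais_soma_area_ratio <- function(soma_length = 20.4, soma_width = 9.5,
                                ais_length = 20, ais_diameter = 1) {
  cylinder_lateral_area(ais_length, ais_diameter) /
    prolate_spheroid_area(soma_length, soma_width)
}
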