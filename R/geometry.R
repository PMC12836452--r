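#' Idealized spheroidal left-ventricle geometry
#'
#' Truncated prolate-spheroid wall bounded by endocardial and epicardial
#' surfaces of the form
#' \deqn{x(\theta,\phi) = (R \sin\theta \cos\phi,\; R \sin\theta \sin\phi,\;
#'   H (1 + \cos\theta))}
#' with \eqn{\theta} the polar angle (0 at the apex), \eqn{\phi} the azimuth.
#' The wall is truncated at \code{theta_max} (basal plane); with the default
#' \code{theta_max = pi/2} the apex sits at \eqn{z = 2H} and the base at
#' \eqn{z = H}, so the apex-to-base height equals \eqn{H}.  All lengths in mm.
#'
#' @param R_epi epicardial basal radius, mm
#' @param H_epi epicardial height parameter (apex-to-base height), mm
#' @param T_base basal wall thickness, mm
#' @param T_apex apical wall thickness parameter, mm
#' @param theta_max basal truncation polar angle, rad (0, pi]
#' @param scale uniform geometric scale factor (> 0)
#' @return object of class \code{lv_geometry_spec} with derived
#'   \code{R_endo = R_epi - T_base} and \code{H_endo = H_epi - T_apex}
#' @export
lv_geometry_spec <- function(R_epi = 2.72, H_epi = 5.92,
                             T_base = 0.67, T_apex = 0.77,
                             theta_max = pi / 2, scale = 1) {
  if (R_epi <= 0 || H_epi <= 0) stop("radii and heights must be > 0")
  if (T_base < 0 || T_apex < 0) stop("wall thicknesses must be >= 0")
  if (T_base >= R_epi || T_apex >= H_epi) stop("wall thicker than the chamber")
  if (theta_max <= 0 || theta_max > pi) stop("theta_max must be in (0, pi]")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(R_epi = R_epi, H_epi = H_epi,
                 R_endo = R_epi - T_base, H_endo = H_epi - T_apex,
                 T_base = T_base, T_apex = T_apex,
                 theta_max = theta_max, scale = scale),
            class = "lv_geometry_spec")
}

#' @export
print.lv_geometry_spec <- function(x, ...) {
  cat(sprintf("lv_geometry_spec: R_epi %.3g, R_endo %.3g, H_epi %.3g, H_endo %.3g mm; theta_max %.3g rad; scale %.4g\n",
              x$R_epi, x$R_endo, x$H_epi, x$H_endo, x$theta_max, x$scale))
  invisible(x)
}

#' Point on the epicardial surface
#'
#' Evaluates the epicardial surface parameterization at polar angle
#' \code{theta} and azimuth \code{phi} (vectorized), including the uniform
#' scale factor.
#'
#' @param theta polar angle, rad, in [0, pi]
#' @param phi azimuth, rad
#' @param spec \code{\link{lv_geometry_spec}}
#' @return matrix with one (x, y, z) row per input point, mm
#' @export
epicardial_surface_point <- function(theta, phi, spec) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  R <- spec$R_epi * spec$scale
  H <- spec$H_epi * spec$scale
  cbind(x = R * sin(theta) * cos(phi),
        y = R * sin(theta) * sin(phi),
        z = H * (1 + cos(theta)))
}

#' Point on the endocardial surface
#'
#' Companion of \code{\link{epicardial_surface_point}} using the endocardial
#' radius and height.
#'
#' @inheritParams epicardial_surface_point
#' @return matrix of (x, y, z) rows, mm
#' @export
endocardial_surface_point <- function(theta, phi, spec) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  R <- spec$R_endo * spec$scale
  H <- spec$H_endo * spec$scale
  cbind(x = R * sin(theta) * cos(phi),
        y = R * sin(theta) * sin(phi),
        z = H * (1 + cos(theta)))
}

# transmural blend map: s = 0 endocardium, s = 1 epicardium
wall_point <- function(theta, phi, s, spec) {
  (1 - s) * endocardial_surface_point(theta, phi, spec) +
    s * epicardial_surface_point(theta, phi, spec)
}

#' Closed-form cavity and wall volumes of the truncated spheroid
#'
#' The cavity (endocardial chamber above its basal truncation circle) is a
#' spheroidal cap: for \code{theta_max = pi/2} the upper half of an ellipsoid
#' with semi-axes (R_endo, R_endo, H_endo), volume \eqn{(2/3)\pi R^2 H}.  The
#' wall is the solid swept between the endocardial and epicardial surfaces by
#' the transmural blend \eqn{x(\theta,\phi,s) = (1-s) x_{endo} + s\,x_{epi}}
#' truncated at \code{theta_max}; its volume follows from the Jacobian of the
#' axisymmetric blend map,
#' \deqn{V = 2\pi \int_0^1\!\!\int_0^{\theta_{max}} \rho \sin\theta\,
#'   [\rho h' \cos\theta (1 + \cos\theta) + \rho' h \sin^2\theta]\,
#'   d\theta\, ds}
#' with \eqn{\rho(s), h(s)} the blended radius and height, integrated in
#' closed form.  Note the basal cut connects the two basal circles (which sit
#' at different heights, \eqn{z = H_{endo}} and \eqn{z = H_{epi}}), so the
#' wall volume is not the difference of the two caps.  Used as the
#' mesh-volume oracle.
#'
#' @param spec \code{\link{lv_geometry_spec}}
#' @return list with \code{cavity} and \code{wall} volumes, mm^3
#' @export
spheroid_volumes <- function(spec) {
  vol_cap <- function(R, H, tmax) {
    # V = int_{z(tmax)}^{2H} pi r(z)^2 dz with r^2 = R^2 (1 - (z/H - 1)^2),
    # substituting z = H(1 + t):  V = int_u^1 pi R^2 (1 - t^2) H dt
    u <- cos(tmax)
    pi * R^2 * H * ((1 - u) - (1 - u^3) / 3)
  }
  s3 <- spec$scale^3
  cavity <- vol_cap(spec$R_endo, spec$H_endo, spec$theta_max) * s3
  A <- spec$R_endo; B <- spec$T_base     # rho(s) = A + B s
  C <- spec$H_endo; D <- spec$T_apex     # h(s)  = C + D s
  u <- cos(spec$theta_max)
  I1 <- (1 - u^2) / 2 + (1 - u^3) / 3    # int sin cos (1 + cos)
  I2 <- (2 - 3 * u + u^3) / 3            # int sin^3
  wall <- 2 * pi * (D * (A^2 + A * B + B^2 / 3) * I1 +
                      B * (A * C + (A * D + B * C) / 2 + B * D / 3) * I2) * s3
  list(cavity = cavity, wall = wall)
}
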