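#' Passive material parameter set
#'
#' Fung-type transversely isotropic constitutive constants for one tissue
#' region.  The strain energy is
#' \deqn{W = c [\exp(Q(\bar E)) - 1] + \frac{K}{2}\left[\frac{J^2-1}{2} -
#'   \ln J\right]}
#' with \eqn{Q = B_1 \bar E_{11}^2 + B_2(\bar E_{22}^2 + \bar E_{33}^2 +
#' 2\bar E_{23}^2) + B_3(\bar E_{12}^2 + \bar E_{13}^2)} evaluated on the
#' deviatoric Green--Lagrange strain in the local fiber frame (axis 1 =
#' fiber).  \code{K} is a bulk penalty enforcing near-incompressibility.
#'
#' @param c_region stiffness scale, kPa (> 0)
#' @param B1,B2,B3 dimensionless anisotropy exponents (> 0)
#' @param K bulk penalty, kPa; defaults to \code{1000 * c_region}
#' @param region label, free text
#' @return object of class \code{passive_params}
#' @export
passive_params <- function(c_region, B1, B2, B3, K = 1000 * c_region,
                           region = "LV") {
  if (!is.numeric(c_region) || c_region <= 0) stop("c_region must be > 0")
  if (any(c(B1, B2, B3) <= 0)) stop("B1, B2, B3 must be > 0")
  if (K <= c_region) stop("K must greatly exceed c_region (near-incompressibility)")
  structure(list(c_region = c_region, B1 = B1, B2 = B2, B3 = B3, K = K,
                 region = region),
            class = "passive_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf("passive_params [%s]: c = %.4g kPa, B1 = %.4g, B2 = %.4g, B3 = %.4g, K = %.4g kPa\n",
              x$region, x$c_region, x$B1, x$B2, x$B3, x$K))
  invisible(x)
}

#' Active contraction parameters
#'
#' Peak calcium-induced active fiber stress and the linear Frank-Starling
#' modulation: active tension scales with the diastolic passive fiber stretch,
#' \eqn{T_a = T_{Ca} \max(0, 1 + s(\lambda_{dia} - \lambda_{ref}))}.
#'
#' @param T_Ca_peak peak calcium-induced active stress, kPa (>= 0)
#' @param fs_slope Frank-Starling slope per unit diastolic fiber stretch
#' @param ref_stretch reference diastolic fiber stretch (dimensionless); by
#'   convention the mean remote diastolic fiber stretch of a no-sleeve run
#' @return object of class \code{active_params}
#' @export
active_params <- function(T_Ca_peak, fs_slope = 2.0, ref_stretch = 1.0) {
  if (T_Ca_peak < 0) stop("T_Ca_peak must be >= 0")
  structure(list(T_Ca_peak = T_Ca_peak, fs_slope = fs_slope,
                 ref_stretch = ref_stretch),
            class = "active_params")
}

#' Pointwise deformation state
#'
#' Derived kinematic quantities at a material point: \code{J = det F}, the
#' deviatoric part \code{Fbar = J^(-1/3) F}, the Green--Lagrange strain
#' \code{E} and its deviatoric counterpart \code{Ebar} built from \code{Fbar}.
#'
#' @param F 3x3 deformation gradient with positive determinant
#' @return object of class \code{deformation_state}
#' @export
deformation_state <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("invalid deformation: det(F) <= 0")
  Fbar <- J^(-1 / 3) * F
  structure(list(F = F, J = J, Fbar = Fbar,
                 E = 0.5 * (crossprod(F) - diag(3)),
                 Ebar = 0.5 * (crossprod(Fbar) - diag(3))),
            class = "deformation_state")
}

#' Anisotropy quadratic form
#'
#' Evaluates \eqn{Q = B_1 \bar E_{11}^2 + B_2(\bar E_{22}^2 + \bar E_{33}^2 +
#' 2\bar E_{23}^2) + B_3(\bar E_{12}^2 + \bar E_{13}^2)} for a symmetric strain
#' tensor expressed in the local fiber-aligned orthonormal frame (axis 1 =
#' fiber).
#'
#' @param E_bar symmetric 3x3 strain tensor in the fiber frame
#' @param params \code{\link{passive_params}}
#' @return non-negative scalar
#' @export
q_form <- function(E_bar, params) {
  stopifnot(is.matrix(E_bar), all(dim(E_bar) == c(3, 3)))
  if (max(abs(E_bar - t(E_bar))) > 1e-10 * max(1, max(abs(E_bar))))
    stop("E_bar must be symmetric")
  # the transverse-shear strain enters through both symmetric components
  # (2 E23^2): with that counting Q is exactly invariant under rotations
  # about the fiber axis, i.e. the law is transversely isotropic and the
  # sheet/sheet-normal completion of the fiber direction is immaterial
  params$B1 * E_bar[1, 1]^2 +
    params$B2 * (E_bar[2, 2]^2 + E_bar[3, 3]^2 + 2 * E_bar[2, 3]^2) +
    params$B3 * (E_bar[1, 2]^2 + E_bar[1, 3]^2)
}

#' Strain-energy density
#'
#' Fung-type deviatoric energy plus volumetric penalty,
#' \eqn{W = c[\exp(Q(\bar E)) - 1] + (K/2)[(J^2 - 1)/2 - \ln J]}; zero at the
#' reference state.
#'
#' @param state \code{\link{deformation_state}} at a point
#' @param params \code{\link{passive_params}}
#' @param frame 3x3 orthonormal matrix whose columns are the fiber, sheet and
#'   sheet-normal directions (axis 1 = fiber); identity by default
#' @return energy density, kPa
#' @export
strain_energy <- function(state, params, frame = diag(3)) {
  stopifnot(inherits(state, "deformation_state"))
  Eh <- crossprod(frame, state$Ebar %*% frame)
  Eh <- 0.5 * (Eh + t(Eh))
  Q <- q_form(Eh, params)
  params$c_region * (exp(Q) - 1) +
    0.5 * params$K * (0.5 * (state$J^2 - 1) - log(state$J))
}

# orthonormal frame completing a unit fiber vector (transverse isotropy makes
# the in-plane choice immaterial)
fiber_frame <- function(fiber) {
  f <- fiber / sqrt(sum(fiber^2))
  h <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  s <- h - sum(h * f) * f
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2],
         f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])
  cbind(f, s, n, deparse.level = 0)
}

# fiber-frame second Piola-Kirchhoff stress conjugate to Ebar:
# Sbar = dW_dev/dEbar (as a symmetric tensor derivative)
sbar_fiber <- function(Eh, params) {
  Q <- q_form(Eh, params)
  G <- matrix(0, 3, 3)
  G[1, 1] <- 2 * params$B1 * Eh[1, 1]
  G[2, 2] <- 2 * params$B2 * Eh[2, 2]
  G[3, 3] <- 2 * params$B2 * Eh[3, 3]
  G[2, 3] <- G[3, 2] <- 2 * params$B2 * Eh[2, 3]
  G[1, 2] <- G[2, 1] <- params$B3 * Eh[1, 2]
  G[1, 3] <- G[3, 1] <- params$B3 * Eh[1, 3]
  params$c_region * exp(Q) * G
}

#' Passive Cauchy stress
#'
#' Assembles the passive Cauchy stress from the deviatoric push-forward and
#' volumetric pressure terms,
#' \deqn{T = \frac{1}{J}\,\mathrm{dev}[\bar F \bar S \bar F^T] +
#'   \frac{K}{2}\left(J - \frac{1}{J}\right) I}
#' with \eqn{\bar S = \partial W_{dev}/\partial \bar E}.  This is the exact
#' derivative of \code{\link{strain_energy}} with respect to the deformation,
#' verified against a finite-difference oracle in the test suite.
#'
#' @param state \code{\link{deformation_state}} at a point
#' @param params \code{\link{passive_params}}
#' @param fiber unit fiber direction (3-vector)
#' @return symmetric 3x3 Cauchy stress, kPa
#' @export
passive_cauchy_stress <- function(state, params, fiber) {
  if (abs(sqrt(sum(fiber^2)) - 1) > 1e-8) stop("fiber must be unit-norm")
  R <- fiber_frame(fiber)
  Eh <- crossprod(R, state$Ebar %*% R)
  Eh <- 0.5 * (Eh + t(Eh))
  Sbar <- R %*% sbar_fiber(Eh, params) %*% t(R)
  A <- state$Fbar %*% Sbar %*% t(state$Fbar)
  dev_A <- A - (sum(diag(A)) / 3) * diag(3)
  sigma <- dev_A / state$J +
    0.5 * params$K * (state$J - 1 / state$J) * diag(3)
  0.5 * (sigma + t(sigma))
}

#' Active second Piola-Kirchhoff stress
#'
#' Fiber-aligned rank-one active stress
#' \eqn{S_{act} = \frac{T_a}{2 E_{ff} + 1} N \otimes N}.  The push-forward to
#' Cauchy stress, \eqn{(1/J) F S_{act} F^T}, is handled by the solver.
#'
#' @param E_ff fiber-direction Green--Lagrange strain (dimensionless)
#' @param T_a active tension, kPa
#' @param fiber unit fiber direction N
#' @return symmetric 3x3 stress tensor, kPa
#' @export
active_second_pk <- function(E_ff, T_a, fiber) {
  den <- 2 * E_ff + 1
  if (den <= 0) stop("invalid fiber stretch: 2*E_ff + 1 <= 0")
  (T_a / den) * tcrossprod(fiber)
}

#' Frank-Starling modulation of active tension
#'
#' Linear length-dependent activation: \eqn{T_a = T_{Ca}\,\max(0, 1 +
#' s(\lambda_{dia} - \lambda_{ref}))}, clamped at zero so the active tension
#' is never negative.
#'
#' @param T_Ca calcium-induced tension, kPa (>= 0)
#' @param diastolic_fiber_stretch diastolic passive fiber stretch
#' @param params \code{\link{active_params}} (slope and reference stretch)
#' @return modulated active tension T_a, kPa
#' @export
frank_starling_Ta <- function(T_Ca, diastolic_fiber_stretch, params) {
  if (any(T_Ca < 0)) stop("T_Ca must be >= 0")
  T_Ca * pmax(0, 1 + params$fs_slope *
                   (diastolic_fiber_stretch - params$ref_stretch))
}

#' Sleeve stiffness from the stiffness ratio
#'
#' The sleeve shares the myocardial constitutive law; only its stiffness scale
#' differs, through the ratio \eqn{\zeta = c_{sleeve}/c_{LV}}.
#'
#' @param zeta stiffness ratio (> 0); continuum designs used
#'   \{1.0, 1.4, 2.0, 5.0\}, the auxetic design \{5, 10, 50\}
#' @param c_LV left-ventricular stiffness scale, kPa
#' @return c_sleeve, kPa
#' @export
sleeve_stiffness <- function(zeta, c_LV) {
  if (!is.numeric(zeta) || zeta <= 0) stop("zeta must be > 0")
  zeta * c_LV
}

#' Named passive material presets
#'
#' Region-specific stiffness scales estimated for a post-infarction rat heart
#' (inverse problem against in-vivo pressure-volume data), with shared
#' anisotropy exponents.
#'
#' @param region one of \code{"LV"}, \code{"RV"}, \code{"infarct"}
#' @param K_factor bulk penalty as a multiple of \code{c_region}
#' @return \code{\link{passive_params}}
#' @export
preset_materials <- function(region = c("LV", "RV", "infarct"),
                             K_factor = 1000) {
  region <- match.arg(region)
  c_region <- switch(region, LV = 0.416, RV = 0.297, infarct = 0.649)
  passive_params(c_region, B1 = 47.15, B2 = 22.55, B3 = 24.60,
                 K = K_factor * c_region, region = region)
}
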