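# Organ-level and regional post-processing: pressure-volume metrics, fiber
# strain fields and regional summaries, ventricular torsion, infarct
# displacement / bulging, and the effective Poisson ratio of lattice panels.

#' Pressure-volume metrics
#'
#' End-diastolic and end-systolic volumes from the cycle volume trace
#' (ED = maximum, ES = minimum), stroke volume \code{SV = EDV - ESV} and
#' ejection fraction \code{EF = 100 SV / EDV}.
#'
#' @param result \code{\link{run_cardiac_cycle}} result, or a list with a
#'   numeric \code{V} (mm^3)
#' @return object of class \code{pv_metrics} with volumes in mL
#' @export
pv_metrics <- function(result) {
  V <- result$V
  if (!length(V) || max(V) <= 0) stop("non-positive end-diastolic volume")
  EDV <- max(V) / 1000; ESV <- min(V) / 1000
  structure(list(EDV = EDV, ESV = ESV, SV = EDV - ESV,
                 EF = 100 * (EDV - ESV) / EDV),
            class = "pv_metrics")
}

#' @export
print.pv_metrics <- function(x, ...) {
  cat(sprintf("pv_metrics: EDV %.4f mL, ESV %.4f mL, SV %.4f mL, EF %.1f%%\n",
              x$EDV, x$ESV, x$SV, x$EF))
  invisible(x)
}

#' Per-element fiber strain field
#'
#' Volume-averaged Green--Lagrange fiber strain \eqn{E_{ff} = N \cdot E N}
#' per element for a displacement state.
#'
#' @param mesh \code{\link{lv_mesh}} with fibers assigned
#' @param u displacement vector (full dofs)
#' @return numeric vector, one value per element
#' @export
fiber_strain_field <- function(mesh, u) {
  if (is.null(mesh$fibers)) stop("mesh has no fiber field")
  ne <- nrow(mesh$elems)
  dummy <- matrix(1, ne, 5)  # kinematic extraction; material constants unused
  fl <- fe_fields(mesh$nodes, mesh$elems - 1L, u, dummy,
                  mesh$fibers$frames, numeric(ne))
  as.numeric(fl$Eff)
}

#' Regional field summary
#'
#' Volume-weighted mean, standard deviation, minimum and maximum of a
#' per-element field for each region label.  Empty regions are absent from
#' the output (not reported as zero).
#'
#' @param field per-element numeric vector
#' @param mesh \code{\link{lv_mesh}} (labels and element volumes)
#' @return data frame with one row per non-empty region
#' @export
regional_summary <- function(field, mesh) {
  stopifnot(length(field) == nrow(mesh$elems))
  w <- mesh$meta$elem_vol
  out <- NULL
  for (rn in sort(unique(mesh$region))) {
    idx <- mesh$region == rn
    if (!any(idx)) next
    wi <- w[idx]; xi <- field[idx]
    mu <- sum(wi * xi) / sum(wi)
    sdv <- sqrt(sum(wi * (xi - mu)^2) / sum(wi))
    out <- rbind(out, data.frame(region = rn, mean = mu, sd = sdv,
                                 min = min(xi), max = max(xi),
                                 volume = sum(wi)))
  }
  out
}

#' Ventricular torsion
#'
#' Relative rotation of an apical slice with respect to a mid-basal slice
#' about the long axis, \eqn{\theta_{torsion} = \theta_{apex} -
#' \theta_{base}}.  The mid-basal slice sits at 20% of the LV height below
#' the base, the apical slice at 20% above the anatomical apex; each slice
#' rotation is the volume-weighted mean angular displacement (atan2-based,
#' unwrapped) of wall nodes in a band around the slice height.
#'
#' @param result \code{\link{run_cardiac_cycle}} result (or a list with
#'   \code{mesh} and \code{states})
#' @param base_fraction,apex_fraction slice locations as fractions of LV
#'   height from base and apex
#' @param band_half band half-width as a fraction of LV height
#' @return data frame (class \code{torsion_result}): time,
#'   \code{theta_base}, \code{theta_apex}, \code{theta_torsion} in degrees
#' @export
torsion <- function(result, base_fraction = 0.20, apex_fraction = 0.20,
                    band_half = 0.05) {
  mesh <- result$mesh
  states <- result$states
  if (is.null(states)) stop("cycle was run without stored states")
  wall_elems <- mesh$region %in% c("remote", "infarct")
  wall_nodes <- sort(unique(as.vector(mesh$elems[wall_elems, ])))
  z <- mesh$nodes[wall_nodes, 3]
  z_apex <- max(z)
  z_base <- mean(mesh$nodes[unique(as.vector(mesh$facets$basal_plane)), 3])
  L <- z_apex - z_base
  # nodal volume weights
  wnode <- numeric(nrow(mesh$nodes))
  ev <- mesh$meta$elem_vol[wall_elems]
  el <- mesh$elems[wall_elems, , drop = FALSE]
  for (cidx in 1:10) wnode[el[, cidx]] <- wnode[el[, cidx]] + ev / 10
  r_xy <- sqrt(mesh$nodes[wall_nodes, 1]^2 + mesh$nodes[wall_nodes, 2]^2)
  slice_nodes <- function(zc) {
    # nodes on the long axis carry no angular information and are excluded
    idx <- wall_nodes[abs(z - zc) <= band_half * L & r_xy > 1e-9 * L]
    if (!length(idx))
      stop("empty slice band; widen band_half or refine the mesh")
    idx
  }
  nb <- slice_nodes(z_base + base_fraction * L)
  na_ <- slice_nodes(z_apex - apex_fraction * L)
  zc_of <- function(idx)
    sum(wnode[idx] * mesh$nodes[idx, 3]) / sum(wnode[idx])
  rot_of <- function(idx, u) {
    x0 <- mesh$nodes[idx, 1]; y0 <- mesh$nodes[idx, 2]
    x1 <- x0 + u[3 * (idx - 1) + 1]; y1 <- y0 + u[3 * (idx - 1) + 2]
    dpsi <- atan2(x0 * y1 - y0 * x1, x0 * x1 + y0 * y1)
    sum(wnode[idx] * dpsi) / sum(wnode[idx]) * 180 / pi
  }
  tb <- vapply(states, function(u) rot_of(nb, u), 0)
  ta <- vapply(states, function(u) rot_of(na_, u), 0)
  structure(data.frame(time = result$time, theta_base = tb, theta_apex = ta,
                       theta_torsion = ta - tb),
            class = c("torsion_result", "data.frame"),
            slices = list(base_fraction = base_fraction,
                          apex_fraction = apex_fraction,
                          band_half = band_half, L = L,
                          z_base = z_base, z_apex = z_apex,
                          z_mean_base = zc_of(nb), z_mean_apex = zc_of(na_)))
}

#' Infarct displacement statistics
#'
#' Per-element mean displacement of the infarct region in the long-axis
#' frame of the surface parameterization (z increases from the basal plane
#' towards the apex): the axial component \eqn{\Delta z}, the outward radial
#' component (bulging proxy), the fraction of elements with positive
#' \eqn{\Delta z} (longitudinal elevation), and the maximum outward radial
#' displacement.
#'
#' @param mesh \code{\link{lv_mesh}} with an infarct region
#' @param u displacement vector at the analysis time (typically ES)
#' @return list with per-element components and scalar summaries
#' @export
infarct_displacement <- function(mesh, u) {
  idx <- which(mesh$region == "infarct")
  if (!length(idx)) stop("no infarct elements in the mesh")
  um <- matrix(u, ncol = 3, byrow = TRUE)
  dz <- numeric(length(idx)); dr <- numeric(length(idx))
  for (k in seq_along(idx)) {
    nn <- mesh$elems[idx[k], ]
    du <- colMeans(um[nn, , drop = FALSE])
    ctr <- colMeans(mesh$nodes[nn, , drop = FALSE])
    r0 <- sqrt(ctr[1]^2 + ctr[2]^2)
    er <- c(ctr[1], ctr[2], 0) / max(r0, 1e-12)
    dz[k] <- du[3]
    dr[k] <- sum(du[1:2] * er[1:2])
  }
  list(element = idx, dz = dz, dr = dr,
       fraction_positive_dz = mean(dz > 0),
       mean_dz = mean(dz),
       max_outward_radial = max(dr))
}

#' Effective Poisson ratio of a panel
#'
#' Uniaxial stretch test of a flat specimen: the panel is extruded to its
#' design thickness, one end is clamped axially, the other is displaced to
#' the prescribed axial strain with lateral edges traction-free, and the
#' lateral strain is measured from the width change of the central gauge
#' region; \eqn{\nu = -\varepsilon_{lat}/\varepsilon_{ax}}.
#'
#' @param panel \code{\link{panel_mesh}} (auxetic tiling or
#'   \code{solid_panel} control sheet)
#' @param materials \code{\link{passive_params}} for the specimen
#' @param axial_strain prescribed strain (nonzero; default 0.05)
#' @param thickness out-of-plane thickness, mm (defaults to the cell spec)
#' @param fiber_angle_deg fiber angle from the stretch axis
#' @param n_steps displacement sub-steps
#' @return object of class \code{lattice_test_result}: \code{nu},
#'   \code{eps_ax}, \code{eps_lat} and the deformed state
#' @export
lattice_poisson_ratio <- function(panel, materials, axial_strain = 0.05,
                                  thickness = NULL, fiber_angle_deg = 0,
                                  n_steps = 20) {
  if (axial_strain == 0) stop("axial strain must be nonzero")
  t <- thickness %||% panel$spec$t %||% 0.16
  surface <- list(nodes3d = cbind(panel$nodes, 0), tris = panel$tris,
                  normals = matrix(rep(c(0, 0, 1), each = nrow(panel$nodes)),
                                   ncol = 3))
  ext <- extrude_sleeve(surface, t, n_layers = 1)
  nodes <- ext$nodes; elems <- ext$elems
  ne <- nrow(elems)
  a <- fiber_angle_deg * pi / 180
  f <- c(cos(a), sin(a), 0); s2 <- c(-sin(a), cos(a), 0); n2 <- c(0, 0, 1)
  frames <- matrix(rep(c(f, s2, n2), each = ne), nrow = ne)
  matpar <- matrix(rep(c(materials$c_region, materials$B1, materials$B2,
                         materials$B3, materials$K), each = ne), nrow = ne)

  xr <- range(nodes[, 1]); Lx <- diff(xr)
  tolx <- 0.04 * Lx          # grip bands at both ends
  left <- which(nodes[, 1] < xr[1] + tolx)
  right <- which(nodes[, 1] > xr[2] - tolx)
  if (!length(left) || !length(right)) stop("specimen ends not found")
  ymid <- mean(range(nodes[, 2]))
  pick <- function(cand) cand[order(abs(nodes[cand, 2] - ymid))][1]
  nyL <- pick(left); nyR <- pick(right)
  zfix <- c(left[order(abs(nodes[left, 2] - ymid))][1:2],
            right[order(abs(nodes[right, 2] - ymid))][1])
  fixed <- c(3 * (left - 1) + 1, 3 * (right - 1) + 1,
             3 * (nyL - 1) + 2, 3 * (nyR - 1) + 2,
             3 * (zfix - 1) + 3)
  ndof <- 3 * nrow(nodes)
  Tm <- constraint_transform(ndof, sort(unique(fixed)), list())
  sys <- list(mesh = list(nodes = nodes, elems = elems),
              matpar = matpar, frames = frames,
              endo_facets = matrix(0L, 0, 6),
              active = NULL, lambda_dia = NULL,
              region_activation = c(remote = 1),
              T = Tm,
              f_floor = 1e-3 * materials$c_region * ext$vol^(2 / 3),
              cache = new.env(parent = emptyenv()))
  sys$mesh$region <- rep("remote", ne)

  # adaptive displacement stepping: the rotating-unit mechanism traverses
  # large hinge rotations, so failed increments are retried at half size
  u <- numeric(ndof)
  eps_done <- 0
  deps <- axial_strain / n_steps
  while (abs(eps_done - axial_strain) > 1e-12 * abs(axial_strain)) {
    eps_try <- if (axial_strain > 0) min(eps_done + deps, axial_strain)
      else max(eps_done + deps, axial_strain)
    u_try <- u
    u_try[3 * (right - 1) + 1] <- eps_try * Lx   # rigid grip band
    res <- newton_increment(sys, u_try, 0, numeric(ne), tol = 1e-8,
                            max_iter = 15, verbose = FALSE)
    if (res$converged) {
      u <- res$u
      eps_done <- eps_try
      if (res$iters <= 5) deps <- deps * 1.5
    } else {
      deps <- deps / 2
      if (abs(deps) < abs(axial_strain) / 2048)
        stop("lattice test failed to converge")
    }
  }

  # gauge region: central third in x; width from the mean lateral position
  # of the outermost material fringes
  yr <- range(nodes[, 2]); Ly <- diff(yr)
  gauge <- abs(nodes[, 1] - mean(xr)) < Lx / 6
  topg <- which(gauge & nodes[, 2] > yr[2] - 0.08 * Ly)
  botg <- which(gauge & nodes[, 2] < yr[1] + 0.08 * Ly)
  if (!length(topg) || !length(botg)) stop("gauge fringe nodes not found")
  w_ref <- mean(nodes[topg, 2]) - mean(nodes[botg, 2])
  w_def <- mean(nodes[topg, 2] + u[3 * (topg - 1) + 2]) -
    mean(nodes[botg, 2] + u[3 * (botg - 1) + 2])
  eps_lat <- (w_def - w_ref) / w_ref
  structure(list(nu = -eps_lat / axial_strain, eps_ax = axial_strain,
                 eps_lat = eps_lat, u = u, nodes = nodes, elems = elems),
            class = "lattice_test_result")
}
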