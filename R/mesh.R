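# Structured quadratic-tetrahedral mesh of the truncated spheroidal LV wall.
#
# The wall is gridded in parameter space (theta, phi, s) with s the
# normalized transmural coordinate (0 = endocardium, 1 = epicardium); the
# (theta, phi) shell is triangulated (pole fan + quads split along the
# diagonal through the smallest global node id), extruded into prisms through
# the transmural layers, and each prism is split into three tetrahedra with
# the same smallest-vertex diagonal rule, which makes the decomposition
# conforming across all shared faces.  Midside nodes are generated at
# parameter-space edge midpoints and mapped through the exact surface blend,
# so elements are curved and surface volumes converge fast.

# split prisms (P x 6 global ids, bottom 1:3 / top 4:6) into 3 tets each,
# diagonals through the smallest node id on every quad face
prisms_to_tets <- function(pr) {
  nt <- nrow(pr)
  out <- matrix(0L, 3 * nt, 4)
  rot <- function(v, r) c(v[1 + (r %% 3)], v[1 + ((r + 1) %% 3)],
                          v[1 + ((r + 2) %% 3)])
  for (i in seq_len(nt)) {
    v <- pr[i, ]
    im <- which.min(v)
    if (im > 3) {
      # orientation-preserving top/bottom flip: (b1 b2 b3 | t1 t2 t3) ->
      # (t1 t3 t2 | b1 b3 b2)
      v <- c(v[4], v[6], v[5], v[1], v[3], v[2])
      im <- which.min(v)
    }
    r <- im - 1
    v <- c(rot(v[1:3], r), rot(v[4:6], r))
    q <- if (min(v[2], v[6]) < min(v[3], v[5])) {
      rbind(c(v[1], v[2], v[3], v[6]),
            c(v[1], v[2], v[6], v[5]),
            c(v[1], v[5], v[6], v[4]))
    } else {
      rbind(c(v[1], v[2], v[3], v[5]),
            c(v[1], v[5], v[3], v[6]),
            c(v[1], v[5], v[6], v[4]))
    }
    out[(3 * i - 2):(3 * i), ] <- q
  }
  out
}

# signed volumes of linear (corner) tets
corner_tet_volume <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
     b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
     b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# flip negatively oriented tets (swap vertices 3 and 4)
orient_tets <- function(nodes, tets) {
  v <- corner_tet_volume(nodes, tets)
  bad <- which(v < 0)
  if (length(bad)) {
    tmp <- tets[bad, 3]
    tets[bad, 3] <- tets[bad, 4]
    tets[bad, 4] <- tmp
  }
  tets
}

# VTK tet10 edge list: midside columns 5:10 are midpoints of these pairs
TET_EDGES <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))

# promote tet4 connectivity to tet10; midpos(n1, n2) returns midside
# coordinates (and optionally params) for vectors of endpoint ids
quadratize_tets <- function(tets4, nnode, midpos) {
  e1 <- c(tets4[, TET_EDGES[, 1]])
  e2 <- c(tets4[, TET_EDGES[, 2]])
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  key <- as.numeric(lo) * (nnode + 1) + as.numeric(hi)
  uk <- !duplicated(key)
  ukey <- key[uk]
  mid_id <- nnode + match(key, ukey)
  elems <- cbind(tets4, matrix(mid_id, nrow(tets4), 6))
  mp <- midpos(lo[uk], hi[uk])
  list(elems = elems, mid_coords = mp$coords, mid_param = mp$param,
       edge_key = ukey, edge_mid = nnode + seq_along(ukey),
       edge_lo = lo[uk], edge_hi = hi[uk])
}

# lookup midside node of an edge (vectors n1, n2) via the stored edge map
edge_midnode <- function(mesh, n1, n2) {
  key <- as.numeric(pmin(n1, n2)) * (mesh$meta$nnode_key + 1) +
    as.numeric(pmax(n1, n2))
  mesh$meta$edge_mid[match(key, mesh$meta$edge_key)]
}

# mean azimuth with wrap handling; phi may be NA on the axis
mid_phi <- function(p1, p2) {
  out <- ifelse(is.na(p1), p2, ifelse(is.na(p2), p1,
                atan2(sin(p1) + sin(p2), cos(p1) + cos(p2))))
  ifelse(is.na(out), 0, out)
}

#' Build the spheroidal LV wall mesh
#'
#' Structured quadratic-tetrahedral mesh of the wall between the endocardial
#' and epicardial spheroids, truncated at \code{theta_max}.  Midside nodes
#' are placed at parameter-space midpoints and mapped through the exact
#' surface blend, so boundary facets are curved.  Facet sets
#' (\code{endocardium}, \code{epicardium}, \code{basal_plane}) are tagged and
#' the endocardial set is closed by the basal cap when computing cavity
#' volumes.
#'
#' @param spec \code{\link{lv_geometry_spec}}
#' @param target_edge_length optional target element edge length, mm; when
#'   given, the grid resolution is derived from the surface arc lengths.
#'   Must be positive and below twice the minimum wall thickness.
#' @param n_theta,n_phi,n_layers explicit grid resolution (polar rings,
#'   azimuthal divisions, transmural layers); ignored when
#'   \code{target_edge_length} is given
#' @return object of class \code{lv_mesh}
#' @export
build_lv_mesh <- function(spec, target_edge_length = NULL,
                          n_theta = 6, n_phi = 12, n_layers = 2) {
  stopifnot(inherits(spec, "lv_geometry_spec"))
  if (spec$T_base <= 0 && spec$T_apex <= 0)
    stop("degenerate geometry: zero-thickness wall cannot be meshed")
  wall_min <- min(spec$T_base, spec$T_apex)
  if (wall_min <= 0)
    stop("degenerate geometry: wall thickness vanishes at base or apex")
  if (!is.null(target_edge_length)) {
    h <- target_edge_length
    if (h <= 0) stop("target_edge_length must be > 0")
    if (h >= 2 * wall_min * spec$scale)
      stop("target_edge_length too coarse for the wall thickness")
    arc_theta <- spec$theta_max *
      sqrt((spec$R_epi^2 + spec$H_epi^2) / 2) * spec$scale
    n_theta <- max(3L, as.integer(round(arc_theta / h)))
    n_phi <- max(6L, as.integer(round(2 * pi * spec$R_epi * spec$scale / h)))
    n_layers <- max(1L, as.integer(round(spec$T_base * spec$scale / h)))
  }
  n_phi <- max(6L, as.integer(n_phi))
  n_theta <- max(2L, as.integer(n_theta))
  n_layers <- max(1L, as.integer(n_layers))

  theta <- seq(0, spec$theta_max, length.out = n_theta + 1)
  svals <- seq(0, 1, length.out = n_layers + 1)
  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi

  # node numbering: pole nodes (one per layer), then ring nodes (j, k, l)
  n_pole <- n_layers + 1
  ring_id <- function(j, k, l) {
    n_pole + ((l) * n_theta + (j - 1)) * n_phi + (k %% n_phi) + 1
  }
  nnode <- n_pole + n_theta * n_phi * (n_layers + 1)
  param <- matrix(NA_real_, nnode, 3)
  colnames(param) <- c("theta", "phi", "s")
  for (l in 0:n_layers) param[l + 1, ] <- c(0, NA, svals[l + 1])
  for (l in 0:n_layers) for (j in 1:n_theta) for (k in 0:(n_phi - 1))
    param[ring_id(j, k, l), ] <- c(theta[j + 1], phi[k + 1], svals[l + 1])
  nodes <- wall_point(param[, 1], ifelse(is.na(param[, 2]), 0, param[, 2]),
                      param[, 3], spec)
  dimnames(nodes) <- NULL

  # shell triangulation in (j, k): pole fan plus quads, the quad diagonal
  # chosen once (from layer-0 ids) so every layer stacks conformally
  quad_tris <- list()
  if (n_theta >= 2) {
    for (j in 1:(n_theta - 1)) for (k in 0:(n_phi - 1)) {
      A <- ring_id(j, k, 0); B <- ring_id(j + 1, k, 0)
      C <- ring_id(j + 1, k + 1, 0); D <- ring_id(j, k + 1, 0)
      if (min(A, C) < min(B, D)) {
        quad_tris <- c(quad_tris, list(c(j, k, 1L), c(j, k, 2L)))
      } else {
        quad_tris <- c(quad_tris, list(c(j, k, 3L), c(j, k, 4L)))
      }
    }
  }

  # prisms
  prisms <- list()
  for (l in 0:(n_layers - 1)) {
    for (k in 0:(n_phi - 1)) {
      prisms[[length(prisms) + 1]] <-
        c(l + 1, ring_id(1, k, l), ring_id(1, k + 1, l),
          l + 2, ring_id(1, k, l + 1), ring_id(1, k + 1, l + 1))
    }
    for (q in quad_tris) {
      j <- q[1]; k <- q[2]; typ <- q[3]
      tri <- switch(typ,
        c(ring_id(j, k, l), ring_id(j + 1, k, l), ring_id(j + 1, k + 1, l)),
        c(ring_id(j, k, l), ring_id(j + 1, k + 1, l), ring_id(j, k + 1, l)),
        c(ring_id(j, k, l), ring_id(j + 1, k, l), ring_id(j, k + 1, l)),
        c(ring_id(j + 1, k, l), ring_id(j + 1, k + 1, l), ring_id(j, k + 1, l)))
      up <- tri + (n_theta * n_phi)  # next layer ring ids differ by stride
      prisms[[length(prisms) + 1]] <- c(tri, up)
    }
  }
  pr <- do.call(rbind, prisms)
  tets4 <- prisms_to_tets(pr)
  tets4 <- orient_tets(nodes, tets4)

  # quadratic midside nodes at parameter-space midpoints
  midpos <- function(n1, n2) {
    th <- (param[n1, 1] + param[n2, 1]) / 2
    ph <- mid_phi(param[n1, 2], param[n2, 2])
    ss <- (param[n1, 3] + param[n2, 3]) / 2
    list(coords = wall_point(th, ph, ss, spec), param = cbind(th, ph, ss))
  }
  qz <- quadratize_tets(tets4, nnode, midpos)
  mid_coords <- qz$mid_coords
  dimnames(mid_coords) <- NULL
  nodes <- rbind(nodes, mid_coords)
  param <- rbind(param, qz$mid_param)
  elems <- qz$elems

  mesh <- structure(list(
    nodes = nodes, param = param, elems = elems,
    region = rep("remote", nrow(elems)),
    spec = spec,
    meta = list(n_theta = n_theta, n_phi = n_phi, n_layers = n_layers,
                nnode_key = nnode, edge_key = qz$edge_key,
                edge_mid = qz$edge_mid, n_wall_elems = nrow(elems))
  ), class = "lv_mesh")

  mesh$elem_param <- elem_param_centroids(mesh)
  mesh <- extract_wall_facets(mesh)
  vq <- tet_volumes(mesh$nodes, mesh$elems - 1L)
  if (any(vq$min_detJ <= 0))
    stop("mesh construction failed: inverted quadratic elements")
  mesh$meta$elem_vol <- vq$vol
  # element quality: smallest quadrature-point Jacobian over the element
  # mean (1 for affine elements); floor 0.05 guards against collapsing
  # curved elements
  mesh$meta$quality <- min(vq$min_detJ / (6 * vq$vol))
  if (mesh$meta$quality < 0.05)
    warning(sprintf("mesh quality %.3f below the 0.05 floor", mesh$meta$quality))
  mesh
}

# per-element parameter centroids (theta and s averaged over corners; phi
# from the Cartesian centroid so azimuthal wrap is handled exactly).  Sleeve
# elements whose corners carry no surface parameters get theta by inverting
# the epicardial height map at the centroid.
elem_param_centroids <- function(mesh) {
  corners <- mesh$elems[, 1:4, drop = FALSE]
  th <- rowMeans(matrix(mesh$param[corners, 1], ncol = 4), na.rm = TRUE)
  ss <- rowMeans(matrix(mesh$param[corners, 3], ncol = 4), na.rm = TRUE)
  cx <- rowMeans(matrix(mesh$nodes[corners, 1], ncol = 4))
  cy <- rowMeans(matrix(mesh$nodes[corners, 2], ncol = 4))
  cz <- rowMeans(matrix(mesh$nodes[corners, 3], ncol = 4))
  bad <- !is.finite(th)
  if (any(bad)) {
    H <- mesh$spec$H_epi * mesh$spec$scale
    th[bad] <- acos(pmin(pmax(cz[bad] / H - 1, -1), 1))
  }
  ss[!is.finite(ss)] <- 1.5
  cbind(theta = th, phi = atan2(cy, cx), s = ss, x = cx, y = cy, z = cz)
}

# boundary facet extraction for the wall mesh with endo/epi/base tags
extract_wall_facets <- function(mesh) {
  tets <- mesh$elems[, 1:4, drop = FALSE]
  faces <- rbind(
    tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
    tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  skey <- apply(faces, 1, function(f) paste(sort(f), collapse = "_"))
  tab <- table(skey)
  bnd <- faces[skey %in% names(tab)[tab == 1L], , drop = FALSE]

  s_of <- mesh$param[, 3]
  th_of <- mesh$param[, 1]
  tol <- 1e-9
  cls <- function(f) {
    if (all(abs(s_of[f]) < tol)) return("endocardium")
    if (all(abs(s_of[f] - 1) < tol)) return("epicardium")
    if (all(abs(th_of[f] - mesh$spec$theta_max) < tol)) return("basal_plane")
    NA_character_
  }
  tags <- apply(bnd, 1, cls)
  if (anyNA(tags)) stop("untagged boundary facet; mesh construction error")
  tri6 <- cbind(bnd,
                edge_midnode(mesh, bnd[, 1], bnd[, 2]),
                edge_midnode(mesh, bnd[, 2], bnd[, 3]),
                edge_midnode(mesh, bnd[, 1], bnd[, 3]))
  mesh$facets <- list(
    endocardium = tri6[tags == "endocardium", , drop = FALSE],
    epicardium = tri6[tags == "epicardium", , drop = FALSE],
    basal_plane = tri6[tags == "basal_plane", , drop = FALSE])

  # ordered endocardial basal ring (corner, midside, corner, ...) for the cap
  ring_c <- which(abs(s_of) < tol & abs(th_of - mesh$spec$theta_max) < tol &
                    !is.na(mesh$param[, 2]))
  ring_c <- ring_c[ring_c <= mesh$meta$nnode_key]     # corners only
  ring_c <- ring_c[order(mesh$param[ring_c, 2])]
  nxt <- c(ring_c[-1], ring_c[1])
  ring_m <- edge_midnode(mesh, ring_c, nxt)
  mesh$endo_ring <- list(corners = ring_c, mids = ring_m)
  mesh
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("lv_mesh: %d nodes, %d quadratic tets (%s)\n",
              nrow(x$nodes), nrow(x$elems),
              paste(sprintf("%s: %d", names(table(x$region)),
                            table(x$region)), collapse = ", ")))
  cat(sprintf("  facets: %s\n",
              paste(sprintf("%s %d", names(x$facets),
                            vapply(x$facets, nrow, 1L)), collapse = ", ")))
  invisible(x)
}

#' Infarct region specification
#'
#' Angular window on the wall, centered at \code{(theta_c, phi_c)} with
#' half-widths \code{(dtheta, dphi)}, and a transmural extent measured from
#' the endocardium (\code{transmurality = 1} is full thickness).
#'
#' @param theta_c,phi_c window center, rad
#' @param dtheta,dphi angular half-widths, rad (zero half-width means an
#'   empty infarct)
#' @param transmurality fraction of the wall thickness, in (0, 1]
#' @return object of class \code{infarct_spec}
#' @export
infarct_spec <- function(theta_c = pi / 3, phi_c = 0,
                         dtheta = pi / 5, dphi = pi / 4,
                         transmurality = 1) {
  if (dtheta < 0 || dphi < 0) stop("half-widths must be >= 0")
  if (transmurality <= 0 || transmurality > 1)
    stop("transmurality must be in (0, 1]")
  structure(list(theta_c = theta_c, phi_c = phi_c, dtheta = dtheta,
                 dphi = dphi, transmurality = transmurality),
            class = "infarct_spec")
}

#' Assign the infarct region
#'
#' Relabels wall elements whose parameter-space centroid falls inside the
#' angular window and transmural band of \code{infarct}.  Deterministic and
#' invariant under node reordering (centroids are symmetric functions of the
#' corners).
#'
#' @param mesh \code{\link{build_lv_mesh}} result
#' @param infarct \code{\link{infarct_spec}}
#' @return mesh with updated region labels
#' @export
assign_infarct <- function(mesh, infarct) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(infarct, "infarct_spec"))
  if (infarct$dtheta == 0 || infarct$dphi == 0) return(mesh)
  ep <- mesh$elem_param
  wall <- mesh$region %in% c("remote", "infarct")
  dphi <- abs(atan2(sin(ep[, "phi"] - infarct$phi_c),
                    cos(ep[, "phi"] - infarct$phi_c)))
  inwin <- wall &
    abs(ep[, "theta"] - infarct$theta_c) <= infarct$dtheta &
    dphi <= infarct$dphi &
    ep[, "s"] <= infarct$transmurality + 1e-9
  mesh$region[inwin] <- "infarct"
  mesh$infarct <- infarct
  mesh
}

# local orthonormal surface basis at (theta, phi, s): circumferential e_c,
# longitudinal (apex-directed) e_l tangent, outward transmural e_r
local_basis <- function(theta, phi, s, spec) {
  e_c <- c(-sin(phi), cos(phi), 0)
  h <- 1e-6
  tl <- (wall_point(theta + h, phi, s, spec) -
           wall_point(theta - h, phi, s, spec))[1, ] / (2 * h)
  tl <- tl - sum(tl * e_c) * e_c
  nl <- sqrt(sum(tl^2))
  if (nl < 1e-12) return(NULL)
  e_l <- tl / nl
  e_r <- c(e_c[2] * e_l[3] - e_c[3] * e_l[2],
           e_c[3] * e_l[1] - e_c[1] * e_l[3],
           e_c[1] * e_l[2] - e_c[2] * e_l[1])
  list(e_c = e_c, e_l = e_l, e_r = e_r)
}

#' Assign the myofiber field
#'
#' Rule-based fiber architecture: the helix angle (measured from the local
#' circumferential direction, in the circumferential-longitudinal tangent
#' plane) interpolates linearly in transmural depth from \code{helix_endo} at
#' the endocardium to \code{helix_epi} at the epicardium.  Sleeve elements
#' get a single fiber family at the sleeve fiber angle stored on the mesh by
#' the sleeve builder (default 0 deg = circumferential).
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param helix_endo,helix_epi helix angles at endo/epicardium, degrees
#' @return mesh with a \code{fibers} field (class \code{fiber_field}):
#'   per-element unit fiber vectors \code{N}, local frames, helix angles and
#'   a report of degenerate (axis) elements
#' @export
assign_fibers <- function(mesh, helix_endo = 60, helix_epi = -60) {
  stopifnot(inherits(mesh, "lv_mesh"))
  ne <- nrow(mesh$elems)
  N <- matrix(0, ne, 3)
  frames <- matrix(0, ne, 9)
  helix <- numeric(ne)
  degen <- integer(0)
  sleeve_angle <- if (!is.null(mesh$sleeve)) mesh$sleeve$angle_deg else 0
  ep <- mesh$elem_param
  for (e in seq_len(ne)) {
    th <- ep[e, "theta"]; ph <- ep[e, "phi"]; sc <- ep[e, "s"]
    is_sleeve <- mesh$region[e] == "sleeve"
    sb <- local_basis(th, ph, min(sc, 1), mesh$spec)
    if (is.null(sb) || sqrt(ep[e, "x"]^2 + ep[e, "y"]^2) <
        1e-9 * mesh$spec$R_epi * mesh$spec$scale) {
      # circumferential direction degenerates on the axis: fall back to the
      # longitudinal tangent and flag
      degen <- c(degen, e)
      zdir <- c(0, 0, -1)
      f <- zdir; s2 <- c(1, 0, 0); n2 <- c(0, -1, 0)
      N[e, ] <- f
      frames[e, ] <- c(f, s2, n2)
      helix[e] <- NA
      next
    }
    ang <- if (is_sleeve) sleeve_angle else
      helix_endo + (helix_epi - helix_endo) * min(max(sc, 0), 1)
    a <- ang * pi / 180
    f <- cos(a) * sb$e_c + sin(a) * sb$e_l
    f <- f / sqrt(sum(f^2))
    s2 <- sb$e_r
    n2 <- c(f[2] * s2[3] - f[3] * s2[2],
            f[3] * s2[1] - f[1] * s2[3],
            f[1] * s2[2] - f[2] * s2[1])
    N[e, ] <- f
    frames[e, ] <- c(f, s2, n2)
    helix[e] <- ang
  }
  mesh$fibers <- structure(
    list(N = N, frames = frames, helix = helix,
         helix_endo = helix_endo, helix_epi = helix_epi,
         report = data.frame(element = degen)),
    class = "fiber_field")
  mesh
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("fiber_field: %d elements, helix %+.0f to %+.0f deg, %d degenerate\n",
              nrow(x$N), x$helix_endo, x$helix_epi, nrow(x$report)))
  invisible(x)
}
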