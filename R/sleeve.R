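# Epicardial sleeve generators: the continuum shell (S0) extruded from the
# epicardial surface with shared nodes, and the auxetic metamaterial panel
# (A0) built as a planar rotating-triangles lattice, lifted onto the
# epicardium by barycentric mapping and tied to it through multi-point
# constraints.

#' Auxetic unit-cell specification
#'
#' Triangular rotating-unit cell of the auxetic lattice: a triangular
#' lattice of pitch \code{a} carries an inner triangle of edge \code{b} in
#' every lattice triangle; neighbouring inner triangles are separated by
#' slits of clearance \eqn{(a-b)/\sqrt{3}} and welded pairwise near each
#' lattice vertex by short hinge ligaments of length \code{w}.  The default
#' A0 design has \eqn{(a-b)/\sqrt 3 = 0.110 \approx w}, i.e. the clearance
#' and hinge scales coincide.
#'
#' @param a outer edge length (lattice pitch), mm
#' @param b inner edge length, mm (\code{0 < b < a})
#' @param w inner edge clearance / hinge length, mm (\code{0 < w < b})
#' @param t out-of-plane thickness, mm
#' @return object of class \code{auxetic_cell_spec}
#' @export
auxetic_cell_spec <- function(a = 1.17, b = 0.98, w = 0.11, t = 0.16) {
  if (!(a > b && b > 0)) stop("degenerate cell: need a > b > 0")
  if (!(w > 0 && w < b)) stop("degenerate cell: need 0 < w < b")
  if (t <= 0) stop("thickness must be > 0")
  structure(list(a = a, b = b, w = w, t = t), class = "auxetic_cell_spec")
}

#' @export
print.auxetic_cell_spec <- function(x, ...) {
  cat(sprintf("auxetic_cell_spec: a = %.3g, b = %.3g, w = %.3g, t = %.3g mm (slit %.3g mm)\n",
              x$a, x$b, x$w, x$t, (x$a - x$b) / sqrt(3)))
  invisible(x)
}

# lattice vectors of the triangular tiling
cell_lattice <- function(a) {
  list(v1 = c(a, 0), v2 = c(a / 2, a * sqrt(3) / 2))
}

# inner (shrunk) triangle corners of an up or down lattice triangle
inner_triangle <- function(spec, i, j, up = TRUE) {
  lv <- cell_lattice(spec$a)
  P <- i * lv$v1 + j * lv$v2
  corners <- if (up) rbind(P, P + lv$v1, P + lv$v2)
  else rbind(P + lv$v1, P + lv$v1 + lv$v2, P + lv$v2)
  G <- colMeans(corners)
  beta <- spec$b / spec$a
  sweep(sweep(corners, 2, G, "-") * beta, 2, G, "+")
}

# weld (hinge) quads around lattice vertex (i, j): three parallelograms
# joining inner-triangle corners of alternating up/down neighbours in a
# chiral matching (pairs at 30-90, 150-210, 270-330 degrees), each attached
# along a hinge segment of length w on the member triangle edges.  Each
# entry records the two member triangles so tilings can drop welds whose
# members are absent.
vertex_welds <- function(spec, i, j) {
  # triangles around vertex (i,j): (up/down, cell indices, corner index)
  nbr <- list(
    list(up = TRUE,  ci = i,     cj = j,     corner = 1, edge_to = 3), # 30
    list(up = FALSE, ci = i - 1, cj = j,     corner = 1, edge_to = 2), # 90
    list(up = TRUE,  ci = i - 1, cj = j,     corner = 2, edge_to = 1), # 150
    list(up = FALSE, ci = i - 1, cj = j - 1, corner = 2, edge_to = 3), # 210
    list(up = TRUE,  ci = i,     cj = j - 1, corner = 3, edge_to = 2), # 270
    list(up = FALSE, ci = i,     cj = j - 1, corner = 3, edge_to = 1)) # 330
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  out <- list()
  for (p in pairs) {
    t1 <- nbr[[p[1]]]; t2 <- nbr[[p[2]]]
    g1 <- inner_triangle(spec, t1$ci, t1$cj, t1$up)
    g2 <- inner_triangle(spec, t2$ci, t2$cj, t2$up)
    c1 <- g1[t1$corner, ]; c2 <- g2[t2$corner, ]
    u1 <- g1[t1$edge_to, ] - c1; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- g2[t2$edge_to, ] - c2; u2 <- u2 / sqrt(sum(u2^2))
    m1 <- c1 + spec$w * u1
    m2 <- c2 + spec$w * u2
    out[[length(out) + 1]] <- list(
      poly = rbind(c1, m1, m2, c2),
      members = list(t1[c("up", "ci", "cj")], t2[c("up", "ci", "cj")]))
  }
  out
}

#' Generate one auxetic unit cell
#'
#' Emits the material polygons of a single rhombic unit cell (one up and one
#' down inner triangle plus the three hinge ligaments owned by the cell's
#' lattice vertex).  The polygon set is chiral with three-fold rotational
#' symmetry about the lattice vertex; it tiles the plane edge-to-edge under
#' the lattice translations.
#'
#' @param spec \code{\link{auxetic_cell_spec}}
#' @return list with \code{polygons} (list of n x 2 matrices),
#'   \code{lattice} vectors and the cell specification
#' @export
generate_auxetic_cell <- function(spec) {
  stopifnot(inherits(spec, "auxetic_cell_spec"))
  polys <- list(up = inner_triangle(spec, 0, 0, TRUE),
                down = inner_triangle(spec, 0, 0, FALSE))
  welds <- vertex_welds(spec, 0, 0)
  for (k in seq_along(welds)) polys[[paste0("weld", k)]] <- welds[[k]]$poly
  list(polygons = polys, lattice = cell_lattice(spec$a), spec = spec)
}

# shoelace area of a polygon
polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# --- panel triangulation ----------------------------------------------------

# boundary points of an inner triangle in CCW order, including the hinge
# attachment points and `sub` extra subdivisions of the free segments.  The
# chiral hinge matching attaches each weld near the END corner of a CCW edge
# on up triangles (edges A->C, B->A, C->B seen from their corners) but near
# the START corner on down triangles (A'->B', B'->C', C'->A').
triangle_boundary <- function(g, w, sub = 1, up = TRUE) {
  pts <- NULL
  for (e in 1:3) {
    p <- g[e, ]; q <- g[(e %% 3) + 1, ]
    L <- sqrt(sum((q - p)^2))
    inner_f <- seq(0, 1, length.out = sub + 2)[-c(1, sub + 2)]
    seg <- rbind(p)
    if (up) {
      m <- q + (w / L) * (p - q)          # attachment near corner q
      for (f in inner_f * (1 - w / L)) seg <- rbind(seg, p + f * (q - p))
      seg <- rbind(seg, m)
    } else {
      m <- p + (w / L) * (q - p)          # attachment near corner p
      seg <- rbind(seg, m)
      for (f in w / L + inner_f * (1 - w / L)) seg <- rbind(seg, p + f * (q - p))
    }
    pts <- rbind(pts, seg)
  }
  pts
}

# fan-triangulate a convex-ish polygon about its centroid; returns local
# nodes and triangles
fan_triangulate <- function(boundary) {
  G <- colMeans(boundary)
  n <- nrow(boundary)
  nodes <- rbind(G, boundary)
  tris <- cbind(1, 1 + seq_len(n), 1 + c(2:n, 1))
  list(nodes = nodes, tris = tris)
}

#' Tile the auxetic cell into a panel
#'
#' Edge-to-edge tiling of \code{n_rows} x \code{n_cols} rhombic cells with
#' shared hinge nodes (single connected component), triangulated for finite
#' elements.  Hinge ligaments are emitted wherever both member triangles
#' exist, so interior and boundary cells knit together consistently.
#'
#' @param cell \code{\link{generate_auxetic_cell}} result or an
#'   \code{\link{auxetic_cell_spec}}
#' @param n_rows,n_cols tiling extent (>= 1)
#' @param sub extra subdivision points per free edge segment (0 = coarsest)
#' @return object of class \code{panel_mesh}: 2-D nodes, triangles, polygon
#'   bookkeeping and lattice metadata
#' @export
tile_panel <- function(cell, n_rows, n_cols, sub = 1) {
  if (inherits(cell, "auxetic_cell_spec")) cell <- generate_auxetic_cell(cell)
  spec <- cell$spec
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  # brick-staggered cell selection: row j shifts its column origin by
  # -floor(j/2) so the panel footprint stays rectangular despite the
  # rhombic lattice vectors
  cells <- NULL
  for (j in 0:(n_rows - 1))
    cells <- rbind(cells, cbind(0:(n_cols - 1) - floor(j / 2), j))
  cell_key <- paste(cells[, 1], cells[, 2])
  tri_exists <- function(ci, cj) paste(ci, cj) %in% cell_key

  nodes <- NULL; tris <- NULL; polys <- list()
  add_patch <- function(local) {
    off <- nrow(nodes %||% matrix(0, 0, 2))
    nodes <<- rbind(nodes, local$nodes)
    tris <<- rbind(tris, local$tris + off)
  }
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    for (up in c(TRUE, FALSE)) {
      g <- inner_triangle(spec, i, j, up)
      polys[[length(polys) + 1]] <- g
      add_patch(fan_triangulate(triangle_boundary(g, spec$w, sub, up)))
    }
  }
  verts <- unique(rbind(cells, cells + rep(c(1, 0), each = nrow(cells)),
                        cells + rep(c(0, 1), each = nrow(cells)),
                        cells + rep(c(1, 1), each = nrow(cells))))
  for (r in seq_len(nrow(verts))) {
    for (wd in vertex_welds(spec, verts[r, 1], verts[r, 2])) {
      ok <- vapply(wd$members, function(m) tri_exists(m$ci, m$cj), TRUE)
      if (all(ok)) {
        polys[[length(polys) + 1]] <- wd$poly
        q <- wd$poly
        add_patch(list(nodes = q, tris = rbind(c(1, 2, 3), c(1, 3, 4))))
      }
    }
  }

  # merge coincident nodes
  tol <- 1e-7 * spec$a
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  nodes <- nodes[uk, , drop = FALSE]
  tris <- matrix(map[tris], ncol = 3)

  # orientation: make all triangles CCW
  v1 <- nodes[tris[, 2], ] - nodes[tris[, 1], ]
  v2 <- nodes[tris[, 3], ] - nodes[tris[, 1], ]
  cwl <- (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) < 0
  tris[cwl, 2:3] <- tris[cwl, 3:2]

  # connectivity (union-find over shared nodes)
  parent <- seq_len(nrow(nodes))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(tris))) {
    a <- find(tris[r, 1])
    for (cidx in 2:3) { b <- find(tris[r, cidx]); if (a != b) parent[b] <- a }
  }
  comp <- vapply(seq_len(nrow(nodes)), find, 1L)
  used <- sort(unique(as.vector(tris)))
  if (length(unique(comp[used])) != 1L)
    stop("tiling is disconnected; hinge matching failed")

  structure(list(nodes = nodes, tris = tris, polygons = polys,
                 spec = spec, lattice = cell_lattice(spec$a),
                 n_rows = n_rows, n_cols = n_cols),
            class = "panel_mesh")
}

#' @export
print.panel_mesh <- function(x, ...) {
  cat(sprintf("panel_mesh: %d x %d cells, %d nodes, %d triangles\n",
              x$n_rows, x$n_cols, nrow(x$nodes), nrow(x$tris)))
  invisible(x)
}

# solid (continuum) rectangular panel triangulation, for control specimens
solid_panel <- function(width, height, nx, ny) {
  xs <- seq(0, width, length.out = nx + 1)
  ys <- seq(0, height, length.out = ny + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  id <- function(i, j) (j - 1) * (nx + 1) + i
  tris <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    aa <- id(i, j); bb <- id(i + 1, j); cc <- id(i + 1, j + 1); dd <- id(i, j + 1)
    tris <- rbind(tris, c(aa, bb, cc), c(aa, cc, dd))
  }
  structure(list(nodes = nodes, tris = tris, polygons = list(),
                 spec = NULL, n_rows = ny, n_cols = nx),
            class = "panel_mesh")
}

# --- barycentric mapping ----------------------------------------------------

# locate 2-D points in a reference triangulation: containing triangle index
# (0 when outside) and barycentric coordinates
locate_in_patch <- function(pts, epi_patch) {
  np <- nrow(pts)
  tri_id <- integer(np); lam <- matrix(NA_real_, np, 3)
  ref <- epi_patch$ref2d
  for (tt in seq_len(nrow(epi_patch$tri))) {
    v <- epi_patch$tri[tt, ]
    p0 <- ref[v[1], ]; p1 <- ref[v[2], ]; p2 <- ref[v[3], ]
    d <- (p1[1] - p0[1]) * (p2[2] - p0[2]) - (p2[1] - p0[1]) * (p1[2] - p0[2])
    if (abs(d) < 1e-14) next
    need <- which(tri_id == 0L)
    if (!length(need)) break
    dx <- pts[need, 1] - p0[1]; dy <- pts[need, 2] - p0[2]
    l1 <- ((p2[2] - p0[2]) * dx - (p2[1] - p0[1]) * dy) / d
    l2 <- (-(p1[2] - p0[2]) * dx + (p1[1] - p0[1]) * dy) / d
    l0 <- 1 - l1 - l2
    inside <- l0 >= -1e-9 & l1 >= -1e-9 & l2 >= -1e-9
    hit <- need[inside]
    tri_id[hit] <- tt
    lam[hit, ] <- pmax(cbind(l0[inside], l1[inside], l2[inside]), 0)
  }
  list(tri = tri_id, lambda = lam)
}

#' Map a planar panel onto the epicardial surface
#'
#' Lifts every panel node onto the triangulated epicardial patch by
#' barycentric interpolation: a node with coordinates \eqn{(\lambda_0,
#' \lambda_1, \lambda_2)} inside reference triangle \eqn{(p_0, p_1, p_2)}
#' maps to \eqn{\Phi(p) = \lambda_0 V_0 + \lambda_1 V_1 + \lambda_2 V_2}
#' with \eqn{V_i} the corresponding epicardial nodes.
#'
#' @param panel \code{\link{tile_panel}} result (2-D)
#' @param epi_patch list with \code{ref2d} (n x 2 planar reference
#'   coordinates), \code{tri} (m x 3 triangle index matrix), \code{V3d}
#'   (n x 3 surface positions) and optionally \code{node_ids} (mesh node ids)
#' @return list: \code{nodes3d}, per-node \code{tri} index and \code{lambda}
#'   matrix; error listing offending nodes if any node lies outside the patch
#' @export
map_panel_to_epicardium <- function(panel, epi_patch) {
  loc <- locate_in_patch(panel$nodes, epi_patch)
  tri_id <- loc$tri; lam <- loc$lambda
  np <- nrow(panel$nodes)
  if (any(tri_id == 0L))
    stop(sprintf("panel nodes outside the reference triangulation: %s",
                 paste(utils::head(which(tri_id == 0L), 20), collapse = ", ")))
  lam <- lam / rowSums(lam)
  nodes3d <- matrix(0, np, 3)
  for (k in seq_len(np)) {
    v <- epi_patch$tri[tri_id[k], ]
    nodes3d[k, ] <- lam[k, 1] * epi_patch$V3d[v[1], ] +
      lam[k, 2] * epi_patch$V3d[v[2], ] + lam[k, 3] * epi_patch$V3d[v[3], ]
  }
  list(nodes3d = nodes3d, tri = tri_id, lambda = lam,
       epi_patch = epi_patch)
}

# --- extrusion --------------------------------------------------------------

# area-weighted outward node normals of a 3-D triangulated surface
surface_node_normals <- function(nodes3d, tris, orient = NULL) {
  nrm <- matrix(0, nrow(nodes3d), 3)
  for (r in seq_len(nrow(tris))) {
    v <- tris[r, ]
    e1 <- nodes3d[v[2], ] - nodes3d[v[1], ]
    e2 <- nodes3d[v[3], ] - nodes3d[v[1], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    for (cidx in v) nrm[cidx, ] <- nrm[cidx, ] + cr / 2
  }
  if (!is.null(orient)) {
    flip <- rowSums(nrm * orient) < 0
    nrm[flip, ] <- -nrm[flip, ]
  }
  nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
}

#' Extrude a surface mesh into a solid sleeve layer
#'
#' Offsets the surface along its (outward) nodal normals by \code{thickness}
#' and fills the gap with quadratic tetrahedra (three per prism, smallest-id
#' diagonals so the decomposition conforms).
#'
#' @param surface list with \code{nodes3d} (n x 3) and \code{tris} (m x 3);
#'   normals may be supplied as \code{normals}, otherwise area-weighted
#'   triangle normals are used
#' @param thickness extrusion distance, mm (> 0)
#' @param n_layers transmural element layers
#' @return local solid mesh: \code{nodes}, tet10 \code{elems},
#'   \code{base_nodes} (ids of the inner-surface corners),
#'   \code{edge_lo}/\code{edge_hi} midside bookkeeping,
#'   \code{outer_tris} (corner triangles of the outermost surface)
#' @export
extrude_sleeve <- function(surface, thickness, n_layers = 1) {
  if (thickness <= 0) stop("degenerate extrusion: thickness must be > 0")
  nb <- nrow(surface$nodes3d)
  nrm <- surface$normals %||%
    surface_node_normals(surface$nodes3d, surface$tris)
  nodes <- surface$nodes3d
  for (l in seq_len(n_layers))
    nodes <- rbind(nodes, surface$nodes3d + (l * thickness / n_layers) * nrm)
  prisms <- NULL
  for (l in 0:(n_layers - 1)) {
    base <- surface$tris + l * nb
    top <- surface$tris + (l + 1) * nb
    prisms <- rbind(prisms, cbind(base, top))
  }
  tets4 <- prisms_to_tets(prisms)
  tets4 <- orient_tets(nodes, tets4)
  midpos <- function(n1, n2) {
    list(coords = (nodes[n1, , drop = FALSE] + nodes[n2, , drop = FALSE]) / 2,
         param = NULL)
  }
  qz <- quadratize_tets(tets4, nrow(nodes), midpos)
  nodes <- rbind(nodes, qz$mid_coords)
  vq <- tet_volumes(nodes, qz$elems - 1L)
  if (any(vq$min_detJ <= 0))
    stop("sleeve extrusion produced inverted elements (self-intersection)")
  list(nodes = nodes, elems = qz$elems, base_nodes = seq_len(nb),
       edge_lo = qz$edge_lo, edge_hi = qz$edge_hi,
       edge_mid = qz$edge_mid,
       outer_tris = surface$tris + n_layers * nb,
       vol = sum(vq$vol))
}

# --- coverage band and epicardial patch ------------------------------------

#' Sleeve specification
#'
#' @param kind \code{"continuum_S0"} or \code{"auxetic_A0"}
#' @param zeta sleeve-to-LV stiffness ratio
#' @param angle_deg sleeve fiber angle from the circumferential axis, degrees
#' @param thickness sleeve thickness, mm
#' @param coverage list with \code{theta = c(lo, hi)} and
#'   \code{phi = c(lo, hi)} (radians) or \code{NULL} to cover the infarct
#'   window plus \code{margin}
#' @param margin angular margin added around the infarct window, rad
#' @param cell \code{\link{auxetic_cell_spec}} for auxetic sleeves
#' @param sub auxetic panel subdivision level passed to
#'   \code{\link{tile_panel}}
#' @return object of class \code{sleeve_spec}
#' @export
sleeve_spec <- function(kind = c("continuum_S0", "auxetic_A0"),
                        zeta = 5, angle_deg = 0, thickness = 0.16,
                        coverage = NULL, margin = 0.25,
                        cell = auxetic_cell_spec(), sub = 1) {
  kind <- match.arg(kind)
  if (!angle_deg %in% c(0, 45, 90))
    warning("sleeve fiber angle outside the studied set {0, 45, 90} deg")
  structure(list(kind = kind, zeta = zeta, angle_deg = angle_deg,
                 thickness = thickness, coverage = coverage,
                 margin = margin, cell = cell, sub = sub),
            class = "sleeve_spec")
}

# resolve the coverage band on the epicardium
coverage_band <- function(mesh, sleeve) {
  if (!is.null(sleeve$coverage)) return(sleeve$coverage)
  if (is.null(mesh$infarct))
    stop("no coverage band given and no infarct to cover")
  inf <- mesh$infarct
  m <- sleeve$margin
  list(theta = c(max(0.05, inf$theta_c - inf$dtheta - m),
                 min(mesh$spec$theta_max, inf$theta_c + inf$dtheta + m)),
       phi = c(inf$phi_c - inf$dphi - m, inf$phi_c + inf$dphi + m))
}

wrap_dphi <- function(phi, phi0) atan2(sin(phi - phi0), cos(phi - phi0))

# epicardial surface patch (corner triangulation) restricted to a band,
# with unrolled planar reference coordinates: v = meridional arc length
# from the band's upper rim, u = azimuthal arc length at the node's own
# parallel (so circumference is locally metric-true)
epi_patch_band <- function(mesh, band) {
  epi <- mesh$facets$epicardium[, 1:3, drop = FALSE]
  th <- mesh$param[, 1]; ph <- mesh$param[, 2]
  phic <- mean(band$phi)
  innode <- th >= band$theta[1] - 1e-9 & th <= band$theta[2] + 1e-9 &
    !is.na(ph) &
    wrap_dphi(ph, phic) >= wrap_dphi(band$phi[1], phic) - 1e-9 &
    wrap_dphi(ph, phic) <= wrap_dphi(band$phi[2], phic) + 1e-9
  keep <- innode[epi[, 1]] & innode[epi[, 2]] & innode[epi[, 3]]
  tri_glob <- epi[keep, , drop = FALSE]
  if (!nrow(tri_glob)) stop("empty coverage band on the epicardium")
  ids <- sort(unique(as.vector(tri_glob)))
  tri <- matrix(match(tri_glob, ids), ncol = 3)
  sc <- mesh$spec$scale
  R <- mesh$spec$R_epi * sc; H <- mesh$spec$H_epi * sc
  arc <- function(theta) {  # meridional arc length from theta_0
    vapply(theta, function(tt)
      stats::integrate(function(q) sqrt(R^2 * cos(q)^2 + H^2 * sin(q)^2),
                       band$theta[1], tt, rel.tol = 1e-10)$value, 0)
  }
  thn <- th[ids]; phn <- ph[ids]
  ref2d <- cbind(u = wrap_dphi(phn, phic) * R * sin(thn), v = arc(thn))
  list(ref2d = ref2d, tri = tri, V3d = mesh$nodes[ids, , drop = FALSE],
       node_ids = ids, band = band, phic = phic)
}

# --- continuum sleeve -------------------------------------------------------

#' Build the continuum sleeve (S0)
#'
#' Extrudes the epicardial facets of the coverage band outward along the
#' analytic surface normal into a solid shell whose inner nodes (corner and
#' midside) are the epicardial nodes themselves, so sleeve and wall share a
#' single displacement field across the interface.
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param sleeve \code{\link{sleeve_spec}} of kind \code{"continuum_S0"}
#' @param n_layers transmural element layers in the sleeve
#' @return merged \code{lv_mesh} with region \code{"sleeve"} and sleeve
#'   metadata (\code{zeta}, fiber angle)
#' @export
build_continuum_sleeve <- function(mesh, sleeve, n_layers = 1) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(sleeve, "sleeve_spec"))
  band <- coverage_band(mesh, sleeve)
  tw <- mean_wall_thickness(mesh)
  if (sleeve$thickness / tw >= 1)
    stop("sleeve thickness must stay below the mean wall thickness")
  epi <- mesh$facets$epicardium
  th <- mesh$param[, 1]; ph <- mesh$param[, 2]
  phic <- mean(band$phi)
  innode <- th >= band$theta[1] - 1e-9 & th <= band$theta[2] + 1e-9 &
    !is.na(ph) &
    wrap_dphi(ph, phic) >= wrap_dphi(band$phi[1], phic) - 1e-9 &
    wrap_dphi(ph, phic) <= wrap_dphi(band$phi[2], phic) + 1e-9
  keep <- innode[epi[, 1]] & innode[epi[, 2]] & innode[epi[, 3]]
  if (!any(keep)) stop("empty coverage band on the epicardium")
  facets <- epi[keep, , drop = FALSE]
  # only corner nodes get offset copies: inner-surface midsides are reused
  # from the wall mesh, all other midsides are created by quadratization
  surf_ids <- sort(unique(as.vector(facets[, 1:3])))

  # analytic outward normal of the epicardial surface at (theta, phi)
  out_normal <- function(theta, phi) {
    b <- local_basis(theta, phi, 1, mesh$spec)
    b$e_r
  }
  nrm <- t(vapply(surf_ids, function(n)
    out_normal(th[n], ph[n]), numeric(3)))

  nn0 <- nrow(mesh$nodes)
  new_nodes <- NULL
  layer_id <- matrix(0L, length(surf_ids), n_layers)  # offset copies
  for (l in seq_len(n_layers)) {
    off <- (l * sleeve$thickness / n_layers) * nrm
    layer_id[, l] <- nn0 + nrow(new_nodes %||% matrix(0, 0, 3)) +
      seq_along(surf_ids)
    new_nodes <- rbind(new_nodes, mesh$nodes[surf_ids, , drop = FALSE] + off)
  }
  all_nodes <- rbind(mesh$nodes, new_nodes)
  gid <- function(n, l) {      # global id of surface node n at layer l
    if (l == 0) n else layer_id[match(n, surf_ids), l]
  }
  prisms <- NULL
  for (l in 0:(n_layers - 1)) {
    base <- cbind(gid(facets[, 1], l), gid(facets[, 2], l), gid(facets[, 3], l))
    top <- cbind(gid(facets[, 1], l + 1), gid(facets[, 2], l + 1),
                 gid(facets[, 3], l + 1))
    prisms <- rbind(prisms, cbind(base, top))
  }
  tets4 <- prisms_to_tets(prisms)
  tets4 <- orient_tets(all_nodes, tets4)

  # quadratize, reusing the wall's curved midside nodes for edges that lie
  # on the epicardial surface (conforming interface)
  e1 <- c(tets4[, TET_EDGES[, 1]]); e2 <- c(tets4[, TET_EDGES[, 2]])
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  key <- as.numeric(lo) * (nrow(all_nodes) + 1) + as.numeric(hi)
  exist_mid <- rep(NA_integer_, length(key))
  on_wall <- lo <= nn0 & hi <= nn0
  exist_mid[on_wall] <- edge_midnode(mesh, lo[on_wall], hi[on_wall])
  uk <- !duplicated(key)
  need_new <- uk & is.na(exist_mid)
  new_mid_id <- rep(NA_integer_, length(key))
  new_mid_id[need_new] <- nrow(all_nodes) + seq_len(sum(need_new))
  # propagate ids to duplicate edges
  first_idx <- match(key, key[uk])
  mid_id <- ifelse(is.na(exist_mid[which(uk)[first_idx]]),
                   new_mid_id[which(uk)[first_idx]],
                   exist_mid[which(uk)[first_idx]])
  mid_nodes <- (all_nodes[lo[need_new], , drop = FALSE] +
                  all_nodes[hi[need_new], , drop = FALSE]) / 2
  all_nodes <- rbind(all_nodes, mid_nodes)
  elems_slv <- cbind(tets4, matrix(mid_id, nrow(tets4), 6))

  ne0 <- nrow(mesh$elems)
  mesh$nodes <- all_nodes
  mesh$param <- rbind(mesh$param,
                      matrix(NA_real_, nrow(all_nodes) - nrow(mesh$param), 3))
  mesh$elems <- rbind(mesh$elems, elems_slv)
  mesh$region <- c(mesh$region, rep("sleeve", nrow(elems_slv)))
  mesh$elem_param <- elem_param_centroids(mesh)
  mesh$elem_param[(ne0 + 1):nrow(mesh$elems), "s"] <- 1.5   # marks sleeve
  vq <- tet_volumes(mesh$nodes, mesh$elems - 1L)
  if (any(vq$min_detJ <= 0)) stop("sleeve merge produced inverted elements")
  mesh$meta$elem_vol <- vq$vol
  mesh$sleeve <- list(kind = "continuum_S0", zeta = sleeve$zeta,
                      angle_deg = sleeve$angle_deg,
                      thickness = sleeve$thickness, band = band,
                      n_elems = nrow(elems_slv))
  # outer sleeve surface (constructive): top-layer facet copies
  mesh$facets$sleeve_outer <- NULL
  mesh
}

# --- auxetic sleeve ---------------------------------------------------------

#' Build the auxetic sleeve (A0)
#'
#' Generates the rotating-triangles panel sized to the coverage band,
#' maps it onto the epicardial patch by barycentric lifting, extrudes it to
#' its design thickness, and ties every inner-surface node to the epicardial
#' facet it lies on through multi-point constraints (the displacement-field
#' counterpart of the barycentric map), so the interface carries a single
#' displacement field without contact surfaces.
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param sleeve \code{\link{sleeve_spec}} of kind \code{"auxetic_A0"}
#' @return merged \code{lv_mesh} with region \code{"sleeve"}, the MPC tie
#'   list and sleeve metadata
#' @export
build_auxetic_sleeve <- function(mesh, sleeve) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(sleeve, "sleeve_spec"))
  band <- coverage_band(mesh, sleeve)
  tw <- mean_wall_thickness(mesh)
  if (sleeve$thickness / tw >= 1)
    stop("sleeve thickness must stay below the mean wall thickness")
  patch <- epi_patch_band(mesh, band)

  # usable rectangle inside the patch (the unrolled band narrows towards the
  # apex); panel rows laid along u (circumferential), columns along v
  spec_c <- sleeve$cell
  lv <- cell_lattice(spec_c$a)
  u_rng <- range(patch$ref2d[, 1]); v_rng <- range(patch$ref2d[, 2])
  # conservative interior margins: half a cell all round plus the narrowing
  width_u <- 2 * min(abs(u_rng[1]), u_rng[2]) * 0.92
  height_v <- diff(v_rng) * 0.92
  n_cols <- max(1L, floor((width_u - spec_c$a) / lv$v1[1]))
  n_rows <- max(1L, floor((height_v - lv$v2[2]) / lv$v2[2]))
  panel <- tile_panel(spec_c, n_rows, n_cols, sub = sleeve$sub)
  # centre the panel inside the band
  pr <- panel$nodes
  pr[, 1] <- pr[, 1] - (min(pr[, 1]) + max(pr[, 1])) / 2 +
    (u_rng[1] + u_rng[2]) / 2
  pr[, 2] <- pr[, 2] - (min(pr[, 2]) + max(pr[, 2])) / 2 +
    (v_rng[1] + v_rng[2]) / 2
  panel$nodes <- pr

  # clip panel triangles that fall outside the (narrowing) unrolled band,
  # keep the largest connected component, then map
  loc <- locate_in_patch(panel$nodes, patch)
  keep_tri <- loc$tri[panel$tris[, 1]] > 0 &
    loc$tri[panel$tris[, 2]] > 0 & loc$tri[panel$tris[, 3]] > 0
  tris <- panel$tris[keep_tri, , drop = FALSE]
  if (!nrow(tris)) stop("no panel cells fit inside the coverage band")
  parent <- seq_len(nrow(panel$nodes))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(tris))) {
    a <- find(tris[r, 1])
    for (cidx in 2:3) { b <- find(tris[r, cidx]); if (a != b) parent[b] <- a }
  }
  comp <- vapply(tris[, 1], find, 1L)
  main <- as.integer(names(which.max(table(comp))))
  tris <- tris[comp == main, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  panel$nodes <- panel$nodes[used, , drop = FALSE]
  panel$tris <- matrix(match(tris, used), ncol = 3)

  mp <- map_panel_to_epicardium(panel, patch)
  # outward normals: analytic surface normal at the containing triangle
  th <- mesh$param[, 1]; ph <- mesh$param[, 2]
  nrm <- matrix(0, nrow(mp$nodes3d), 3)
  for (k in seq_len(nrow(nrm))) {
    v <- patch$tri[mp$tri[k], ]
    gl <- patch$node_ids[v]
    thk <- sum(mp$lambda[k, ] * th[gl])
    phk <- atan2(sum(mp$lambda[k, ] * sin(ph[gl])),
                 sum(mp$lambda[k, ] * cos(ph[gl])))
    nrm[k, ] <- local_basis(thk, phk, 1, mesh$spec)$e_r
  }
  ext <- extrude_sleeve(list(nodes3d = mp$nodes3d, tris = panel$tris,
                             normals = nrm), sleeve$thickness, n_layers = 1)

  nn0 <- nrow(mesh$nodes)
  mesh$nodes <- rbind(mesh$nodes, ext$nodes)
  mesh$param <- rbind(mesh$param,
                      matrix(NA_real_, nrow(ext$nodes), 3))
  elems_slv <- ext$elems + nn0
  ne0 <- nrow(mesh$elems)
  mesh$elems <- rbind(mesh$elems, elems_slv)
  mesh$region <- c(mesh$region, rep("sleeve", nrow(elems_slv)))
  mesh$elem_param <- elem_param_centroids(mesh)
  mesh$elem_param[(ne0 + 1):nrow(mesh$elems), "s"] <- 1.5

  # multi-point ties: inner-surface corners carry the barycentric weights of
  # their epicardial triangle; inner-surface midsides chain to the two
  # corners they bisect (resolved to the same masters automatically)
  nb <- length(ext$base_nodes)
  mpc <- list()
  for (k in seq_len(nb)) {
    v <- patch$tri[mp$tri[k], ]
    gl <- patch$node_ids[v]
    lamk <- mp$lambda[k, ]
    keep <- lamk > 1e-12
    for (d in 1:3) {
      mpc[[length(mpc) + 1]] <- list(
        dof = 3 * (nn0 + k - 1) + d,
        masters = 3 * (gl[keep] - 1) + d,
        w = lamk[keep])
    }
  }
  base_mid <- which(ext$edge_lo <= nb & ext$edge_hi <= nb)
  for (idx in base_mid) {
    mid_g <- nn0 + ext$edge_mid[idx]
    a_g <- nn0 + ext$edge_lo[idx]; b_g <- nn0 + ext$edge_hi[idx]
    for (d in 1:3) {
      mpc[[length(mpc) + 1]] <- list(
        dof = 3 * (mid_g - 1) + d,
        masters = c(3 * (a_g - 1) + d, 3 * (b_g - 1) + d),
        w = c(0.5, 0.5))
    }
  }
  mesh$mpc <- c(mesh$mpc, mpc)
  vq <- tet_volumes(mesh$nodes, mesh$elems - 1L)
  if (any(vq$min_detJ <= 0)) stop("sleeve merge produced inverted elements")
  mesh$meta$elem_vol <- vq$vol
  mesh$sleeve <- list(kind = "auxetic_A0", zeta = sleeve$zeta,
                      angle_deg = sleeve$angle_deg,
                      thickness = sleeve$thickness, band = band,
                      n_rows = n_rows, n_cols = n_cols,
                      n_elems = nrow(elems_slv), cell = spec_c,
                      n_tied = nb, panel = panel)
  mesh
}
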