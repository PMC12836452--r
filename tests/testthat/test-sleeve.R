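# Auxetic cell generation, panel tiling, barycentric mapping, extrusion and
# sleeve merging.

test_that("cell spec invariants reject degenerate cells", {
  expect_s3_class(auxetic_cell_spec(), "auxetic_cell_spec")
  expect_error(auxetic_cell_spec(a = 0.9, b = 0.98), "a > b")
  expect_error(auxetic_cell_spec(w = 0.98), "w < b")
  expect_error(auxetic_cell_spec(w = 1.2), "w < b")
  expect_error(auxetic_cell_spec(t = 0), "thickness")
})

test_that("the unit cell's solid-area fraction lies strictly inside (0,1)", {
  cs <- auxetic_cell_spec()
  cell <- generate_auxetic_cell(cs)
  areas <- vapply(cell$polygons, shoelace, 0)
  frac <- sum(areas) / (2 * sqrt(3) / 4 * cs$a^2)  # rhombus = two triangles
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  # inner triangles shrink with b
  expect_equal(shoelace(cell$polygons$up), sqrt(3) / 4 * cs$b^2,
               tolerance = 1e-12)
})

test_that("the cell pattern has three-fold rotational symmetry about a vertex", {
  # the rotating-triangle family is chiral: its symmetry is the C3 rotation
  # about each lattice vertex, not a mirror
  cs <- auxetic_cell_spec()
  welds <- sleevesim:::vertex_welds(cs, 0, 0)
  rot120 <- function(p) {
    a <- 2 * pi / 3
    cbind(cos(a) * p[, 1] - sin(a) * p[, 2],
          sin(a) * p[, 1] + cos(a) * p[, 2])
  }
  polys <- lapply(welds, `[[`, "poly")
  keyset <- function(ps) {
    sort(unlist(lapply(ps, function(p) {
      p <- round(p, 9)
      paste(sort(paste(p[, 1], p[, 2])), collapse = ";")
    })))
  }
  expect_identical(keyset(lapply(polys, rot120)), keyset(polys))
})

test_that("tiling is edge-to-edge, connected, and translation-periodic", {
  cs <- auxetic_cell_spec()
  p11 <- tile_panel(cs, 1, 1, sub = 0)
  expect_s3_class(p11, "panel_mesh")
  p22 <- tile_panel(cs, 2, 2, sub = 0)
  expect_gt(nrow(p22$tris), nrow(p11$tris))
  # connectivity is enforced in the constructor; reaching here means one
  # component.  Translation periodicity of the lattice construction:
  lv <- sleevesim:::cell_lattice(cs$a)
  g00 <- sleevesim:::inner_triangle(cs, 0, 0, TRUE)
  g23 <- sleevesim:::inner_triangle(cs, 2, 3, TRUE)
  shift <- matrix(2 * lv$v1 + 3 * lv$v2, 3, 2, byrow = TRUE)
  expect_lt(max(abs(g23 - (g00 + shift))), 1e-12)
})

test_that("tiled strut area follows the per-cell bookkeeping", {
  cs <- auxetic_cell_spec()
  p <- tile_panel(cs, 3, 4, sub = 0)
  areas <- vapply(p$polygons, shoelace, 0)
  tri_area <- sqrt(3) / 4 * cs$b^2
  n_tri <- 2 * 3 * 4
  # every polygon is either an inner triangle or a hinge parallelogram;
  # hinge count equals the number of welds with both members present
  n_weld <- length(p$polygons) - n_tri
  weld_area <- shoelace(sleevesim:::vertex_welds(cs, 0, 0)[[1]]$poly)
  expect_equal(sum(areas), n_tri * tri_area + n_weld * weld_area,
               tolerance = 1e-9)
  # interior vertices carry all three welds: well above one per cell
  expect_gt(n_weld, 3 * 2)
})

test_that("barycentric lifting reproduces reference points exactly", {
  # single reference triangle: identity configuration
  patch <- list(ref2d = rbind(c(0, 0), c(4, 0), c(0, 4)),
                tri = matrix(c(1, 2, 3), 1),
                V3d = rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
  panel <- list(nodes = rbind(c(0, 0), c(4 / 3, 4 / 3), c(1, 1), c(2, 1)))
  mp <- map_panel_to_epicardium(panel, patch)
  expect_equal(mp$nodes3d[1, ], c(0, 0, 0))                  # vertex
  expect_equal(mp$nodes3d[2, ], c(4 / 3, 4 / 3, 0))          # centroid
  expect_equal(mp$lambda[3, ], c(0.5, 0.25, 0.25))           # (1,1)
  expect_equal(mp$nodes3d[3, ], c(1, 1, 0))
  # affine map: epicardial triangle equal to the reference triangle is the
  # identity
  expect_lt(max(abs(mp$nodes3d[, 1:2] - panel$nodes)), 1e-12)
  # offending nodes are reported
  bad <- list(nodes = rbind(c(9, 9)))
  expect_error(map_panel_to_epicardium(bad, patch), "outside")
})

test_that("a lifted panel lies on the piecewise-linear epicardial surface", {
  mesh <- build_lv_mesh(lv_geometry_spec(scale = 2.24), n_theta = 5,
                        n_phi = 10, n_layers = 1)
  mesh <- assign_infarct(mesh, infarct_spec())
  band <- sleevesim:::coverage_band(mesh, sleeve_spec("auxetic_A0"))
  patch <- sleevesim:::epi_patch_band(mesh, band)
  panel <- tile_panel(auxetic_cell_spec(), 2, 2, sub = 0)
  # centre a small panel in the patch
  ur <- range(patch$ref2d[, 1]); vr <- range(patch$ref2d[, 2])
  panel$nodes[, 1] <- panel$nodes[, 1] - mean(range(panel$nodes[, 1])) +
    mean(ur)
  panel$nodes[, 2] <- panel$nodes[, 2] - mean(range(panel$nodes[, 2])) +
    mean(vr)
  mp <- map_panel_to_epicardium(panel, patch)
  for (k in seq_len(nrow(mp$nodes3d))) {
    v <- patch$tri[mp$tri[k], ]
    expected <- drop(mp$lambda[k, ] %*% patch$V3d[v, ])
    expect_lt(max(abs(mp$nodes3d[k, ] - expected)), 1e-10)
  }
})

test_that("extrusion produces exact prism volumes on flat patches", {
  expect_error(extrude_sleeve(list(nodes3d = cbind(0, 0, 0)), 0),
               "thickness")
  # flat unit square split into two triangles, extruded by t
  surf <- list(nodes3d = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                               c(0, 1, 0)),
               tris = rbind(c(1, 2, 3), c(1, 3, 4)),
               normals = matrix(rep(c(0, 0, 1), each = 4), ncol = 3))
  ext <- extrude_sleeve(surf, 0.16)
  expect_equal(ext$vol, 1 * 0.16, tolerance = 1e-10)
  # spherical patch: volume between A t and A t (1 + t/R)^2
  R <- 5
  th <- seq(0.3, 0.7, length.out = 5); ph <- seq(-0.3, 0.3, length.out = 5)
  g <- expand.grid(th = th, ph = ph)
  nodes <- R * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  id <- function(i, j) (j - 1) * 5 + i
  tris <- NULL
  for (j in 1:4) for (i in 1:4)
    tris <- rbind(tris, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                  c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  nrm <- nodes / R
  t <- 0.3
  ext2 <- extrude_sleeve(list(nodes3d = nodes, tris = tris, normals = nrm), t)
  A <- sum(vapply(seq_len(nrow(tris)), function(r) {
    e1 <- nodes[tris[r, 2], ] - nodes[tris[r, 1], ]
    e2 <- nodes[tris[r, 3], ] - nodes[tris[r, 1], ]
    sqrt(sum(crossprod(matrix(c(e1[2] * e2[3] - e1[3] * e2[2],
                                e1[3] * e2[1] - e1[1] * e2[3],
                                e1[1] * e2[2] - e1[2] * e2[1])))) ) / 2
  }, 0))
  expect_gt(ext2$vol, A * t * 0.999)
  expect_lt(ext2$vol, A * t * (1 + t / R)^2)
})

test_that("the continuum sleeve shares the epicardial interface nodes", {
  mesh <- build_lv_mesh(lv_geometry_spec(scale = 2.24), n_theta = 5,
                        n_phi = 10, n_layers = 1)
  mesh <- assign_infarct(mesh, infarct_spec())
  mS <- build_continuum_sleeve(mesh, sleeve_spec("continuum_S0", zeta = 5))
  expect_true(any(mS$region == "sleeve"))
  # sleeve elements reference wall epicardial nodes directly (shared dofs)
  slv <- mS$elems[mS$region == "sleeve", , drop = FALSE]
  expect_true(any(slv <= nrow(mesh$nodes)))
  # thickness-to-wall-thickness ratio below one
  tw <- sleevesim:::mean_wall_thickness(mesh)
  expect_lt(mS$sleeve$thickness / tw, 1)
  # zeta = 1 reproduces the remote passive record except for the label
  sc <- make_scenario("MI_S0", zeta = 1)
  mats <- sleevesim:::scenario_materials(sc)
  expect_equal(mats$sleeve$c_region, mats$remote$c_region)
  expect_equal(mats$sleeve$B1, mats$remote$B1)
  expect_error(build_continuum_sleeve(mesh,
    sleeve_spec("continuum_S0", coverage = list(theta = c(0.01, 0.02),
                                                phi = c(0, 0.01)))),
    "empty coverage")
})

test_that("the auxetic sleeve ties are structural multi-point constraints", {
  mesh <- build_lv_mesh(lv_geometry_spec(scale = 2.24), n_theta = 5,
                        n_phi = 10, n_layers = 1)
  mesh <- assign_infarct(mesh, infarct_spec())
  mA <- build_auxetic_sleeve(mesh, sleeve_spec("auxetic_A0", zeta = 5,
                                               sub = 0))
  mA <- assign_fibers(mA)
  expect_gt(mA$sleeve$n_tied, 0)
  expect_gt(length(mA$mpc), 0)
  # each tie row: weights sum to one (partition of unity of the barycentric
  # coordinates), masters are wall dofs
  nn0 <- nrow(mesh$nodes)
  for (m in mA$mpc[seq(1, min(60, length(mA$mpc)))]) {
    expect_equal(sum(m$w), 1, tolerance = 1e-9)
  }
  # the reduced system has no dofs for tied nodes: slave columns are absent
  sys <- sleevesim:::solver_system(mA, wall_materials() |>
    c(list(sleeve = passive_params(2.08, 47.15, 22.55, 24.60, K = 20800,
                                   region = "sleeve"))))
  n_slave <- length(mA$mpc) + 1   # + the basal rotation restraint
  expect_equal(ncol(sys$T),
               3 * nrow(mA$nodes) - length(sys$bc$fixed) - n_slave)
  # tied displacements follow their masters exactly in a solved state
  sol <- solve_static(sys, 0.5, 0)
  u <- sol$u
  for (m in mA$mpc[seq(1, min(30, length(mA$mpc)))]) {
    expect_equal(u[m$dof], sum(m$w * u[m$masters]), tolerance = 1e-12)
  }
})
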