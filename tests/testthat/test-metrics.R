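# Organ-level and regional metrics.

test_that("pressure-volume metrics satisfy their identities", {
  pv <- pv_metrics(list(V = c(500, 650, 390, 420)))
  expect_equal(pv$EDV, 0.65)
  expect_equal(pv$ESV, 0.39)
  expect_equal(pv$SV, 0.26)
  expect_equal(pv$EF, 40)
  flat <- pv_metrics(list(V = rep(500, 4)))
  expect_equal(flat$SV, 0)
  expect_equal(flat$EF, 0)
  # uniform 10% shrink: EF invariant, SV scales
  pv2 <- pv_metrics(list(V = 0.9 * c(500, 650, 390, 420)))
  expect_equal(pv2$EF, pv$EF)
  expect_equal(pv2$SV, 0.9 * pv$SV)
  expect_error(pv_metrics(list(V = c(-1, 0))), "volume")
})

test_that("fiber strain projects the affine strain onto the fibers", {
  mesh <- coarse_mesh()
  # affine stretch along x: F = diag(1.1, 1, 1)
  F <- diag(c(1.1, 1, 1))
  u <- as.vector(t(mesh$nodes %*% t(F) - mesh$nodes))
  eff <- fiber_strain_field(mesh, u)
  E <- 0.5 * (t(F) %*% F - diag(3))
  oracle <- vapply(seq_len(nrow(mesh$elems)), function(e) {
    N <- mesh$fibers$N[e, ]
    drop(N %*% E %*% N)
  }, 0)
  expect_equal(eff, oracle, tolerance = 1e-9)
  # uniaxial stretch along the fiber itself gives (lambda^2 - 1)/2
  expect_equal(max(abs(oracle - eff)), 0, tolerance = 1e-9)
  lam <- 1.1
  expect_equal((lam^2 - 1) / 2, 0.105)
  # rigid rotation produces zero strain
  a <- 0.4
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  u_rot <- as.vector(t(mesh$nodes %*% t(Rz) - mesh$nodes))
  expect_lt(max(abs(fiber_strain_field(mesh, u_rot))), 1e-9)
})

test_that("regional summaries are volume-weighted and skip empty regions", {
  mesh <- coarse_mesh()
  ne <- nrow(mesh$elems)
  # uniform field
  rs <- regional_summary(rep(3.5, ne), mesh)
  expect_true(all(abs(rs$mean - 3.5) < 1e-12))
  expect_true(all(rs$sd < 1e-12))
  # indicator field reproduces the indicator
  ind <- as.numeric(mesh$region == "infarct")
  rs2 <- regional_summary(ind, mesh)
  expect_equal(rs2$mean[rs2$region == "infarct"], 1)
  expect_equal(rs2$mean[rs2$region == "remote"], 0)
  # random field against a direct accumulation oracle
  set.seed(9)
  f <- rnorm(ne)
  rs3 <- regional_summary(f, mesh)
  w <- mesh$meta$elem_vol
  for (rn in rs3$region) {
    i <- mesh$region == rn
    mu <- sum(w[i] * f[i]) / sum(w[i])
    expect_equal(rs3$mean[rs3$region == rn], mu, tolerance = 1e-12)
    expect_equal(rs3$sd[rs3$region == rn],
                 sqrt(sum(w[i] * (f[i] - mu)^2) / sum(w[i])),
                 tolerance = 1e-12)
  }
})

test_that("torsion vanishes for rigid motions and recovers a linear twist", {
  mesh <- coarse_mesh()
  states <- list()
  zs <- mesh$nodes[, 3]
  # rigid rotation about the long axis
  a <- 0.3
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  states[[1]] <- as.vector(t(mesh$nodes %*% t(Rz) - mesh$nodes))
  # linear twist theta(z) = k z
  k <- 0.05  # rad per mm
  twist_u <- function(kk) {
    ang <- kk * zs
    cbind(mesh$nodes[, 1] * cos(ang) - mesh$nodes[, 2] * sin(ang) -
            mesh$nodes[, 1],
          mesh$nodes[, 1] * sin(ang) + mesh$nodes[, 2] * cos(ang) -
            mesh$nodes[, 2],
          0)
  }
  states[[2]] <- as.vector(t(twist_u(k)))
  fake <- list(mesh = mesh, states = states, time = c(0, 1))
  tor <- torsion(fake)
  expect_lt(abs(tor$theta_torsion[1]), 1e-10)
  expect_equal(tor$theta_base[1], a * 180 / pi, tolerance = 1e-6)
  sl <- attr(tor, "slices")
  z_b <- sl$z_base + 0.2 * sl$L
  z_a <- sl$z_apex - 0.2 * sl$L
  # the slice rotation equals the twist angle at the slice centroid, so the
  # analytic expectation uses the centroid separation
  expected <- k * (sl$z_mean_apex - sl$z_mean_base) * 180 / pi
  expect_lt(abs(tor$theta_torsion[2] - expected) / abs(expected), 0.02)
  # and the nominal slice heights bound the centroids
  expect_lt(abs(sl$z_mean_base - z_b), sl$band_half * sl$L)
  expect_lt(abs(sl$z_mean_apex - z_a), sl$band_half * sl$L)
  # synthetic +5 deg apex / -2 deg base rotation
  band <- 0.05 * sl$L
  ang <- numeric(nrow(mesh$nodes))
  ang[abs(zs - z_a) <= band] <- 5 * pi / 180
  ang[abs(zs - z_b) <= band] <- -2 * pi / 180
  u3 <- cbind(mesh$nodes[, 1] * cos(ang) - mesh$nodes[, 2] * sin(ang) -
                mesh$nodes[, 1],
              mesh$nodes[, 1] * sin(ang) + mesh$nodes[, 2] * cos(ang) -
                mesh$nodes[, 2], 0)
  fake3 <- list(mesh = mesh, states = list(as.vector(t(u3))), time = 0)
  tor3 <- torsion(fake3)
  expect_equal(tor3$theta_torsion[1], 7, tolerance = 1e-6)
})

test_that("infarct displacement separates axial and radial components", {
  mesh <- coarse_mesh()
  nn <- nrow(mesh$nodes)
  zero <- infarct_displacement(mesh, numeric(3 * nn))
  expect_equal(zero$fraction_positive_dz, 0)
  expect_equal(zero$max_outward_radial, 0)
  # uniform apex-ward translation
  up <- rep(c(0, 0, 1), nn)
  expect_equal(infarct_displacement(mesh, up)$fraction_positive_dz, 1)
  # synthetic radial bulge of known amplitude on infarct element nodes
  amp <- 0.123
  idx <- which(mesh$region == "infarct")
  nodes_inf <- sort(unique(as.vector(mesh$elems[idx, ])))
  um <- matrix(0, nn, 3)
  r <- sqrt(mesh$nodes[nodes_inf, 1]^2 + mesh$nodes[nodes_inf, 2]^2)
  um[nodes_inf, 1] <- amp * mesh$nodes[nodes_inf, 1] / r
  um[nodes_inf, 2] <- amp * mesh$nodes[nodes_inf, 2] / r
  got <- infarct_displacement(mesh, as.vector(t(um)))
  # element means of nodal radial offsets shrink by the cosine of the node-
  # to-centroid azimuthal spread, so the recovered amplitude sits just below
  # the imposed one
  expect_lte(got$max_outward_radial, amp + 1e-12)
  expect_equal(got$max_outward_radial, amp, tolerance = 0.05)
  # meshes without an infarct are rejected
  m2 <- build_lv_mesh(lv_geometry_spec(), n_theta = 3, n_phi = 6,
                      n_layers = 1)
  expect_error(infarct_displacement(m2, numeric(3 * nrow(m2$nodes))),
               "no infarct")
})

test_that("an axial strain of zero is rejected by the lattice test", {
  panel <- tile_panel(auxetic_cell_spec(), 1, 1, sub = 0)
  expect_error(lattice_poisson_ratio(panel, preset_materials("LV"),
                                     axial_strain = 0), "nonzero")
})
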