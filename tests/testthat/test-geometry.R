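# Spheroidal geometry, meshing, infarct and fiber assignment.

spec <- lv_geometry_spec()

test_that("epicardial surface points follow the parameterization", {
  p <- epicardial_surface_point(pi / 2, 0, spec)
  expect_equal(as.numeric(p), c(2.72, 0, 5.92))
  apex <- epicardial_surface_point(0, 1.234, spec)
  expect_equal(as.numeric(apex), c(0, 0, 11.84))
  p90 <- epicardial_surface_point(pi / 2, pi / 2, spec)
  expect_equal(as.numeric(p90), c(0, 2.72, 5.92))
  expect_error(epicardial_surface_point(-0.1, 0, spec), "theta")
  expect_error(epicardial_surface_point(3.2, 0, spec), "theta")
  # scale acts uniformly
  sp2 <- lv_geometry_spec(scale = 2)
  expect_equal(as.numeric(epicardial_surface_point(pi / 2, 0, sp2)),
               c(5.44, 0, 11.84))
})

test_that("quadrature integrates degree-5 monomials exactly", {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  X10 <- rbind(corners, (corners[edges[, 1], ] + corners[edges[, 2], ]) / 2)
  exact <- function(a, b, c)
    factorial(a) * factorial(b) * factorial(c) / factorial(a + b + c + 3)
  for (a in 0:5) for (b in 0:(5 - a)) for (c in 0:(5 - a - b)) {
    expect_equal(quadrature_monomial(X10, a, b, c), exact(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("meshed cavity and wall volumes converge to the closed forms", {
  vols <- spheroid_volumes(spec)
  mesh <- coarse_mesh()
  expect_gt(mesh$meta$quality, 0.05)   # curved-element Jacobian-ratio floor
  expect_lt(abs(cavity_volume(mesh) - vols$cavity) / vols$cavity, 0.01)
  expect_lt(abs(sum(mesh$meta$elem_vol) - vols$wall) / vols$wall, 0.01)
  # refinement shrinks the error (order >= 2 observed on the cavity)
  m2 <- build_lv_mesh(spec, n_theta = 8, n_phi = 16, n_layers = 1)
  e1 <- abs(cavity_volume(mesh) - vols$cavity)
  e2 <- abs(cavity_volume(m2) - vols$cavity)
  expect_lt(e2, e1 / 3.5)
})

test_that("uniform scaling multiplies mesh volumes by scale cubed", {
  m1 <- build_lv_mesh(spec, n_theta = 3, n_phi = 6, n_layers = 1)
  sp2 <- lv_geometry_spec(scale = 1.7)
  m2 <- build_lv_mesh(sp2, n_theta = 3, n_phi = 6, n_layers = 1)
  expect_equal(sum(m2$meta$elem_vol), 1.7^3 * sum(m1$meta$elem_vol),
               tolerance = 1e-10)
  expect_equal(cavity_volume(m2), 1.7^3 * cavity_volume(m1),
               tolerance = 1e-10)
})

test_that("degenerate geometry is rejected", {
  expect_error(lv_geometry_spec(T_base = -1), "thickness")
  sp0 <- lv_geometry_spec(T_base = 0, T_apex = 0)
  expect_error(build_lv_mesh(sp0), "zero-thickness")
  expect_error(build_lv_mesh(spec, target_edge_length = 5), "coarse")
  expect_error(lv_geometry_spec(theta_max = 0), "theta_max")
})

test_that("infarct windows relabel deterministically", {
  mesh <- build_lv_mesh(spec, n_theta = 4, n_phi = 8, n_layers = 1)
  m0 <- assign_infarct(mesh, infarct_spec(dtheta = 0, dphi = 0))
  expect_equal(sum(m0$region == "infarct"), 0)
  mall <- assign_infarct(mesh, infarct_spec(dtheta = pi, dphi = pi))
  expect_equal(sum(mall$region == "infarct"), nrow(mesh$elems))
  m1 <- assign_infarct(mesh, infarct_spec())
  m2 <- assign_infarct(mesh, infarct_spec())
  expect_identical(m1$region, m2$region)
})

test_that("infarct volume fraction matches a Monte-Carlo window oracle", {
  inf <- infarct_spec()
  mesh <- assign_infarct(build_lv_mesh(spec, n_theta = 8, n_phi = 16,
                                       n_layers = 2), inf)
  frac_mesh <- sum(mesh$meta$elem_vol[mesh$region == "infarct"]) /
    sum(mesh$meta$elem_vol)
  # sample points uniformly in the wall solid via parameter-space sampling
  # weighted by the blend-map Jacobian
  set.seed(123)
  n <- 2e5
  th <- acos(runif(n, cos(spec$theta_max), 1))  # proposal density ~ sin
  ph <- runif(n, -pi, pi)
  ss <- runif(n)
  rho <- spec$R_endo + spec$T_base * ss
  hh <- spec$H_endo + spec$T_apex * ss
  jac <- rho * (rho * spec$T_apex * cos(th) * (1 + cos(th)) +
                  spec$T_base * hh * sin(th)^2)  # / sin(th) proposal
  inwin <- abs(th - inf$theta_c) <= inf$dtheta &
    abs(atan2(sin(ph - inf$phi_c), cos(ph - inf$phi_c))) <= inf$dphi &
    ss <= inf$transmurality
  frac_mc <- sum(jac[inwin]) / sum(jac)
  expect_lt(abs(frac_mesh - frac_mc), 0.03)
})

test_that("infarct labeling is invariant under node reordering", {
  mesh <- build_lv_mesh(spec, n_theta = 3, n_phi = 6, n_layers = 1)
  set.seed(1)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- mesh
  m2$nodes <- mesh$nodes[perm, ]
  m2$param <- mesh$param[perm, ]
  m2$elems <- matrix(inv[mesh$elems], ncol = 10)
  m2$elem_param <- sleevesim:::elem_param_centroids(m2)
  a1 <- assign_infarct(mesh, infarct_spec())
  a2 <- assign_infarct(m2, infarct_spec())
  expect_identical(a1$region, a2$region)
})

test_that("rule-based fibers interpolate the helix transmurally", {
  mesh <- build_lv_mesh(spec, n_theta = 4, n_phi = 8, n_layers = 2)
  m0 <- assign_fibers(mesh, 0, 0)
  # zero helix: every fiber is the local circumferential unit vector
  for (e in sample(nrow(mesh$elems), 20)) {
    phc <- unname(m0$elem_param[e, "phi"])
    expect_equal(as.numeric(m0$fibers$N[e, ]),
                 c(-sin(phc), cos(phc), 0), tolerance = 1e-9)
  }
  mh <- assign_fibers(mesh, 60, -60)
  expect_lt(max(abs(sqrt(rowSums(mh$fibers$N^2)) - 1)), 1e-12)
  # helix angle interpolates linearly in transmural depth, so an element at
  # mid-depth carries a zero helix
  expect_equal(mh$fibers$helix, 60 - 120 * mh$elem_param[, "s"],
               tolerance = 1e-12)
  # fibers are orthogonal to the transmural direction
  for (e in sample(nrow(mesh$elems), 10)) {
    f <- mh$fibers$N[e, ]
    er <- mh$fibers$frames[e, 4:6]
    expect_lt(abs(sum(f * er)), 1e-9)
  }
})
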