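# Static solver, cavity volume, cardiac cycle and ED calibration.

test_that("the unloaded state is an exact equilibrium", {
  mesh <- coarse_mesh()
  sol <- solve_static(mesh, 0, 0, materials = wall_materials())
  expect_equal(max(abs(sol$u)), 0)
  # stored energy at rest is assembly roundoff (the bulk penalty amplifies
  # partition-of-unity cancellation error)
  expect_lt(abs(sol$energy), 1e-9)
})

test_that("cavity volume is exact, translation-invariant and scale-cubed", {
  mesh <- coarse_mesh()
  vols <- spheroid_volumes(mesh$spec)
  V0 <- cavity_volume(mesh)
  expect_lt(abs(V0 - vols$cavity) / vols$cavity, 0.01)
  # rigid translation leaves the closed-surface volume unchanged
  u_tr <- rep(c(0.37, -1.2, 5.1), nrow(mesh$nodes))
  expect_equal(cavity_volume(mesh, u_tr), V0, tolerance = 1e-12 * V0)
  # uniform scaling of the deformed shape by 2 multiplies the volume by 8
  u_sc <- as.vector(t(2 * mesh$nodes - mesh$nodes))
  expect_equal(cavity_volume(mesh, u_sc), 8 * V0, tolerance = 1e-10 * V0)
})

test_that("mid-wall hoop stress approaches the thin-shell estimate", {
  # thin-wall spheroid in the linear regime: hoop stress ~ P r / (2 h) at
  # the equator of a sphere-like cap; tolerance reflects the spheroidal
  # shape and finite thickness
  sp <- lv_geometry_spec(R_epi = 5.15, H_epi = 5.25, T_base = 0.15,
                         T_apex = 0.15)
  mesh <- build_lv_mesh(sp, n_theta = 6, n_phi = 12, n_layers = 1)
  mesh <- assign_fibers(mesh, 0, 0)
  P <- 0.002   # small enough for linearity
  mats <- list(remote = preset_materials("LV", K_factor = 1000))
  sys <- sleevesim:::solver_system(mesh, mats)
  sol <- solve_static(sys, P, 0)
  fl <- fe_fields(mesh$nodes, mesh$elems - 1L, sol$u, sys$matpar,
                  sys$frames, numeric(nrow(mesh$elems)))
  # the wall construction offsets the surfaces in R and H separately, so
  # the apical wall is about twice as thick as the basal one; the thin-shell
  # estimate with h = T_base applies near the equator
  eq <- which(mesh$elem_param[, "theta"] > 1.2)
  # hoop = circumferential normal stress: rotate cauchy into (e_c, ...)
  hoop <- vapply(eq, function(e) {
    phc <- mesh$elem_param[e, "phi"]
    ec <- c(-sin(phc), cos(phc), 0)
    s <- fl$cauchy[e, ]
    Tm <- matrix(c(s[1], s[4], s[5], s[4], s[2], s[6], s[5], s[6], s[3]), 3)
    drop(ec %*% Tm %*% ec)
  }, 0)
  r_mid <- (sp$R_endo + sp$R_epi) / 2
  laplace <- P * r_mid / (2 * 0.15)
  expect_lt(abs(mean(hoop) - laplace) / laplace, 0.2)
})

test_that("passive inflation keeps the wall nearly incompressible", {
  mesh <- coarse_mesh()
  sys <- sleevesim:::solver_system(mesh, wall_materials())
  sol <- solve_static(sys, 1.5, 0)
  expect_lt(abs(sol$Jmin - 1), 0.02)
  expect_lt(abs(sol$Jmax - 1), 0.02)
  # deformed wall volume conserved within 2%
  fl <- fe_fields(mesh$nodes, mesh$elems - 1L, sol$u, sys$matpar,
                  sys$frames, numeric(nrow(mesh$elems)))
  expect_lt(abs(sum(fl$vol_def) - sum(fl$vol0)) / sum(fl$vol0), 0.02)
})

test_that("the solution is objective under rotations of the whole problem", {
  # rotate the discrete problem about the long axis (same connectivity,
  # rotated coordinates, fibers and follower loads; the basal-plane
  # constraints are invariant under rotations about z): the solution must
  # be the rotated solution of the original problem
  mesh <- coarse_mesh()
  sys <- sleevesim:::solver_system(mesh, wall_materials())
  sol <- solve_static(sys, 1.0, 0)
  a <- 0.7712   # arbitrary angle
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  m2 <- mesh
  m2$nodes <- mesh$nodes %*% t(Rz)
  fr <- mesh$fibers$frames
  m2$fibers$frames <- cbind(fr[, 1:3] %*% t(Rz), fr[, 4:6] %*% t(Rz),
                            fr[, 7:9] %*% t(Rz))
  sys2 <- sleevesim:::solver_system(m2, wall_materials())
  sol2 <- solve_static(sys2, 1.0, 0)
  u1 <- matrix(sol$u, ncol = 3, byrow = TRUE)
  u2 <- matrix(sol2$u, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(u2 - u1 %*% t(Rz))), 1e-6)
})

test_that("a short cycle is deterministic and ejects volume", {
  mesh <- coarse_mesh()
  ptr <- make_pressure_trace(1.5, 8, n_steps = 8)
  atr <- make_activation_trace(30, n_steps = 8)
  run1 <- run_cardiac_cycle(mesh, wall_materials(), ptr, atr,
                            active = active_params(30))
  run2 <- run_cardiac_cycle(mesh, wall_materials(), ptr, atr,
                            active = active_params(30))
  expect_identical(run1$V, run2$V)          # bitwise determinism
  expect_lt(min(run1$V), max(run1$V))       # V(ES) < V(ED)
  expect_equal(run1$i_ed, which.max(run1$V))
})

test_that("without contraction the volume holds at the filling pressure", {
  mesh <- coarse_mesh()
  # pressure reaches EDP at the end of filling and stays there
  n <- 6
  ptr <- make_pressure_trace(1.5, 8, n_steps = n)
  ptr$pressure[] <- 1.5 * sleevesim:::smoothstep(ptr$time / 0.4)
  atr <- make_activation_trace(0, n_steps = n)
  run <- run_cardiac_cycle(mesh, wall_materials(), ptr, atr)
  i_hold <- which(ptr$pressure == 1.5)
  expect_lt(diff(range(run$V[i_hold])) / max(run$V), 1e-8)
})

test_that("ED calibration closes on the target volume", {
  mats <- wall_materials()
  # zero-pressure fixed point: target equal to the unloaded volume gives the
  # exact cube-root scale
  vols <- spheroid_volumes(lv_geometry_spec())
  cal0 <- calibrate_ed_state(lv_geometry_spec(), mats,
                             target_EDV = vols$cavity * 8, EDP = 0,
                             n_theta = 3, n_phi = 6, n_layers = 1)
  expect_equal(cal0$scale, 2, tolerance = 1e-9)
  # with pressure: bisection closes within 0.5% and scale grows with target
  cal1 <- calibrate_ed_state(lv_geometry_spec(), mats, target_EDV = 400,
                             EDP = 1.5, n_theta = 3, n_phi = 6, n_layers = 1)
  expect_lt(abs(cal1$EDV - 400) / 400, 0.005)
  cal2 <- calibrate_ed_state(lv_geometry_spec(), mats, target_EDV = 800,
                             EDP = 1.5, n_theta = 3, n_phi = 6, n_layers = 1)
  expect_gt(cal2$scale, cal1$scale)
})
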