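# Synthetic waveforms, named scenarios and serialization.

test_that("pressure traces honor their landmarks", {
  ptr <- make_pressure_trace(1.5, 12, n_steps = 50)
  expect_equal(max(ptr$pressure), 12)
  expect_equal(ptr$pressure[ptr$i_end_filling], 1.5)
  expect_true(all(ptr$pressure >= 0))
  expect_equal(sum(ptr$pressure == 12), 1)      # single systolic peak
  expect_error(make_pressure_trace(12, 12), "degenerate")
  expect_error(make_pressure_trace(-1, 12), "EDP")
  # C1 continuity: numerical slope has no jumps at the joins
  tfine <- seq(0, 1, 1e-4)
  p <- ptr$fun(tfine)
  dp <- diff(p) / 1e-4
  expect_lt(max(abs(diff(dp))), 0.05 * max(abs(dp)))
})

test_that("activation traces are unimodal pulses with closed-form integral", {
  atr <- make_activation_trace(55, n_steps = 50)
  expect_equal(max(atr$T_Ca), max(atr$T_Ca[atr$T_Ca > 0]))
  expect_equal(sum(atr$T_Ca == max(atr$T_Ca)), 1)
  expect_true(all(atr$T_Ca[atr$time < 0.4] == 0))
  z <- make_activation_trace(0, n_steps = 20)
  expect_true(all(z$T_Ca == 0))
  # integral over the cycle = T_peak * window / 2 for the squared sine
  tfine <- seq(0, 1, 1e-5)
  num <- sum(atr$fun(tfine)) * 1e-5
  expect_equal(num, 55 * 0.45 / 2, tolerance = 1e-3)
})

test_that("landmarks are invariant under time-grid refinement", {
  p1 <- make_pressure_trace(1.5, 12, n_steps = 20)
  p2 <- make_pressure_trace(1.5, 12, n_steps = 200)
  expect_equal(max(p1$pressure), max(p2$pressure))
  expect_equal(p1$pressure[p1$i_end_filling], p2$pressure[p2$i_end_filling])
  a1 <- make_activation_trace(40, n_steps = 20)
  a2 <- make_activation_trace(40, n_steps = 400)
  expect_equal(a1$timings, a2$timings)
  expect_equal(max(a2$T_Ca), 40, tolerance = 1e-6)
})

test_that("named scenarios assemble the study configurations", {
  mi <- make_scenario("MI")
  expect_null(mi$sleeve)
  a0 <- make_scenario("MI_A0")
  expect_equal(a0$sleeve$zeta, 5)
  expect_equal(a0$sleeve$angle_deg, 0)
  expect_equal(a0$sleeve$cell$a, 1.17)
  expect_equal(a0$sleeve$cell$b, 0.98)
  expect_equal(a0$sleeve$cell$w, 0.11)
  expect_equal(a0$sleeve$cell$t, 0.16)
  expect_error(make_scenario("MI_S9"), "available")
  # zeta variants wire through to the sleeve material
  for (z in c(1.0, 1.4, 2.0, 5.0, 10, 50)) {
    sc <- make_scenario("MI_S0", zeta = z)
    mats <- sleevesim:::scenario_materials(sc)
    expect_equal(mats$sleeve$c_region, z * 0.416, tolerance = 1e-12)
  }
})

test_that("scenarios survive a YAML round trip", {
  sc <- make_scenario("MI_A0", zeta = 10, n_steps = 9, scale = 2.1,
                      T_Ca_peak = 48)
  f <- tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, f)
  sc2 <- read_scenario_yaml(f)
  expect_equal(sc2$name, "MI_A0")
  expect_equal(sc2$sleeve$zeta, 10)
  expect_equal(sc2$geometry$scale, 2.1)
  expect_equal(sc2$active$T_Ca_peak, 48)
  expect_equal(sc2$n_steps, 9)
  unlink(f)
})

test_that("mesh and panel writers emit readable files", {
  mesh <- coarse_mesh()
  f_vtu <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f_vtu, cell_data = list(vol = mesh$meta$elem_vol))
  ln <- readLines(f_vtu)
  expect_true(any(grepl("UnstructuredGrid", ln)))
  expect_true(any(grepl('Name="region"', ln)))
  f_msh <- tempfile(fileext = ".msh")
  write_msh(mesh, f_msh)
  back <- read_msh(f_msh)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-12)
  expect_identical(back$elems, matrix(as.integer(mesh$elems),
                                      nrow(mesh$elems)))
  expect_identical(back$region, mesh$region)
  panel <- tile_panel(auxetic_cell_spec(), 1, 2, sub = 0)
  f_svg <- tempfile(fileext = ".svg")
  write_panel_svg(panel, f_svg)
  expect_true(any(grepl("polygon", readLines(f_svg))))
  unlink(c(f_vtu, f_msh, f_svg))
})
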