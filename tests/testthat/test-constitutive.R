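# Fung-type passive law, active stress and Frank-Starling modulation.

lv <- preset_materials("LV")

test_that("material presets carry the estimated passive constants", {
  expect_equal(lv$c_region, 0.416)
  expect_equal(c(lv$B1, lv$B2, lv$B3), c(47.15, 22.55, 24.60))
  expect_equal(preset_materials("RV")$c_region, 0.297)
  expect_equal(preset_materials("infarct")$c_region, 0.649)
  expect_error(passive_params(-1, 1, 1, 1), "c_region")
  expect_error(passive_params(1, 1, 1, 1, K = 0.5), "incompressibility")
})

test_that("the anisotropy quadratic form matches direct arithmetic", {
  E0 <- matrix(0, 3, 3)
  expect_identical(q_form(E0, lv), 0)
  E1 <- E0; E1[1, 1] <- 0.1
  expect_equal(q_form(E1, lv), 47.15 * 0.01)   # 0.4715
  E2 <- E0; E2[1, 2] <- E2[2, 1] <- 0.1
  expect_equal(q_form(E2, lv), 24.60 * 0.01)   # 0.2460
  E3 <- E0; E3[2, 3] <- E3[3, 2] <- 0.05
  expect_equal(q_form(E3, lv), 2 * 22.55 * 0.05^2)
  bad <- E0; bad[1, 2] <- 1
  expect_error(q_form(bad, lv), "symmetric")
})

test_that("strain energy evaluates the deviatoric and volumetric parts", {
  expect_equal(strain_energy(deformation_state(diag(3)), lv), 0)
  # isochoric fiber-direction strain Ebar11 = 0.1: build F = diag(l1,l2,l2)
  # with l1 l2^2 = 1 and E11 = (l1^2-1)/2 = 0.1
  l1 <- sqrt(1.2); l2 <- 1 / sqrt(l1)
  st <- deformation_state(diag(c(l1, l2, l2)))
  expect_equal(st$J, 1, tolerance = 1e-12)
  W <- strain_energy(st, lv)
  Q <- q_form(st$Ebar, lv)
  expect_equal(W, 0.416 * (exp(Q) - 1), tolerance = 1e-12)
  expect_equal(0.416 * (exp(0.4715) - 1), 0.2506, tolerance = 2e-4)
  # pure dilation with the c-term suppressed: J = 1.1, K = 100
  p_dil <- passive_params(1e-9, 1, 1, 1, K = 100)
  st_d <- deformation_state(diag(rep(1.1^(1 / 3), 3)))
  expect_equal(strain_energy(st_d, p_dil),
               50 * ((1.1^2 - 1) / 2 - log(1.1)), tolerance = 1e-9)
  expect_equal(50 * ((1.21 - 1) / 2 - log(1.1)), 0.4845, tolerance = 2e-4)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "det")
})

test_that("passive Cauchy stress is the derivative of the strain energy", {
  set.seed(42)
  expect_equal(passive_cauchy_stress(deformation_state(diag(3)), lv,
                                     c(1, 0, 0)),
               matrix(0, 3, 3))
  for (k in 1:25) {
    F <- random_F()
    fib <- random_unit()
    sig <- passive_cauchy_stress(deformation_state(F), lv, fib)
    sig_fd <- fd_cauchy_stress(F, lv, fib)
    expect_lt(max(abs(sig - sig_fd)) / max(abs(sig_fd)), 1e-5)
  }
})

test_that("passive stress is objective and transversely isotropic", {
  set.seed(7)
  for (k in 1:10) {
    F <- random_F(); fib <- random_unit()
    sig <- passive_cauchy_stress(deformation_state(F), lv, fib)
    R <- random_rotation()
    sig_rot <- passive_cauchy_stress(deformation_state(R %*% F), lv, fib)
    expect_lt(max(abs(sig_rot - R %*% sig %*% t(R))), 1e-10)
  }
  # rotating the reference about the fiber axis leaves the response
  # invariant (B2 couples axes 2 and 3 symmetrically)
  fib <- c(1, 0, 0)
  a <- 0.83
  Rf <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  for (k in 1:10) {
    F <- random_F()
    W1 <- strain_energy(deformation_state(F), lv,
                        sleevesim:::fiber_frame(fib))
    W2 <- strain_energy(deformation_state(F %*% Rf), lv,
                        sleevesim:::fiber_frame(fib))
    expect_equal(W1, W2, tolerance = 1e-10)
  }
})

test_that("strain energy is non-negative and vanishes only at rest", {
  set.seed(11)
  for (k in 1:2000) {
    F <- random_F()
    W <- strain_energy(deformation_state(F), lv,
                       sleevesim:::fiber_frame(random_unit()))
    expect_gte(W, 0)
  }
  st <- deformation_state(diag(3))
  expect_identical(strain_energy(st, lv), 0)
})

test_that("the R and compiled stress paths agree", {
  set.seed(3)
  for (k in 1:10) {
    F <- random_F(); fib <- random_unit()
    st <- deformation_state(F)
    Rfr <- sleevesim:::fiber_frame(fib)
    sig_R <- passive_cauchy_stress(st, lv, fib)
    S_cpp <- pk2_stress_cpp(crossprod(F), lv$c_region, lv$B1, lv$B2, lv$B3,
                            lv$K, Rfr, 0)
    sig_cpp <- F %*% S_cpp %*% t(F) / det(F)
    expect_lt(max(abs(sig_R - sig_cpp)), 1e-10)
  }
})

test_that("active stress follows the fiber-aligned rank-one form", {
  N <- c(0, 1, 0)
  expect_equal(active_second_pk(0, 10, N), 10 * tcrossprod(N))
  expect_equal(active_second_pk(0.1, 10, N), (10 / 1.2) * tcrossprod(N))
  expect_equal(max(abs(active_second_pk(0.3, 0, N))), 0)
  expect_error(active_second_pk(-0.6, 10, N), "fiber stretch")
  S <- active_second_pk(0.05, 7, random_unit())
  expect_equal(qr(S)$rank, 1)
})

test_that("Frank-Starling modulation is linear and clamped at zero", {
  ap <- active_params(10, fs_slope = 2, ref_stretch = 1.0)
  expect_equal(frank_starling_Ta(10, 1.0, ap), 10)
  expect_equal(frank_starling_Ta(10, 0.9, ap), 8.0)
  expect_equal(frank_starling_Ta(10, 0.2, ap), 0)
  set.seed(5)
  stretches <- runif(200, 0.2, 1.4)
  expect_true(all(frank_starling_Ta(10, stretches, ap) >= 0))
})

test_that("sleeve stiffness scales with the stiffness ratio", {
  expect_equal(sleeve_stiffness(1.0, 0.416), 0.416)
  expect_equal(sleeve_stiffness(5.0, 0.416), 2.080)
  expect_equal(sleeve_stiffness(50, 0.416), 20.80)
  expect_error(sleeve_stiffness(0, 0.416), "zeta")
})
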