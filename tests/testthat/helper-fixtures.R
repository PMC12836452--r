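# Shared fixtures, built lazily and memoized so expensive objects (meshes,
# cycle runs) are constructed once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

coarse_mesh <- function() {
  fixture("coarse_mesh", function() {
    mesh <- build_lv_mesh(lv_geometry_spec(), n_theta = 4, n_phi = 8,
                          n_layers = 1)
    mesh <- assign_infarct(mesh, infarct_spec())
    assign_fibers(mesh)
  })
}

wall_materials <- function(K_factor = 10000) {
  list(remote = preset_materials("LV", K_factor = K_factor),
       infarct = preset_materials("infarct", K_factor = K_factor))
}

# random admissible deformation gradient with J in [0.9, 1.1]
random_F <- function() {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    J <- det(F)
    if (J > 0.9 && J < 1.1) return(F)
  }
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rotation matrix about a random axis
random_rotation <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# central finite difference of the strain energy with respect to F,
# converted to a Cauchy stress: sigma = (1/J) dW/dF F^T
fd_cauchy_stress <- function(F, params, fiber, h = 1e-6) {
  R <- sleevesim:::fiber_frame(fiber)
  dWdF <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    dWdF[i, j] <- (strain_energy(deformation_state(Fp), params, R) -
                     strain_energy(deformation_state(Fm), params, R)) / (2 * h)
  }
  J <- det(F)
  sig <- dWdF %*% t(F) / J
  0.5 * (sig + t(sig))
}

# shoelace polygon area (independent of the package's internal helper)
shoelace <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
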