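# Quasi-static nonlinear solution of the pressure-loaded, actively
# contracting ventricle.  Displacement-based total-Lagrangian formulation;
# Dirichlet constraints and linear multi-point constraints (sleeve ties) are
# eliminated structurally through a sparse transformation u = T u_r, so tied
# interfaces share one displacement field (no penalties, no contact).

#' Basal-plane boundary conditions
#'
#' Zero normal (out-of-plane) translation on every basal node, suppressing
#' out-of-plane motion while leaving in-plane contraction and rotation free;
#' the remaining rigid-body modes are removed by pinning one basal node in
#' both in-plane directions and restricting a second basal node's in-plane
#' motion to the line towards the first.
#'
#' @param mesh \code{\link{lv_mesh}}
#' @return object of class \code{boundary_conditions}: fixed dofs and one
#'   directional multi-point constraint
#' @export
boundary_conditions <- function(mesh) {
  bas <- sort(unique(as.vector(mesh$facets$basal_plane)))
  fixed <- 3 * (bas - 1) + 3                       # u_z = 0 on the base
  ph <- mesh$param[bas, 2]
  ph[is.na(ph)] <- 0
  pin <- bas[which.min(abs(atan2(sin(ph), cos(ph))))]       # phi ~ 0
  opp <- bas[which.max(abs(atan2(sin(ph), cos(ph))))]       # phi ~ pi
  fixed <- c(fixed, 3 * (pin - 1) + 1, 3 * (pin - 1) + 2)
  # second node: kill the remaining in-plane rigid rotation; constrain the
  # motion component perpendicular to the chord pin -> opp
  d <- mesh$nodes[opp, 1:2] - mesh$nodes[pin, 1:2]
  d <- d / sqrt(sum(d^2))
  tang <- c(-d[2], d[1])
  mpc <- NULL
  if (abs(tang[1]) >= abs(tang[2])) {
    # tang . u = 0  =>  u_x = -(tang_y/tang_x) u_y
    mpc <- list(list(dof = 3 * (opp - 1) + 1,
                     masters = 3 * (opp - 1) + 2,
                     w = -tang[2] / tang[1]))
  } else {
    mpc <- list(list(dof = 3 * (opp - 1) + 2,
                     masters = 3 * (opp - 1) + 1,
                     w = -tang[1] / tang[2]))
  }
  structure(list(fixed = sort(unique(fixed)), mpc = mpc,
                 pin_node = pin, second_node = opp),
            class = "boundary_conditions")
}

# build the sparse reduction u_full = T u_red from fixed dofs and MPCs
# (slave dof = sum w_i * master dof).  Chained constraints are resolved
# recursively; all chains terminate at free or fixed dofs.
constraint_transform <- function(ndof, fixed, mpc) {
  slave_of <- new.env(hash = TRUE)
  for (m in mpc) assign(as.character(m$dof), m, envir = slave_of)
  is_fixed <- logical(ndof); is_fixed[fixed] <- TRUE
  is_slave <- logical(ndof)
  for (m in mpc) is_slave[m$dof] <- TRUE
  if (any(is_fixed & is_slave))
    stop("dof both fixed and slaved; inconsistent constraints")
  free <- which(!is_fixed & !is_slave)
  red_index <- integer(ndof)
  red_index[free] <- seq_along(free)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  cache <- new.env(hash = TRUE)
  resolve <- function(dof) {
    # returns list(j = reduced indices, x = weights)
    key <- as.character(dof)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- if (is_fixed[dof]) {
      list(j = integer(0), x = numeric(0))
    } else if (is_slave[dof]) {
      m <- slave_of[[key]]
      jj <- integer(0); xx <- numeric(0)
      for (q in seq_along(m$masters)) {
        r <- resolve(m$masters[q])
        jj <- c(jj, r$j); xx <- c(xx, m$w[q] * r$x)
      }
      if (length(jj)) {
        agg <- rowsum(xx, jj)
        list(j = as.integer(rownames(agg)), x = as.numeric(agg))
      } else list(j = integer(0), x = numeric(0))
    } else {
      list(j = red_index[dof], x = 1)
    }
    cache[[key]] <- out
    out
  }
  # free dofs are identity rows (handled in bulk); only slaves need the
  # recursive resolution
  slaves <- which(is_slave)
  acc <- vector("list", length(slaves))
  for (q in seq_along(slaves)) {
    r <- resolve(slaves[q])
    acc[[q]] <- list(i = rep.int(slaves[q], length(r$j)), j = r$j, x = r$x)
  }
  ti <- c(free, unlist(lapply(acc, `[[`, "i")))
  tj <- c(red_index[free], unlist(lapply(acc, `[[`, "j")))
  tx <- c(rep(1, length(free)), unlist(lapply(acc, `[[`, "x")))
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, length(free)))
}

# material parameter matrix (c, B1, B2, B3, K) per element from region labels
material_matrix <- function(mesh, materials) {
  reg <- mesh$region
  out <- matrix(0, length(reg), 5)
  for (rn in unique(reg)) {
    p <- materials[[rn]]
    if (is.null(p)) stop(sprintf("no material assigned to region '%s'", rn))
    out[reg == rn, ] <- matrix(rep(c(p$c_region, p$B1, p$B2, p$B3, p$K),
                                   each = sum(reg == rn)), ncol = 5)
  }
  out
}

# per-element active tension from the calcium level and Frank-Starling state
elem_active_tension <- function(mesh, T_Ca, active, lambda_dia = NULL,
                                region_activation = c(remote = 1,
                                                      infarct = 0,
                                                      sleeve = 0)) {
  ne <- nrow(mesh$elems)
  act <- region_activation[mesh$region]
  act[is.na(act)] <- 0
  if (is.null(lambda_dia) || T_Ca == 0) return(T_Ca * act)
  frank_starling_Ta(T_Ca, lambda_dia, active) * act
}

# assemble reduced residual/stiffness at displacement u for pressure p.
# The triplet pattern is identical across calls with the same pressure
# on/off state, so the sparse skeleton (and the aggregation map from
# triplets to compressed-column slots) is built once and reused.
assemble_system <- function(sys, u, p, Ta_elem, want_K = TRUE) {
  asm <- fe_assemble(sys$mesh$nodes, sys$mesh$elems - 1L, u,
                     sys$matpar, sys$frames, Ta_elem, want_K)
  pl <- facet_pressure(sys$mesh$nodes, sys$endo_facets - 1L, u, p, want_K)
  R <- asm$fint - pl$fext
  out <- list(R = R, fext = pl$fext, energy = asm$energy,
              Jmin = asm$Jmin, Jmax = asm$Jmax)
  if (want_K) {
    Ki <- c(asm$Ki, pl$Ki); Kj <- c(asm$Kj, pl$Kj); Kx <- c(asm$Kx, pl$Kx)
    ndof <- length(u)
    tag <- if (p != 0) "skel_p" else "skel_0"
    ce <- sys$cache
    sk <- if (!is.null(ce)) ce[[tag]] else NULL
    if (is.null(sk)) {
      key <- (as.numeric(Kj)) * ndof + as.numeric(Ki)
      K <- Matrix::sparseMatrix(i = Ki + 1L, j = Kj + 1L, x = Kx,
                                dims = c(ndof, ndof))
      # dgCMatrix entries are column-major sorted, i.e. sorted by key
      pos <- match(key, sort(unique(key)))
      sk <- list(K = K, pos = pos)
      if (!is.null(ce)) ce[[tag]] <- sk
      out$K <- K
    } else {
      K <- sk$K
      K@x <- accumulate_triplets(Kx, sk$pos, length(K@x))
      out$K <- K
    }
  }
  out
}

# prepared solver context
solver_system <- function(mesh, materials, active = NULL,
                          lambda_dia = NULL,
                          region_activation = c(remote = 1, infarct = 0,
                                                sleeve = 0)) {
  if (is.null(mesh$fibers)) stop("mesh has no fiber field; call assign_fibers()")
  bc <- boundary_conditions(mesh)
  mpc <- c(bc$mpc, mesh$mpc)
  ndof <- 3 * nrow(mesh$nodes)
  Tm <- constraint_transform(ndof, bc$fixed, mpc)
  list(mesh = mesh, matpar = material_matrix(mesh, materials),
       frames = mesh$fibers$frames, bc = bc, T = Tm,
       endo_facets = mesh$facets$endocardium,
       active = active, lambda_dia = lambda_dia,
       region_activation = region_activation,
       # characteristic force scale (stiffness times area): floors the
       # convergence reference so unloaded states at assembly precision are
       # recognized as equilibria
       f_floor = 1e-3 * mean(material_matrix(mesh, materials)[, 1]) *
         sum(mesh$meta$elem_vol)^(2 / 3),
       cache = new.env(parent = emptyenv()))
}

#' Static equilibrium solve
#'
#' Newton iteration with structural constraint elimination, follower
#' (deformation-dependent) endocardial pressure, and load continuation:
#' failed steps are retried with halved load increments from the last
#' converged state.
#'
#' @param sys solver context from \code{solver_system} (internal) or an
#'   \code{\link{lv_mesh}}; in the latter case \code{materials} must be given
#' @param P_endo endocardial pressure, kPa
#' @param T_Ca calcium-induced activation level, kPa
#' @param u0 initial guess (full dof vector), zeros by default
#' @param materials named list of \code{\link{passive_params}} per region
#' @param tol relative residual tolerance
#' @param max_iter Newton iteration cap per load increment
#' @param verbose print convergence log
#' @return list: displacement \code{u}, convergence log, energy, J range
#' @export
solve_static <- function(sys, P_endo, T_Ca = 0, u0 = NULL, materials = NULL,
                         tol = 1e-8, max_iter = 25, verbose = FALSE) {
  if (inherits(sys, "lv_mesh")) {
    if (is.null(materials)) stop("materials required when passing a mesh")
    sys <- solver_system(sys, materials)
  }
  if (P_endo < 0) stop("P_endo must be >= 0")
  if (T_Ca < 0) stop("T_Ca must be >= 0")
  ndof <- 3 * nrow(sys$mesh$nodes)
  u <- if (is.null(u0)) numeric(ndof) else u0
  # start-of-step values implied by the initial guess are taken as converged
  lam0 <- 0; lam1 <- 1; dlam <- 1
  P0 <- attr(u, "P") %||% 0; T0 <- attr(u, "Ta") %||% 0
  log <- list()
  while (lam0 < 1 - 1e-12) {
    lam_t <- min(1, lam0 + dlam)
    p <- P0 + (P_endo - P0) * lam_t
    tca <- T0 + (T_Ca - T0) * lam_t
    Ta_elem <- elem_active_tension(sys$mesh, tca, sys$active,
                                   sys$lambda_dia, sys$region_activation)
    res <- newton_increment(sys, u, p, Ta_elem, tol, max_iter, verbose)
    if (res$converged) {
      u <- res$u
      lam0 <- lam_t
      log[[length(log) + 1]] <- c(lambda = lam_t, iters = res$iters,
                                  resid = res$resid)
      dlam <- min(1, dlam * ifelse(res$iters <= 6, 2, 1))
    } else {
      dlam <- dlam / 2
      if (dlam < 1 / 1024)
        stop(sprintf(
          "static solve failed to converge (last relative residual %.3e)",
          res$resid))
    }
  }
  attr(u, "P") <- P_endo; attr(u, "Ta") <- T_Ca
  final <- assemble_system(sys, u, P_endo,
                           elem_active_tension(sys$mesh, T_Ca, sys$active,
                                               sys$lambda_dia,
                                               sys$region_activation),
                           want_K = FALSE)
  list(u = u, log = log, energy = final$energy,
       Jmin = final$Jmin, Jmax = final$Jmax)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sparse symmetric solve with escalating Levenberg-style diagonal shifts:
# a transiently indefinite Newton tangent yields a damped (shifted) step
# instead of a failed factorization.  Every solve is validated through its
# linear residual before being trusted.
solve_spd_cached <- function(sys, Ks, b) {
  dscale <- max(abs(Matrix::diag(Ks)))
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(numeric(length(b)))
  try_factor <- function(LDL, super, tau) {
    x <- tryCatch({
      ch <- Matrix::Cholesky(Ks, LDL = LDL, super = super, perm = TRUE,
                             Imult = tau)
      x0 <- as.numeric(Matrix::solve(ch, b))
      # one iterative-refinement pass against the (shifted) system
      r <- b - as.numeric(Ks %*% x0) - tau * x0
      x0 + as.numeric(Matrix::solve(ch, r))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(x) && all(is.finite(x))) {
      lin_res <- sqrt(sum((as.numeric(Ks %*% x) + tau * x - b)^2)) / nb
      if (lin_res < 1e-6) return(x)
    }
    NULL
  }
  # positive-definite fast path, then LDL^T (handles the transiently
  # indefinite follower-load tangent exactly), then escalating shifts
  x <- try_factor(FALSE, TRUE, 0)
  if (!is.null(x)) return(x)
  x <- try_factor(TRUE, FALSE, 0)
  if (!is.null(x)) return(x)
  for (tau in c(1e-8, 1e-5, 1e-2, 1) * dscale) {
    x <- try_factor(FALSE, TRUE, tau)
    if (!is.null(x)) return(x)
  }
  tryCatch(as.numeric(Matrix::solve(Ks, b)), error = function(e) NULL)
}

newton_increment <- function(sys, u, p, Ta_elem, tol, max_iter, verbose) {
  Tm <- sys$T
  rnorm_red <- function(uu, want_K) {
    a <- assemble_system(sys, uu, p, Ta_elem, want_K)
    a$Rr <- as.numeric(Matrix::crossprod(Tm, a$R))
    a$ref <- max(sqrt(sum(as.numeric(Matrix::crossprod(Tm, a$fext))^2)), 1e-8)
    a$nr <- sqrt(sum(a$Rr^2))
    ce <- sys$cache
    if (!is.null(ce)) ce$f_ref_max <- max(ce$f_ref_max %||% 0, a$ref)
    a
  }
  a <- tryCatch(rnorm_red(u, FALSE), error = function(e) NULL)
  if (is.null(a)) return(list(converged = FALSE, resid = Inf))
  # convergence is relative to the largest of the current external load, the
  # increment's initial imbalance, and a small fraction of the largest load
  # the system has carried (so unloaded late-cycle states at machine-precision
  # equilibrium are accepted)
  nr0 <- a$nr
  floor_ref <- max(1e-3 * (sys$cache$f_ref_max %||% 0), sys$f_floor %||% 0)
  ref_of <- function(x) max(x$ref, nr0, floor_ref)
  hist_nr <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (verbose) message(sprintf("  newton %2d: |R| = %.3e (ref %.3e)",
                                 it - 1, a$nr, a$ref))
    if (is.finite(a$nr) && a$nr <= tol * ref_of(a))
      return(list(converged = TRUE, u = u, iters = it - 1,
                  resid = a$nr / ref_of(a)))
    # numerical floor: accept stagnation well below a soft tolerance (the
    # attainable residual scales with the bulk penalty's cancellation noise)
    hist_nr <- c(hist_nr, a$nr)
    if (it > 4 && is.finite(a$nr) && a$nr <= 1e-6 * ref_of(a) &&
        a$nr > 0.9 * min(utils::head(hist_nr, -1)))
      return(list(converged = TRUE, u = u, iters = it - 1,
                  resid = a$nr / ref_of(a)))
    aK <- tryCatch(rnorm_red(u, TRUE), error = function(e) NULL)
    if (is.null(aK)) return(list(converged = FALSE, resid = a$nr / ref_of(a)))
    Kr <- Matrix::crossprod(Tm, aK$K %*% Tm)
    # follower pressure on the closed cavity is conservative, so the exact
    # reduced tangent is symmetric; symmetrize and use a sparse Cholesky
    # (symbolic factor cached across iterations), regularizing the diagonal
    # if a transient Newton state turns the tangent indefinite
    Ks <- Matrix::forceSymmetric(Kr + Matrix::t(Kr)) / 2
    if (!all(is.finite(Ks@x)))
      return(list(converged = FALSE, resid = a$nr / ref_of(a)))
    du_r <- solve_spd_cached(sys, Ks, -a$Rr)
    if (is.null(du_r) || !all(is.finite(du_r)))
      return(list(converged = FALSE, resid = a$nr / ref_of(a)))
    step <- 1
    for (ls in 1:7) {
      u_try <- u + as.numeric(Tm %*% (step * du_r))
      a_try <- tryCatch(rnorm_red(u_try, FALSE), error = function(e) NULL)
      if (!is.null(a_try) && is.finite(a_try$nr) &&
          (a_try$nr < a$nr * 1.5 || a_try$nr <= tol * ref_of(a_try))) break
      step <- step / 2
      a_try <- NULL
    }
    if (is.null(a_try)) return(list(converged = FALSE, resid = a$nr / ref_of(a)))
    if (verbose && step < 1)
      message(sprintf("    line search accepted step %.3f", step))
    u <- u_try; a <- a_try
  }
  if (is.finite(a$nr) && a$nr <= tol * ref_of(a))
    return(list(converged = TRUE, u = u, iters = max_iter,
                resid = a$nr / ref_of(a)))
  list(converged = FALSE, resid = a$nr / ref_of(a))
}

#' Deformed cavity volume
#'
#' Volume enclosed by the deformed endocardial surface closed by its basal
#' cap, computed with the divergence theorem
#' \eqn{V = \frac{1}{3}\oint x \cdot n \, dA}; exact for the quadratic
#' facets used here, and translation-invariant because the surface is closed.
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param u displacement vector (full dofs), zeros for the reference state
#' @return cavity volume, mm^3
#' @export
cavity_volume <- function(mesh, u = NULL) {
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  endo <- mesh$facets$endocardium
  if (is.null(endo) || nrow(endo) == 0) stop("no endocardial facet set")
  # reverse orientation: stored facets are wall-element-outward (into the
  # cavity); the divergence theorem needs cavity-outward normals
  endo_rev <- endo[, c(1, 3, 2, 6, 5, 4), drop = FALSE]
  V <- surface_divergence_volume(mesh$nodes, endo_rev - 1L, u)

  # basal cap: quadratic fan closing the endocardial ring exactly
  rc <- mesh$endo_ring$corners; rm <- mesh$endo_ring$mids
  def <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  ctr <- colMeans(def[rc, , drop = FALSE])
  nr <- length(rc)
  cap_nodes <- rbind(ctr, def[rc, , drop = FALSE], def[rm, , drop = FALSE])
  # also midpoints centre-corner
  mid_cc <- (matrix(ctr, nr, 3, byrow = TRUE) + def[rc, , drop = FALSE]) / 2
  cap_nodes <- rbind(cap_nodes, mid_cc)
  idx_ctr <- 1L
  idx_c <- 1L + seq_len(nr)
  idx_m <- 1L + nr + seq_len(nr)
  idx_cc <- 1L + 2L * nr + seq_len(nr)
  nxt <- c(2:nr, 1L)
  # facets (centre, c_{i+1}, c_i) so the cap normal points out of the cavity
  cap_facets <- cbind(idx_ctr, idx_c[nxt], idx_c,
                      idx_cc[nxt], idx_m, idx_cc)
  V_cap <- surface_divergence_volume(cap_nodes, cap_facets - 1L,
                                     numeric(3 * nrow(cap_nodes)))
  V + V_cap
}

#' Run a full cardiac cycle
#'
#' Sequential static solves over a normalized-time pressure and activation
#' schedule, each warm-started from the previous step.  End-diastole is the
#' step of maximum cavity volume, end-systole the minimum.
#'
#' @param mesh \code{\link{lv_mesh}} with fibers assigned
#' @param materials named list of \code{\link{passive_params}} per region
#' @param P_trace \code{\link{make_pressure_trace}} result
#' @param activation_trace \code{\link{make_activation_trace}} result
#' @param active \code{\link{active_params}}; when its reference stretch is
#'   \code{NA} the mean remote diastolic fiber stretch of this run is used
#' @param store_states keep the displacement field of every step
#' @param verbose print per-step convergence
#' @return object of class \code{cycle_result}: time grid, V(t), P(t),
#'   activation, ED/ES indices, stored states and the diastolic stretch field
#' @export
run_cardiac_cycle <- function(mesh, materials, P_trace, activation_trace,
                              active = active_params(0),
                              store_states = TRUE, verbose = FALSE) {
  if (!identical(P_trace$time, activation_trace$time))
    stop("pressure and activation traces must share the time grid")
  tgrid <- P_trace$time
  ns <- length(tgrid)
  sys <- solver_system(mesh, materials, active = active)

  # diastolic pass: inflate to the end of filling to obtain the diastolic
  # fiber stretch field for the Frank-Starling modulation
  i_ed_fill <- P_trace$i_end_filling
  u <- numeric(3 * nrow(mesh$nodes))
  sol <- solve_static(sys, P_trace$pressure[i_ed_fill], 0, u0 = u)
  fl <- fe_fields(mesh$nodes, mesh$elems - 1L, sol$u, sys$matpar,
                  sys$frames, numeric(nrow(mesh$elems)))
  lambda_dia <- fl$fiber_stretch
  if (is.na(active$ref_stretch)) {
    rem <- mesh$region == "remote"
    active$ref_stretch <- sum(lambda_dia[rem] * fl$vol0[rem]) /
      sum(fl$vol0[rem])
  }
  sys$active <- active
  sys$lambda_dia <- lambda_dia

  V <- numeric(ns); Jmin <- numeric(ns); Jmax <- numeric(ns)
  wall_vol <- numeric(ns)
  states <- if (store_states) vector("list", ns) else NULL
  u <- numeric(3 * nrow(mesh$nodes))
  for (i in seq_len(ns)) {
    sol <- solve_static(sys, P_trace$pressure[i], activation_trace$T_Ca[i],
                        u0 = u, verbose = verbose)
    u <- sol$u
    V[i] <- cavity_volume(mesh, u)
    if (V[i] <= 0) stop(sprintf("non-positive cavity volume at step %d", i))
    Jmin[i] <- sol$Jmin; Jmax[i] <- sol$Jmax
    if (store_states) states[[i]] <- u
    if (verbose) message(sprintf("step %2d/%d: t = %.3f  P = %6.3f kPa  V = %8.4f mm^3",
                                 i, ns, tgrid[i], P_trace$pressure[i], V[i]))
  }
  structure(list(time = tgrid, V = V, P = P_trace$pressure,
                 T_Ca = activation_trace$T_Ca,
                 i_ed = which.max(V), i_es = which.min(V),
                 states = states, lambda_dia = lambda_dia,
                 active = sys$active, Jmin = Jmin, Jmax = Jmax,
                 mesh = mesh, materials = materials),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("cycle_result: %d steps; EDV %.4f, ESV %.4f mm^3 (ED step %d, ES step %d)\n",
              length(x$time), max(x$V), min(x$V), x$i_ed, x$i_es))
  invisible(x)
}

#' Calibrate the end-diastolic state
#'
#' Deterministic bisection over the uniform geometric scale factor at fixed
#' end-diastolic pressure until the passively inflated cavity volume matches
#' \code{target_EDV}.  Scaling acts on the reference geometry before
#' inflation.
#'
#' @param spec \code{\link{lv_geometry_spec}} (its \code{scale} is replaced)
#' @param materials named list of \code{\link{passive_params}} per region
#' @param target_EDV target end-diastolic volume, mm^3
#' @param EDP end-diastolic pressure, kPa
#' @param infarct optional \code{\link{infarct_spec}} applied before scaling
#' @param n_theta,n_phi,n_layers mesh resolution
#' @param tol_frac relative volume closure (default 0.2%, comfortably inside
#'   the 0.5% contract)
#' @param max_iter bisection cap
#' @return list: \code{scale}, \code{EDP}, achieved \code{EDV}, the ED
#'   displacement and mesh, and the mean ED wall thickness (deformed wall
#'   volume divided by the deformed mid-surface area)
#' @export
calibrate_ed_state <- function(spec, materials, target_EDV, EDP = 1.5,
                               infarct = NULL,
                               n_theta = 4, n_phi = 8, n_layers = 1,
                               tol_frac = 0.002, max_iter = 40) {
  base_spec <- spec
  run_at <- function(s) {
    sp <- base_spec; sp$scale <- s
    mesh <- build_lv_mesh(sp, n_theta = n_theta, n_phi = n_phi,
                          n_layers = n_layers)
    if (!is.null(infarct)) mesh <- assign_infarct(mesh, infarct)
    mesh <- assign_fibers(mesh)
    sys <- solver_system(mesh, materials)
    sol <- solve_static(sys, EDP, 0)
    list(V = cavity_volume(mesh, sol$u), mesh = mesh, u = sol$u)
  }
  sp1 <- base_spec; sp1$scale <- 1
  V_unloaded <- spheroid_volumes(sp1)$cavity
  if (EDP == 0) {
    # no inflation: volumes scale exactly with s^3, the search has the
    # closed-form fixed point s = (V_target / V_unloaded)^(1/3)
    s <- (target_EDV / V_unloaded)^(1 / 3)
    r <- run_at(s)
    thick <- mean_wall_thickness(r$mesh, r$u)
    return(list(scale = s, EDP = EDP, EDV = r$V, u = r$u, mesh = r$mesh,
                mean_wall_thickness = thick))
  }
  s_hat <- (target_EDV / V_unloaded)^(1 / 3)
  lo <- 0.5 * s_hat; hi <- 1.2 * s_hat
  r_lo <- run_at(lo); r_hi <- run_at(hi)
  it_expand <- 0
  while (r_lo$V > target_EDV && it_expand < 8) {
    lo <- lo / 1.5; r_lo <- run_at(lo); it_expand <- it_expand + 1
  }
  while (r_hi$V < target_EDV && it_expand < 16) {
    hi <- hi * 1.3; r_hi <- run_at(hi); it_expand <- it_expand + 1
  }
  if (r_lo$V > target_EDV || r_hi$V < target_EDV)
    stop("calibration target unreachable within search bounds")
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- run_at(mid)
    best <- c(r, list(scale = mid))
    if (abs(r$V - target_EDV) <= tol_frac * target_EDV) break
    if (r$V < target_EDV) lo <- mid else hi <- mid
  }
  if (abs(best$V - target_EDV) > 0.005 * target_EDV)
    stop("bisection did not close the EDV target to 0.5%")
  thick <- mean_wall_thickness(best$mesh, best$u)
  list(scale = best$scale, EDP = EDP, EDV = best$V,
       u = best$u, mesh = best$mesh, mean_wall_thickness = thick)
}

# mean wall thickness of a (possibly deformed) state: wall volume divided by
# the mid-surface area, the latter approximated by the mean of the deformed
# endocardial and epicardial areas
mean_wall_thickness <- function(mesh, u = NULL) {
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  fl <- tet_volumes(mesh$nodes + matrix(u, ncol = 3, byrow = TRUE),
                    mesh$elems - 1L)
  wall <- mesh$region %in% c("remote", "infarct")
  vol <- sum(fl$vol[wall])
  a_endo <- facet_area(mesh, mesh$facets$endocardium, u)
  a_epi <- facet_area(mesh, mesh$facets$epicardium, u)
  vol / ((a_endo + a_epi) / 2)
}

# total area of a tri6 facet set in the deformed configuration
facet_area <- function(mesh, facets, u = NULL) {
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  def <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  # 3-point mid-edge rule, degree 2, adequate for areas of curved facets
  gp <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  total <- 0
  shp <- function(L) {
    c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1), L[3] * (2 * L[3] - 1),
      4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[1] * L[3])
  }
  dshp <- function(L) {
    rbind(c(-(4 * L[1] - 1), -(4 * L[1] - 1)),
          c(4 * L[2] - 1, 0),
          c(0, 4 * L[3] - 1),
          c(4 * (L[1] - L[2]), -4 * L[2]),
          c(4 * L[3], 4 * L[2]),
          c(-4 * L[3], 4 * (L[1] - L[3])))
  }
  for (g in 1:3) {
    dg <- dshp(gp[g, ])
    for (f in seq_len(nrow(facets))) {
      xf <- def[facets[f, ], , drop = FALSE]
      g1 <- colSums(xf * dg[, 1]); g2 <- colSums(xf * dg[, 2])
      cr <- c(g1[2] * g2[3] - g1[3] * g2[2],
              g1[3] * g2[1] - g1[1] * g2[3],
              g1[1] * g2[2] - g1[2] * g2[1])
      total <- total + sqrt(sum(cr^2)) / 3 * 0.5
    }
  }
  total
}
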