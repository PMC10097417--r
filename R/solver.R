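#' Solver configuration
#'
#' Time integration and nonlinear-solver settings for the staggered
#' two-field scheme: implicit Euler for the density balance, Newton
#' iteration with a consistent tangent for the quasi-static mechanics,
#' and adaptive time-step halving on Newton failure.
#'
#' @param dt time step, days.
#' @param t_end final time, days (t = 0 is gestational week 11; 175 days
#'   reaches week 36).
#' @param newton_tol relative residual tolerance of the Newton loop.
#' @param newton_max_iter maximum Newton iterations per step.
#' @param coupling `"staggered"` (one transport-growth-mechanics pass per
#'   step) or `"staggered_iterated"` (a second fixed-point pass).
#' @param max_subdivisions maximum successive halvings of `dt` when a
#'   step fails.
#' @param checkpoint_every store a full field checkpoint every this many
#'   accepted steps (0 = only the final state).
#' @param ratchet logical: enforce irreversible growth (componentwise
#'   non-decreasing multipliers). Disabling allows the raw algebraic law
#'   to reverse if the density drops.
#' @return an object of class `cg_solver`.
#' @export
solverConfig <- function(dt = 0.25, t_end = 175, newton_tol = 1e-8,
                         newton_max_iter = 25L,
                         coupling = c("staggered", "staggered_iterated"),
                         max_subdivisions = 8L, checkpoint_every = 0L,
                         ratchet = TRUE) {
  coupling <- match.arg(coupling)
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0")
  if (newton_tol <= 0) stop("newton_tol must be > 0")
  structure(list(dt = dt, t_end = t_end, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 coupling = coupling,
                 max_subdivisions = as.integer(max_subdivisions),
                 checkpoint_every = as.integer(checkpoint_every),
                 ratchet = isTRUE(ratchet)),
            class = "cg_solver")
}

# quadrature basis cache for a mesh: shape values, reference gradients,
# weights, GP positions, and the sparse GP-interpolation matrix Phi
gpBasis <- function(mesh) {
  gp <- cg_gp_basis(mesh$nodes, mesh$elems)
  gp$w <- as.numeric(gp$w)
  ngp <- length(gp$w); nn <- nrow(mesh$nodes)
  ii <- rep(seq_len(ngp), 4L)
  jj <- as.integer(mesh$elems[rep(seq_len(nrow(mesh$elems)), each = 4L), ])
  gp$Phi <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(gp$Nsh),
                                 dims = c(ngp, nn))
  gp
}

# deformed element size: longest diagonal of each quad
elementSize <- function(mesh, u) {
  xy <- mesh$nodes + u
  e <- mesh$elems
  d1 <- sqrt(rowSums((xy[e[, 3], , drop = FALSE] -
                      xy[e[, 1], , drop = FALSE])^2))
  d2 <- sqrt(rowSums((xy[e[, 4], , drop = FALSE] -
                      xy[e[, 2], , drop = FALSE])^2))
  pmax(d1, d2)
}

# fixed displacement dofs (1-based indices into the interleaved 2n
# vector): inner boundary pinned, symmetry edges constrained normal to
# themselves
mechFixedDofs <- function(mesh) {
  b <- mesh$boundary
  sort(unique(c(2L * b$inner - 1L, 2L * b$inner,
                2L * b$edge_x0 - 1L,   # x = 0 edge: u_x = 0
                2L * b$edge_y0)))      # y = 0 edge: u_y = 0
}

#' Assemble the growth-mechanics system
#'
#' Total-Lagrangian residual and consistent tangent of the quasi-static
#' balance of linear momentum, with the growth tensor built from the
#' supplied per-quadrature-point multipliers and fiber directions and
#' the neo-Hookean stress from the local Lame parameters.
#'
#' @param mesh a [buildQuarterAnnulus()] mesh (or compatible structure).
#' @param u n x 2 displacement matrix, mm.
#' @param growth list with per-GP `theta_perp`, `theta_par`.
#' @param mu_gp,lam_gp per-GP Lame parameters, kPa.
#' @param gp quadrature cache (computed from the mesh if omitted).
#' @param want_tangent assemble the sparse tangent as well.
#' @return list with `res` (length 2n), `K` (sparse tangent, if
#'   requested), `energy` (total strain energy, kPa mm^2), `minDetF`,
#'   `minJe`.
#' @export
assembleMechanics <- function(mesh, u, growth, mu_gp, lam_gp,
                              gp = gpBasis(mesh), want_tangent = TRUE) {
  nn <- nrow(mesh$nodes)
  out <- cg_mech_assemble(gp$dNdX, gp$w, mesh$elems, nn,
                          as.numeric(t(u)), growth$theta_perp,
                          growth$theta_par, gp$Ngp %||% gpFiber(gp),
                          mu_gp, lam_gp, want_tangent)
  out$res <- as.numeric(out$res)
  if (want_tangent)
    out$K <- Matrix::sparseMatrix(i = as.numeric(out$Ki),
                                  j = as.numeric(out$Kj),
                                  x = as.numeric(out$Kv),
                                  dims = c(2L * nn, 2L * nn))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gpFiber <- function(gp) referenceFiberDirection(gp$xy)

# Newton solve of the mechanics field at fixed growth state.
newtonMechanics <- function(mesh, u0, growth, mu_gp, lam_gp, gp,
                            fixed, tol = 1e-8, max_iter = 25L) {
  nn <- nrow(mesh$nodes)
  free <- setdiff(seq_len(2L * nn), fixed)
  u <- as.numeric(t(u0))
  Ngp <- gp$Ngp %||% gpFiber(gp)
  asm <- function(uv, tang) {
    cg_mech_assemble(gp$dNdX, gp$w, mesh$elems, nn, uv, growth$theta_perp,
                     growth$theta_par, Ngp, mu_gp, lam_gp, tang)
  }
  a <- asm(u, TRUE)
  if (a$minDetF <= 0 || a$minJe <= 0)
    return(list(converged = FALSE, reason = "element inversion at start"))
  r0 <- sqrt(sum(a$res[free]^2))
  rn <- r0
  iters <- 0L
  while (iters < max_iter) {
    if (rn <= tol * max(r0, 1e-8) || rn < 1e-12) break
    K <- Matrix::sparseMatrix(i = as.numeric(a$Ki), j = as.numeric(a$Kj),
                              x = as.numeric(a$Kv),
                              dims = c(2L * nn, 2L * nn))
    du <- tryCatch(
      as.numeric(Matrix::solve(K[free, free, drop = FALSE], -a$res[free])),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(converged = FALSE, reason = "singular tangent"))
    # backtracking line search on the residual norm
    alpha <- 1; ok <- FALSE
    for (ls in 1:6) {
      ut <- u; ut[free] <- ut[free] + alpha * du
      at <- asm(ut, FALSE)
      rt <- sqrt(sum(at$res[free]^2))
      if (at$minDetF > 0 && at$minJe > 0 &&
          (rt < rn || rt < tol * max(r0, 1e-8))) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok)
      return(list(converged = FALSE, reason = "line search failed"))
    u <- ut
    a <- asm(u, TRUE)
    rn <- sqrt(sum(a$res[free]^2))
    iters <- iters + 1L
  }
  if (rn > tol * max(r0, 1e-8) && rn >= 1e-12)
    return(list(converged = FALSE, reason = "max iterations"))
  list(converged = TRUE, u = matrix(u, ncol = 2, byrow = TRUE),
       iters = iters, resnorm = rn, resnorm0 = r0, energy = a$energy,
       minDetF = a$minDetF)
}

# static per-run transport/constitutive profile cache at the GPs
staticProfiles <- function(mesh, gp, mat, trans) {
  geom <- mesh$geom
  ri <- as.numeric(gp$Phi %*% mesh$material_radius)
  th <- atan2(gp$xy[, 2], gp$xy[, 1])
  kap <- growthFactors(ri, mat, geom$r_cp)
  list(ri = ri, theta = th,
       Ngp = gpFiber(gp),
       w_vz = zoneWeightVZ(ri, geom),
       mult = patternMultiplier(th, trans$heterogeneity),
       vprof = migrationSpeedProfile(ri, trans, geom$r_cp),
       dprof = diffusivityProfile(ri, trans, geom$r_cp),
       H20 = smoothHeaviside(ri - geom$r_cp, 20),
       kappa_perp = kap$kappa_perp, kappa_par = kap$kappa_par)
}

# one implicit-Euler transport step on frozen mechanics
transportStep <- function(mesh, gp, prof, u, c_old, dt, t_new, s_lag,
                          nu_e, trans, geom) {
  nn <- nrow(mesh$nodes)
  Gvz_s <- stretchModulatedRate(trans$G_vz, s_lag)
  Gosvz_s <- stretchModulatedRate(trans$G_osvz * prof$mult, s_lag)
  rsrc <- Gvz_s * prof$w_vz +
    Gosvz_s * zoneWeightOSVZ(prof$ri, t_new, geom)
  dtot <- prof$dprof + rep(nu_e, each = 4L)
  h_e <- elementSize(mesh, u)
  tr <- cg_transport_assemble(gp$Nsh, gp$dNdX, gp$w, mesh$elems, nn,
                              as.numeric(t(u)), c_old, prof$Ngp,
                              prof$vprof, dtot, rsrc, trans$c0,
                              trans$gamma_c, trans$supg, h_e)
  M <- Matrix::sparseMatrix(i = as.numeric(tr$Ti), j = as.numeric(tr$Tj),
                            x = as.numeric(tr$Mv), dims = c(nn, nn))
  A <- Matrix::sparseMatrix(i = as.numeric(tr$Ti), j = as.numeric(tr$Tj),
                            x = as.numeric(tr$Av), dims = c(nn, nn))
  L <- M / dt + A
  rhs <- M %*% c_old / dt + as.numeric(tr$F)
  c_new <- as.numeric(Matrix::solve(L, rhs))
  # positivity clip; log clipped cell number (J-weighted lumped mass)
  mlump <- as.numeric(Matrix::rowSums(M))
  clipped <- sum(mlump * pmax(0, -c_new))
  c_new <- pmax(c_new, 0)
  # residual-based artificial viscosity for the next step
  rr <- cg_transport_residual(gp$Nsh, gp$dNdX, gp$w, mesh$elems,
                              as.numeric(t(u)), c_new, c_old, 1 / dt,
                              prof$Ngp, prof$vprof, rsrc, trans$c0,
                              trans$gamma_c)
  nu_next <- artificialViscosity(as.numeric(rr$res), as.numeric(rr$grad),
                                 h_e, trans$C_art,
                                 trans$nu_cap, trans$eps_reg)
  list(c = c_new, clipped = clipped, nu_e = nu_next, rsrc = rsrc,
       mass_lumped = mlump)
}

# dilution across a mechanics update: rescale the nodal density by the
# ratio of old to new nodal Jacobian so total cell number J*c over the
# material frame is conserved (realizes the (Jdot/J)c term)
dilutionUpdate <- function(gp, c_nod, Jnod_old, Jgp_new) {
  Jnod_new <- pmax(projectToNodes(gp, Jgp_new), 1e-12)
  list(c = c_nod * Jnod_old / Jnod_new, Jnod = Jnod_new)
}

# project a per-GP field to nodes (lumped L2, reference measure)
projectToNodes <- function(gp, field_gp) {
  num <- as.numeric(Matrix::crossprod(gp$Phi, gp$w * field_gp))
  den <- as.numeric(Matrix::crossprod(gp$Phi, gp$w))
  num / den
}

newSimulationState <- function(mesh, gp) {
  ngp <- length(gp$w)
  list(t = 0, u = matrix(0, nrow(mesh$nodes), 2),
       c = numeric(nrow(mesh$nodes)),
       growth = list(theta_perp = rep(1, ngp), theta_par = rep(1, ngp)),
       s = 1, Jnod = rep(1, nrow(mesh$nodes)),
       nu_e = numeric(nrow(mesh$elems)), energy = 0,
       clipped_total = 0, mesh = mesh)
}

# growth + mechanics pass at given nodal density; returns NULL on failure
mechanicsPass <- function(mesh, gp, prof, mat, solver, state, c_nod, fixed) {
  c_gp <- pmax(as.numeric(gp$Phi %*% c_nod), 0)
  prop <- growthMultipliers(c_gp, prof$kappa_perp, prof$kappa_par,
                            mat$alpha)
  growth <- if (solver$ratchet) updateGrowthState(state$growth, prop)
            else prop
  mu_gp <- prof$mu_sub + (corticalShearModulus(c_gp, mat) - mat$mu_s) *
    prof$H20
  lam_gp <- lameLambda(mu_gp, mat$poisson_nu)
  nm <- newtonMechanics(mesh, state$u, growth, mu_gp, lam_gp, gp, fixed,
                        tol = solver$newton_tol,
                        max_iter = solver$newton_max_iter)
  if (!nm$converged) return(NULL)
  list(growth = growth, nm = nm)
}

# one staggered time step; returns list(ok, state)
simStep <- function(mesh, gp, prof, mat, trans, solver, geom, state, dt,
                    fixed) {
  t_new <- state$t + dt
  ts <- transportStep(mesh, gp, prof, state$u, state$c, dt, t_new,
                      state$s, state$nu_e, trans, geom)
  mp <- mechanicsPass(mesh, gp, prof, mat, solver, state, ts$c, fixed)
  if (is.null(mp)) return(list(ok = FALSE))
  if (solver$coupling == "staggered_iterated") {
    # one fixed-point sweep with the updated mechanics
    kin1 <- cg_kinematics(gp$dNdX, gp$w, mesh$elems,
                          as.numeric(t(mp$nm$u)))
    ts2 <- transportStep(mesh, gp, prof, state$u, state$c, dt, t_new,
                         max(state$s, kin1$smax), ts$nu_e, trans, geom)
    mp2 <- mechanicsPass(mesh, gp, prof, mat, solver, state, ts2$c, fixed)
    if (!is.null(mp2)) { ts <- ts2; mp <- mp2 }
  }
  kin <- cg_kinematics(gp$dNdX, gp$w, mesh$elems, as.numeric(t(mp$nm$u)))
  if (kin$minDetF <= 0) return(list(ok = FALSE))
  dil <- dilutionUpdate(gp, ts$c, state$Jnod, as.numeric(kin$Jgp))
  state$c <- dil$c
  state$Jnod <- dil$Jnod
  state$u <- mp$nm$u
  state$growth <- mp$growth
  state$s <- kin$smax
  state$t <- t_new
  state$nu_e <- ts$nu_e
  state$energy <- mp$nm$energy
  state$clipped_total <- state$clipped_total + ts$clipped
  state$newton_iters <- mp$nm$iters
  state$mech_resnorm <- mp$nm$resnorm
  state$mech_resnorm0 <- mp$nm$resnorm0
  list(ok = TRUE, state = state)
}

#' Run a cortical-folding simulation
#'
#' Integrates the coupled growth-mechanics / cell-density system from
#' the reference state (gestational week 11) to `t_end`, with staggered
#' field coupling per step: (1) implicit-Euler transport on the frozen
#' mechanics of the previous step, (2) ratcheted growth update from the
#' new density, (3) Newton solve of the quasi-static mechanics, then a
#' dilution correction that conserves total cell number over the moving
#' tissue frame. On Newton failure the step is retried with halved dt,
#' up to `max_subdivisions` times.
#'
#' @param config a run configuration from [loadConfig()] /
#'   [presetConfig()] / [defaultConfig()].
#' @return an object of class `cg_result`: list with `trace` (the
#'   per-step morphometric time series, a data frame of class
#'   `cg_morpho`), `state` (final fields), `mesh`, `checkpoints`,
#'   `config`, and an `events` log (step subdivisions, clipping totals).
#' @export
runSimulation <- function(config) {
  geom <- config$geometry; mat <- config$material
  trans <- config$transport; solver <- config$solver
  mesh <- buildQuarterAnnulus(geom, config$mesh$n_radial,
                              config$mesh$n_circumferential)
  if (config$mesh$perturb_amplitude > 0)
    mesh <- applyBoundaryPerturbation(mesh, config$mesh$perturb_amplitude,
                                      config$mesh$perturb_modes,
                                      seed = config$seed)
  gp <- gpBasis(mesh)
  prof <- staticProfiles(mesh, gp, mat, trans)
  prof$mu_sub <- mat$mu_s
  fixed <- mechFixedDofs(mesh)
  state <- newSimulationState(mesh, gp)
  outer_idx <- mesh$boundary$outer
  p0 <- polylineLength(mesh$nodes[outer_idx, , drop = FALSE])
  nsteps <- ceiling(solver$t_end / solver$dt - 1e-9)
  rows <- vector("list", nsteps)
  checkpoints <- list()
  events <- list(subdivisions = 0L, failed = FALSE, self_contact = FALSE)
  for (istep in seq_len(nsteps)) {
    dt_target <- min(solver$dt, solver$t_end - state$t)
    if (dt_target <= 1e-12) break
    advanced <- advanceAdaptive(mesh, gp, prof, mat, trans, solver, geom,
                                state, dt_target, fixed)
    events$subdivisions <- events$subdivisions + advanced$subdivisions
    if (!advanced$ok) {
      events$failed <- TRUE
      events$fail_time <- state$t
      warning(sprintf("step failed at t = %.3f days after %d subdivisions",
                      state$t, solver$max_subdivisions))
      rows <- rows[seq_len(istep - 1L)]
      break
    }
    state <- advanced$state
    tr <- surfaceTrace(mesh, state$u)
    if (polylineSelfIntersects(tr$points)) {
      # deep sulci have pinched: contact is not modeled, stop cleanly
      events$self_contact <- TRUE
      events$contact_time <- state$t
      rows <- rows[seq_len(istep - 1L)]
      break
    }
    sul <- detectSulci(tr)
    depths <- interiorSulcusDepths(tr, sul)
    rows[[istep]] <- data.frame(
      step = istep, time = state$t, gw = 11 + state$t / 7,
      folding_evolution = polylineLength(tr$points) / p0,
      max_density = max(state$c), total_cells = sum(state$c * state$Jnod *
        lumpedRefMass(gp, mesh)),
      s = state$s, energy = state$energy,
      n_sulci = length(depths),
      depth_max = if (length(depths)) max(depths) else 0,
      depth_min = if (length(depths)) min(depths) else 0,
      wavelength = dominantWavelength(tr),
      clipped_total = state$clipped_total,
      newton_iters = state$newton_iters %||% 0L,
      mech_resnorm = state$mech_resnorm %||% 0,
      mech_resnorm0 = state$mech_resnorm0 %||% 0)
    if (solver$checkpoint_every > 0L &&
        istep %% solver$checkpoint_every == 0L)
      checkpoints[[length(checkpoints) + 1L]] <- state
    if (state$t >= solver$t_end - 1e-9) { rows <- rows[seq_len(istep)]; break }
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("cg_morpho", "data.frame")
  structure(list(trace = trace, state = state, mesh = mesh,
                 checkpoints = checkpoints, config = config,
                 events = events),
            class = "cg_result")
}

# lumped reference mass per node (cached computation is cheap)
lumpedRefMass <- function(gp, mesh) {
  as.numeric(Matrix::crossprod(gp$Phi, gp$w))
}

# attempt one macro step with recursive dt halving
advanceAdaptive <- function(mesh, gp, prof, mat, trans, solver, geom,
                            state, dt, fixed, depth = 0L) {
  st <- simStep(mesh, gp, prof, mat, trans, solver, geom, state, dt, fixed)
  if (st$ok) return(list(ok = TRUE, state = st$state, subdivisions = depth))
  if (depth >= solver$max_subdivisions)
    return(list(ok = FALSE, state = state, subdivisions = depth))
  h1 <- advanceAdaptive(mesh, gp, prof, mat, trans, solver, geom, state,
                        dt / 2, fixed, depth + 1L)
  if (!h1$ok) return(h1)
  h2 <- advanceAdaptive(mesh, gp, prof, mat, trans, solver, geom,
                        h1$state, dt / 2, fixed, depth + 1L)
  h2$subdivisions <- h2$subdivisions + h1$subdivisions
  h2
}

#' @export
print.cg_result <- function(x, ...) {
  tr <- x$trace
  cat("cortigrow run:", nrow(tr), "steps to t =",
      round(max(tr$time), 2), "days (GW", round(max(tr$gw), 1), ")\n")
  cat("  folding evolution:", round(tail(tr$folding_evolution, 1), 4),
      " max density:", round(tail(tr$max_density, 1), 1), "mm^-2\n")
  if (x$events$failed) cat("  NOTE: run terminated early (step failure)\n")
  invisible(x)
}
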