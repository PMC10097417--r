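# shared fixtures: simple structured meshes compatible with the solver
# internals, and a cache so each desk-scale simulation runs once per
# test session

patchMesh <- function(n, L = 1) {
  xs <- seq(0, L, length.out = n + 1)
  grid <- expand.grid(i = seq_len(n + 1), j = seq_len(n + 1))
  nodes <- cbind(xs[grid$i], xs[grid$j])
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  e <- list(); k <- 0
  for (j in seq_len(n)) for (i in seq_len(n)) {
    k <- k + 1
    e[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  elems <- do.call(rbind, e); storage.mode(elems) <- "integer"
  structure(list(nodes = nodes, elems = elems,
                 material_radius = nodes[, 1] + 1, boundary = list()),
            class = "cg_mesh")
}

stripMesh <- function(nx, ny, Lx = 2, Ly = 0.3) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  grid <- expand.grid(i = seq_len(nx + 1), j = seq_len(ny + 1))
  nodes <- cbind(xs[grid$i], ys[grid$j])
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  e <- list(); k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    e[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  elems <- do.call(rbind, e); storage.mode(elems) <- "integer"
  structure(list(nodes = nodes, elems = elems,
                 material_radius = nodes[, 1], boundary = list()),
            class = "cg_mesh")
}

# constant-coefficient transport profile on an arbitrary mesh
flatProfiles <- function(gp, v = 0, d = 0) {
  ngp <- length(gp$w)
  list(ri = as.numeric(gp$Phi %*% rep(1, ncol(gp$Phi))),
       Ngp = matrix(rep(c(1, 0), each = ngp), ncol = 2),
       w_vz = rep(0, ngp), mult = rep(1, ngp),
       vprof = rep(v, ngp), dprof = rep(d, ngp),
       H20 = rep(0, ngp), kappa_perp = rep(0, ngp),
       kappa_par = rep(0, ngp))
}

# ---- desk-scale simulation cache -------------------------------------
# resolution/time-step used for all simulation-backed tests; the methods
# vignette documents these as the package's desk-scale study conditions
DESK_MESH <- list(n_radial = 20L, n_circumferential = 48L)
DESK_DT <- 0.5
DESK_TEND <- 60

.run_cache <- new.env(parent = emptyenv())

deskRun <- function(name, preset = NULL, t_end = DESK_TEND, seed = 1L,
                    ...) {
  key <- paste0(name, "_s", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  args <- c(list(mesh = DESK_MESH,
                 solver = list(dt = DESK_DT, t_end = t_end,
                               checkpoint_every = 10L),
                 seed = seed), list(...))
  cfg <- if (is.null(preset)) do.call(defaultConfig, args)
         else do.call(presetConfig, c(list(preset), args))
  res <- suppressWarnings(runSimulation(cfg))
  .run_cache[[key]] <- res
  res
}

# metric value at the latest recorded time <= t
traceAt <- function(res, t, col) {
  tr <- res$trace
  i <- max(which(tr$time <= t + 1e-9))
  tr[[col]][i]
}

endTime <- function(res) max(res$trace$time)

# mean inter-sulcal distance of the checkpointed state nearest time t
meanISDAt <- function(res, t) {
  cks <- res$checkpoints
  dt <- vapply(cks, function(s) abs(s$t - t), numeric(1))
  st <- cks[[which.min(dt)]]
  tr <- surfaceTrace(res$mesh, st$u)
  d <- intersulcalDistance(tr)
  if (length(d)) mean(d) else NA_real_
}
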