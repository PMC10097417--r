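#' Default run configuration
#'
#' The baseline parameter set of the two-dimensional model: quarter
#' annulus with outer radius 2 mm, varying cortical stiffness with
#' stiffness ratio 3, VZ division rate 120 and OSVZ division rate 20
#' mm^-2/day, MST factor 0.02 mm/day, integrated from gestational week
#' 11 (t = 0) to week 36 (t = 175 days).
#'
#' @param ... named overrides applied on top of the defaults; blocks
#'   (`geometry`, `material`, `transport`, `solver`, `mesh`, `output`)
#'   may be given as lists of field overrides.
#' @param seed integer seed controlling the boundary perturbation phases
#'   and any random heterogeneity pattern.
#' @return an object of class `cg_config`.
#' @export
defaultConfig <- function(..., seed = 1L) {
  cfg <- list(
    geometry = geometryParams(),
    material = materialParams(),
    transport = transportParams(),
    solver = solverConfig(),
    mesh = list(n_radial = 40L, n_circumferential = 80L,
                perturb_amplitude = 0.002, perturb_modes = 8L),
    output = list(dir = NULL, vtk_every = 0L),
    seed = as.integer(seed))
  class(cfg) <- "cg_config"
  overrides <- list(...)
  if (length(overrides)) cfg <- applyOverrides(cfg, overrides)
  cfg
}

applyOverrides <- function(cfg, ov) {
  for (nm in names(ov)) {
    if (!nm %in% c("geometry", "material", "transport", "solver", "mesh",
                   "output", "seed"))
      stop("unknown configuration block: ", nm)
    if (nm == "seed") { cfg$seed <- as.integer(ov[[nm]]); next }
    if (nm %in% c("mesh", "output")) {
      bad <- setdiff(names(ov[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown ", nm, " key: ", bad[1])
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
      next
    }
    cfg[[nm]] <- rebuildBlock(nm, cfg[[nm]], ov[[nm]])
  }
  cfg
}

# rebuild a parameter object through its constructor so invariants are
# re-validated on every change
rebuildBlock <- function(block, current, overrides) {
  ctor <- switch(block, geometry = geometryParams,
                 material = materialParams, transport = transportParams,
                 solver = solverConfig)
  keep <- intersect(names(current), names(formals(ctor)))
  args <- current[keep]
  if (block == "material") args$beta_mu <- current$beta_mu
  if (inherits(overrides, class(current))) return(overrides)
  aliases <- c(nu = "poisson_nu", v = "v_max", range = "relative_range")
  nms <- names(overrides)
  nms[nms %in% names(aliases)] <- aliases[nms[nms %in% names(aliases)]]
  names(overrides) <- nms
  if (block == "transport" && !is.null(overrides$heterogeneity) &&
      !inherits(overrides$heterogeneity, "cg_hetero")) {
    h <- overrides$heterogeneity
    hn <- names(h); hn[hn == "range"] <- "relative_range"; names(h) <- hn
    bad <- setdiff(names(h), names(formals(heterogeneityPattern)))
    if (length(bad)) stop("unknown heterogeneity key: ", bad[1])
    overrides$heterogeneity <- do.call(heterogeneityPattern, h)
  }
  bad <- setdiff(names(overrides), names(formals(ctor)))
  if (length(bad))
    stop("unknown ", block, " key: ", bad[1], " (allowed: ",
         paste(names(formals(ctor)), collapse = ", "), ")")
  do.call(ctor, modifyList(args, overrides))
}

#' @export
print.cg_config <- function(x, ...) {
  cat("cortigrow run configuration (seed ", x$seed, ")\n", sep = "")
  print(x$geometry); print(x$material); print(x$transport)
  cat("Mesh:", x$mesh$n_radial, "x", x$mesh$n_circumferential,
      "; perturbation", x$mesh$perturb_amplitude, "mm x",
      x$mesh$perturb_modes, "modes\n")
  cat("Time: dt =", x$solver$dt, "days to t_end =", x$solver$t_end,
      "days\n")
  invisible(x)
}

#' Named experiment presets
#'
#' Ready-made configurations mirroring the in-silico experiments:
#' `varying_g120_o{0,10,20,30}` and `constant_g120_o{0,10,20}` (OSVZ
#' division-rate sweeps at VZ rate 120 for the two stiffness modes),
#' `tradeoff_{120_0,90_10,60_20,30_30}` (VZ/OSVZ trade-off),
#' `mst_sweep` (the MST base case, VZ 30 / OSVZ 30, vary `m_mst` on
#' top), and `hetero_gradient` / `hetero_random` (angularly
#' heterogeneous OSVZ division rate at VZ 120 / OSVZ 20).
#'
#' @param name preset name.
#' @param ... further overrides, as in [defaultConfig()].
#' @param seed run seed.
#' @return a `cg_config`.
#' @export
presetConfig <- function(name, ..., seed = 1L) {
  presets <- list(
    varying_g120_o0 = list(material = list(stiffness_mode = "varying",
                                           beta_mu = 3),
                           transport = list(G_vz = 120, G_osvz = 0)),
    varying_g120_o10 = list(material = list(stiffness_mode = "varying",
                                            beta_mu = 3),
                            transport = list(G_vz = 120, G_osvz = 10)),
    varying_g120_o20 = list(material = list(stiffness_mode = "varying",
                                            beta_mu = 3),
                            transport = list(G_vz = 120, G_osvz = 20)),
    varying_g120_o30 = list(material = list(stiffness_mode = "varying",
                                            beta_mu = 3),
                            transport = list(G_vz = 120, G_osvz = 30)),
    constant_g120_o0 = list(material = list(stiffness_mode = "constant",
                                            beta_mu = 8),
                            transport = list(G_vz = 120, G_osvz = 0)),
    constant_g120_o10 = list(material = list(stiffness_mode = "constant",
                                             beta_mu = 8),
                             transport = list(G_vz = 120, G_osvz = 10)),
    constant_g120_o20 = list(material = list(stiffness_mode = "constant",
                                             beta_mu = 8),
                             transport = list(G_vz = 120, G_osvz = 20)),
    tradeoff_120_0 = list(transport = list(G_vz = 120, G_osvz = 0)),
    tradeoff_90_10 = list(transport = list(G_vz = 90, G_osvz = 10)),
    tradeoff_60_20 = list(transport = list(G_vz = 60, G_osvz = 20)),
    tradeoff_30_30 = list(transport = list(G_vz = 30, G_osvz = 30)),
    mst_sweep = list(transport = list(G_vz = 30, G_osvz = 30)),
    hetero_gradient = list(transport = list(
      G_vz = 120, G_osvz = 20,
      heterogeneity = list(kind = "circumferential_gradient",
                           relative_range = c(0, 1)))),
    hetero_random = list(transport = list(
      G_vz = 120, G_osvz = 20,
      heterogeneity = list(kind = "random_sectors", n_sectors = 8L,
                           relative_range = c(0.5, 1.5)))))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  cfg <- do.call(defaultConfig, c(presets[[name]], list(seed = seed)))
  ov <- list(...)
  if (length(ov)) cfg <- applyOverrides(cfg, ov)
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose blocks mirror the model parameter names
#' (`geometry: {R, r, r_vz, r_isvz, r_cp, m_mst}`, `material:
#' {mu_inf, nu, beta_mu, c_max, c_min, kappa_s, alpha, beta_kappa,
#' stiffness_mode}`, `transport: {G_vz, G_osvz, v, c0, gamma_c, d_cc,
#' heterogeneity}`, `solver`, `mesh`, `output`, `seed`, and optionally
#' `preset` to start from a named preset). Missing fields take the
#' defaults; unknown keys are rejected with a message naming the key;
#' all parameter invariants are re-validated.
#'
#' @param path YAML file path.
#' @return a `cg_config`.
#' @export
loadConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  seed <- if (!is.null(y$seed)) y$seed else 1L
  preset <- y$preset
  y$seed <- NULL; y$preset <- NULL
  cfg <- if (is.null(preset)) defaultConfig(seed = seed)
         else presetConfig(preset, seed = seed)
  if (length(y)) cfg <- applyOverrides(cfg, y)
  cfg
}

# 32-bit FNV-1a over the YAML rendering of the semantic fields; changes
# iff a semantic field changes
configHash <- function(config) {
  sem <- list(geometry = unclass(config$geometry),
              material = unclass(config$material),
              transport = rapply(unclass(config$transport), unclass,
                                 how = "replace"),
              solver = unclass(config$solver),
              mesh = config$mesh, seed = config$seed)
  s <- yaml::as.yaml(sem, precision = 15L)
  # two Horner polynomial hashes over primes below 2^26 (safe in doubles)
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 31 + b) %% 67108859
    h2 <- (h2 * 131 + b) %% 33554393
  }
  sprintf("%07x%07x", h1, h2)
}

vtkNum <- function(x) sprintf("%.17g", x)

#' Write a simulation state as legacy VTK
#'
#' Writes the deformed mesh as an ASCII unstructured grid with point
#' data (displacement, density) and, when material/transport parameters
#' are supplied, cell data (shear modulus, growth multipliers, zone
#' weights, division-rate field). Readable by standard VTK tools and by
#' [readStateVTK()].
#'
#' @param state a simulation state (`result$state`).
#' @param path output file.
#' @param material,transport optional [materialParams()] /
#'   [transportParams()] for the derived cell fields.
#' @export
writeStateVTK <- function(state, path, material = NULL, transport = NULL) {
  mesh <- state$mesh
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  xy <- mesh$nodes + state$u
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0",
    sprintf("cortigrow state t=%s days", vtkNum(state$t)),
    "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", n))
  w(paste(vtkNum(xy[, 1]), vtkNum(xy[, 2]), "0"))
  w(sprintf("CELLS %d %d", ne, 5L * ne))
  w(paste(4L, mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
          mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L))
  w(sprintf("CELL_TYPES %d", ne))
  w(as.character(rep(9L, ne)))
  w(sprintf("POINT_DATA %d", n))
  w("VECTORS displacement double")
  w(paste(vtkNum(state$u[, 1]), vtkNum(state$u[, 2]), "0"))
  w("SCALARS density double 1", "LOOKUP_TABLE default")
  w(vtkNum(state$c))
  cellFields <- list()
  if (!is.null(material) || !is.null(transport)) {
    elemMean <- function(gpfield)
      colMeans(matrix(gpfield, nrow = 4L))
    gp <- gpBasis(mesh)
    ri_gp <- as.numeric(gp$Phi %*% mesh$material_radius)
    c_gp <- pmax(as.numeric(gp$Phi %*% state$c), 0)
    geom <- mesh$geom
    if (!is.null(material)) {
      cellFields$mu <- elemMean(shearModulusProfile(ri_gp, c_gp, material,
                                                    geom$r_cp))
      cellFields$theta_perp <- elemMean(projectGrowth(state, "theta_perp",
                                                      ne))
      cellFields$theta_par <- elemMean(projectGrowth(state, "theta_par",
                                                     ne))
    }
    if (!is.null(transport)) {
      th_gp <- atan2(gp$xy[, 2], gp$xy[, 1])
      cellFields$zone_vz <- elemMean(zoneWeightVZ(ri_gp, geom))
      cellFields$zone_osvz <- elemMean(zoneWeightOSVZ(ri_gp, state$t,
                                                      geom))
      cellFields$division_rate <- elemMean(
        sourceVZ(ri_gp, state$s, transport, geom) +
          sourceOSVZ(ri_gp, th_gp, state$t, state$s, transport, geom))
    }
  }
  if (length(cellFields)) {
    w(sprintf("CELL_DATA %d", ne))
    for (nm in names(cellFields)) {
      w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      w(vtkNum(cellFields[[nm]]))
    }
  }
  invisible(path)
}

projectGrowth <- function(state, field, ne) {
  g <- state$growth[[field]]
  if (length(g) == 4L * ne) g else rep(1, 4L * ne)
}

#' Read back a legacy-VTK state file
#'
#' Minimal reader for the files produced by [writeStateVTK()] (ASCII
#' unstructured grid with point vectors/scalars and cell scalars).
#'
#' @param path VTK file path.
#' @return list with `points`, `cells` (1-based), `point_data`,
#'   `cell_data`.
#' @export
readStateVTK <- function(path) {
  ln <- readLines(path)
  i <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[i], " ")[[1]][2])
  pts <- matrix(scan(text = ln[(i + 1):(i + n)], quiet = TRUE),
                ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  i <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[i], " ")[[1]][2])
  cells <- matrix(scan(text = ln[(i + 1):(i + ne)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)[, 2:5, drop = FALSE] + 1L
  point_data <- list(); cell_data <- list()
  readBlock <- function(start, count, ncol_) {
    matrix(scan(text = ln[(start + 1):(start + count)], quiet = TRUE),
           ncol = ncol_, byrow = TRUE)
  }
  for (i in grep("^VECTORS", ln)) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    point_data[[nm]] <- readBlock(i, n, 3)[, 1:2, drop = FALSE]
  }
  for (i in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    isPoint <- i < ifelse(any(grepl("^CELL_DATA", ln)),
                          grep("^CELL_DATA", ln)[1], length(ln) + 1)
    count <- if (isPoint) n else ne
    vals <- scan(text = ln[(i + 2):(i + 1 + count)], quiet = TRUE)
    if (isPoint) point_data[[nm]] <- vals else cell_data[[nm]] <- vals
  }
  list(points = pts, cells = cells, point_data = point_data,
       cell_data = cell_data)
}

#' Tidy metrics CSV
#'
#' Writes the per-step morphometric trace in tidy long format (`time`,
#' `gw`, `metric`, `label`, `value`); [readMetricsCSV()] loads it back
#' to an identical data frame.
#'
#' @param morpho a `cg_morpho` trace (or any data frame with a `time`
#'   column; a `gw` column is derived as `11 + time/7` if absent).
#' @param path output CSV path.
#' @export
emitMetricsCSV <- function(morpho, path) {
  base <- c("time", "gw", "step")
  if (is.null(morpho) || !nrow(morpho)) {
    writeLines("time,gw,metric,label,value", path)
    return(invisible(path))
  }
  gw <- if ("gw" %in% names(morpho)) morpho$gw else 11 + morpho$time / 7
  metrics <- setdiff(names(morpho), base)
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(time = morpho$time, gw = gw, metric = m, label = NA_character_,
               value = as.numeric(morpho[[m]]))))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname emitMetricsCSV
#' @export
readMetricsCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(label = "character"))
}

#' Write a run manifest
#'
#' JSON record of a run: configuration hash, seed, package version,
#' wall-clock times, termination status and event log (time-step
#' subdivisions, clipped-mass total). Written atomically (temp file +
#' rename).
#'
#' @param result a `cg_result` from [runSimulation()].
#' @param path output JSON path.
#' @param started,finished POSIXct wall times (optional).
#' @export
writeManifest <- function(result, path, started = NULL, finished = NULL) {
  man <- list(
    config_hash = configHash(result$config),
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("cortigrow")),
    started = if (!is.null(started)) format(started) else NULL,
    finished = if (!is.null(finished)) format(finished) else NULL,
    status = if (result$events$failed) "failed" else "completed",
    steps = nrow(result$trace),
    t_end_reached = max(result$trace$time),
    subdivisions = result$events$subdivisions,
    clipped_cells_total = result$state$clipped_total)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}
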