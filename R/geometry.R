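#' Geometry parameters of the quarter-annulus brain section
#'
#' Reference-configuration radii of the simulated frontal-lobe section at
#' gestational week 11, plus the MST rate that moves the OSVZ outer
#' boundary. All radii are material coordinates in mm and are ordered
#' `r < r_vz < r_isvz < r_cp < R`.
#'
#' @param R outer brain radius, mm.
#' @param r inner (ventricular) radius, mm.
#' @param r_vz outer radius of the ventricular zone, mm.
#' @param r_isvz outer radius of the inner subventricular zone, mm.
#' @param r_cp inner radius of the cortical plate, mm.
#' @param m_mst mitotic somal translocation rate (OSVZ boundary speed),
#'   mm/day.
#' @return an object of class `cg_geometry`.
#' @export
geometryParams <- function(R = 2, r = 0.4, r_vz = 0.5, r_isvz = 0.8,
                           r_cp = 1.8, m_mst = 0.02) {
  stopifnot(is.numeric(R), is.numeric(r), is.numeric(m_mst))
  if (!(r > 0 && r < r_vz && r_vz < r_isvz && r_isvz < r_cp && r_cp < R))
    stop("geometry radii must satisfy 0 < r < r_vz < r_isvz < r_cp < R")
  if (m_mst < 0) stop("m_mst must be >= 0")
  structure(list(R = R, r = r, r_vz = r_vz, r_isvz = r_isvz,
                 r_cp = r_cp, m_mst = m_mst),
            class = "cg_geometry")
}

#' @export
print.cg_geometry <- function(x, ...) {
  cat("Quarter-annulus geometry (mm): r =", x$r, " r_vz =", x$r_vz,
      " r_isvz =", x$r_isvz, " r_cp =", x$r_cp, " R =", x$R,
      "\nMST rate m_mst =", x$m_mst, "mm/day\n")
  invisible(x)
}

# radial node coordinates with optional grading: the cortical band
# [r_cp, R] is guaranteed at least four element layers so wrinkles of a
# few cortical thicknesses are resolved.
radialGrading <- function(geom, n_radial) {
  if (n_radial >= 8) {
    n_cortex <- max(4L, round(0.2 * n_radial))
    n_sub <- n_radial - n_cortex
    c(seq(geom$r, geom$r_cp, length.out = n_sub + 1L),
      seq(geom$r_cp, geom$R, length.out = n_cortex + 1L)[-1L])
  } else {
    seq(geom$r, geom$R, length.out = n_radial + 1L)
  }
}

#' Build a structured quarter-annulus mesh
#'
#' Generates a structured bilinear-quadrilateral mesh of the annular
#' sector theta in \[0, pi/2\], radius in \[r, R\]. The radial spacing is
#' graded so that the cortical band \[r_cp, R\] holds at least four element
#' layers. Each node carries its material radius (the reference radial
#' coordinate used by all zone indicator functions, which convects with
#' the tissue as it deforms).
#'
#' @param geom a [geometryParams()] object.
#' @param n_radial number of element layers in the radial direction
#'   (>= 2).
#' @param n_circumferential number of element columns over the quarter
#'   turn (>= 2).
#' @return an object of class `cg_mesh` with fields `nodes` (n x 2
#'   matrix, mm), `elems` (ne x 4 integer connectivity, counterclockwise),
#'   `material_radius`, and `boundary` (`inner`, `outer`, `edge_x0`,
#'   `edge_y0` node index sets; `outer` is ordered by angle).
#' @export
buildQuarterAnnulus <- function(geom, n_radial, n_circumferential) {
  stopifnot(inherits(geom, "cg_geometry"))
  n_radial <- as.integer(n_radial); n_circ <- as.integer(n_circumferential)
  if (n_radial < 2L || n_circ < 2L)
    stop("n_radial and n_circumferential must both be >= 2")
  radii <- radialGrading(geom, n_radial)
  thetas <- seq(0, pi / 2, length.out = n_circ + 1L)
  nr <- n_radial + 1L; nc <- n_circ + 1L
  grid <- expand.grid(ri = seq_len(nr), tj = seq_len(nc))
  rho <- radii[grid$ri]; th <- thetas[grid$tj]
  nodes <- cbind(x = rho * cos(th), y = rho * sin(th))
  idx <- function(i, j) (j - 1L) * nr + i
  e <- vector("list", n_radial * n_circ)
  k <- 0L
  for (j in seq_len(n_circ)) for (i in seq_len(n_radial)) {
    k <- k + 1L
    e[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  elems <- do.call(rbind, e)
  storage.mode(elems) <- "integer"
  boundary <- list(
    inner   = idx(1L, seq_len(nc)),
    outer   = idx(nr, seq_len(nc)),          # ordered by increasing angle
    edge_y0 = idx(seq_len(nr), 1L),          # theta = 0 edge (y = 0)
    edge_x0 = idx(seq_len(nr), nc)           # theta = pi/2 edge (x = 0)
  )
  structure(list(nodes = nodes, elems = elems, material_radius = rho,
                 boundary = boundary, n_radial = n_radial,
                 n_circumferential = n_circ, geom = geom,
                 radii = radii, thetas = thetas),
            class = "cg_mesh")
}

#' @export
print.cg_mesh <- function(x, ...) {
  cat("Quarter-annulus mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "bilinear quads (", x$n_radial, "x", x$n_circumferential, ")\n")
  invisible(x)
}

#' Reference glial fiber direction
#'
#' The radial unit vector at a reference point: radial glial fibers run
#' from the ventricular surface to the outer cortex, so in the
#' (undeformed) reference configuration they point radially outward.
#'
#' @param point numeric length-2 reference position (mm), or an n x 2
#'   matrix of positions.
#' @return unit vector(s) of the same shape as `point`.
#' @export
referenceFiberDirection <- function(point) {
  if (is.matrix(point)) {
    nrm <- sqrt(rowSums(point^2))
    if (any(nrm == 0)) stop("fiber direction undefined at the origin")
    return(point / nrm)
  }
  nrm <- sqrt(sum(point^2))
  if (nrm == 0) stop("fiber direction undefined at the origin")
  point / nrm
}

#' Zone indicator weights
#'
#' Smooth (logistic) indicator fields of the proliferating zones as
#' functions of the material radius `ri`. `zoneWeightVZ` is ~1 inside the
#' ventricular zone and decays across `r_vz` with logistic exponent 50.
#' `zoneWeightOSVZ` is the band indicator of the outer subventricular
#' zone, whose outer boundary `rosvz(t)` moves outward at the MST rate
#' (see [osvzOuterRadius()]); it has zero width at t = 0 and is clamped at
#' zero where the two logistic tails cross.
#'
#' @param ri material radius, mm (vectorized).
#' @param t gestational time since the reference state, days.
#' @param geom a [geometryParams()] object.
#' @return weight(s) in \[0, 1\].
#' @export
zoneWeightVZ <- function(ri, geom = geometryParams()) {
  1 - smoothHeaviside(ri - geom$r_vz, 50)
}

#' @rdname zoneWeightVZ
#' @export
zoneWeightOSVZ <- function(ri, t, geom = geometryParams()) {
  ro <- osvzOuterRadius(t, geom)
  pmax(0, smoothHeaviside(ri - geom$r_isvz, 50) - smoothHeaviside(ri - ro, 50))
}

#' Seeded multi-mode perturbation of the outer boundary
#'
#' Perturbs the radius of cortical-band nodes by a sum of `mode_count`
#' random-phase cosine modes of the polar angle, with amplitude tapering
#' linearly to zero at material radius `r_cp`. This is the explicit,
#' reproducible imperfection that selects the buckling branch: a
#' perfectly symmetric discrete system would otherwise fold only through
#' accumulated round-off, at an unpredictable step.
#'
#' @param mesh a [buildQuarterAnnulus()] mesh.
#' @param amplitude perturbation amplitude per mode, mm (default 0.1% of
#'   the outer radius).
#' @param mode_count number of cosine modes (full waves over the quarter
#'   turn run from 1 to `mode_count`).
#' @param seed integer seed for the mode phases.
#' @return the mesh with perturbed node coordinates; `material_radius`
#'   and boundary tags are unchanged.
#' @export
applyBoundaryPerturbation <- function(mesh, amplitude = 0.002, mode_count = 8L,
                                      seed = 1L) {
  stopifnot(inherits(mesh, "cg_mesh"), amplitude >= 0)
  if (amplitude == 0) return(mesh)
  geom <- mesh$geom
  phases <- withSeed(seed, runif(mode_count, 0, 2 * pi))
  th <- atan2(mesh$nodes[, 2], mesh$nodes[, 1])
  dr <- numeric(nrow(mesh$nodes))
  for (k in seq_len(mode_count))
    dr <- dr + amplitude * cos(4 * k * th + phases[k])
  taper <- pmin(1, pmax(0, (mesh$material_radius - geom$r_cp) /
                             (geom$R - geom$r_cp)))
  rho <- sqrt(rowSums(mesh$nodes^2)) + taper * dr
  if (any(rho <= 0)) stop("perturbation amplitude inverts the mesh")
  mesh$nodes <- cbind(x = rho * cos(th), y = rho * sin(th))
  mesh
}

# total area of the mesh by 2x2 Gauss quadrature (used in tests and
# sanity checks against the closed-form sector area)
meshArea <- function(mesh) {
  gp <- gpBasis(mesh)
  sum(gp$w)
}
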