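#' Outer-surface trace of a deformed state
#'
#' The ordered polyline of deformed outer-boundary points, with
#' arc-length parameter. All surface morphometrics operate on this
#' object.
#'
#' @param mesh a [buildQuarterAnnulus()] mesh.
#' @param u n x 2 displacement matrix (zero for the reference surface).
#' @return an object of class `cg_surface`: list with `points` (m x 2,
#'   mm, ordered by boundary connectivity) and `arc` (cumulative
#'   arc length, mm).
#' @export
surfaceTrace <- function(mesh, u = NULL) {
  idx <- mesh$boundary$outer
  pts <- mesh$nodes[idx, , drop = FALSE]
  if (!is.null(u)) pts <- pts + u[idx, , drop = FALSE]
  newSurfaceTrace(pts)
}

newSurfaceTrace <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  structure(list(points = pts, arc = c(0, cumsum(seg))),
            class = "cg_surface")
}

polylineLength <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

#' Folding evolution
#'
#' The ratio of the current outer perimeter to the initial one; equal to
#' 1 for the undeformed reference surface and rising as the cortex
#' expands and folds. A kink in its time course marks the primary
#' wrinkling instability.
#'
#' @param trace a [surfaceTrace()].
#' @param initial_perimeter reference outer perimeter, mm.
#' @return dimensionless ratio.
#' @export
foldingEvolution <- function(trace, initial_perimeter) {
  if (nrow(trace$points) < 2) stop("empty surface trace")
  if (initial_perimeter <= 0) stop("initial perimeter must be > 0")
  polylineLength(trace$points) / initial_perimeter
}

movingAverage <- function(x, win) {
  if (win <= 1) return(x)
  k <- rep(1 / win, win)
  n <- length(x)
  # reflect-pad so endpoints are usable
  xp <- c(rev(x[seq_len(win)]), x, rev(x[seq(n - win + 1, n)]))
  stats::filter(xp, k, sides = 2)[(win + 1):(win + n)]
}

#' Detect sulci and gyri on a surface trace
#'
#' Local minima (sulci) and maxima (gyri) of the radial distance from
#' the origin along the trace, after moving-average smoothing; extrema
#' pairs whose amplitude difference falls below the persistence
#' threshold are pruned as mesh-scale noise, and extrema at the symmetry
#' edges (trace endpoints) are excluded.
#'
#' @param trace a [surfaceTrace()].
#' @param smooth_frac smoothing window as a fraction of trace length.
#' @param persistence minimum amplitude (mm) for an extremum to count
#'   (default 0.5% of the maximum radius).
#' @return list with integer index vectors `sulci` and `gyri` into the
#'   trace, plus the radius vector `rho`.
#' @export
detectSulci <- function(trace, smooth_frac = 0.05, persistence = NULL) {
  rho <- sqrt(rowSums(trace$points^2))
  m <- length(rho)
  if (is.null(persistence)) persistence <- 0.005 * max(rho)
  win <- max(1L, round(smooth_frac * m))
  rs <- movingAverage(rho, win)
  ext <- list()  # (index, type) alternating extrema of the smoothed signal
  for (i in 2:(m - 1)) {
    if (rs[i] < rs[i - 1] && rs[i] <= rs[i + 1])
      ext[[length(ext) + 1L]] <- c(i, -1)
    else if (rs[i] > rs[i - 1] && rs[i] >= rs[i + 1])
      ext[[length(ext) + 1L]] <- c(i, 1)
  }
  if (!length(ext))
    return(list(sulci = integer(), gyri = integer(), rho = rho))
  ex <- do.call(rbind, ext)
  # enforce alternation: among consecutive same-type extrema keep extremest
  keep <- rep(TRUE, nrow(ex))
  j <- 1
  for (i in seq_len(nrow(ex))[-1]) {
    if (ex[i, 2] == ex[j, 2]) {
      better <- if (ex[i, 2] < 0) rs[ex[i, 1]] < rs[ex[j, 1]]
                else rs[ex[i, 1]] > rs[ex[j, 1]]
      if (better) { keep[j] <- FALSE; j <- i } else keep[i] <- FALSE
    } else j <- i
  }
  ex <- ex[keep, , drop = FALSE]
  # persistence pruning: drop adjacent pairs closer than the threshold
  repeat {
    if (nrow(ex) < 2) break
    d <- abs(rs[ex[-1, 1]] - rs[ex[-nrow(ex), 1]])
    if (all(d >= persistence)) break
    i <- which.min(d)
    ex <- ex[-c(i, i + 1), , drop = FALSE]
  }
  if (!nrow(ex))
    return(list(sulci = integer(), gyri = integer(), rho = rho))
  # refine each index to the raw-signal extremum nearby
  half <- max(1L, win %/% 2L)
  refine <- function(i, type) {
    lo <- max(2L, i - half); hi <- min(m - 1L, i + half)
    w <- lo:hi
    w[if (type < 0) which.min(rho[w]) else which.max(rho[w])]
  }
  idx <- mapply(refine, ex[, 1], ex[, 2])
  list(sulci = idx[ex[, 2] < 0], gyri = idx[ex[, 2] > 0], rho = rho)
}

#' Sulcus depth against the flanking gyral crowns
#'
#' Depth of one sulcus: the mean radial distance of the two flanking
#' gyral maxima minus the radial distance of the sulcal minimum. A
#' sulcus lacking a flank on one side (next to a symmetry edge) uses the
#' single available flank and is flagged.
#'
#' @param trace a [surfaceTrace()].
#' @param landmarks output of [detectSulci()].
#' @param sulcus index (into the trace) of the sulcal minimum, as
#'   returned in `landmarks$sulci`.
#' @return depth in mm, with attribute `single_flank` if only one gyral
#'   flank was available.
#' @export
sulcusDepth <- function(trace, landmarks, sulcus) {
  rho <- landmarks$rho
  g <- landmarks$gyri
  left <- g[g < sulcus]; right <- g[g > sulcus]
  if (!length(left) && !length(right)) return(0)
  flanks <- c(if (length(left)) rho[max(left)],
              if (length(right)) rho[min(right)])
  out <- mean(flanks) - rho[sulcus]
  if (length(flanks) == 1L) attr(out, "single_flank") <- TRUE
  out
}

# depths of all interior sulci with two flanks (used by the per-step trace)
interiorSulcusDepths <- function(trace, landmarks) {
  s <- landmarks$sulci
  s <- s[vapply(s, function(i) any(landmarks$gyri < i) &&
                  any(landmarks$gyri > i), logical(1))]
  vapply(s, function(i) as.numeric(sulcusDepth(trace, landmarks, i)),
         numeric(1))
}

#' Inter-sulcal distances
#'
#' Euclidean (chord) distances in the deformed configuration between
#' consecutive sulcal minima.
#'
#' @param trace a [surfaceTrace()].
#' @param landmarks optional [detectSulci()] output (computed if
#'   missing).
#' @return numeric vector of distances, mm; empty if fewer than two
#'   sulci are present.
#' @export
intersulcalDistance <- function(trace, landmarks = detectSulci(trace)) {
  s <- sort(landmarks$sulci)
  if (length(s) < 2) return(numeric())
  p <- trace$points[s, , drop = FALSE]
  sqrt(rowSums(diff(p)^2))
}

#' Detect primary and secondary instability points
#'
#' The primary (wrinkling) instability is the first time the maximum
#' sulcus depth exceeds `depth_eps` while still growing; the secondary
#' (period-doubling) instability is the first time the ratio of deepest
#' to shallowest tracked sulcus exceeds `ratio_threshold` for `persist`
#' consecutive steps. The kink (maximum discrete curvature) of the
#' folding-evolution series is returned as an independent cross-check of
#' the primary point.
#'
#' @param morpho a `cg_morpho` trace from [runSimulation()] (data frame
#'   with columns `time`, `folding_evolution`, `depth_max`, `depth_min`,
#'   `n_sulci`).
#' @param depth_eps primary-instability depth threshold, mm (default 1%
#'   of the 0.2 mm cortical thickness).
#' @param ratio_threshold depth-ratio threshold of the pitchfork.
#' @param persist number of consecutive steps the ratio must hold.
#' @return list with `t_primary`, `t_secondary` (NA if absent) and
#'   `t_kink`.
#' @export
detectInstabilityPoints <- function(morpho, depth_eps = 0.002,
                                    ratio_threshold = 1.5, persist = 5L) {
  n <- nrow(morpho)
  if (n < 10) stop("need at least 10 recorded steps")
  dm <- morpho$depth_max
  # measure in excess of the seeded imperfection present at the start
  base <- dm[1]
  growing <- c(diff(dm) > 0, FALSE)
  ip <- which(dm - base > depth_eps & growing)
  t_primary <- if (length(ip)) morpho$time[ip[1]] else NA_real_
  # pitchfork: persistent divergence of tracked sulcus depths
  ratio <- ifelse(morpho$n_sulci >= 2 & morpho$depth_min > 1e-9,
                  dm / pmax(morpho$depth_min, 1e-12), 1)
  flag <- ratio > ratio_threshold & morpho$n_sulci >= 2 & dm > depth_eps
  t_secondary <- NA_real_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (flag[i]) run + 1L else 0L
    if (run >= persist) { t_secondary <- morpho$time[i - persist + 1L]; break }
  }
  fe <- morpho$folding_evolution
  curv <- abs(diff(fe, differences = 2))
  t_kink <- if (length(curv)) morpho$time[which.max(curv) + 1L] else NA_real_
  list(t_primary = t_primary, t_secondary = t_secondary, t_kink = t_kink)
}

# bilinear interpolation of nodal fields along the deformed image of a
# reference ray, using the structured (radius, angle) parameterization
rayInterp <- function(mesh, u, c_nod, angle, ri_samples) {
  radii <- mesh$radii; thetas <- mesh$thetas
  angle <- min(max(angle, 0), pi / 2)
  j <- max(1L, min(length(thetas) - 1L, findInterval(angle, thetas)))
  tj <- (angle - thetas[j]) / (thetas[j + 1] - thetas[j])
  nr <- length(radii)
  xy <- mesh$nodes + u
  idx <- function(i, jj) (jj - 1L) * nr + i
  out_xy <- matrix(0, length(ri_samples), 2)
  out_c <- numeric(length(ri_samples))
  for (k in seq_along(ri_samples)) {
    ri <- min(max(ri_samples[k], radii[1]), radii[nr])
    i <- max(1L, min(nr - 1L, findInterval(ri, radii)))
    ti <- (ri - radii[i]) / (radii[i + 1] - radii[i])
    w <- c((1 - ti) * (1 - tj), ti * (1 - tj), ti * tj, (1 - ti) * tj)
    nd <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    out_xy[k, ] <- colSums(w * xy[nd, , drop = FALSE])
    out_c[k] <- sum(w * c_nod[nd])
  }
  list(xy = out_xy, c = out_c)
}

#' Normalized radial density profile
#'
#' Samples the cell density along the deformed image of a reference ray
#' at a given angle, from the ventricular to the outer cortical surface.
#' The abscissa is normalized to \[0, 1\] by the arc length of the
#' deformed ray; the ordinate is normalized by the maximum density among
#' samples with material radius inside the cortex (`> r_cp`), falling
#' back to the global maximum (with a warning) if the cortex is empty.
#'
#' @param state a simulation state (list with `mesh`, `u`, `c`), e.g.
#'   `result$state` from [runSimulation()].
#' @param angle ray angle, rad, in \[0, pi/2\].
#' @param n_samples number of sample points.
#' @return data frame with `radius_norm`, `density_norm`,
#'   `material_radius`, `density`.
#' @export
radialProfile <- function(state, angle = pi / 4, n_samples = 100L) {
  mesh <- state$mesh
  geom <- mesh$geom
  ri_s <- seq(geom$r, geom$R, length.out = n_samples)
  s <- rayInterp(mesh, state$u, state$c, angle, ri_s)
  arc <- c(0, cumsum(sqrt(rowSums(diff(s$xy)^2))))
  cmaxc <- suppressWarnings(max(s$c[ri_s > geom$r_cp]))
  if (!is.finite(cmaxc) || cmaxc <= 1e-6 * max(s$c, 1e-12)) {
    if (max(s$c) > 0)
      warning("no cortical density; normalizing by global maximum")
    cmaxc <- max(s$c, 1e-12)
  }
  data.frame(radius_norm = arc / max(arc, 1e-12),
             density_norm = s$c / cmaxc,
             material_radius = ri_s, density = s$c)
}

#' OSVZ thickness beneath gyri and sulci
#'
#' For each angular column of the mesh, measures the deformed arc length
#' of the material OSVZ band \[r_isvz, rosvz(t)\] along the deformed ray,
#' and tags the angle gyral or sulcal depending on whether the outer
#' surface above it lies outside or inside its smoothed mean.
#'
#' @param state a simulation state with fields `mesh`, `u`, `t`.
#' @param smooth_frac smoothing window for the gyral/sulcal reference
#'   datum, as a fraction of the trace (1 = global mean radius).
#' @return data frame with `theta`, `thickness` (mm) and `class`
#'   ("gyrus"/"sulcus").
#' @export
osvzThicknessMap <- function(state, smooth_frac = 1) {
  mesh <- state$mesh; geom <- mesh$geom
  ro <- osvzOuterRadius(state$t, geom)
  thetas <- mesh$thetas
  ri_s <- seq(geom$r_isvz, max(ro, geom$r_isvz + 1e-6), length.out = 25L)
  thick <- vapply(thetas, function(th) {
    s <- rayInterp(mesh, state$u, state$c, th, ri_s)
    polylineLength(s$xy)
  }, numeric(1))
  tr <- surfaceTrace(mesh, state$u)
  rho <- sqrt(rowSums(tr$points^2))
  rs <- movingAverage(rho, max(1L, round(smooth_frac * length(rho))))
  data.frame(theta = thetas, thickness = thick,
             class = ifelse(rho >= rs, "gyrus", "sulcus"))
}

#' Dominant surface wavelength
#'
#' Estimates the wrinkling wavelength as twice the mean arc spacing
#' between consecutive alternating extrema of the (smoothed) radial
#' profile. The trace endpoints are included as extrema: on the
#' symmetry edges the radial derivative vanishes, so every admissible
#' pattern has a crest or trough there.
#'
#' @param trace a [surfaceTrace()].
#' @param smooth_frac,persistence as in [detectSulci()].
#' @return wavelength in mm, or `NA` if fewer than two extrema exist.
#' @export
dominantWavelength <- function(trace, smooth_frac = 0.05,
                               persistence = NULL) {
  lm <- detectSulci(trace, smooth_frac, persistence)
  idx <- sort(c(1L, lm$sulci, lm$gyri, length(lm$rho)))
  if (length(idx) < 3) return(NA_real_)
  2 * mean(diff(trace$arc[idx]))
}

# TRUE if the open polyline crosses itself (segment-pair intersection
# test with a bounding-box prefilter); used to stop runs at sulcal
# self-contact
polylineSelfIntersects <- function(pts) {
  m <- nrow(pts) - 1L
  if (m < 3L) return(FALSE)
  p <- pts[-(m + 1L), , drop = FALSE]; q <- pts[-1L, , drop = FALSE]
  lo <- pmin(p, q); hi <- pmax(p, q)
  for (i in seq_len(m - 2L)) {
    js <- (i + 2L):m
    cand <- js[lo[js, 1] <= hi[i, 1] & hi[js, 1] >= lo[i, 1] &
               lo[js, 2] <= hi[i, 2] & hi[js, 2] >= lo[i, 2]]
    if (!length(cand)) next
    d <- q[i, ] - p[i, ]
    for (j in cand) {
      e <- q[j, ] - p[j, ]
      den <- d[1] * e[2] - d[2] * e[1]
      if (abs(den) < 1e-14) next
      w <- p[j, ] - p[i, ]
      t1 <- (w[1] * e[2] - w[2] * e[1]) / den
      t2 <- (w[1] * d[2] - w[2] * d[1]) / den
      if (t1 >= 0 && t1 <= 1 && t2 >= 0 && t2 <= 1) return(TRUE)
    }
  }
  FALSE
}

#' Analytic fixture surfaces and states
#'
#' Closed-form boundaries and density fields used to test the
#' morphometric operations without running the solver:
#' `"smooth"` (a circle of radius `R0`), `"wavy"`
#' (`rho = R0 + amplitude * sin(modes * theta)`), and
#' `"period_doubled"` (Gaussian troughs of alternating deep/shallow
#' depth at equally spaced angles).
#'
#' @param kind fixture kind.
#' @param n number of trace points over \[0, pi/2\].
#' @param R0 base radius, mm.
#' @param amplitude,modes wavy parameters.
#' @param deep,shallow,n_troughs,width period-doubled parameters.
#' @return a `cg_surface` trace.
#' @export
generateFixtureSurface <- function(kind = c("smooth", "wavy",
                                            "period_doubled"),
                                   n = 400L, R0 = 2,
                                   amplitude = 0.1, modes = 8,
                                   deep = 0.3, shallow = 0.1,
                                   n_troughs = 4L, width = 0.06) {
  kind <- match.arg(kind)
  th <- seq(0, pi / 2, length.out = n)
  rho <- switch(kind,
    smooth = rep(R0, n),
    wavy = R0 + amplitude * sin(modes * th),
    period_doubled = {
      centers <- seq(0, pi / 2, length.out = n_troughs + 2L)[-c(1L,
                      n_troughs + 2L)]
      depths <- rep(c(deep, shallow), length.out = n_troughs)
      r <- rep(R0, n)
      for (k in seq_len(n_troughs))
        r <- r - depths[k] * exp(-(th - centers[k])^2 / (2 * width^2))
      r
    })
  newSurfaceTrace(cbind(rho * cos(th), rho * sin(th)))
}

#' @rdname generateFixtureSurface
#' @param mesh mesh on which to build a synthetic density state.
#' @param peaks list with numeric vectors `centers` (material radii,
#'   mm), `widths` (mm) and `amps` (mm^-2) of Gaussian density bumps.
#' @param t synthetic time, days.
#' @export
generateFixtureState <- function(mesh, peaks = list(centers = c(0.45, 0.9,
                                                                1.9),
                                                    widths = c(0.05, 0.08,
                                                               0.08),
                                                    amps = c(800, 600,
                                                             700)),
                                 t = 0) {
  c_nod <- numeric(nrow(mesh$nodes))
  for (k in seq_along(peaks$centers))
    c_nod <- c_nod + peaks$amps[k] *
      exp(-(mesh$material_radius - peaks$centers[k])^2 /
            (2 * peaks$widths[k]^2))
  list(mesh = mesh, u = matrix(0, nrow(mesh$nodes), 2), c = c_nod, t = t)
}
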