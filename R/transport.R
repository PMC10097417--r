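#' Cell-transport parameters
#'
#' Parameters of the neuron-density balance: division rates in the two
#' proliferating zones, migration speed and threshold, cortical
#' diffusivity, and the stabilization constants for the advective terms.
#'
#' @param G_vz initial division rate in the ventricular zone,
#'   mm^-2 day^-1 (study range 30-120).
#' @param G_osvz initial division rate in the outer subventricular zone,
#'   mm^-2 day^-1 (study range 0-30).
#' @param v_max maximum migration speed, mm/day.
#' @param c0 migration threshold density, mm^-2: cells migrate only once
#'   the local density exceeds this value (logistic gate).
#' @param gamma_c logistic exponent of the migration gate, mm^2.
#' @param d_cc cortical diffusivity, mm^2/day.
#' @param heterogeneity a [heterogeneityPattern()] describing angular
#'   variation of the OSVZ division rate.
#' @param C_art,nu_cap,eps_reg constants of the residual-based artificial
#'   viscosity (see [artificialViscosity()]); `nu_cap` defaults to
#'   `d_cc`.
#' @param supg logical: add conservative streamline-upwind stabilization
#'   to the advective term.
#' @return an object of class `cg_transport`.
#' @export
transportParams <- function(G_vz = 120, G_osvz = 20, v_max = 5, c0 = 500,
                            gamma_c = 0.008, d_cc = 0.11,
                            heterogeneity = heterogeneityPattern(),
                            C_art = 0.5, nu_cap = NULL, eps_reg = 1e-8,
                            supg = TRUE) {
  vals <- c(G_vz, G_osvz, v_max, c0, gamma_c, d_cc, C_art, eps_reg)
  if (any(vals < 0)) stop("transport rates/speeds/diffusivities must be >= 0")
  if (is.null(nu_cap)) nu_cap <- d_cc
  structure(list(G_vz = G_vz, G_osvz = G_osvz, v_max = v_max, c0 = c0,
                 gamma_c = gamma_c, d_cc = d_cc,
                 heterogeneity = heterogeneity, C_art = C_art,
                 nu_cap = nu_cap, eps_reg = eps_reg, supg = isTRUE(supg)),
            class = "cg_transport")
}

#' @export
print.cg_transport <- function(x, ...) {
  cat("Cell transport: G_vz =", x$G_vz, " G_osvz =", x$G_osvz,
      "mm^-2/day; v_max =", x$v_max, "mm/day; c0 =", x$c0,
      "mm^-2; d_cc =", x$d_cc, "mm^2/day\n  OSVZ pattern:",
      x$heterogeneity$kind, "\n")
  invisible(x)
}

#' Angular heterogeneity of the OSVZ division rate
#'
#' Describes how the OSVZ division rate varies with the polar angle:
#' `"homogeneous"` (multiplier 1 everywhere),
#' `"circumferential_gradient"` (linear drop from 1 at theta = 0 to
#' `relative_range[1]` at theta = pi/2), or `"random_sectors"` (seeded
#' piecewise-constant multipliers, uniform in `relative_range`, over
#' `n_sectors` equal angular sectors).
#'
#' @param kind pattern kind.
#' @param n_sectors number of angular sectors for `"random_sectors"`.
#' @param relative_range multiplier range: lower bound of the gradient,
#'   or the \[lo, hi\] sampling interval for random sectors.
#' @param seed integer seed for the random sectors.
#' @return an object of class `cg_hetero`.
#' @export
heterogeneityPattern <- function(kind = c("homogeneous",
                                          "circumferential_gradient",
                                          "random_sectors"),
                                 n_sectors = 8L,
                                 relative_range = c(0.5, 1.5),
                                 seed = 1L) {
  kind <- match.arg(kind)
  if (any(relative_range < 0)) stop("multipliers must be >= 0")
  structure(list(kind = kind, n_sectors = as.integer(n_sectors),
                 relative_range = relative_range, seed = as.integer(seed)),
            class = "cg_hetero")
}

#' OSVZ division-rate multiplier at an angle
#'
#' @param theta polar angle(s), rad, in \[0, pi/2\].
#' @param pattern a [heterogeneityPattern()].
#' @return multiplier(s) >= 0; identically 1 for the homogeneous pattern.
#' @export
patternMultiplier <- function(theta, pattern) {
  switch(pattern$kind,
    homogeneous = rep(1, length(theta)),
    circumferential_gradient = {
      lo <- pattern$relative_range[1]
      1 + (lo - 1) * pmin(1, pmax(0, theta / (pi / 2)))
    },
    random_sectors = {
      mult <- withSeed(pattern$seed,
        runif(pattern$n_sectors, pattern$relative_range[1],
              pattern$relative_range[2]))
      sec <- pmin(pattern$n_sectors,
                  pmax(1L, ceiling(theta / (pi / 2) * pattern$n_sectors)))
      sec[theta <= 0] <- 1L
      mult[sec]
    })
}

#' Outer radius of the OSVZ over gestational time
#'
#' `rosvz(t) = r_isvz + m_mst t`, the linear outward motion of the OSVZ
#' boundary driven by mitotic somal translocation, capped at the cortical
#' boundary `r_cp` (the band cannot grow into the cortex).
#'
#' @param t time since the reference state (gestational week 11), days.
#' @param geom a [geometryParams()] object.
#' @return radius, mm; non-decreasing in `t`.
#' @export
osvzOuterRadius <- function(t, geom = geometryParams()) {
  if (any(t < 0)) stop("t must be >= 0")
  pmin(geom$r_isvz + geom$m_mst * t, geom$r_cp)
}

#' Stretch-modulated division rate
#'
#' The division rate decreases linearly with the maximum stretch `s` in
#' the domain, `G_s = G - (s - 1) G` for `s < 1.8`, saturating at
#' `0.2 G` beyond: increasing deformation feeds back negatively on
#' proliferation.
#'
#' @param G initial division rate, mm^-2 day^-1.
#' @param s maximum principal stretch in the domain (>= 1; values below
#'   1 are clamped to 1).
#' @return modulated rate, continuous at `s = 1.8`, never negative.
#' @export
stretchModulatedRate <- function(G, s) {
  s <- pmax(s, 1)
  ifelse(s < 1.8, G - (s - 1) * G, 0.2 * G)
}

#' Proliferation source terms
#'
#' `sourceVZ` is the ventricular-zone source
#' `G_vz_s(s) * (1 - H(ri - r_vz; 50))`; `sourceOSVZ` is the OSVZ source
#' `G_osvz_s(s) * (H(ri - r_isvz; 50) - H(ri - rosvz(t); 50))`, with the
#' division rate scaled by the angular heterogeneity multiplier before
#' stretch modulation.
#'
#' @param ri material radius, mm (vectorized).
#' @param theta polar angle, rad (for the OSVZ pattern).
#' @param t time, days.
#' @param s maximum stretch in the domain.
#' @param p a [transportParams()] object.
#' @param geom a [geometryParams()] object.
#' @return source rate, mm^-2 day^-1.
#' @export
sourceVZ <- function(ri, s, p, geom = geometryParams()) {
  stretchModulatedRate(p$G_vz, s) * zoneWeightVZ(ri, geom)
}

#' @rdname sourceVZ
#' @export
sourceOSVZ <- function(ri, theta, t, s, p, geom = geometryParams()) {
  G <- p$G_osvz * patternMultiplier(theta, p$heterogeneity)
  stretchModulatedRate(G, s) * zoneWeightOSVZ(ri, t, geom)
}

#' Radial migration-speed profile
#'
#' `v(ri) = v_max (1 - H(ri - r_cp; 10))`: full speed in the subcortex,
#' vanishing smoothly at the cortical boundary where migration ends.
#'
#' @inheritParams sourceVZ
#' @param r_cp cortical boundary radius, mm.
#' @return speed, mm/day.
#' @export
migrationSpeedProfile <- function(ri, p, r_cp = 1.8) {
  p$v_max * (1 - smoothHeaviside(ri - r_cp, 10))
}

#' Migration velocity along deformed fibers
#'
#' `vhat = H(c - c0; gamma_c) v(ri) n / |n|`, where `n = F N` is the
#' push-forward of the reference radial fiber direction: cells migrate
#' along the deformed glial scaffold, but only once the local density
#' exceeds the threshold `c0`.
#'
#' @param c local cell density, mm^-2.
#' @param ri material radius, mm.
#' @param n deformed fiber vector (length-2, need not be unit).
#' @param p a [transportParams()] object.
#' @param r_cp cortical boundary radius, mm.
#' @return velocity vector, mm/day; magnitude bounded by `v_max`.
#' @export
migrationVelocity <- function(c, ri, n, p, r_cp = 1.8) {
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("zero fiber vector")
  smoothHeaviside(c - p$c0, p$gamma_c) *
    migrationSpeedProfile(ri, p, r_cp) * n / nn
}

#' Cortical diffusivity profile
#'
#' `d(ri) = d_cc H(ri - r_cp; 10)`: neuronal-connectivity-driven
#' spreading acts only in the cortex.
#'
#' @inheritParams migrationSpeedProfile
#' @return diffusivity, mm^2/day.
#' @export
diffusivityProfile <- function(ri, p, r_cp = 1.8) {
  p$d_cc * smoothHeaviside(ri - r_cp, 10)
}

#' Residual-based artificial viscosity
#'
#' Consistent stabilization of the advection-dominated density balance:
#' `nu_c = C_art h |residual| / (|grad c| + eps_reg)`, capped at
#' `nu_cap`. It vanishes wherever the discrete balance is satisfied, so
#' exact solutions are unperturbed, and it decays at least linearly with
#' the element size on smooth solutions.
#'
#' @param element_residual element-mean strong residual of the density
#'   balance, mm^-2 day^-1.
#' @param grad_c norm of the density gradient, mm^-3.
#' @param h element size, mm.
#' @param C_art dimensionless constant.
#' @param nu_cap cap, mm^2/day.
#' @param eps_reg gradient regularization.
#' @return added isotropic diffusivity, mm^2/day.
#' @export
artificialViscosity <- function(element_residual, grad_c, h, C_art = 0.5,
                                nu_cap = 0.11, eps_reg = 1e-8) {
  if (any(h <= 0)) stop("element size must be > 0")
  pmin(nu_cap, C_art * h * abs(element_residual) / (grad_c + eps_reg))
}

#' Maximum principal stretch in the domain
#'
#' The largest singular value of the total deformation gradient over all
#' quadrature points of the current displacement solution. This is the
#' kinematic quantity that feeds back on the division rates.
#'
#' @param state a simulation state (see [runSimulation()]), or a list
#'   with `mesh` and `u` (n x 2 displacement matrix).
#' @return maximum stretch `s >= 0` (1 for the undeformed state).
#' @export
maxStretch <- function(state) {
  gp <- gpBasis(state$mesh)
  kin <- cg_kinematics(gp$dNdX, gp$w, state$mesh$elems,
                       as.numeric(t(state$u)))
  if (kin$minDetF <= 0) stop("element inversion: det F <= 0")
  kin$smax
}
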