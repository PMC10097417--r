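#' Smoothed Heaviside (logistic) function
#'
#' `H(x; gamma) = exp(gamma * x) / (1 + exp(gamma * x))`, the smooth step
#' used throughout the model to blend zone boundaries, the cortical
#' stiffness transition and the migration threshold. Overflow-safe:
#' evaluated via `plogis`-style branching.
#'
#' @param x argument (vectorized).
#' @param gamma sharpness exponent; larger values give sharper steps.
#' @return values in (0, 1), with `H(0) = 0.5` and `H(x) + H(-x) = 1`.
#' @export
smoothHeaviside <- function(x, gamma) {
  z <- gamma * x
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Material parameters of the brain-tissue model
#'
#' Neo-Hookean elasticity with a density-dependent cortical shear
#' modulus, and the anisotropic growth law parameters. Two stiffness
#' modes are supported: `"varying"` (the cortical modulus ramps linearly
#' with cell density between `c_min` and `c_max`, default stiffness ratio
#' 3) and `"constant"` (the cortical modulus is always `mu_inf`, default
#' stiffness ratio 8). In both modes the subcortical modulus is
#' `mu_s = mu_inf / beta_mu`.
#'
#' @param mu_inf cortical shear modulus at full density, kPa.
#' @param poisson_nu Poisson ratio (plane strain), in (0, 0.5).
#' @param beta_mu stiffness ratio `mu_inf / mu_s`; if `NULL`, defaults to
#'   3 for varying and 8 for constant stiffness.
#' @param c_max,c_min density thresholds of the stiffness ramp, mm^-2.
#' @param kappa_s subcortical growth factor, mm^2.
#' @param alpha growth exponent.
#' @param beta_kappa cortical growth anisotropy ratio
#'   (circumferential/subcortical).
#' @param stiffness_mode `"varying"` or `"constant"`.
#' @return an object of class `cg_material` with derived fields `mu_s`
#'   and ramp slope `m_c = (mu_inf - mu_s) / (c_max - c_min)`.
#' @export
materialParams <- function(mu_inf = 2.07, poisson_nu = 0.38, beta_mu = NULL,
                           c_max = 700, c_min = 200, kappa_s = 4.07e-4,
                           alpha = 1.65, beta_kappa = 3,
                           stiffness_mode = c("varying", "constant")) {
  stiffness_mode <- match.arg(stiffness_mode)
  if (is.null(beta_mu))
    beta_mu <- if (stiffness_mode == "varying") 3 else 8
  if (!(mu_inf > 0)) stop("mu_inf must be > 0")
  if (!(poisson_nu > 0 && poisson_nu < 0.5))
    stop("poisson_nu must lie in (0, 0.5)")
  if (beta_mu < 1) stop("beta_mu must be >= 1")
  if (!(c_max > c_min && c_min >= 0)) stop("need c_max > c_min >= 0")
  if (kappa_s < 0) stop("kappa_s must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta_kappa < 1) stop("beta_kappa must be >= 1")
  mu_s <- mu_inf / beta_mu
  structure(list(mu_inf = mu_inf, poisson_nu = poisson_nu, beta_mu = beta_mu,
                 c_max = c_max, c_min = c_min, kappa_s = kappa_s,
                 alpha = alpha, beta_kappa = beta_kappa,
                 stiffness_mode = stiffness_mode, mu_s = mu_s,
                 m_c = (mu_inf - mu_s) / (c_max - c_min)),
            class = "cg_material")
}

#' @export
print.cg_material <- function(x, ...) {
  cat("Brain tissue material (", x$stiffness_mode, " cortical stiffness)\n",
      "  mu_inf = ", x$mu_inf, " kPa, mu_s = ", signif(x$mu_s, 4),
      " kPa (beta_mu = ", x$beta_mu, "), nu = ", x$poisson_nu, "\n",
      "  growth: kappa_s = ", x$kappa_s, " mm^2, alpha = ", x$alpha,
      ", beta_kappa = ", x$beta_kappa, "\n", sep = "")
  invisible(x)
}

#' Cortical shear modulus as a function of cell density
#'
#' In varying mode the cortical modulus ramps piecewise-linearly from
#' `mu_s` (below `c_min`) to `mu_inf` (above `c_max`); in constant mode
#' it is `mu_inf` regardless of density.
#'
#' @param c cell density, mm^-2 (vectorized).
#' @param p a [materialParams()] object.
#' @return shear modulus, kPa.
#' @export
corticalShearModulus <- function(c, p) {
  if (p$stiffness_mode == "constant") return(rep(p$mu_inf, length(c)))
  pmin(p$mu_inf, pmax(p$mu_s, p$mu_s + p$m_c * (c - p$c_min)))
}

#' Radial shear-modulus profile
#'
#' Blends the subcortical modulus `mu_s` into the (possibly
#' density-dependent) cortical modulus across the cortical boundary
#' `r_cp` with logistic exponent 20:
#' `mu(ri) = mu_s + (mu_c(c) - mu_s) H(ri - r_cp; 20)`.
#'
#' @param ri material radius, mm (vectorized).
#' @param c local cell density, mm^-2.
#' @param p a [materialParams()] object.
#' @param r_cp cortical boundary radius, mm.
#' @return shear modulus, kPa.
#' @export
shearModulusProfile <- function(ri, c, p, r_cp = 1.8) {
  p$mu_s + (corticalShearModulus(c, p) - p$mu_s) *
    smoothHeaviside(ri - r_cp, 20)
}

#' First Lame parameter from shear modulus and Poisson ratio
#'
#' `lambda = 2 mu nu / (1 - 2 nu)`. The Poisson ratio is held fixed, so
#' lambda varies wherever mu does.
#'
#' @param mu shear modulus, kPa.
#' @param nu Poisson ratio, in \[0, 0.5).
#' @return lambda, kPa.
#' @export
lameLambda <- function(mu, nu) {
  if (any(nu >= 0.5)) stop("nu must be < 0.5 (incompressible limit)")
  2 * mu * nu / (1 - 2 * nu)
}

#' Radial growth-factor profiles
#'
#' Growth is isotropic (`kappa_s` in both directions) in the subcortex
#' and anisotropic in the cortex, where the circumferential factor rises
#' to `kappa_s * beta_kappa` and the radial factor drops to
#' `kappa_s / beta_kappa`, blended across `r_cp` with logistic
#' exponent 20.
#'
#' @inheritParams shearModulusProfile
#' @return a list with vectors `kappa_perp` (circumferential) and
#'   `kappa_par` (radial), mm^2.
#' @export
growthFactors <- function(ri, p, r_cp = 1.8) {
  H <- smoothHeaviside(ri - r_cp, 20)
  list(kappa_perp = p$kappa_s + p$kappa_s * (p$beta_kappa - 1) * H,
       kappa_par  = p$kappa_s + p$kappa_s * (1 / p$beta_kappa - 1) * H)
}

#' Density-driven growth multipliers
#'
#' `theta = (1 + kappa * c)^alpha` in each direction: no cells, no
#' growth; strictly increasing in density.
#'
#' @param c cell density, mm^-2 (vectorized).
#' @param kappa_perp,kappa_par growth factors, mm^2.
#' @param alpha growth exponent.
#' @return a list with vectors `theta_perp` and `theta_par`.
#' @export
growthMultipliers <- function(c, kappa_perp, kappa_par, alpha) {
  list(theta_perp = (1 + kappa_perp * pmax(c, 0))^alpha,
       theta_par  = (1 + kappa_par  * pmax(c, 0))^alpha)
}

#' Anisotropic growth tensor
#'
#' `Fg = theta_perp (I - N x N) + theta_par N x N`: stretch `theta_par`
#' along the fiber direction `N`, `theta_perp` transverse to it.
#'
#' @param theta_perp,theta_par growth multipliers.
#' @param N unit fiber direction (length-2).
#' @return a 2 x 2 symmetric positive-definite matrix with
#'   `det Fg = theta_perp * theta_par`.
#' @export
growthTensor <- function(theta_perp, theta_par, N) {
  if (abs(sum(N^2) - 1) > 1e-8) stop("N must be a unit vector")
  NN <- tcrossprod(N)
  theta_perp * (diag(2) - NN) + theta_par * NN
}

#' Elastic part of the deformation gradient
#'
#' `Fe = F Fg^-1`, the stress-carrying part of the multiplicative split
#' `F = Fe Fg`.
#'
#' @param F total deformation gradient (2 x 2 or 3 x 3).
#' @param Fg growth tensor of matching size.
#' @return Fe.
#' @export
elasticPart <- function(F, Fg) {
  if (det(Fg) <= 0) stop("growth tensor must have positive determinant")
  F %*% solve(Fg)
}

# embed a 2x2 tensor as 3x3 plane strain (out-of-plane stretch 1)
embedPlaneStrain <- function(A) {
  if (all(dim(A) == c(3L, 3L))) return(A)
  B <- diag(3)
  B[1:2, 1:2] <- A
  B
}

#' Neo-Hookean strain energy density
#'
#' `psi = lambda/2 ln^2(Je) + mu/2 (Fe:Fe - 3 - 2 ln Je)` with Fe
#' embedded as 3 x 3 under plane strain (out-of-plane stretch 1), so a
#' 2 x 2 input contributes the +1 out-of-plane term to `Fe:Fe`.
#'
#' @param Fe elastic deformation gradient (2 x 2 or 3 x 3), `det Fe > 0`.
#' @param mu shear modulus, kPa.
#' @param lam first Lame parameter, kPa.
#' @return energy density, kPa.
#' @export
strainEnergy <- function(Fe, mu, lam) {
  Fe <- embedPlaneStrain(Fe)
  Je <- det(Fe)
  if (Je <= 0) stop("det Fe must be > 0")
  0.5 * lam * log(Je)^2 + 0.5 * mu * (sum(Fe^2) - 3 - 2 * log(Je))
}

#' Cauchy stress of the neo-Hookean law
#'
#' Closed form of `sigma = (1/Je) dpsi/dFe Fe^T`:
#' `sigma = (1/Je) (lambda ln(Je) I + mu (Fe Fe^T - I))`. Symmetric, and
#' zero at `Fe = I`.
#'
#' @inheritParams strainEnergy
#' @return 3 x 3 Cauchy stress, kPa (plane strain embedding).
#' @export
cauchyStress <- function(Fe, mu, lam) {
  Fe <- embedPlaneStrain(Fe)
  Je <- det(Fe)
  if (Je <= 0) stop("det Fe must be > 0")
  (lam * log(Je) * diag(3) + mu * (tcrossprod(Fe) - diag(3))) / Je
}

#' Irreversibility ratchet for the growth state
#'
#' Growth is irreversible: the stored multipliers can only increase.
#' Returns the componentwise maximum of the previous and proposed state.
#'
#' @param prev,proposed lists with numeric fields `theta_perp` and
#'   `theta_par` on the same quadrature points.
#' @return the ratcheted growth state.
#' @export
updateGrowthState <- function(prev, proposed) {
  if (length(prev$theta_perp) != length(proposed$theta_perp) ||
      length(prev$theta_par) != length(proposed$theta_par))
    stop("growth states live on different quadrature point sets")
  list(theta_perp = pmax(prev$theta_perp, proposed$theta_perp),
       theta_par  = pmax(prev$theta_par,  proposed$theta_par))
}
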