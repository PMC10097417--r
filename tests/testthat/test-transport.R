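test_that("OSVZ outer boundary moves at the MST rate and is capped", {
  g <- geometryParams()
  expect_equal(osvzOuterRadius(0, g), 0.8)
  expect_equal(osvzOuterRadius(10, g), 1.0)
  expect_equal(osvzOuterRadius(100, g), 1.8)  # capped at r_cp
  t <- seq(0, 120, by = 5)
  expect_true(all(diff(osvzOuterRadius(t, g)) >= 0))
  expect_error(osvzOuterRadius(-1, g), ">= 0")
})

test_that("stretch modulation is linear then saturated, continuous", {
  expect_equal(stretchModulatedRate(120, 1), 120)
  expect_equal(stretchModulatedRate(120, 1.4), 72)
  expect_equal(stretchModulatedRate(120, 1.8), 24)
  expect_equal(stretchModulatedRate(120, 1.8 - 1e-10),
               stretchModulatedRate(120, 1.8 + 1e-10), tolerance = 1e-7)
  expect_equal(stretchModulatedRate(120, 0.7), 120)  # clamped below 1
  expect_gte(stretchModulatedRate(120, 50), 0)
})

test_that("VZ source is the modulated rate times the zone weight", {
  p <- transportParams(G_vz = 120)
  g <- geometryParams()
  expect_equal(sourceVZ(0.2, 1, p, g), 120, tolerance = 1e-4)
  expect_lt(sourceVZ(1.5, 1, p, g), 1e-10)
  expect_equal(sourceVZ(0.2, 2.5, p, g), 24, tolerance = 1e-4)
})

test_that("OSVZ source combines band weight, pattern and stretch", {
  p <- transportParams(G_osvz = 20)
  g <- geometryParams()
  expect_equal(sourceOSVZ(seq(0.4, 2, 0.2), 0.3, 0, 1, p, g),
               rep(0, 9))
  expect_equal(sourceOSVZ(0.9, 0.3, 10, 1, p, g), 20 * 0.98661,
               tolerance = 1e-4)
  grad <- heterogeneityPattern("circumferential_gradient",
                               relative_range = c(0, 1))
  expect_equal(patternMultiplier(0, grad), 1)
  expect_equal(patternMultiplier(pi / 2, grad), 0)
  expect_equal(patternMultiplier(pi / 4, grad), 0.5)
  rs <- heterogeneityPattern("random_sectors", n_sectors = 8,
                             relative_range = c(0.5, 1.5), seed = 3)
  th <- seq(0.01, pi / 2 - 0.01, length.out = 40)
  m1 <- patternMultiplier(th, rs)
  expect_true(all(m1 >= 0.5 & m1 <= 1.5))
  expect_identical(m1, patternMultiplier(th, rs))  # seeded
  expect_equal(length(unique(round(m1, 10))), 8)
})

test_that("migration speed and diffusivity profiles split the domain", {
  p <- transportParams()
  expect_equal(migrationSpeedProfile(1.8, p), 2.5)
  expect_equal(migrationSpeedProfile(1.0, p), 4.99832, tolerance = 1e-5)
  expect_equal(migrationSpeedProfile(2.0, p), 5 * (1 - smoothHeaviside(2, 1)))
  expect_equal(migrationSpeedProfile(2.0, p), 0.596, tolerance = 1e-3)
  expect_equal(diffusivityProfile(1.8, p), 0.055)
  expect_equal(diffusivityProfile(2.0, p), 0.11 * smoothHeaviside(2, 1))
  expect_equal(diffusivityProfile(2.0, p), 0.09689, tolerance = 1e-4)
  expect_lt(diffusivityProfile(0.5, p), 1e-5)
})

test_that("migration velocity is gated by density and follows fibers", {
  p <- transportParams()
  v <- migrationVelocity(500, 1.0, c(0, 2), p)
  expect_equal(sqrt(sum(v^2)), 0.5 * migrationSpeedProfile(1.0, p))
  expect_equal(v / sqrt(sum(v^2)), c(0, 1))
  v2 <- migrationVelocity(1000, 1.0, c(1, 0), p)
  expect_equal(sqrt(sum(v2^2)), 4.909, tolerance = 1e-3)
  v3 <- migrationVelocity(0, 1.0, c(1, 0), p)
  expect_equal(sqrt(sum(v3^2)),
               smoothHeaviside(-4, 1) * migrationSpeedProfile(1.0, p))
  expect_true(all(abs(migrationVelocity(1e6, 0.4, c(3, 4), p)) <= 5))
  expect_error(migrationVelocity(500, 1, c(0, 0), p), "zero fiber")
})

test_that("artificial viscosity is consistent, capped and regular", {
  expect_equal(artificialViscosity(0, 10, 0.1), 0)
  expect_equal(artificialViscosity(100, 0, 0.1, nu_cap = 0.11), 0.11)
  expect_equal(artificialViscosity(2, 100, 0.1, C_art = 0.5),
               0.5 * 0.1 * 2 / (100 + 1e-8))
  expect_error(artificialViscosity(1, 1, 0), "element size")
})

test_that("max stretch equals the largest singular value of F", {
  m <- patchMesh(4)
  st <- list(mesh = m, u = matrix(0, nrow(m$nodes), 2))
  expect_equal(maxStretch(st), 1)
  # uniform affine maps: oracle via svd of the exact gradient
  set.seed(21)
  for (rep in 1:10) {
    A <- diag(2) + matrix(runif(4, -0.3, 0.3), 2)
    if (det(A) <= 0.1) next
    st$u <- t(A %*% t(m$nodes)) - m$nodes
    expect_equal(maxStretch(st), max(svd(A)$d), tolerance = 1e-12)
  }
  st$u <- t(diag(c(1.3, 0.9)) %*% t(m$nodes)) - m$nodes
  expect_equal(maxStretch(st), 1.3)
})

test_that("density balance conserves total cell number with no sources", {
  m <- stripMesh(30, 2)
  gp <- cortigrow:::gpBasis(m)
  prof <- flatProfiles(gp, v = 2, d = 0.05)
  prof$ri <- as.numeric(gp$Phi %*% m$material_radius)
  trans <- transportParams(G_vz = 0, G_osvz = 0, c0 = 0.2, supg = TRUE)
  geom <- geometryParams()
  u <- matrix(0, nrow(m$nodes), 2)
  cc <- exp(-(m$nodes[, 1] - 0.5)^2 / 0.02)
  nu <- numeric(nrow(m$elems))
  tot0 <- NA
  for (k in 1:100) {
    ts <- cortigrow:::transportStep(m, gp, prof, u, cc, 0.01, k * 0.01,
                                    1, nu, trans, geom)
    cc <- ts$c; nu <- ts$nu_e
    if (k == 1) tot0 <- sum(ts$mass_lumped * cc)
  }
  expect_lt(abs(sum(ts$mass_lumped * cc) - tot0) / tot0, 0.001)
  expect_true(all(cc >= 0))
})

test_that("cortical diffusion matches the 1D heat kernel under refinement", {
  runDiff <- function(nx, dt, nsteps, d = 0.11) {
    m <- stripMesh(nx, 2)
    gp <- cortigrow:::gpBasis(m)
    prof <- flatProfiles(gp, v = 0, d = d)
    trans <- transportParams(G_vz = 0, G_osvz = 0, v_max = 0, d_cc = d,
                             supg = FALSE, C_art = 0)
    geom <- geometryParams()
    u <- matrix(0, nrow(m$nodes), 2)
    s0 <- 0.05
    cc <- exp(-(m$nodes[, 1] - 1)^2 / (2 * s0^2))
    nu <- numeric(nrow(m$elems))
    for (k in seq_len(nsteps))
      cc <- cortigrow:::transportStep(m, gp, prof, u, cc, dt, k * dt, 1,
                                      nu, trans, geom)$c
    st2 <- sqrt(s0^2 + 2 * d * nsteps * dt)
    exact <- s0 / st2 * exp(-(m$nodes[, 1] - 1)^2 / (2 * st2^2))
    mid <- abs(m$nodes[, 2] - 0.15) < 1e-9
    sqrt(mean((cc[mid] - exact[mid])^2)) / sqrt(mean(exact[mid]^2))
  }
  e_coarse <- runDiff(40, 0.02, 25)
  e_fine <- runDiff(80, 0.005, 100)
  expect_lt(e_coarse, 0.05)
  expect_lt(e_fine, e_coarse)
})

test_that("uniform expansion dilutes density as c0/J", {
  m <- patchMesh(3)
  gp <- cortigrow:::gpBasis(m)
  cc <- rep(100, nrow(m$nodes))
  Jnod <- rep(1, nrow(m$nodes))
  gs <- c(1.1, 1.25, 1.4)  # growing uniform stretch sequence
  for (g in gs) {
    u <- (g - 1) * m$nodes
    kin <- cortigrow:::cg_kinematics(gp$dNdX, gp$w, m$elems,
                                     as.numeric(t(u)))
    dil <- cortigrow:::dilutionUpdate(gp, cc, Jnod, as.numeric(kin$Jgp))
    cc <- dil$c; Jnod <- dil$Jnod
  }
  expect_equal(cc, rep(100 / 1.4^2, length(cc)), tolerance = 1e-12)
})

test_that("artificial viscosity decays with mesh refinement", {
  # manufactured smooth monotone front on square elements; measure nu in
  # the resolved interior window (the advective boundary layers at the
  # closed ends are genuinely unresolved and keep their stabilization)
  runNu <- function(nx) {
    dx <- 2 / nx
    m <- stripMesh(nx, 2, Lx = 2, Ly = 2 * dx)
    gp <- cortigrow:::gpBasis(m)
    prof <- flatProfiles(gp, v = 1, d = 0.05)
    trans <- transportParams(G_vz = 0, G_osvz = 0, c0 = 0.1,
                             gamma_c = 100, supg = FALSE)
    geom <- geometryParams()
    u <- matrix(0, nrow(m$nodes), 2)
    cc <- 1 / (1 + exp((m$nodes[, 1] - 0.8) / 0.15))
    nu <- numeric(nrow(m$elems))
    dt <- 0.2 * dx
    for (k in seq_len(round(0.05 / dt))) {
      ts <- cortigrow:::transportStep(m, gp, prof, u, cc, dt, k * dt, 1,
                                      nu, trans, geom)
      cc <- ts$c; nu <- ts$nu_e
    }
    ex <- (m$nodes[m$elems[, 1], 1] + m$nodes[m$elems[, 2], 1]) / 2
    max(nu[ex > 0.5 & ex < 1.2])
  }
  nus <- vapply(c(20, 40, 80), runNu, numeric(1))
  expect_true(all(diff(nus) < 0))
  # close to linear decay over a fourfold refinement
  expect_lt(nus[3] / nus[1], 0.35)
})

test_that("migration gate keeps the cortex empty at early times", {
  res <- deskRun("vz_only", transport = list(G_osvz = 0), t_end = 3)
  st <- res$state
  mrad <- st$mesh$material_radius
  vz_max <- max(st$c[mrad < 0.55])
  cortex_max <- max(st$c[mrad > 1.8])
  # VZ has reached its quasi-steady filling level, far below c0, and
  # essentially nothing has crossed into the cortex yet
  expect_gt(vz_max, 30)
  expect_lt(vz_max, res$config$transport$c0)
  expect_lt(cortex_max, 0.01 * vz_max)
})

test_that("transport parameter invariants are enforced", {
  expect_error(transportParams(G_vz = -1), ">= 0")
  expect_error(heterogeneityPattern(relative_range = c(-1, 1)), ">= 0")
})
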