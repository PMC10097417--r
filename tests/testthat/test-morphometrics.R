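wavyTrace <- function(n = 400, amplitude = 0.1, modes = 8)
  generateFixtureSurface("wavy", n = n, amplitude = amplitude,
                         modes = modes)

test_that("folding evolution measures the perimeter ratio", {
  m <- buildQuarterAnnulus(geometryParams(), 4, 48)
  tr <- surfaceTrace(m)
  p0 <- cortigrow:::polylineLength(tr$points)
  expect_equal(p0, pi, tolerance = 1e-3)  # quarter circle R = 2
  expect_equal(foldingEvolution(tr, p0), 1)
  # quadrature oracle for the wavy closed form
  tw <- wavyTrace(400)
  arcfun <- function(th) sqrt((2 + 0.1 * sin(8 * th))^2 +
                                (0.8 * cos(8 * th))^2)
  exact <- integrate(arcfun, 0, pi / 2, rel.tol = 1e-10)$value
  expect_equal(foldingEvolution(tw, exact), 1, tolerance = 2e-3)
  # polyline length increases monotonically with sampling
  lens <- vapply(c(50, 100, 200, 400), function(n)
    cortigrow:::polylineLength(wavyTrace(n)$points), numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("sulcus detection finds the closed-form extrema", {
  lm <- detectSulci(wavyTrace())
  expect_length(lm$sulci, 2)   # troughs at 3pi/16 and 7pi/16
  expect_length(lm$gyri, 2)
  th <- atan2(wavyTrace()$points[lm$sulci, 2],
              wavyTrace()$points[lm$sulci, 1])
  expect_equal(sort(th), c(3 * pi / 16, 7 * pi / 16), tolerance = 0.02)
  # smooth circle: nothing
  sm <- generateFixtureSurface("smooth")
  expect_length(detectSulci(sm)$sulci, 0)
  # sub-threshold noise: nothing
  set.seed(2)
  thg <- seq(0, pi / 2, length.out = 400)
  rho <- 2 + rnorm(400, 0, 0.0005)
  noisy <- cortigrow:::newSurfaceTrace(cbind(rho * cos(thg),
                                             rho * sin(thg)))
  expect_length(detectSulci(noisy)$sulci, 0)
})

test_that("sulcus depth is measured against the flanking crowns", {
  tw <- wavyTrace()
  lm <- detectSulci(tw)
  sm <- generateFixtureSurface("smooth")
  expect_length(detectSulci(sm)$sulci, 0)
  for (s in lm$sulci) {
    d <- sulcusDepth(tw, lm, s)
    expect_equal(as.numeric(d), 0.2, tolerance = 0.01)
  }
  # invariant under rigid rotation about the origin
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  rot <- cortigrow:::newSurfaceTrace(tw$points %*% t(R))
  lmr <- detectSulci(rot)
  expect_equal(sort(vapply(lmr$sulci, function(s)
    as.numeric(sulcusDepth(rot, lmr, s)), numeric(1))),
    sort(vapply(lm$sulci, function(s)
      as.numeric(sulcusDepth(tw, lm, s)), numeric(1))),
    tolerance = 1e-6)
})

test_that("inter-sulcal distance is the chord between minima", {
  tw <- wavyTrace()
  d <- intersulcalDistance(tw)
  expect_length(d, 1)
  # trough localization is limited by the 400-point sampling
  expect_equal(d, 2 * 1.9 * sin(pi / 8), tolerance = 5e-3)
  # direction reversal leaves distances unchanged
  rev_tr <- cortigrow:::newSurfaceTrace(tw$points[nrow(tw$points):1, ])
  expect_equal(intersulcalDistance(rev_tr), d, tolerance = 1e-9)
  # single or no fold: empty
  expect_length(intersulcalDistance(generateFixtureSurface("smooth")),
                0)
})

test_that("instability detection flags constructed change points", {
  n <- 60
  # no folds at all: nothing detected
  flat <- data.frame(time = 1:n, folding_evolution = 1 + 0.001 * (1:n),
                     depth_max = 0, depth_min = 0, n_sulci = 0)
  ip0 <- detectInstabilityPoints(flat)
  expect_true(is.na(ip0$t_primary))
  expect_true(is.na(ip0$t_secondary))
  # depths equal then diverging at step 30
  dmax <- c(rep(0.05, 29), 0.05 + 0.01 * (1:31))
  dmin <- rep(0.05, n)
  fe <- c(1 + 0.002 * (1:20), 1.04 + 0.01 * (1:40))  # kink at index 20
  synth <- data.frame(time = 1:n, folding_evolution = fe,
                      depth_max = dmax, depth_min = dmin,
                      n_sulci = 2)
  ip <- detectInstabilityPoints(synth, depth_eps = 0.002, persist = 3)
  expect_false(is.na(ip$t_secondary))
  expect_gte(ip$t_secondary, 30)
  expect_lte(ip$t_secondary, 30 + 7 + 3)
  expect_equal(ip$t_kink, 20, tolerance = 1.5)
  # period-doubled fixture boundary: depth ratio far above threshold
  pd <- generateFixtureSurface("period_doubled", deep = 0.3,
                               shallow = 0.1)
  lmp <- detectSulci(pd)
  depths <- sort(vapply(lmp$sulci, function(s)
    as.numeric(sulcusDepth(pd, lmp, s)), numeric(1)))
  expect_gte(length(depths), 2)
  expect_gt(max(depths) / min(depths), 1.5)
})

test_that("radial profile is normalized and recovers prescribed peaks", {
  m <- buildQuarterAnnulus(geometryParams(), 24, 12)
  st <- generateFixtureState(m, peaks = list(centers = 1.0, widths = 1e6,
                                             amps = 100))
  pr <- radialProfile(st, pi / 4, 50)
  expect_equal(pr$density_norm, rep(1, 50), tolerance = 1e-6)
  expect_equal(pr$radius_norm[1], 0)
  expect_equal(pr$radius_norm[50], 1)
  # peaks resolved by the mesh are recovered to within a sample spacing
  # plus half a radial element
  mf <- buildQuarterAnnulus(geometryParams(), 60, 12)
  st2 <- generateFixtureState(mf, peaks = list(
    centers = c(0.45, 0.9, 1.9), widths = c(0.1, 0.1, 0.08),
    amps = c(800, 600, 700)))
  pr2 <- radialProfile(st2, pi / 3, 200)
  spacing <- diff(pr2$material_radius[1:2])
  dr_mesh <- max(diff(mf$radii))
  for (ctr in c(0.45, 0.9, 1.9)) {
    sel <- abs(pr2$material_radius - ctr) < 0.15
    pk <- pr2$material_radius[sel][which.max(pr2$density[sel])]
    expect_lt(abs(pk - ctr), spacing + dr_mesh / 2 + 1e-9)
  }
  # empty cortex falls back to the global maximum with a warning
  st3 <- generateFixtureState(m, peaks = list(centers = 0.45,
                                              widths = 0.05, amps = 10))
  expect_warning(radialProfile(st3, pi / 4, 50), "global maximum")
})

test_that("OSVZ thickness map is uniform pre-folding and tags gyri", {
  m <- buildQuarterAnnulus(geometryParams(), 20, 40)
  st <- list(mesh = m, u = matrix(0, nrow(m$nodes), 2),
             c = numeric(nrow(m$nodes)), t = 15)
  tm <- osvzThicknessMap(st)
  expect_lt(diff(range(tm$thickness)) / mean(tm$thickness), 0.02)
  expect_equal(mean(tm$thickness), osvzOuterRadius(15) - 0.8,
               tolerance = 1e-6)
  # synthetic radial bump deformation: thickness follows prescription
  taper <- pmax(0, (m$material_radius - 0.8) / (2 - 0.8))
  th <- atan2(m$nodes[, 2], m$nodes[, 1])
  ur <- 0.1 * sin(8 * th) * taper
  u <- cbind(ur * cos(th), ur * sin(th))
  st2 <- list(mesh = m, u = u, c = numeric(nrow(m$nodes)), t = 15)
  tm2 <- osvzThicknessMap(st2)
  gyral <- sin(8 * tm2$theta) > 0.3
  sulcal <- sin(8 * tm2$theta) < -0.3
  expect_equal(tm2$class[gyral], rep("gyrus", sum(gyral)))
  expect_equal(tm2$class[sulcal], rep("sulcus", sum(sulcal)))
  # outward bump stretches the band: thicker beneath displaced crests
  expect_gt(mean(tm2$thickness[gyral]), mean(tm2$thickness[sulcal]))
})

test_that("dominant wavelength matches a pure cosine boundary", {
  th <- seq(0, pi / 2, length.out = 500)
  rho <- 2 + 0.1 * cos(8 * th)
  tr <- cortigrow:::newSurfaceTrace(cbind(rho * cos(th), rho * sin(th)))
  lam <- dominantWavelength(tr)
  # period of cos(8 theta) at radius ~2: arc length ~ 2 * pi/4
  expect_equal(lam, 2 * pi / 4, tolerance = 0.1)
})

test_that("fixture generation is deterministic and degenerates cleanly", {
  t1 <- generateFixtureSurface("wavy", amplitude = 0)
  expect_equal(sqrt(rowSums(t1$points^2)), rep(2, 400))
  expect_identical(generateFixtureSurface("period_doubled")$points,
                   generateFixtureSurface("period_doubled")$points)
})
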