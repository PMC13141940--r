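test_that("background subtraction is exact and linear", {
  q <- seq(0.01, 0.3, by = 0.01)
  flat <- ScatteringProfile(q, rep(0, length(q)))
  ser <- simulateSECSeries(flat, nFrames = 30, peakCenter = 20, peakWidth = 3,
                           peakAmplitude = 0, bufferLevel = 7)
  out <- subtractBackground(ser, 1:5, 10:15)
  expect_equal(intensity(out), rep(0, length(q)), tolerance = 1e-12)

  ## sample = buffer + g(q): recover g exactly
  g <- 3 * exp(-q^2 * 100)
  ints <- cbind(matrix(5, length(q), 4), 5 + g, 5 + g)
  ser2 <- new("FrameSeries", q = q, intensities = ints,
              sigmas = matrix(numeric(), 0, 0), elutionIndex = 1:6,
              groundTruth = list())
  out2 <- subtractBackground(ser2, 1:4, 5:6)
  expect_equal(intensity(out2), g, tolerance = 1e-12)

  ## subtracting twice the background from sample+background: -background
  ser3 <- new("FrameSeries", q = q, intensities = cbind(10 + g, 2 * (10 + g)),
              sigmas = matrix(numeric(), 0, 0), elutionIndex = 1:2,
              groundTruth = list())
  out3 <- subtractBackground(ser3, 2, 1)
  expect_equal(intensity(out3), -(10 + g), tolerance = 1e-12)
})

test_that("background subtraction validates its index sets", {
  q <- seq(0.01, 0.1, by = 0.01)
  ser <- simulateSECSeries(ScatteringProfile(q, q), nFrames = 20,
                           peakCenter = 10, peakWidth = 2)
  expect_error(subtractBackground(ser, 1:5, 5:8), "overlap")
  expect_error(subtractBackground(ser, 1:5, integer()), "non-empty")
  expect_error(subtractBackground(ser, 1:5, 19:25), "out of range")
})

test_that("sigma propagation follows quadrature through both averages", {
  q <- c(0.01, 0.02)
  ints <- matrix(1, 2, 4)
  sigs <- matrix(c(1, 2), 2, 4)
  ser <- new("FrameSeries", q = q, intensities = ints, sigmas = sigs,
             elutionIndex = 1:4, groundTruth = list())
  out <- subtractBackground(ser, 1:2, 3:4)
  ## var = sigma^2/2 from each mean; total sigma = sigma
  expect_equal(uncertainty(out), c(1, 2), tolerance = 1e-12)
})

test_that("coordinate Rg handles closed-form cases and weighting", {
  one <- StructureModel(data.frame(chain = "A", resno = 1L, resid = "GLY",
                                   elety = "CA", elesy = "C", x = 0, y = 0, z = 0))
  expect_equal(rgFromCoords(one), 0)
  two <- StructureModel(data.frame(chain = "A", resno = 1:2, resid = "GLY",
                                   elety = "CA", elesy = "C",
                                   x = c(0, 2), y = 0, z = 0))
  expect_equal(rgFromCoords(two, "uniform"), 1)
  ## unequal electron weights shift the centroid toward the heavier atom
  cn <- StructureModel(data.frame(chain = "A", resno = 1:2, resid = "GLY",
                                  elety = c("CA", "SD"), elesy = c("C", "S"),
                                  x = c(0, 2), y = 0, z = 0))
  wrg <- sqrt((6 * (2 * 16 / 22)^2 + 16 * (2 * 6 / 22)^2) / 22)
  expect_equal(rgFromCoords(cn, "electron"), wrg, tolerance = 1e-12)

  sph <- makeBeadSphere(10, 5000, seed = 8)
  expect_equal(rgFromCoords(sph, "uniform"), sqrt(3 / 5) * 10, tolerance = 0.02)
})

test_that("Debye profile reproduces closed forms and the forward limit", {
  q <- seq(0, 0.5, by = 0.05)
  one <- StructureModel(data.frame(chain = "A", resno = 1L, resid = "GLY",
                                   elety = "CA", elesy = "C", x = 0, y = 0, z = 0))
  p1 <- debyeProfile(one, q)
  expect_equal(intensity(p1), rep(36, length(q)))   # f_C^2, flat

  d <- 10
  two <- StructureModel(data.frame(chain = "A", resno = 1:2, resid = "GLY",
                                   elety = "CA", elesy = "C",
                                   x = c(0, d), y = 0, z = 0))
  p2 <- debyeProfile(two, q, formFactor = "uniform")
  expected <- vapply(q, function(qq)
    if (qq == 0) 1 else (1 + sin(qq * d) / (qq * d)) / 2, numeric(1))
  expect_equal(intensity(p2) / intensity(p2)[1], expected, tolerance = 1e-12)
  expect_equal(intensity(p2)[1], 4)                 # (sum f)^2 at q -> 0

  ## binned large-n path agrees with the exact path
  sph <- makeBeadSphere(8, 700, seed = 2)
  qs <- seq(0.02, 0.4, by = 0.02)
  pe <- debyeProfile(sph, qs, formFactor = "uniform", exactPairLimit = 1e9)
  pb <- debyeProfile(sph, qs, formFactor = "uniform", exactPairLimit = 10)
  expect_equal(intensity(pb), intensity(pe), tolerance = 2e-3)
})

test_that("lattice-sphere Debye curve matches the analytic form factor", {
  m <- makeLatticeSphere(10, spacing = 1)
  n <- nAtoms(m)
  qs <- seq(0.02, 0.4, by = 0.02)
  I <- intensity(debyeProfile(m, qs, formFactor = "uniform"))
  coh <- (I - n) / ((n^2) - n)          # coherent pair part, normalized
  rel <- coh / sphereFormFactor(qs, 10) - 1
  expect_lt(max(abs(rel[qs * 10 <= 4])), 0.03)
})

test_that("Guinier fit inverts an exact Guinier curve to machine precision", {
  q <- seq(0.005, 0.1, length.out = 60)
  p <- ScatteringProfile(q, 7 * exp(-q^2 * 25^2 / 3))
  g <- guinierFit(p)
  expect_equal(radiusOfGyration(g), 25, tolerance = 1e-6)
  expect_equal(forwardIntensity(g), 7, tolerance = 1e-6)
  expect_gt(g@rSquared, 1 - 1e-9)
  ## applied window respects the dimensionless bound
  expect_lte(max(q[fitRange(g)]) * radiusOfGyration(g), 1.3 + 1e-9)
})

test_that("Guinier fit is scale-equivariant and rejects bad input", {
  q <- seq(0.005, 0.08, length.out = 40)
  I <- 2 * exp(-q^2 * 20^2 / 3)
  g1 <- guinierFit(ScatteringProfile(q, I))
  g2 <- guinierFit(ScatteringProfile(q, 1000 * I))
  expect_equal(radiusOfGyration(g1), radiusOfGyration(g2), tolerance = 1e-9)
  expect_equal(forwardIntensity(g2), 1000 * forwardIntensity(g1),
               tolerance = 1e-6)
  expect_error(guinierFit(ScatteringProfile(q, rev(I))), "non-Guinier")
  expect_error(guinierFit(ScatteringProfile(q[1:4], I[1:4])), "fit error")
})

test_that("Guinier Rg is recovered within 2% from 1% noise", {
  set.seed(17)
  q <- seq(0.004, 0.08, length.out = 50)
  I0 <- 5 * exp(-q^2 * 25^2 / 3)
  noisy <- I0 * (1 + rnorm(length(q), sd = 0.01))
  g <- guinierFit(ScatteringProfile(q, noisy, sigma = 0.01 * I0))
  expect_equal(radiusOfGyration(g), 25, tolerance = 0.02)
})

test_that("normalized Kratky peaks at (sqrt(3), 3/e) for a Guinier curve", {
  q <- seq(0.001, 0.35, by = 0.001)
  p <- ScatteringProfile(q, 5 * exp(-q^2 * 25^2 / 3))
  g <- guinierFit(p)
  k <- normalizedKratky(p, g)
  expect_equal(nrow(k), length(q))
  expect_equal(max(k$value), 3 / exp(1), tolerance = 1e-4)
  expect_equal(k$qRg[which.max(k$value)], sqrt(3), tolerance = 0.01)
  expect_lt(k$value[1], 1e-3)   # -> 0 as q -> 0 (first grid point)
})

test_that("an extended-chain curve rises monotonically to a plateau", {
  rg <- 28
  q <- seq(0.002, 0.25, by = 0.002)
  p <- ScatteringProfile(q, 10 * gaussianChainIntensity(q * rg))
  g <- guinierFit(p)
  k <- normalizedKratky(p, g)
  lowSide <- k$value[k$qRg <= 2]
  expect_true(all(diff(lowSide) > 0))          # monotonic rise
  plateau <- k$value[k$qRg > 4]
  expect_lt(diff(range(plateau)) / mean(plateau), 0.12)  # flattens out
  expect_gt(mean(plateau), 1.5)                # well above the globular peak
})

test_that("theoretical-profile fitting recovers scale and offset exactly", {
  q <- seq(0.01, 0.3, by = 0.01)
  th <- ScatteringProfile(q, 100 * exp(-q^2 * 20^2 / 3))
  exper <- ScatteringProfile(q, 3 * intensity(th) + 2, rep(1, length(q)))
  ft <- fitTheoretical(th, exper)
  expect_equal(ft$scale, 3, tolerance = 1e-9)
  expect_equal(ft$offset, 2, tolerance = 1e-9)
  expect_lt(ft$chiSquareReduced, 1e-18)
})

test_that("reduced chi-square is near 1 for noise at the stated sigma", {
  set.seed(23)
  q <- seq(0.005, 0.3, length.out = 100)
  th <- ScatteringProfile(q, 50 * exp(-q^2 * 18^2 / 3))
  sig <- 0.02 * intensity(th)
  exper <- ScatteringProfile(q, intensity(th) + rnorm(100, sd = sig), sig)
  ft <- fitTheoretical(th, exper)
  expect_equal(ft$chiSquareReduced, 1, tolerance = 0.3)
})

test_that("fitting without uncertainties warns and proceeds unweighted", {
  q <- seq(0.01, 0.2, by = 0.01)
  th <- ScatteringProfile(q, exp(-q^2 * 50))
  exper <- ScatteringProfile(q, 2 * intensity(th))
  expect_warning(ft <- fitTheoretical(th, exper), "unweighted")
  expect_equal(ft$scale, 2, tolerance = 1e-9)
})

test_that("Guinier fit of a Debye curve recovers the coordinate Rg", {
  m <- makeLatticeSphere(10, spacing = 1.1)
  rgTrue <- rgFromCoords(m, "uniform")
  q <- seq(0.002, 0.2, by = 0.002)
  p <- debyeProfile(m, q, formFactor = "uniform")
  g <- guinierFit(p, qRgMax = 0.9)
  expect_equal(radiusOfGyration(g), rgTrue, tolerance = 0.01)
})

test_that("scattering profiles round-trip through .dat text", {
  q <- seq(0.01, 0.2, by = 0.01)
  p <- ScatteringProfile(q, exp(-q^2 * 100), 0.01 * exp(-q^2 * 100))
  f <- tempfile(fileext = ".dat")
  writeProfile(p, f)
  p2 <- readProfile(f)
  expect_equal(profileQ(p2), q, tolerance = 1e-9)
  expect_equal(intensity(p2), intensity(p), tolerance = 1e-9)
  expect_equal(uncertainty(p2), uncertainty(p), tolerance = 1e-9)
  ## header/comment lines and csv separators are tolerated
  f2 <- tempfile(fileext = ".dat")
  writeLines(c("# synthetic profile", "Q I ERR",
               "0.01,1.0,0.1", "0.02,0.9,0.1"), f2)
  p3 <- readProfile(f2)
  expect_equal(length(profileQ(p3)), 2L)
  expect_equal(uncertainty(p3), c(0.1, 0.1))
})
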