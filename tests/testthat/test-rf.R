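test_that("scatterer seeding is reproducible with Poisson-consistent counts", {
  spec <- psfSpec()
  s1 <- seedScatterers(seed = 3, spec = spec)
  s2 <- seedScatterers(seed = 3, spec = spec)
  expect_identical(s1@x, s2@x)
  expect_identical(s1@amplitude, s2@amplitude)
  lambda <- spec@soundSpeed / spec@f0
  expected <- 36 * (2.5 * 5 / 1e4) / lambda^2
  expect_lt(abs(length(s1@x) - expected), 4 * sqrt(expected))
  expect_equal(length(seedScatterers(c(0, 0, 0, 5), spec = spec)@x), 0)
  expect_error(seedScatterers(density = 0), "positive")
})

test_that("PSF kernels match the stated spectral and lateral widths", {
  psf <- makePSF()
  n <- 8192
  fs <- 40e6
  amp <- Mod(fft(c(psf$axial, rep(0, n - length(psf$axial)))))[1:(n / 2)]
  f <- (seq_len(n / 2) - 1) / n * fs
  expect_lt(abs(f[which.max(amp)] - 5e6), 5e4)  # spectrum peaks at f0
  # half-power (power spectrum) full width = 2.5 MHz
  pw <- amp^2 / max(amp^2)
  above <- range(f[pw >= 0.5])
  expect_lt(abs(diff(above) / 2.5e6 - 1), 0.02)
  # lateral Gaussian FWHM 0.5 mm (interpolated on the beam lattice)
  bp <- imagingGeometry()$beamPitch
  xl <- (seq_along(psf$lateral) - (length(psf$lateral) + 1) / 2) * bp
  half <- approx(psf$lateral[xl >= 0], xl[xl >= 0], xout = 0.5)$y
  expect_lt(abs(2 * half - 0.5e-3), 0.01e-3)
})

test_that("a point scatterer lands at the pulse-echo depth sample", {
  spec <- psfSpec()
  geom <- imagingGeometry(spec)
  psf <- makePSF(spec, geom$beamPitch)
  set <- new("ScattererSet", x = 1.25, y = 2.5, amplitude = 1, seed = 1L)
  fr <- synthesizeFrame(set, psf, geom)
  env <- USWIcrack:::.envelope(fr)
  peak <- arrayInd(which.max(env), dim(env))
  expect_lt(abs(peak[1] - 2.5e-2 / geom$axialPitch), 1.6)
  expect_equal(peak[2], which.min(abs((seq_len(256) - 0.5) *
                                        geom$beamPitch - 1.25e-2)))
})

test_that("frame synthesis is linear and handles empty sets", {
  fx <- cachedSpeckleFrame()
  doubled <- new("ScattererSet", x = fx$set@x, y = fx$set@y,
                 amplitude = 2 * fx$set@amplitude, seed = fx$set@seed)
  expect_equal(synthesizeFrame(doubled, fx$psf, fx$geom), 2 * fx$rf)
  empty <- new("ScattererSet", x = numeric(0), y = numeric(0),
               amplitude = numeric(0), seed = 1L)
  expect_true(all(synthesizeFrame(empty, fx$psf, fx$geom) == 0))
})

test_that("scatterer displacement follows the interpolated field", {
  roi <- cachedWave("none")
  set <- seedScatterers(c(0.2, 2.3, 0.2, 4.8), seed = 5)
  expect_equal(displaceScatterers(set, roi, 1)@y, set@y)  # u = 0 at t = 0
  # uniform shift
  uni <- roi
  uni@u[, , 2] <- 1e-5
  d <- displaceScatterers(set, uni, 2)
  expect_equal(d@y, set@y + 1e-3, tolerance = 1e-12)
  # linear ramp in x: shift proportional to lateral position
  ramp <- roi
  for (k in seq_along(roi@x)) ramp@u[k, , 3] <- 1e-5 * roi@x[k]
  d2 <- displaceScatterers(set, ramp, 3)
  expect_equal(d2@y - set@y, 1e-3 * set@x, tolerance = 1e-3)
  expect_error(displaceScatterers(set, roi, 200), "out of range")
})

test_that("full-density speckle has Rayleigh envelope statistics", {
  fx <- cachedSpeckleFrame()
  snr <- envelopeSNR(fx$rf)
  expect_gt(snr, 1.7)
  expect_lt(snr, 2.4)
  env <- USWIcrack:::.envelope(fx$rf)
  sub <- as.vector(env[seq(60, 1140, 8), seq(8, 152, 4)])
  sigma <- sqrt(mean(sub^2) / 2)
  ks <- stats::ks.test(sub, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
  expect_error(envelopeSNR(matrix(0, 64, 8)), "zero")
})
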