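test_that("demodulation preserves envelope and encodes delay as phase", {
  fs <- 40e6; f0 <- 5e6
  n <- 512
  t <- (seq_len(n) - 1) / fs
  rf <- matrix(cos(2 * pi * f0 * t), n, 4)
  stack <- new("RFStack", frames = array(rf, c(n, 4, 1)), fs = fs, f0 = f0,
               soundSpeed = 1540, axialPitch = 1540 / (2 * fs),
               beamPitch = 1e-4, times = 0)
  iq <- demodulate(stack)@frames[, , 1]
  core <- 50:462
  expect_lt(sd(Mod(iq[core, 1])), 0.01)            # constant magnitude
  expect_lt(sd(Arg(iq[core, 1])), 0.01)            # constant phase
  # one-sample delay -> phase shift of -2 pi f0 / fs
  rf2 <- matrix(cos(2 * pi * f0 * (t - 1 / fs)), n, 4)
  stack@frames <- array(rf2, c(n, 4, 1))
  iq2 <- demodulate(stack)@frames[, , 1]
  dphi <- Arg(mean(iq2[core, 1] * Conj(iq[core, 1])))
  expect_lt(abs(dphi - (-2 * pi * f0 / fs)), 0.01)
  stack@frames <- array(0, c(n, 4, 1))
  expect_true(all(demodulate(stack)@frames == 0))
  expect_error(demodulate(stack, cutoff = 30e6), "cutoff")
})

test_that("speckle size estimates match the imaging point spread function", {
  fx <- cachedSpeckleFrame()
  ss <- estimateSpeckleSize(fx$iq, fx$geom$axialPitch, fx$geom$beamPitch)
  expect_lt(abs(ss["axial"] / 0.270e-3 - 1), 0.15)
  expect_lt(abs(ss["lateral"] / 0.586e-3 - 1), 0.15)
  # white noise decorrelates within one lattice pitch
  set.seed(9)
  wn <- matrix(complex(real = rnorm(256 * 64), imaginary = rnorm(256 * 64)),
               256, 64)
  ssw <- estimateSpeckleSize(wn, fx$geom$axialPitch, fx$geom$beamPitch)
  expect_lte(ssw["axial"], fx$geom$axialPitch)
  expect_lte(ssw["lateral"], fx$geom$beamPitch)
  expect_error(estimateSpeckleSize(matrix(1 + 0i, 64, 8), 1, 1),
               "degenerate")
})

test_that("correlation volumes peak at the true lag", {
  fx <- cachedSpeckleFrame()
  spec <- trackingSpec(gridDx = 1e-3, gridDy = 1e-3)
  vol <- correlatePair(fx$iq, fx$iq, spec, fx$geom$axialPitch,
                       fx$geom$beamPitch)
  est <- peakDisplacement(vol, 5e6, 1540)
  expect_true(all(abs(est$dispAx) < 1e-9, na.rm = TRUE))
  expect_true(all(est$peakMag > 0.999, na.rm = TRUE))
  # integer two-sample axial shift of the RF (demodulated afterwards so
  # the carrier phase is consistent with the shift)
  n <- nrow(fx$rf)
  rfShift <- rbind(fx$rf[3:n, ], matrix(0, 2, ncol(fx$rf)))
  iqShift <- demodFrame(rfShift)
  vol2 <- correlatePair(fx$iq, iqShift, spec, fx$geom$axialPitch,
                        fx$geom$beamPitch)
  est2 <- peakDisplacement(vol2, 5e6, 1540)
  expect_equal(stats::median(est2$dispAx, na.rm = TRUE),
               -2 * fx$geom$axialPitch,
               tolerance = 0.05)
  # independent noise frames decorrelate
  set.seed(4)
  nA <- matrix(complex(real = rnorm(1200 * 160),
                       imaginary = rnorm(1200 * 160)), 1200, 160)
  nB <- matrix(complex(real = rnorm(1200 * 160),
                       imaginary = rnorm(1200 * 160)), 1200, 160)
  spec2 <- trackingSpec(kernelAxial = 0.35e-3, gridDx = 2e-3, gridDy = 2e-3)
  voln <- correlatePair(nA, nB, spec2, fx$geom$axialPitch,
                        fx$geom$beamPitch)
  estn <- peakDisplacement(voln, 5e6, 1540)
  expect_lt(stats::median(estn$peakMag, na.rm = TRUE), 0.5)
})

test_that("the correlation filter is a unit-sum separable smoother", {
  fx <- cachedSpeckleFrame()
  spec <- trackingSpec(gridDx = 0.25e-3, gridDy = 0.25e-3,
                       searchAxial = 0.1e-3, searchLateral = 0.2e-3)
  vol <- correlatePair(fx$iq[1:400, ], fx$iq[1:400, ], spec,
                       fx$geom$axialPitch, fx$geom$beamPitch)
  d <- dim(vol$corr)
  # constant field stays constant
  volc <- vol
  volc$corr[] <- 0.7 + 0.1i
  sm <- filterCorrelations(volc, spec)
  expect_equal(sm$corr, volc$corr, tolerance = 1e-12)
  # impulse spreads but keeps its mass
  voli <- vol
  voli$corr[] <- 0i
  voli$corr[round(d[1] / 2), round(d[2] / 2), 1, 1] <- 1
  smi <- filterCorrelations(voli, spec)
  expect_equal(sum(Re(smi$corr[, , 1, 1])), 1, tolerance = 1e-9)
  expect_lt(max(Re(smi$corr[, , 1, 1])), 1)
  # window wider than the grid is refused
  tiny <- vol
  tiny$corr <- vol$corr[1:2, 1:2, , , drop = FALSE]
  tiny$valid <- vol$valid[1:2, 1:2, , , drop = FALSE]
  expect_error(filterCorrelations(tiny, trackingSpec(filterLateral = 5e-3,
                                                     gridDx = 0.25e-3,
                                                     gridDy = 0.25e-3)),
               "larger")
})

test_that("known sub-sample shifts are recovered to a fraction of a sample", {
  deltas <- c(5e-6, 12e-6, 19e-6, 28.9e-6, 45e-6, 70e-6)
  errs <- vapply(deltas, function(d) {
    fx <- makeFixture("shifted_speckle",
                      list(delta = d, nAxial = 600L, nBeams = 96L,
                           lateralExtent = 0.9375), seed = 11)
    a <- demodFrame(fx$rfA); b <- demodFrame(fx$rfB)
    v <- correlatePair(a, b, trackingSpec(gridDx = 1e-3, gridDy = 1e-3),
                       fx$geom$axialPitch, fx$geom$beamPitch)
    e <- peakDisplacement(v, 5e6, 1540)
    mean(abs(e$dispAx - d), na.rm = TRUE)
  }, numeric(1))
  lambda <- 1540 / 5e6
  expect_lt(mean(errs), lambda / 20)
  # the 28.9 um (1.5-sample) case individually within 3 um
  expect_lt(errs[4], 3e-6)
  # lambda/16 ~ 19 um within 10%
  expect_lt(errs[3], 0.1 * 19e-6)
})

test_that("accumulation is a cumulative sum on fixed grid points", {
  one <- matrix(1e-6, 5, 4)
  dm <- accumulateDisplacements(rep(list(one), 105), xCm = 1:4, yCm = 1:5,
                                times = seq(0, 21e-3, by = 0.2e-3))
  expect_equal(dim(dm@u), c(4, 5, 106))
  expect_equal(max(dm@u[, , 106]), 105e-6)
  alt <- accumulateDisplacements(list(one, -one, one),
                                 xCm = 1:4, yCm = 1:5,
                                 times = (0:3) * 2e-4)
  expect_true(all(dm@u[, , 1] == 0))
  expect_true(all(alt@u[, , c(1, 3)] == 0) && all(alt@u[, , 2] == 1e-6))
  expect_error(accumulateDisplacements(list(one, matrix(0, 3, 3)),
                                       1:4, 1:5, (0:2) * 2e-4),
               "inconsistent")
})

test_that("accumulation cancels shared-frame noise (sub-linear error growth)", {
  fx <- makeFixture("shifted_speckle",
                    list(delta = 0, nAxial = 500L, nBeams = 64L,
                         lateralExtent = 0.625), seed = 21)
  set.seed(77)
  sdn <- 0.05 * sd(fx$rfA)
  nFrames <- 6
  frames <- lapply(seq_len(nFrames), function(k)
    demodFrame(fx$rfA + matrix(rnorm(length(fx$rfA), sd = sdn),
                               nrow(fx$rfA))))
  spec <- trackingSpec(gridDx = 1e-3, gridDy = 1e-3,
                       searchAxial = 0.1e-3, searchLateral = 0.2e-3)
  pairErr <- function(a, b) {
    v <- correlatePair(a, b, spec, fx$geom$axialPitch, fx$geom$beamPitch)
    peakDisplacement(v, 5e6, 1540)$dispAx
  }
  steps <- lapply(seq_len(nFrames - 1), function(k)
    pairErr(frames[[k]], frames[[k + 1]]))
  acc <- Reduce(`+`, steps)
  varAcc <- stats::var(as.vector(acc), na.rm = TRUE)
  varOne <- mean(vapply(steps, function(s)
    stats::var(as.vector(s), na.rm = TRUE), numeric(1)))
  # a random walk would give varAcc ~ 5 * varOne; shared frames cancel
  expect_lt(varAcc, (nFrames - 1) * varOne)
})
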