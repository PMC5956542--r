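# Reference right-edge positions ("given" columns) at the reported depths,
# used as the geometry oracle for all three cracks.
given <- list(
  straight = cbind(depth = c(0.208, 0.291, 0.416, 0.917, 1.291, 1.709,
                             2.083, 2.500, 2.917),
                   x = c(1.464, 1.441, 1.408, 1.274, 1.173, 1.062,
                         0.961, 0.850, 0.738)),
  curved = cbind(depth = c(0.208, 0.291, 0.416, 0.917, 1.291, 1.709),
                 x = c(1.515, 1.510, 1.500, 1.425, 1.328, 1.183)),
  slim = cbind(depth = c(0.208, 0.291, 0.416),
               x = c(1.464, 1.441, 1.408)))

test_that("analytic right edge reproduces every printed reference position", {
  for (shape in names(given)) {
    crack <- crackSpec(shape)
    tab <- given[[shape]]
    expect_true(all(abs(rightEdgeX(crack, tab[, "depth"]) - tab[, "x"])
                    <= 0.002),
                label = paste(shape, "edge within printed rounding"))
  }
})

test_that("edge functions honour top positions, sharing and range checks", {
  st <- crackSpec("straight"); sl <- crackSpec("slim"); cu <- crackSpec("curved")
  expect_equal(rightEdgeX(st, 0), 1.519)
  expect_equal(leftEdgeX(st, 0), 1.354)
  expect_equal(leftEdgeX(cu, 0), -3.146 + 4.5)
  expect_equal(leftEdgeX(sl, 0), 1.467)
  # the slim crack shares the straight crack's right edge
  expect_equal(rightEdgeX(sl, 0.291), rightEdgeX(st, 0.291))
  expect_error(rightEdgeX(st, 3.3), "outside")
  expect_error(rightEdgeX(sl, -0.1), "outside")
  expect_error(rightEdgeX(crackSpec("none"), 0), "homogeneous")
})

test_that("crack thickness bookkeeping is consistent", {
  st <- crackSpec("straight")
  expect_equal(horizontalThickness(st), 0.165)
  expect_equal(horizontalThickness(crackSpec("slim")), 0.052)
  expect_equal(horizontalThickness(crackSpec("curved")), 0.165)
  # perpendicular thickness: 1.6 mm straight, 0.5 mm slim
  expect_equal(horizontalThickness(st) * cos(15 * pi / 180), 0.160,
               tolerance = 1e-2 / 0.16)
  expect_lt(abs(horizontalThickness(st) * cos(15 * pi / 180) - 0.160),
            0.001)
  expect_lt(abs(horizontalThickness(crackSpec("slim")) * cos(15 * pi / 180)
                - 0.050), 0.001)
})

test_that("material constants give liver-like shear properties", {
  lv <- liverMaterial()
  expect_equal(shearModulus(lv), 6000 / (2 * 1.499))
  # nearly incompressible: c within 0.5% of sqrt(E / (3 rho))
  expect_lt(abs(shearSpeed(lv) / sqrt(6000 / (3 * 1200)) - 1), 0.005)
  expect_error(materialSpec(1000, 0.6, 1000), "Poisson")
})

test_that("rasterized material maps assign the right material per cell", {
  mf0 <- buildMaterialField(domainSpec(), crackSpec("none"))
  expect_equal(dim(mf0@mu), c(400, 400))
  expect_true(all(abs(mf0@mu - 2001.3) < 0.1))
  expect_false(any(mf0@mask))

  mf <- buildMaterialField(domainSpec(), crackSpec("straight"))
  at <- function(x, y) mf@mask[which.min(abs(mf@x - x)),
                               which.min(abs(mf@y - y))]
  expect_true(at(1.45, 0.10))   # inside the band near the top
  expect_false(at(0.5, 2.0))    # far from the crack
  expect_false(at(1.45, 3.5))   # below the crack tip
  expect_equal(unique(mf@density[mf@mask]), 1060)
  expect_equal(unique(mf@density[!mf@mask]), 1200)
  # band thickness across a row matches the horizontal gap within one cell
  j <- which.min(abs(mf@y - 1.0))
  expect_equal(sum(mf@mask[, j]) * mf@resolution, 0.165,
               tolerance = mf@resolution / 0.165)
  expect_error(buildMaterialField(domainSpec(), crackSpec("slim"),
                                  resolution = 0.05), "resolution")
})

test_that("crack mask area converges to the analytic band area", {
  crack <- crackSpec("straight")
  areaTrue <- 0.165 * 3.2
  areaAt <- function(res) {
    mf <- buildMaterialField(domainSpec(), crack, resolution = res)
    sum(mf@mask) * res^2
  }
  errCoarse <- abs(areaAt(0.016) - areaTrue) / areaTrue
  errFine <- abs(areaAt(0.008) - areaTrue) / areaTrue
  expect_lt(errFine, errCoarse / 2)
})

test_that("ground-truth tables are monotone and propagate range errors", {
  crack <- crackSpec("straight")
  tab <- groundTruthTable(crack, c(2.5, 0.5, 1.5))
  expect_equal(tab$depth, c(0.5, 1.5, 2.5))
  expect_true(all(diff(tab$given_x) < 0))
  expect_equal(nrow(groundTruthTable(crack, numeric(0))), 0)
  expect_error(groundTruthTable(crack, c(1, 4)), "outside")
  cu <- groundTruthTable(crackSpec("curved"), 0.416)
  expect_lt(abs(cu$given_x - 1.500), 0.002)
})

test_that("domain spec validates ROI alignment", {
  expect_error(domainSpec(roiX = c(0, 2.51)), "integer|inside")
  d <- domainSpec()
  expect_equal(diff(d@roiX) / d@dx, 200)
  expect_equal(diff(d@roiY) / d@dy, 400)
})
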