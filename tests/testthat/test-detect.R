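stepMap <- function(nx = 60, ny = 80, jcol = 30) {
  v <- matrix(0, nx, ny)
  v[seq_len(jcol), ] <- 1
  new("ReflectedAmplitudeMap", values = v,
      x = (seq_len(nx) - 0.5) * 0.0125, y = (seq_len(ny) - 0.5) * 0.0125)
}

test_that("Sobel edge maps respond to steps and ignore flats", {
  em <- detectEdges(stepMap(), borderPx = 0)
  hit <- which(em@mask, arr.ind = TRUE)
  expect_true(all(hit[, 1] %in% c(30, 31)))
  expect_gt(nrow(hit), 0)
  flat <- stepMap()
  flat@values[] <- 0.7
  expect_false(any(detectEdges(flat)@mask))
  expect_error(detectEdges(new("ReflectedAmplitudeMap",
                               values = matrix(c(1, NaN, 1, 1), 2, 2),
                               x = 1:2, y = 1:2)))
})

test_that("the leftmost long component is selected as the crack edge", {
  em <- makeFixture("two_line_mask", list(x1 = 1.0, x2 = 1.5))
  ct <- extractContour(em)
  expect_true(all(abs(ct@points$x - 1.0) < 0.0125))
  expect_equal(nrow(ct@points), length(unique(ct@points$y)))
  expect_false(is.unsorted(ct@points$y))
  # a single line is returned as-is
  one <- makeFixture("two_line_mask", list(x1 = 1.2, x2 = 1.2))
  expect_true(all(abs(extractContour(one)@points$x - 1.2) < 0.0125))
  # empty mask and too-short components raise the no-crack condition
  empty <- one
  empty@mask[] <- FALSE
  expect_error(extractContour(empty), class = "uswiNoCrackError")
  shorty <- makeFixture("two_line_mask",
                        list(x1 = 1.0, x2 = 1.5, rows = 10:20))
  expect_error(extractContour(shorty, minExtent = 0.3),
               class = "uswiNoCrackError")
})

test_that("detection reports mirror the reference error arithmetic", {
  ct <- new("CrackContour",
            points = data.frame(x = c(1.431, 1.0), y = c(0.208, 3.0)),
            detectedDepth = 3.09, provenance = "direct")
  truth <- data.frame(depth = c(0.208, 3.1), given_x = c(1.464, 0.9))
  rep <- measureContour(ct, truth, givenDepth = 3.2)
  expect_equal(rep@table$relative_error[1], -2.25, tolerance = 0.005)
  expect_true(is.na(rep@table$detected_x[2]))  # outside contour: dash row
  expect_equal(rep@detectedDepth, 3.09)
  expect_equal(rep@depthRatio, 3.09 / 3.2, tolerance = 1e-9)
  same <- new("CrackContour",
              points = data.frame(x = c(1.464, 1.2), y = c(0.208, 2)),
              detectedDepth = 1.8, provenance = "direct")
  rep2 <- measureContour(same, truth[1, ], 3.2)
  expect_equal(rep2@table$relative_error[1], 0)
})

test_that("a contour's vertical extent is its detected depth", {
  pts <- data.frame(y = seq(0.05, 3.14, by = 0.01))
  pts$x <- 1.5 - 0.27 * pts$y
  mask <- matrix(FALSE, 220, 420)
  x <- (seq_len(220) - 0.5) * 0.0125
  y <- (seq_len(420) - 0.5) * 0.0125
  # two pixels wide, like a real Sobel response
  for (k in seq_len(nrow(pts))) {
    i <- which.min(abs(x - pts$x[k]))
    mask[c(i, i + 1), which.min(abs(y - pts$y[k]))] <- TRUE
  }
  em <- new("EdgeMap", gradient = mask * 1, mask = mask, threshold = 0.5,
            x = x, y = y)
  ct <- extractContour(em)
  # grid quantization permits up to one pixel (0.0125 cm) of slack
  expect_equal(ct@detectedDepth, 3.09, tolerance = 0.013 / 3.09)
})
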