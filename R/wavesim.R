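#' @include phantom.R
NULL

#' Excitation (push rod) specification
#'
#' A thin vertical rod on the centre plane of the medium oscillates
#' vertically for one cycle of a low-frequency harmonic vibration,
#' launching plane shear waves that travel laterally to either side. After
#' the push window the rod cells revert to ordinary elastic cells.
#'
#' @param rodHeight,rodWidth rod extent (cm); the rod is centred vertically.
#' @param frequency push frequency (Hz).
#' @param cycles number of push cycles.
#' @param amplitude peak rod displacement (m).
#' @return a named list used by \code{\link{simulateWaveField}}.
#' @export
excitationSpec <- function(rodHeight = 3.8, rodWidth = 0.05,
                           frequency = 100, cycles = 1,
                           amplitude = 100e-6) {
  stopifnot(amplitude >= 0, frequency > 0, cycles > 0)
  list(rodHeight = rodHeight, rodWidth = rodWidth, frequency = frequency,
       cycles = cycles, amplitude = amplitude)
}

#' Time-base specification
#'
#' @param tEnd end of the simulated interval (s).
#' @param frameInterval frame spacing (s); 0.2 ms gives the 5000 frames/s
#'   acquisition and 106 frames over 21 ms.
#' @param cflSafety internal step as a fraction of the CFL bound.
#' @param step optional explicit internal step (s); must satisfy the CFL
#'   bound for the fastest cell.
#' @return a named list.
#' @export
timeSpec <- function(tEnd = 21e-3, frameInterval = 0.2e-3, cflSafety = 0.5,
                     step = NULL) {
  nf <- tEnd / frameInterval + 1
  stopifnot(abs(nf - round(nf)) < 1e-9)
  list(tEnd = tEnd, frameInterval = frameInterval, cflSafety = cflSafety,
       step = step, nFrames = as.integer(round(nf)))
}

#' Simulate shear-wave propagation in the phantom
#'
#' Solves the heterogeneous scalar shear-wave equation
#' \eqn{\rho \, u_{tt} = \nabla \cdot (\mu \nabla u)} for the axial
#' displacement with an explicit leapfrog finite-difference scheme
#' (edge stiffness by harmonic averaging, so the nearly stress-free crack
#' filler transmits essentially no shear traction). Boundary conditions:
#' traction-free top surface, fixed bottom, zero normal derivative at the
#' sides. The internal step defaults to \code{cflSafety} times the CFL bound
#' of the fastest cell and subdivides the frame interval exactly.
#'
#' @param material a \linkS4class{MaterialField}.
#' @param excitation from \code{\link{excitationSpec}}.
#' @param time from \code{\link{timeSpec}}.
#' @return a \linkS4class{WaveField} over the full domain.
#' @export
simulateWaveField <- function(material, excitation = excitationSpec(),
                              time = timeSpec()) {
  stopifnot(is(material, "MaterialField"))
  dxm <- material@resolution / 100
  cmax <- sqrt(max(material@mu / material@density))
  dtmax <- dxm / (cmax * sqrt(2))
  if (!is.null(time$step)) {
    if (time$step > dtmax)
      stop("internal step violates the CFL bound; need <= ",
           signif(dtmax, 3), " s")
    nsub <- ceiling(time$frameInterval / time$step)
  } else {
    nsub <- ceiling(time$frameInterval / (time$cflSafety * dtmax))
  }
  height <- max(material@y) + material@resolution / 2
  xc <- (min(material@x) + max(material@x)) / 2
  rod <- outer(abs(material@x - xc) <= excitation$rodWidth / 2 + 1e-12,
               abs(material@y - height / 2) <= excitation$rodHeight / 2 + 1e-12,
               "&")
  u <- fd_wave_solve_cpp(material@mu, material@density, dxm,
                         time$frameInterval, time$nFrames, as.integer(nsub),
                         which(rod) - 1L, excitation$amplitude,
                         excitation$frequency,
                         excitation$cycles / excitation$frequency)
  new("WaveField", u = u, x = material@x, y = material@y,
      times = seq(0, time$tEnd, by = time$frameInterval))
}

#' Extract the imaging region of interest
#'
#' @param field a \linkS4class{WaveField} over the full domain.
#' @param domain a \linkS4class{DomainSpec}; the ROI grid must coincide with
#'   the solved grid.
#' @return a \linkS4class{WaveField} restricted to the ROI (200 x 400 x 106
#'   at the default spacing).
#' @export
exportROI <- function(field, domain = domainSpec()) {
  stopifnot(is(field, "WaveField"), is(domain, "DomainSpec"))
  dx <- if (length(field@x) > 1) field@x[2] - field@x[1] else domain@dx
  if (abs(dx - domain@dx) > 1e-9)
    stop("ROI grid spacing does not match the solved grid")
  ix <- which(field@x > domain@roiX[1] & field@x < domain@roiX[2])
  iy <- which(field@y > domain@roiY[1] & field@y < domain@roiY[2])
  nxw <- round(diff(domain@roiX) / domain@dx)
  nyw <- round(diff(domain@roiY) / domain@dy)
  if (length(ix) != nxw || length(iy) != nyw)
    stop("ROI does not align with the solved grid")
  new("WaveField", u = field@u[ix, iy, , drop = FALSE], x = field@x[ix],
      y = field@y[iy], times = field@times)
}

#' Estimate the propagation speed of the wave front
#'
#' Fits the time of peak |u| against lateral position along one depth row
#' and returns the inverse slope. Requires a crack-free lateral range.
#'
#' @param field a \linkS4class{WaveField}.
#' @param depthRow depth of the row to use (cm).
#' @param xRange lateral interval (cm) over which to fit.
#' @return speed in m/s.
#' @export
estimateFrontSpeed <- function(field, depthRow = 2.5,
                               xRange = c(0.5, 2.0)) {
  stopifnot(is(field, "WaveField"))
  j <- which.min(abs(field@y - depthRow))
  ix <- which(field@x >= xRange[1] & field@x <= xRange[2])
  if (length(ix) < 5) stop("too few columns in xRange")
  # track the positive (leading-lobe) peak: for a one-cycle push the
  # positive and negative lobes have near-equal |u|, which makes the |u|
  # argmax alternate between them
  tpk <- field@times[apply(field@u[ix, j, ], 1, which.max)]
  xm <- field@x[ix] / 100
  fit <- lm(tpk ~ xm)
  slope <- coef(fit)[2]
  r2 <- summary(fit)$r.squared
  if (!is.finite(slope) || slope == 0 || is.na(r2) || r2 < 0.9)
    stop("arrival times are not monotone across the range; cannot fit a speed")
  unname(1 / abs(slope))
}

#' Estimate the shear wavelength from a snapshot
#'
#' For a one-cycle push the travelling pulse has one positive and one
#' negative lobe half a wavelength apart; the wavelength is returned as
#' twice the distance between the lobe extrema along a depth row.
#'
#' @param field a \linkS4class{WaveField}.
#' @param frameTime snapshot time (s); pick one after the push has fully
#'   detached but before the front reaches the far boundary.
#' @param depthRow depth of the row (cm).
#' @return wavelength in cm.
#' @export
estimateWavelength <- function(field, frameTime = 12e-3, depthRow = 2.5) {
  stopifnot(is(field, "WaveField"))
  k <- which.min(abs(field@times - frameTime))
  j <- which.min(abs(field@y - depthRow))
  prof <- field@u[, j, k]
  2 * abs(field@x[which.max(prof)] - field@x[which.min(prof)])
}
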