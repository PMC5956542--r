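#' @include wavesim.R
NULL

#' PSF specification constructor
#'
#' @param f0 transducer centre frequency (Hz).
#' @param fractionalBandwidth half-power relative bandwidth of the axial
#'   Gaussian envelope (0.5 means the power spectrum's half-power width is
#'   half the centre frequency).
#' @param lateralFWHM lateral Gaussian full width at half maximum (m).
#' @param fs RF sampling frequency (Hz).
#' @param soundSpeed compressional speed used for echo timing (m/s).
#' @return a \linkS4class{PSFSpec}.
#' @export
psfSpec <- function(f0 = 5e6, fractionalBandwidth = 0.5,
                    lateralFWHM = 0.5e-3, fs = 40e6, soundSpeed = 1540) {
  new("PSFSpec", f0 = f0, fractionalBandwidth = fractionalBandwidth,
      lateralFWHM = lateralFWHM, fs = fs, soundSpeed = soundSpeed)
}

#' Imaging lattice geometry
#'
#' @param spec a \linkS4class{PSFSpec}.
#' @param nAxial,nBeams RF samples per A-line and beam count.
#' @param lateralExtent lateral image width (cm).
#' @return list with pitches (m) and extents; axial pitch is
#'   \code{soundSpeed/(2 fs)} (19.25 um at the defaults, so 2596 samples
#'   span 5.0 cm).
#' @export
imagingGeometry <- function(spec = psfSpec(), nAxial = 2596L,
                            nBeams = 256L, lateralExtent = 2.5) {
  list(nAxial = as.integer(nAxial), nBeams = as.integer(nBeams),
       axialPitch = spec@soundSpeed / (2 * spec@fs),
       beamPitch = lateralExtent / 100 / nBeams,
       lateralExtent = lateralExtent)
}

#' Build the separable PSF kernels
#'
#' Axial component: carrier \code{cos(2 pi f0 t)} under a Gaussian envelope
#' whose power spectrum has half-power full width
#' \code{fractionalBandwidth * f0}; lateral component: Gaussian with the
#' stated FWHM, sampled at the beam pitch. Kernels are truncated where the
#' envelope falls below 1e-3 of its peak.
#'
#' @param spec a \linkS4class{PSFSpec}.
#' @param beamPitch lateral sample spacing (m).
#' @return list with \code{axial}, \code{lateral} kernel vectors and the
#'   envelope sigma values (\code{sigmaT} s, \code{sigmaX} m).
#' @export
makePSF <- function(spec = psfSpec(),
                    beamPitch = imagingGeometry(spec)$beamPitch) {
  validObject(spec)
  sigmaT <- sqrt(log(2)) / (pi * spec@fractionalBandwidth * spec@f0)
  reach <- sqrt(2 * log(1e3))
  na <- ceiling(reach * sigmaT * spec@fs)
  t <- (-na:na) / spec@fs
  axial <- cos(2 * pi * spec@f0 * t) * exp(-t^2 / (2 * sigmaT^2))
  sigmaX <- spec@lateralFWHM / (2 * sqrt(2 * log(2)))
  nl <- ceiling(reach * sigmaX / beamPitch)
  xl <- (-nl:nl) * beamPitch
  lateral <- exp(-xl^2 / (2 * sigmaX^2))
  list(axial = axial, lateral = lateral, sigmaT = sigmaT, sigmaX = sigmaX,
       spec = spec, beamPitch = beamPitch)
}

#' Draw the random scatterer field
#'
#' \code{density} is the linear scatterer density per ultrasound wavelength
#' (\code{soundSpeed/f0}, 0.308 mm at the defaults) along each axis, so the
#' expected count is \code{density^2} per squared wavelength of area. The
#' default of six per wavelength puts roughly 36 scatterers in each
#' resolution cell, which yields fully developed (Rayleigh) speckle; the
#' count is Poisson, positions uniform over the region, amplitudes i.i.d.
#' standard normal.
#'
#' @param region \code{c(x0, x1, y0, y1)} in cm.
#' @param density scatterers per wavelength (per axis).
#' @param seed RNG seed.
#' @param spec a \linkS4class{PSFSpec} (sets the wavelength).
#' @return a \linkS4class{ScattererSet}.
#' @export
seedScatterers <- function(region = c(0, 2.5, 0, 5), density = 6,
                           seed = 1L, spec = psfSpec()) {
  if (density <= 0) stop("scatterer density must be positive")
  areaM2 <- (region[2] - region[1]) * (region[4] - region[3]) / 1e4
  lambda <- spec@soundSpeed / spec@f0
  expected <- density^2 * areaM2 / lambda^2
  set.seed(seed)
  n <- if (expected > 0) rpois(1, expected) else 0L
  new("ScattererSet",
      x = runif(n, region[1], region[2]),
      y = runif(n, region[3], region[4]),
      amplitude = rnorm(n), seed = as.integer(seed))
}

#' Displace scatterers by a wave-field frame
#'
#' Adds the axial displacement, bilinearly interpolated from the grid at the
#' reference positions, to the reference depth coordinates. Lateral
#' positions are unchanged (the displacement field is axial).
#'
#' @param set a \linkS4class{ScattererSet}.
#' @param wave a \linkS4class{WaveField} (typically the exported ROI).
#' @param frameIndex frame to apply (1-based).
#' @return a displaced \linkS4class{ScattererSet}.
#' @export
displaceScatterers <- function(set, wave, frameIndex) {
  stopifnot(is(set, "ScattererSet"), is(wave, "WaveField"))
  if (frameIndex < 1 || frameIndex > length(wave@times))
    stop("frame index out of range")
  if (length(set@x) == 0) return(set)
  dx <- wave@x[2] - wave@x[1]
  dy <- wave@y[2] - wave@y[1]
  xi <- (set@x - wave@x[1]) / dx + 1
  yi <- (set@y - wave@y[1]) / dy + 1
  if (any(xi < 0.5 | xi > length(wave@x) + 0.5 |
          yi < 0.5 | yi > length(wave@y) + 0.5))
    warning("scatterers outside the wave grid were clamped to its edge")
  u <- as.vector(interp2_cpp(wave@u[, , frameIndex], xi, yi))
  new("ScattererSet", x = set@x, y = set@y + u * 100,
      amplitude = set@amplitude, seed = set@seed)
}

#' Synthesize one RF frame
#'
#' Deposits the scatterers onto the fine axial-sample by beam lattice with
#' amplitude-weighted bilinear splatting, then convolves with the separable
#' PSF. Axial sample k is centred at depth \code{(k - 0.5) * axialPitch},
#' beam b at lateral position \code{(b - 0.5) * beamPitch}.
#'
#' @param set a \linkS4class{ScattererSet} (deformed or reference).
#' @param psf from \code{\link{makePSF}}.
#' @param geom from \code{\link{imagingGeometry}}.
#' @return numeric matrix \code{(nAxial, nBeams)}.
#' @export
synthesizeFrame <- function(set, psf, geom = imagingGeometry(psf$spec)) {
  stopifnot(is(set, "ScattererSet"))
  if (length(set@x) == 0)
    return(matrix(0, geom$nAxial, geom$nBeams))
  axIdx <- set@y / 100 / geom$axialPitch + 0.5
  bmIdx <- set@x / 100 / geom$beamPitch + 0.5
  raw <- splat_cpp(axIdx, bmIdx, set@amplitude, geom$nAxial, geom$nBeams)
  conv_sep_cpp(raw, psf$axial, psf$lateral)
}

#' Synthesize the full RF stack for a wave movie
#'
#' @param wave ROI \linkS4class{WaveField}.
#' @param set reference \linkS4class{ScattererSet}.
#' @param psf from \code{\link{makePSF}}.
#' @param geom from \code{\link{imagingGeometry}}.
#' @return an \linkS4class{RFStack} with one frame per wave frame.
#' @export
synthesizeRFStack <- function(wave, set, psf,
                              geom = imagingGeometry(psf$spec)) {
  nt <- length(wave@times)
  frames <- array(0, c(geom$nAxial, geom$nBeams, nt))
  for (k in seq_len(nt)) {
    frames[, , k] <- synthesizeFrame(displaceScatterers(set, wave, k), psf,
                                     geom)
  }
  new("RFStack", frames = frames, fs = psf$spec@fs, f0 = psf$spec@f0,
      soundSpeed = psf$spec@soundSpeed, axialPitch = geom$axialPitch,
      beamPitch = geom$beamPitch, times = wave@times)
}

# analytic-signal envelope of an RF frame (columns = A-lines)
.envelope <- function(frame) {
  n <- nrow(frame)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(mvfft(frame) * h, inverse = TRUE) / n)
}

#' Envelope signal-to-noise ratio of a frame
#'
#' Mean over standard deviation of the envelope magnitude in a central
#' window (10 percent borders excluded). Fully developed (Rayleigh) speckle
#' gives \eqn{\sqrt{\pi/(4-\pi)} \approx 1.91}.
#'
#' @param frame RF frame matrix.
#' @return the ratio; \code{Inf} (with a warning) for a constant envelope.
#' @export
envelopeSNR <- function(frame) {
  if (all(frame == 0)) stop("cannot compute envelope SNR of a zero frame")
  env <- .envelope(frame)
  ri <- seq(ceiling(nrow(env) * 0.1), floor(nrow(env) * 0.9))
  ci <- seq(ceiling(ncol(env) * 0.1), floor(ncol(env) * 0.9))
  w <- env[ri, ci]
  if (sd(w) == 0) {
    warning("constant envelope; SNR is infinite")
    return(Inf)
  }
  mean(w) / sd(w)
}
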