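#' @include rf.R
NULL

# Hann window of length n without zero endpoints, normalized to unit sum
.hanning <- function(n) {
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  w / sum(w)
}

# round a physical length to an odd number of lattice samples (>= 1)
.oddCount <- function(len, pitch) {
  max(1L, 2L * as.integer(floor(len / pitch / 2)) + 1L)
}

.demodMatrix <- function(frame, f0, fs, cutoff) {
  n <- nrow(frame)
  ph <- exp(-2i * pi * f0 / fs * (seq_len(n) - 1))
  bb <- frame * ph
  fr <- (seq_len(n) - 1) / n * fs
  fr[fr > fs / 2] <- fr[fr > fs / 2] - fs
  keep <- abs(fr) <= cutoff
  spec <- mvfft(bb)
  spec[!keep, ] <- 0
  mvfft(spec, inverse = TRUE) / n
}

#' Demodulate RF frames to complex baseband
#'
#' Multiplies each A-line by a complex exponential at minus the carrier
#' frequency and applies a zero-phase (frequency-domain) low-pass filter.
#'
#' @param rf an \linkS4class{RFStack}.
#' @param cutoff low-pass cutoff (Hz); defaults to the carrier frequency.
#' @return an \linkS4class{IQStack}.
#' @export
demodulate <- function(rf, cutoff = NULL) {
  stopifnot(is(rf, "RFStack"))
  if (is.null(cutoff)) cutoff <- rf@f0
  if (cutoff <= 0 || cutoff > rf@fs / 2)
    stop("cutoff must be in (0, fs/2]")
  d <- dim(rf@frames)
  iq <- array(0i, d)
  for (k in seq_len(d[3]))
    iq[, , k] <- .demodMatrix(rf@frames[, , k], rf@f0, rf@fs, cutoff)
  new("IQStack", frames = iq, fs = rf@fs, f0 = rf@f0,
      soundSpeed = rf@soundSpeed, axialPitch = rf@axialPitch,
      beamPitch = rf@beamPitch, times = rf@times, cutoff = cutoff)
}

#' Estimate the speckle size from a baseband frame
#'
#' Computes the 2-D autocorrelation magnitude of the complex baseband frame
#' and measures, along each axis through zero lag, the distance between the
#' outermost lags whose correlation stays (contiguously) above half of the
#' zero-lag value. This lattice full-width-at-half-maximum is returned per
#' axis in metres.
#'
#' @param iqFrame complex baseband matrix (axial samples by beams).
#' @param axialPitch,beamPitch lattice spacings (m).
#' @return named vector \code{c(axial =, lateral =)} (m).
#' @export
estimateSpeckleSize <- function(iqFrame, axialPitch, beamPitch) {
  if (sd(Mod(iqFrame)) == 0)
    stop("degenerate (constant) frame: speckle size undefined")
  F2 <- Mod(fft(iqFrame))^2
  ac <- fft(F2, inverse = TRUE)
  ac <- Mod(ac) / Mod(ac[1, 1])
  run <- function(prof, nmax) {
    k <- 0L
    while (k + 1L <= nmax && prof[k + 2L] >= 0.5) k <- k + 1L
    k
  }
  n <- nrow(ac); m <- ncol(ac)
  axProf <- ac[, 1]
  kp <- run(axProf, floor(n / 2) - 1L)
  km <- run(rev(axProf)[c(n, 1:(n - 1))], floor(n / 2) - 1L)
  latProf <- ac[1, ]
  lp <- run(latProf, floor(m / 2) - 1L)
  lm <- run(rev(latProf)[c(m, 1:(m - 1))], floor(m / 2) - 1L)
  c(axial = (kp + km) * axialPitch, lateral = (lp + lm) * beamPitch)
}

#' Tracking specification constructor
#'
#' Defaults follow the printed imaging conditions: correlation kernel about
#' the speckle size (0.270 mm axial by 0.586 mm lateral), 0.781 mm search
#' region in both dimensions, 0.781 mm (lateral) by 0.308 mm (axial)
#' separable Hanning correlation filter, and an estimation grid matching
#' the 0.125 mm wave-field export grid.
#'
#' @param kernelAxial,kernelLateral correlation kernel extents (m).
#' @param searchAxial,searchLateral full widths of the lag search (m).
#' @param filterAxial,filterLateral correlation-filter extents (m).
#' @param gridDx,gridDy estimation grid spacing, lateral and axial (m).
#' @return a \linkS4class{TrackingSpec}.
#' @export
trackingSpec <- function(kernelAxial = 0.270e-3, kernelLateral = 0.586e-3,
                         searchAxial = 0.781e-3, searchLateral = 0.781e-3,
                         filterAxial = 0.308e-3, filterLateral = 0.781e-3,
                         gridDx = 0.125e-3, gridDy = 0.125e-3) {
  new("TrackingSpec", kernelAxial = kernelAxial,
      kernelLateral = kernelLateral, searchAxial = searchAxial,
      searchLateral = searchLateral, filterAxial = filterAxial,
      filterLateral = filterLateral, gridDx = gridDx, gridDy = gridDy)
}

# sample-domain sizes of the tracking windows on a given RF lattice
.trackingSamples <- function(spec, axialPitch, beamPitch) {
  hkAx <- (.oddCount(spec@kernelAxial, axialPitch) - 1L) / 2L
  hkLat <- (.oddCount(spec@kernelLateral, beamPitch) - 1L) / 2L
  list(hkAx = as.integer(hkAx), hkLat = as.integer(hkLat),
       hlAx = as.integer(max(1, floor(spec@searchAxial / 2 / axialPitch))),
       hlLat = as.integer(max(1, floor(spec@searchLateral / 2 / beamPitch))),
       stepAx = max(1L, as.integer(round(spec@gridDy / axialPitch))),
       stepLat = max(1L, as.integer(round(spec@gridDx / beamPitch))))
}

#' Windowed normalized cross-correlation of a baseband frame pair
#'
#' For every estimation-grid point, correlates a kernel-sized window of
#' frame A with shifted windows of frame B over all lags in the search
#' region, normalized so that the autocorrelation at zero lag is 1.
#' Grid points whose windows would leave the frame are flagged invalid.
#'
#' @param iqA,iqB complex baseband matrices of identical geometry.
#' @param spec a \linkS4class{TrackingSpec}.
#' @param axialPitch,beamPitch lattice spacings (m).
#' @return a list of class \code{"CorrVolume"}: complex array \code{corr}
#'   \code{(nyGrid, nxGrid, nLagAx, nLagLat)}, matching \code{valid} array,
#'   grid coordinates \code{yCm}/\code{xCm}, grid sample indices and the
#'   sample-domain window sizes.
#' @export
correlatePair <- function(iqA, iqB, spec = trackingSpec(), axialPitch,
                          beamPitch) {
  stopifnot(all(dim(iqA) == dim(iqB)))
  sz <- .trackingSamples(spec, axialPitch, beamPitch)
  nax <- nrow(iqA); nb <- ncol(iqA)
  margAx <- sz$hkAx + sz$hlAx
  margLat <- sz$hkLat + sz$hlLat
  gy <- seq(margAx + 1L, nax - margAx, by = sz$stepAx)
  gx <- seq(margLat + 1L, nb - margLat, by = sz$stepLat)
  if (length(gy) < 1 || length(gx) < 1)
    stop("kernel and search region exceed the frame extent")
  gs <- rep(gy, times = length(gx))
  gb <- rep(gx, each = length(gy))
  res <- corr_volume_cpp(iqA, iqB, gs, gb, sz$hkAx, sz$hkLat, sz$hlAx,
                         sz$hlLat)
  nla <- 2L * sz$hlAx + 1L; nll <- 2L * sz$hlLat + 1L
  corr <- array(res$corr, c(length(gy), length(gx), nla, nll))
  valid <- array(res$valid > 0, c(length(gy), length(gx), nla, nll))
  structure(list(corr = corr, valid = valid,
                 yCm = (gy - 0.5) * axialPitch * 100,
                 xCm = (gx - 0.5) * beamPitch * 100,
                 gy = gy, gx = gx, sizes = sz,
                 axialPitch = axialPitch, beamPitch = beamPitch),
            class = "CorrVolume")
}

#' Smooth correlation functions across estimation points
#'
#' For each lag, the field of complex correlation values over the
#' estimation grid is convolved with a separable Hanning window (unit sum;
#' edge-renormalized so a spatially constant field is unchanged). The lag
#' axes are untouched.
#'
#' @param vol a \code{"CorrVolume"} from \code{\link{correlatePair}}.
#' @param spec the \linkS4class{TrackingSpec}.
#' @return a filtered \code{"CorrVolume"}.
#' @export
filterCorrelations <- function(vol, spec = trackingSpec()) {
  stopifnot(inherits(vol, "CorrVolume"))
  sz <- vol$sizes
  gridAxM <- sz$stepAx * vol$axialPitch
  gridLatM <- sz$stepLat * vol$beamPitch
  nAx <- .oddCount(spec@filterAxial, gridAxM)
  nLat <- .oddCount(spec@filterLateral, gridLatM)
  d <- dim(vol$corr)
  if (nAx > d[1] || nLat > d[2])
    stop("correlation-filter window larger than the estimation grid")
  if (nAx == 1L && nLat == 1L) return(vol)
  wAx <- .hanning(nAx); wLat <- .hanning(nLat)
  out <- vol$corr
  for (ll in seq_len(d[4])) {
    for (la in seq_len(d[3])) {
      v <- vol$valid[, , la, ll]
      sl <- vol$corr[, , la, ll]
      sl[!v] <- 0
      norm <- conv_sep_cpp(matrix(as.numeric(v), d[1], d[2]), wAx, wLat)
      re <- conv_sep_cpp(Re(sl), wAx, wLat)
      im <- conv_sep_cpp(Im(sl), wAx, wLat)
      sm <- complex(real = re, imaginary = im) / pmax(norm, 1e-12)
      sm[!v] <- 0
      out[, , la, ll] <- sm
    }
  }
  vol$corr <- out
  vol
}

#' Peak search and phase zero-crossing refinement
#'
#' Finds the lag of maximum correlation magnitude per grid point, then
#' refines the axial estimate from the phase of the complex correlation at
#' that lag: after removing the carrier phase of the integer lag, the
#' residual phase maps to distance by the pulse-echo factor
#' \eqn{c / (4 \pi f_0)}. Lateral displacement is the integer beam lag.
#'
#' @param vol a (filtered) \code{"CorrVolume"}.
#' @param f0 carrier frequency (Hz).
#' @param soundSpeed m/s.
#' @return list with matrices (grid axial by grid lateral): \code{dispAx},
#'   \code{dispLat} (m), \code{peakMag}, and logical \code{border}
#'   (peak on the search border) and \code{wrap} (residual phase beyond
#'   pi/2) flags.
#' @export
peakDisplacement <- function(vol, f0, soundSpeed) {
  stopifnot(inherits(vol, "CorrVolume"))
  d <- dim(vol$corr)
  nG <- d[1] * d[2]
  cm <- matrix(vol$corr, nG, d[3] * d[4])
  vm <- matrix(vol$valid, nG, d[3] * d[4])
  mag <- abs(cm)
  mag[!vm] <- -1
  pk <- max.col(mag, ties.method = "first")
  anyValid <- mag[cbind(seq_len(nG), pk)] >= 0
  la <- (pk - 1) %% d[3] + 1
  ll <- (pk - 1) %/% d[3] + 1
  lagAx <- la - (d[3] + 1) / 2
  lagLat <- ll - (d[4] + 1) / 2
  cpk <- cm[cbind(seq_len(nG), pk)]
  fs <- soundSpeed / (2 * vol$axialPitch)
  phi <- Arg(cpk * exp(-1i * 2 * pi * (f0 / fs) * lagAx))
  refine <- phi * soundSpeed / (4 * pi * f0)
  dispAx <- lagAx * vol$axialPitch + refine
  dispLat <- lagLat * vol$beamPitch
  dispAx[!anyValid] <- NA_real_
  dispLat[!anyValid] <- NA_real_
  shape <- function(v) matrix(v, d[1], d[2])
  list(dispAx = shape(dispAx), dispLat = shape(dispLat),
       peakMag = shape(ifelse(anyValid, abs(cpk), NA_real_)),
       border = shape(anyValid &
                      (abs(lagAx) == (d[3] - 1) / 2 & d[3] > 1 |
                       abs(lagLat) == (d[4] - 1) / 2 & d[4] > 1)),
       wrap = shape(anyValid & abs(phi) > pi / 2))
}

#' Accumulate frame-pair displacements
#'
#' Eulerian accumulation: the per-pair axial estimates are summed at fixed
#' grid points, referenced to the first frame. Frame k of the result is the
#' sum of the first k-1 pair estimates.
#'
#' @param pairs list of per-pair \code{dispAx} matrices (m), one per
#'   consecutive frame pair.
#' @param xCm,yCm estimation grid coordinates (cm).
#' @param times frame times (s), one more than pairs.
#' @param quality optional mean peak-correlation matrix.
#' @return a \linkS4class{DisplacementMap} with \code{length(pairs) + 1}
#'   frames.
#' @export
accumulateDisplacements <- function(pairs, xCm, yCm, times,
                                    quality = NULL) {
  stopifnot(length(pairs) >= 1)
  d <- dim(pairs[[1]])
  for (p in pairs) if (!all(dim(p) == d)) stop("inconsistent pair grids")
  nt <- length(pairs) + 1
  u <- array(0, c(d[2], d[1], nt))  # (x, y, t)
  acc <- matrix(0, d[1], d[2])
  for (k in seq_along(pairs)) {
    step <- pairs[[k]]
    step[is.na(step)] <- 0
    acc <- acc + step
    u[, , k + 1] <- t(acc)
  }
  if (is.null(quality)) quality <- matrix(1, d[2], d[1])
  new("DisplacementMap", u = u, x = xCm, y = yCm, times = times,
      quality = quality)
}

#' Track a full baseband stack
#'
#' Runs correlate / filter / refine on every consecutive frame pair and
#' accumulates the axial estimates into a displacement movie on the
#' estimation grid.
#'
#' @param iq an \linkS4class{IQStack}.
#' @param spec a \linkS4class{TrackingSpec}.
#' @param verbose print per-pair progress.
#' @return a \linkS4class{DisplacementMap}.
#' @export
trackStack <- function(iq, spec = trackingSpec(), verbose = FALSE) {
  stopifnot(is(iq, "IQStack"))
  nt <- dim(iq@frames)[3]
  if (nt < 2) stop("need at least two frames to track")
  pairs <- vector("list", nt - 1)
  qsum <- NULL
  grid <- NULL
  for (k in seq_len(nt - 1)) {
    vol <- correlatePair(iq@frames[, , k], iq@frames[, , k + 1], spec,
                         iq@axialPitch, iq@beamPitch)
    vol <- filterCorrelations(vol, spec)
    est <- peakDisplacement(vol, iq@f0, iq@soundSpeed)
    pairs[[k]] <- est$dispAx
    q <- est$peakMag
    q[is.na(q)] <- 0
    qsum <- if (is.null(qsum)) q else qsum + q
    if (is.null(grid)) grid <- vol[c("xCm", "yCm")]
    if (verbose && k %% 10 == 0)
      message("tracked pair ", k, "/", nt - 1)
  }
  accumulateDisplacements(pairs, grid$xCm, grid$yCm, iq@times,
                          quality = t(qsum / (nt - 1)))
}

#' Synthesize a baseband stack directly from a wave movie
#'
#' Streams frame synthesis and demodulation so the real-valued RF stack is
#' never held in memory; equivalent to \code{\link{synthesizeRFStack}}
#' followed by \code{\link{demodulate}}.
#'
#' @param wave ROI \linkS4class{WaveField}.
#' @param set reference \linkS4class{ScattererSet}.
#' @param psf from \code{\link{makePSF}}.
#' @param geom from \code{\link{imagingGeometry}}.
#' @param cutoff demodulation low-pass cutoff (Hz).
#' @return an \linkS4class{IQStack}.
#' @export
synthesizeIQStack <- function(wave, set, psf,
                              geom = imagingGeometry(psf$spec),
                              cutoff = psf$spec@f0) {
  nt <- length(wave@times)
  iq <- array(0i, c(geom$nAxial, geom$nBeams, nt))
  for (k in seq_len(nt)) {
    rfk <- synthesizeFrame(displaceScatterers(set, wave, k), psf, geom)
    iq[, , k] <- .demodMatrix(rfk, psf$spec@f0, psf$spec@fs, cutoff)
  }
  new("IQStack", frames = iq, fs = psf$spec@fs, f0 = psf$spec@f0,
      soundSpeed = psf$spec@soundSpeed, axialPitch = geom$axialPitch,
      beamPitch = geom$beamPitch, times = wave@times, cutoff = cutoff)
}
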