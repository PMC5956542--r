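#' @include USWIcrack-package.R
NULL

#' Simulation domain specification
#'
#' Describes the full phantom extent and the imaging region of interest
#' (ROI). The coordinate frame spans the full medium: \code{x} in
#' \code{[0, width]} with the push rod on the centre plane
#' \code{x = width/2}, and \code{y} as the depth below the top free
#' surface. The ROI sits to the left of the rod, so inside it the incident
#' wave travels toward smaller x and the crack's right edge is the near end
#' facing the source. All lengths in cm.
#'
#' @slot width,height lateral and vertical extent of the full medium (cm).
#' @slot roiX,roiY ROI intervals, \code{c(lo, hi)} (cm).
#' @slot dx,dy grid spacing of the exported displacement grid (cm).
#' @export
setClass("DomainSpec",
  representation(width = "numeric", height = "numeric",
                 roiX = "numeric", roiY = "numeric",
                 dx = "numeric", dy = "numeric"),
  prototype(width = 5, height = 5, roiX = c(0, 2.5), roiY = c(0, 5),
            dx = 0.0125, dy = 0.0125),
  validity = function(object) {
    msg <- NULL
    nxc <- diff(object@roiX) / object@dx
    nyc <- diff(object@roiY) / object@dy
    if (abs(nxc - round(nxc)) > 1e-9 || abs(nyc - round(nyc)) > 1e-9)
      msg <- c(msg, "ROI extent must be an integer number of grid cells")
    if (object@roiX[1] < -1e-12 ||
        object@roiX[2] > object@width + 1e-12 ||
        object@roiY[1] < 0 || object@roiY[2] > object@height + 1e-12)
      msg <- c(msg, "ROI must lie inside the domain")
    if (is.null(msg)) TRUE else msg
  })

#' Material specification
#'
#' A linear-elastic material given by density, Poisson's ratio and Young's
#' modulus. The shear modulus is \eqn{\mu = E / (2 (1 + \nu))} and the shear
#' speed \eqn{c = \sqrt{\mu/\rho}}; for nearly incompressible tissue
#' (\eqn{\nu \to 0.5}) this approaches \eqn{\sqrt{E/(3\rho)}}.
#'
#' @slot density kg/m^3.
#' @slot poisson dimensionless, in (0, 0.5).
#' @slot young Pa.
#' @export
setClass("MaterialSpec",
  representation(density = "numeric", poisson = "numeric", young = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@density <= 0) msg <- c(msg, "density must be positive")
    if (object@poisson <= 0 || object@poisson >= 0.5)
      msg <- c(msg, "Poisson ratio must be in (0, 0.5)")
    if (object@young <= 0) msg <- c(msg, "Young's modulus must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Crack geometry specification
#'
#' Three laceration geometries are supported: a straight crack tilted from
#' the vertical, a slim (shallow, thin) crack sharing the straight crack's
#' right edge, and a curved crack bounded by two circular arcs of equal
#' radius. \code{shape = "none"} denotes the homogeneous control phantom.
#' All lengths in cm, the tilt in degrees from the vertical.
#'
#' @slot shape one of \code{"straight"}, \code{"curved"}, \code{"slim"},
#'   \code{"none"}.
#' @slot topLeftX,topRightX crack edge positions at the top surface (cm).
#' @slot depth vertical extent of the crack (cm).
#' @slot thickness perpendicular thickness (cm).
#' @slot tilt inclination from vertical (degrees; straight/slim only).
#' @slot radius arc radius (cm; curved only).
#' @slot centerX lateral centres of the left and right bounding circles (cm;
#'   curved only). Both circles are centred at the top-surface level.
#' @export
setClass("CrackSpec",
  representation(shape = "character", topLeftX = "numeric",
                 topRightX = "numeric", depth = "numeric",
                 thickness = "numeric", tilt = "numeric",
                 radius = "numeric", centerX = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@shape %in% c("straight", "curved", "slim", "none"))
      msg <- c(msg, "unknown crack shape")
    if (object@shape == "none") return(if (is.null(msg)) TRUE else msg)
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (object@shape %in% c("straight", "slim")) {
      want <- object@thickness / cos(object@tilt * pi / 180)
      if (abs((object@topRightX - object@topLeftX) - want) > 0.005)
        msg <- c(msg, "horizontal gap inconsistent with thickness/cos(tilt)")
    }
    if (object@shape == "curved") {
      for (k in 1:2) {
        top <- c(object@topLeftX, object@topRightX)[k]
        d <- abs(top - object@centerX[k])
        if (abs(d - object@radius) > 1e-6)
          msg <- c(msg, "arc does not pass through its top point")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Rasterized material maps of the phantom
#'
#' Cell-centred grids of density and shear modulus over the full simulation
#' domain, plus the boolean crack mask (cells assigned the blood-mimicking
#' filler).
#'
#' @slot x,y cell-centre coordinates (cm); \code{x} spans the full width.
#' @slot density,mu matrices \code{length(x)} by \code{length(y)} (kg/m^3, Pa).
#' @slot mask logical matrix, \code{TRUE} inside the crack.
#' @slot resolution grid spacing (cm).
#' @slot crack the generating \linkS4class{CrackSpec}.
#' @export
setClass("MaterialField",
  representation(x = "numeric", y = "numeric", density = "matrix",
                 mu = "matrix", mask = "matrix", resolution = "numeric",
                 crack = "CrackSpec"))

#' Axial displacement movie
#'
#' The axial (depth-direction) displacement \eqn{u(x_i, y_j, t_k)} on a
#' regular grid. Displacements in metres, coordinates in cm, time in
#' seconds.
#'
#' @slot u numeric array \code{(nx, ny, nt)} (m).
#' @slot x,y grid coordinates (cm).
#' @slot times frame times (s).
#' @export
setClass("WaveField",
  representation(u = "array", x = "numeric", y = "numeric",
                 times = "numeric"),
  validity = function(object) {
    d <- dim(object@u)
    msg <- NULL
    if (length(d) != 3) msg <- c(msg, "u must be a 3-D array")
    else {
      if (d[1] != length(object@x) || d[2] != length(object@y) ||
          d[3] != length(object@times))
        msg <- c(msg, "array dimensions must match x, y, times")
    }
    if (!all(is.finite(object@u))) msg <- c(msg, "u must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Point-spread-function specification of the imaging system
#'
#' Separable PSF: axially a carrier at the centre frequency under a Gaussian
#' envelope whose power spectrum has the stated half-power fractional
#' bandwidth; laterally a Gaussian of the stated full width at half maximum.
#'
#' @slot f0 centre frequency (Hz).
#' @slot fractionalBandwidth half-power relative bandwidth (e.g. 0.5).
#' @slot lateralFWHM lateral amplitude FWHM (m).
#' @slot fs RF sampling frequency (Hz).
#' @slot soundSpeed compressional sound speed used for echo timing (m/s).
#' @export
setClass("PSFSpec",
  representation(f0 = "numeric", fractionalBandwidth = "numeric",
                 lateralFWHM = "numeric", fs = "numeric",
                 soundSpeed = "numeric"),
  prototype(f0 = 5e6, fractionalBandwidth = 0.5, lateralFWHM = 0.5e-3,
            fs = 40e6, soundSpeed = 1540),
  validity = function(object) {
    msg <- NULL
    if (object@f0 >= object@fs / 2)
      msg <- c(msg, "centre frequency must be below Nyquist")
    if (any(c(object@f0, object@fractionalBandwidth, object@lateralFWHM,
              object@fs, object@soundSpeed) <= 0))
      msg <- c(msg, "all PSF parameters must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Random scatterer field
#'
#' Reference (pre-deformation) scatterer positions and echogenicity
#' amplitudes. Positions in cm within the imaging region.
#'
#' @slot x,y positions (cm).
#' @slot amplitude zero-mean scattering amplitudes.
#' @slot seed RNG seed used to draw the set.
#' @export
setClass("ScattererSet",
  representation(x = "numeric", y = "numeric", amplitude = "numeric",
                 seed = "integer"))

#' RF frame stack
#'
#' Real-valued RF A-line frames on the axial-sample by beam lattice. The
#' axial sample pitch is \code{soundSpeed / (2 fs)} (pulse-echo two-way
#' travel); the beam pitch is the lateral extent divided by the beam count.
#'
#' @slot frames numeric array \code{(nAxial, nBeams, nFrames)}.
#' @slot fs,f0,soundSpeed acquisition parameters (Hz, Hz, m/s).
#' @slot axialPitch,beamPitch sample spacings (m).
#' @slot times frame times (s).
#' @export
setClass("RFStack",
  representation(frames = "array", fs = "numeric", f0 = "numeric",
                 soundSpeed = "numeric", axialPitch = "numeric",
                 beamPitch = "numeric", times = "numeric"))

#' Complex baseband (IQ) frame stack
#'
#' Same lattice as \linkS4class{RFStack}; complex samples after demodulation
#' at the carrier and zero-phase low-pass filtering.
#'
#' @slot frames complex array \code{(nAxial, nBeams, nFrames)}.
#' @slot fs,f0,soundSpeed,axialPitch,beamPitch,times as in
#'   \linkS4class{RFStack}.
#' @slot cutoff low-pass cutoff used at demodulation (Hz).
#' @export
setClass("IQStack",
  representation(frames = "array", fs = "numeric", f0 = "numeric",
                 soundSpeed = "numeric", axialPitch = "numeric",
                 beamPitch = "numeric", times = "numeric",
                 cutoff = "numeric"))

#' Speckle-tracking parameter set
#'
#' All window sizes are physical lengths (m) and are converted to odd sample
#' and beam counts for the given RF lattice. \code{searchAxial} and
#' \code{searchLateral} are full widths of the lag search region;
#' \code{filterAxial}/\code{filterLateral} the separable Hanning correlation
#' filter applied across estimation points; \code{gridDx}/\code{gridDy} the
#' estimation grid spacing (lateral, axial).
#'
#' @slot kernelAxial,kernelLateral correlation kernel extents (m).
#' @slot searchAxial,searchLateral lag search extents (m).
#' @slot filterAxial,filterLateral correlation-filter window extents (m).
#' @slot gridDx,gridDy estimation grid spacing (m).
#' @export
setClass("TrackingSpec",
  representation(kernelAxial = "numeric", kernelLateral = "numeric",
                 searchAxial = "numeric", searchLateral = "numeric",
                 filterAxial = "numeric", filterLateral = "numeric",
                 gridDx = "numeric", gridDy = "numeric"),
  prototype(kernelAxial = 0.270e-3, kernelLateral = 0.586e-3,
            searchAxial = 0.781e-3, searchLateral = 0.781e-3,
            filterAxial = 0.308e-3, filterLateral = 0.781e-3,
            gridDx = 0.125e-3, gridDy = 0.125e-3))

#' Tracked displacement maps
#'
#' Accumulated axial displacement per frame on the estimation grid
#' (Eulerian accumulation of frame-pair estimates referenced to frame 0),
#' with the per-pair peak correlation magnitude as a quality layer.
#'
#' @slot u accumulated axial displacement array \code{(nx, ny, nFrames)} (m).
#' @slot x,y estimation grid coordinates (cm).
#' @slot times frame times (s).
#' @slot quality mean per-pair peak |correlation| per grid point (matrix).
#' @export
setClass("DisplacementMap",
  representation(u = "array", x = "numeric", y = "numeric",
                 times = "numeric", quality = "matrix"))

#' Incident/reflected wave decomposition
#'
#' Output of the \eqn{[k,\omega]} directional filter: the input axial
#' displacement movie split into the component travelling away from the
#' push rod (incident, +x) and the component travelling back (reflected,
#' -x). The sum of the two reproduces the input up to FFT round-off.
#'
#' @slot incident,reflected arrays with the geometry of the input movie (m).
#' @slot x,y,times grid metadata (cm, cm, s).
#' @export
setClass("DirectionalDecomposition",
  representation(incident = "array", reflected = "array", x = "numeric",
                 y = "numeric", times = "numeric"))

#' Accumulated reflected-wave amplitude map
#'
#' \eqn{R(x, y) = \sum_t |u_r(x, y, t)|}: the per-pixel sum of absolute
#' reflected displacement over the imaging period.
#'
#' @slot values matrix \code{(nx, ny)} (m, summed over frames).
#' @slot x,y grid coordinates (cm).
#' @export
setClass("ReflectedAmplitudeMap",
  representation(values = "matrix", x = "numeric", y = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) "amplitude map must be non-negative" else TRUE
  })

#' Sobel edge map
#'
#' Gradient magnitude of the reflected-amplitude image and the thresholded
#' binary edge mask.
#'
#' @slot gradient Sobel gradient-magnitude matrix.
#' @slot mask logical matrix of supra-threshold edge pixels.
#' @slot threshold the applied threshold.
#' @slot x,y grid coordinates (cm).
#' @export
setClass("EdgeMap",
  representation(gradient = "matrix", mask = "matrix",
                 threshold = "numeric", x = "numeric", y = "numeric"))

#' Detected crack contour
#'
#' Ordered edge points of the selected (near-end) edge component, one
#' representative lateral position per depth row.
#'
#' @slot points data.frame with columns \code{x}, \code{y} (cm), sorted by
#'   depth.
#' @slot detectedDepth vertical extent of the contour (cm).
#' @slot provenance \code{"speckle"} or \code{"direct"}.
#' @export
setClass("CrackContour",
  representation(points = "data.frame", detectedDepth = "numeric",
                 provenance = "character"))

#' Quantitative detection report
#'
#' Per-depth comparison of detected and ground-truth right-edge transverse
#' positions, plus depth summary, in the layout usually printed for such
#' comparisons (depth, given, detected, relative error in percent).
#'
#' @slot table data.frame with columns \code{depth}, \code{given_x},
#'   \code{detected_x}, \code{relative_error} (cm, cm, cm, percent).
#' @slot detectedDepth,givenDepth cm.
#' @slot depthRatio detected/given depth.
#' @slot maxAbsError max |relative error| over rows with a detection (%).
#' @slot shape crack shape; @slot path imaging path used.
#' @slot status \code{"ok"} or \code{"no crack detected"}.
#' @slot artifacts optional list of stage intermediates (ROI wave field,
#'   filtered movie, amplitude maps, contour), kept when
#'   \code{runFullDetection(..., keepArtifacts = TRUE)}.
#' @export
setClass("DetectionReport",
  representation(table = "data.frame", detectedDepth = "numeric",
                 givenDepth = "numeric", depthRatio = "numeric",
                 maxAbsError = "numeric", shape = "character",
                 path = "character", status = "character",
                 artifacts = "list"),
  prototype(artifacts = list()))

#' Pipeline configuration
#'
#' Groups the parameters of every stage plus the master seed. Defaults
#' reproduce the reference imaging conditions; \code{preset = "reduced"}
#' (see \code{\link{pipelineConfig}}) lowers the tracking problem size for
#' quick runs.
#'
#' @slot phantom,simulation,imaging,tracking,detection named parameter lists.
#' @slot seed master RNG seed.
#' @slot outputDir where \code{\link{runPipeline}} persists artifacts
#'   (\code{""} disables persistence).
#' @export
setClass("PipelineConfig",
  representation(phantom = "list", simulation = "list", imaging = "list",
                 tracking = "list", detection = "list", seed = "integer",
                 outputDir = "character"))
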