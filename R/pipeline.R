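#' @include detect.R
NULL

#' Build a pipeline configuration
#'
#' Collects every stage parameter with defaults reproducing the reference
#' imaging conditions (5 MHz probe sampled at 40 MHz over a 5.0 x 2.5 cm
#' view, 0.0125 cm wave grid, 106 frames at 5000 frames/s, six scatterers
#' per squared wavelength, speckle-size tracking kernel). The
#' \code{"reduced"} preset keeps the physics and imaging identical but
#' tracks on a 0.25 mm axial by 0.195 mm lateral estimation grid with a
#' lag search trimmed to the small inter-frame motion of the 100 um push,
#' which cuts the tracking cost by well over an order of magnitude for
#' quick, full-chain runs.
#'
#' @param shape crack shape (\code{"straight"}, \code{"curved"},
#'   \code{"slim"}, \code{"none"}).
#' @param preset \code{"full"} or \code{"reduced"}.
#' @param seed master RNG seed (drives the scatterer field).
#' @param outputDir directory for persisted artifacts (\code{""}: none).
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(shape = "straight",
                           preset = c("full", "reduced"), seed = 1L,
                           outputDir = "") {
  preset <- match.arg(preset)
  tracking <- list(kernelAxial = 0.270e-3, kernelLateral = 0.586e-3,
                   searchAxial = 0.781e-3, searchLateral = 0.781e-3,
                   filterAxial = 0.308e-3, filterLateral = 0.781e-3,
                   gridDx = 0.125e-3, gridDy = 0.125e-3)
  if (preset == "reduced") {
    tracking$searchAxial <- 0.15e-3
    tracking$searchLateral <- 0.25e-3
    # two beams laterally: keeps the lateral quantization well under the
    # relative-error scale of the deepest edge positions
    tracking$gridDx <- 0.195e-3
    tracking$gridDy <- 0.25e-3
  }
  new("PipelineConfig",
      phantom = list(shape = shape, resolution = 0.0125),
      simulation = list(frequency = 100, cycles = 1, amplitude = 100e-6,
                        tEnd = 21e-3, frameInterval = 0.2e-3,
                        cflSafety = 0.5),
      imaging = list(f0 = 5e6, fractionalBandwidth = 0.5,
                     lateralFWHM = 0.5e-3, fs = 40e6, soundSpeed = 1540,
                     density = 6, nAxial = 2596L, nBeams = 256L),
      tracking = tracking,
      detection = list(thresholdMethod = "otsu", thresholdQuantile = 0.95,
                       borderPx = 3L, minExtent = 0.3,
                       cropX = 0.1, cropY = 0.025,
                       minReflectedFraction = 0.5,
                       reportDepths = if (shape == "none") numeric(0)
                                      else defaultReportDepths(shape)),
      seed = as.integer(seed), outputDir = outputDir)
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round-trip of all stage parameters.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path file path.
#' @return \code{readPipelineConfig} returns a
#'   \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  yaml::write_yaml(list(phantom = config@phantom,
                        simulation = config@simulation,
                        imaging = config@imaging,
                        tracking = config@tracking,
                        detection = config@detection,
                        seed = config@seed,
                        outputDir = config@outputDir), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  l <- yaml::read_yaml(path)
  l$imaging$nAxial <- as.integer(l$imaging$nAxial)
  l$imaging$nBeams <- as.integer(l$imaging$nBeams)
  l$detection$borderPx <- as.integer(l$detection$borderPx)
  l$detection$reportDepths <- as.numeric(unlist(l$detection$reportDepths))
  new("PipelineConfig", phantom = l$phantom, simulation = l$simulation,
      imaging = l$imaging, tracking = l$tracking, detection = l$detection,
      seed = as.integer(l$seed), outputDir = l$outputDir)
}

#' Run the pipeline and persist the report
#'
#' Executes \code{\link{runFullDetection}} and, when the configuration
#' names an output directory, writes \code{report.csv} (the per-depth
#' comparison table), the configuration as \code{config.yaml} and a small
#' provenance log (seed, path, stage summary).
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path \code{"speckle"} or \code{"direct"}.
#' @param verbose print stage progress.
#' @return the \linkS4class{DetectionReport}.
#' @export
runPipeline <- function(config, path = c("speckle", "direct"),
                        verbose = FALSE) {
  path <- match.arg(path)
  report <- runFullDetection(config, path, verbose = verbose)
  if (nzchar(config@outputDir)) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report@table,
              file.path(config@outputDir, "report.csv"), row.names = FALSE)
    writePipelineConfig(config, file.path(config@outputDir, "config.yaml"))
    writeLines(c(paste("seed:", config@seed),
                 paste("path:", path),
                 paste("shape:", config@phantom$shape),
                 paste("status:", report@status),
                 paste("detectedDepth_cm:", report@detectedDepth)),
               file.path(config@outputDir, "provenance.txt"))
  }
  report
}

#' Deterministic synthetic test inputs
#'
#' Generators for the module-level oracles:
#' \describe{
#'   \item{plane_wave}{an analytic travelling wave
#'     \eqn{A \sin(k_0 x - \omega_0 t)} sampled on a regular grid
#'     (params: \code{k0} rad/cm, \code{omega0} rad/s, \code{nx},
#'     \code{ny}, \code{nt}, \code{dx} cm, \code{dt} s, \code{amplitude}
#'     m). Negative \code{k0} gives a leftward wave.}
#'   \item{shifted_speckle}{a baseband/RF frame pair from one scatterer
#'     realization, the second frame axially displaced by exactly
#'     \code{delta} metres (params: \code{delta}, \code{region} cm,
#'     optional \code{nAxial}, \code{nBeams}).}
#'   \item{two_line_mask}{a binary edge mask holding two vertical lines
#'     (params: \code{x1}, \code{x2} cm, \code{nx}, \code{ny}, \code{dx}
#'     cm).}
#' }
#'
#' @param kind fixture kind.
#' @param params named list of parameters (see above).
#' @param seed RNG seed where randomness is involved.
#' @return kind-specific: a \linkS4class{WaveField}, a list with RF frame
#'   matrices \code{rfA}/\code{rfB} plus geometry, or an
#'   \linkS4class{EdgeMap}.
#' @export
makeFixture <- function(kind = c("plane_wave", "shifted_speckle",
                                 "two_line_mask"),
                        params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  if (kind == "plane_wave") {
    nx <- p$nx %||% 64L; ny <- p$ny %||% 4L; nt <- p$nt %||% 64L
    dx <- p$dx %||% 0.0125; dt <- p$dt %||% 0.2e-3
    amp <- p$amplitude %||% 1e-6
    x <- (seq_len(nx) - 0.5) * dx
    y <- (seq_len(ny) - 0.5) * dx
    times <- (seq_len(nt) - 1) * dt
    u <- array(0, c(nx, ny, nt))
    for (k in seq_len(nt))
      u[, , k] <- amp * sin(p$k0 * x - p$omega0 * times[k])
    new("WaveField", u = u, x = x, y = y, times = times)
  } else if (kind == "shifted_speckle") {
    spec <- psfSpec()
    geom <- imagingGeometry(spec,
                            nAxial = p$nAxial %||% 1200L,
                            nBeams = p$nBeams %||% 160L,
                            lateralExtent = p$lateralExtent %||% 1.5625)
    # cover the whole frame (plus an axial apron) so every kernel window
    # sees fully developed speckle
    region <- p$region %||%
      c(0, geom$lateralExtent, -0.05,
        geom$nAxial * geom$axialPitch * 100 + 0.05)
    psf <- makePSF(spec, geom$beamPitch)
    set <- seedScatterers(region, seed = seed, spec = spec)
    shifted <- new("ScattererSet", x = set@x,
                   y = set@y + (p$delta %||% 0) * 100,
                   amplitude = set@amplitude, seed = set@seed)
    list(rfA = synthesizeFrame(set, psf, geom),
         rfB = synthesizeFrame(shifted, psf, geom),
         psf = psf, geom = geom, spec = spec,
         delta = p$delta %||% 0)
  } else {
    nx <- p$nx %||% 200L; ny <- p$ny %||% 400L; dx <- p$dx %||% 0.0125
    x <- (seq_len(nx) - 0.5) * dx
    y <- (seq_len(ny) - 0.5) * dx
    mask <- matrix(FALSE, nx, ny)
    rows <- p$rows %||% seq(10L, ny - 10L)
    mask[which.min(abs(x - p$x1)), rows] <- TRUE
    mask[which.min(abs(x - p$x2)), rows] <- TRUE
    new("EdgeMap", gradient = mask * 1, mask = mask, threshold = 0.5,
        x = x, y = y)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
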