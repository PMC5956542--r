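#' @include directional.R
NULL

# trim an amplitude map's outer margin (cm per side) where FFT wrap-around
# leakage, the rod cells and the late side-boundary reflection live
.cropMap <- function(rmap, cropX = 0.1, cropY = 0.025) {
  dx <- if (length(rmap@x) > 1) rmap@x[2] - rmap@x[1] else 1
  dy <- if (length(rmap@y) > 1) rmap@y[2] - rmap@y[1] else 1
  cx <- min(round(cropX / dx), (length(rmap@x) - 8) %/% 2)
  cy <- min(round(cropY / dy), (length(rmap@y) - 8) %/% 2)
  ix <- seq(cx + 1, length(rmap@x) - cx)
  iy <- seq(cy + 1, length(rmap@y) - cy)
  new("ReflectedAmplitudeMap", values = rmap@values[ix, iy, drop = FALSE],
      x = rmap@x[ix], y = rmap@y[iy])
}

.noCrack <- function(msg = "no crack detected") {
  stop(structure(class = c("uswiNoCrackError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Sobel edge detection on an amplitude map
#'
#' Applies the 3-by-3 Sobel stencils along both axes, takes the gradient
#' magnitude, and thresholds it. The default threshold is Otsu's method on
#' the gradient-magnitude histogram; a quantile override is available. An
#' optional border margin is cleared from the mask because the Tukey-window
#' compensation of the directional filter makes the outermost rows and
#' columns of the amplitude image unreliable.
#'
#' @param rmap a \linkS4class{ReflectedAmplitudeMap}.
#' @param method \code{"otsu"} or \code{"quantile"}.
#' @param probs quantile level when \code{method = "quantile"}.
#' @param borderPx mask margin cleared at the image border (pixels).
#' @return an \linkS4class{EdgeMap}; a constant map yields an empty mask.
#' @export
detectEdges <- function(rmap, method = c("otsu", "quantile"), probs = 0.95,
                        borderPx = 3L) {
  stopifnot(is(rmap, "ReflectedAmplitudeMap"))
  method <- match.arg(method)
  v <- rmap@values
  if (!all(is.finite(v))) stop("amplitude map must be finite")
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  sy <- t(sx)
  if (diff(range(v)) == 0) {
    g <- matrix(0, nrow(v), ncol(v))
    return(new("EdgeMap", gradient = g, mask = g > 0, threshold = Inf,
               x = rmap@x, y = rmap@y))
  }
  gx <- as.matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(v), sx, boundary = "replicate")))
  gy <- as.matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(v), sy, boundary = "replicate")))
  g <- sqrt(gx^2 + gy^2)
  thr <- if (method == "otsu") {
    max(g) * EBImage::otsu(EBImage::Image(g / max(g)), range = c(0, 1))
  } else {
    quantile(g, probs)
  }
  mask <- g > thr
  if (borderPx > 0) {
    b <- seq_len(borderPx)
    mask[b, ] <- FALSE; mask[nrow(mask) - b + 1, ] <- FALSE
    mask[, b] <- FALSE; mask[, ncol(mask) - b + 1] <- FALSE
  }
  new("EdgeMap", gradient = g, mask = mask, threshold = unname(thr),
      x = rmap@x, y = rmap@y)
}

#' Extract the near-end crack contour from an edge map
#'
#' Labels the connected components of the edge mask, discards components
#' whose vertical extent is below \code{minExtent} (speckle artefacts), and
#' among the survivors returns the leftmost one (smallest mean lateral
#' position) - the reflection artefact runs parallel to the true edge on
#' its right, so the leftmost long component is the crack boundary. Each
#' depth row of the component contributes the position of its strongest
#' gradient (parabolically refined to sub-pixel) as the representative
#' lateral position: the steepest flank is the physical amplitude step at
#' the crack wall, and unlike the mask centroid it stays put when the
#' boundary line and the reflection artefact blur into one component on a
#' coarse estimation grid.
#'
#' @param edges an \linkS4class{EdgeMap}.
#' @param minExtent minimum vertical extent of a component (cm).
#' @param provenance recorded imaging path label.
#' @return a \linkS4class{CrackContour}; raises a condition of class
#'   \code{"uswiNoCrackError"} when no component qualifies.
#' @export
extractContour <- function(edges, minExtent = 0.3,
                           provenance = "direct") {
  stopifnot(is(edges, "EdgeMap"))
  if (!any(edges@mask)) .noCrack()
  lab <- round(as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(edges@mask * 1)))))
  dy <- if (length(edges@y) > 1) edges@y[2] - edges@y[1] else 1
  best <- NULL
  bestX <- Inf
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    ext <- (max(px[, 2]) - min(px[, 2])) * dy
    if (ext < minExtent) next
    mx <- mean(edges@x[px[, 1]])
    if (mx < bestX) {
      bestX <- mx
      best <- px
    }
  }
  if (is.null(best)) .noCrack("no crack detected (no component above minimum extent)")
  rows <- sort(unique(best[, 2]))
  dx <- if (length(edges@x) > 1) edges@x[2] - edges@x[1] else 1
  nx <- length(edges@x)
  pts <- data.frame(
    x = vapply(rows, function(j) {
      ii <- best[best[, 2] == j, 1]
      k <- ii[which.max(edges@gradient[cbind(ii, j)])]
      off <- 0
      if (k > 1 && k < nx) {
        gl <- edges@gradient[k - 1, j]
        gc <- edges@gradient[k, j]
        gr <- edges@gradient[k + 1, j]
        den <- gl - 2 * gc + gr
        if (den < 0) off <- max(-0.5, min(0.5, 0.5 * (gl - gr) / den))
      }
      edges@x[k] + off * dx
    }, numeric(1)),
    y = edges@y[rows])
  # the crack wall is smooth at the map resolution; a short running median
  # along depth removes single-row argmax jitter without biasing the
  # contour
  if (nrow(pts) >= 5) pts$x <- stats::runmed(pts$x, 5)
  new("CrackContour", points = pts,
      detectedDepth = max(pts$y) - min(pts$y), provenance = provenance)
}

#' Quantify a detected contour against ground truth
#'
#' Interpolates the detected lateral position at each ground-truth depth
#' and reports the relative error
#' \eqn{(x_{det} - x_{given}) / x_{given} \times 100}. Depths outside the
#' detected contour's extent yield NA rows (printed as dashes in the usual
#' table layout).
#'
#' @param contour a \linkS4class{CrackContour}.
#' @param truth data.frame from \code{\link{groundTruthTable}}.
#' @param givenDepth the true crack depth (cm).
#' @param shape,path report labels.
#' @return a \linkS4class{DetectionReport}.
#' @export
measureContour <- function(contour, truth, givenDepth,
                           shape = "straight",
                           path = contour@provenance) {
  stopifnot(is(contour, "CrackContour"))
  if (nrow(contour@points) == 0) stop("empty contour")
  det <- approx(contour@points$y, contour@points$x, xout = truth$depth,
                rule = 1, ties = mean)$y
  rel <- (det - truth$given_x) / truth$given_x * 100
  tab <- data.frame(depth = truth$depth, given_x = truth$given_x,
                    detected_x = det, relative_error = rel)
  new("DetectionReport", table = tab,
      detectedDepth = contour@detectedDepth, givenDepth = givenDepth,
      depthRatio = contour@detectedDepth / givenDepth,
      maxAbsError = if (all(is.na(rel))) NA_real_
                    else max(abs(rel), na.rm = TRUE),
      shape = shape, path = path, status = "ok")
}

.emptyReport <- function(shape, path) {
  new("DetectionReport",
      table = data.frame(depth = numeric(0), given_x = numeric(0),
                         detected_x = numeric(0),
                         relative_error = numeric(0)),
      detectedDepth = NA_real_, givenDepth = NA_real_,
      depthRatio = NA_real_, maxAbsError = NA_real_, shape = shape,
      path = path, status = "no crack detected")
}

#' Run the complete detection chain for one phantom
#'
#' Chains phantom rasterization, wave simulation, (for the speckle path) RF
#' synthesis and speckle tracking, directional filtering, reflected-wave
#' accumulation and Sobel edge detection into one detection report. The
#' \code{"direct"} path applies the directional filter to the simulated
#' displacement movie itself, bypassing the imaging chain.
#'
#' A detectability gate precedes edge extraction: if the peak accumulated
#' reflected amplitude is below \code{minReflectedFraction} of the peak
#' accumulated incident amplitude, the movie carries no reflector and the
#' report states "no crack detected" (the homogeneous control ends here).
#'
#' @param config a \linkS4class{PipelineConfig}; see
#'   \code{\link{pipelineConfig}}.
#' @param path \code{"speckle"} (full imaging chain) or \code{"direct"}.
#' @param verbose print stage progress.
#' @param keepArtifacts keep stage intermediates in the report's
#'   \code{artifacts} slot (ROI wave field, displacement movie, amplitude
#'   maps, contour).
#' @return a \linkS4class{DetectionReport}.
#' @export
runFullDetection <- function(config, path = c("speckle", "direct"),
                             verbose = FALSE, keepArtifacts = FALSE) {
  path <- match.arg(path)
  stopifnot(is(config, "PipelineConfig"))
  stage <- function(name, expr) {
    if (verbose) message("[", format(Sys.time(), "%H:%M:%S"), "] ", name)
    expr
  }
  ph <- config@phantom
  crack <- crackSpec(ph$shape)
  domain <- domainSpec(dx = ph$resolution, dy = ph$resolution)
  mf <- stage("rasterizing phantom",
              buildMaterialField(domain, crack, resolution = ph$resolution))
  sim <- config@simulation
  wave <- stage("simulating shear wave",
                simulateWaveField(mf,
                  excitationSpec(frequency = sim$frequency,
                                 cycles = sim$cycles,
                                 amplitude = sim$amplitude),
                  timeSpec(tEnd = sim$tEnd,
                           frameInterval = sim$frameInterval,
                           cflSafety = sim$cflSafety)))
  roi <- exportROI(wave, domain)
  movie <- if (path == "direct") roi else {
    img <- config@imaging
    spec <- psfSpec(f0 = img$f0, fractionalBandwidth = img$fractionalBandwidth,
                    lateralFWHM = img$lateralFWHM, fs = img$fs,
                    soundSpeed = img$soundSpeed)
    geom <- imagingGeometry(spec, img$nAxial, img$nBeams,
                            lateralExtent = diff(domain@roiX))
    psf <- makePSF(spec, geom$beamPitch)
    set <- stage("seeding scatterers",
                 seedScatterers(c(domain@roiX[1], domain@roiX[2],
                                  domain@roiY[1], domain@roiY[2]),
                                density = img$density, seed = config@seed,
                                spec = spec))
    iq <- stage("synthesizing baseband frames",
                synthesizeIQStack(roi, set, psf, geom))
    tr <- config@tracking
    stage("speckle tracking",
          trackStack(iq,
                     trackingSpec(kernelAxial = tr$kernelAxial,
                                  kernelLateral = tr$kernelLateral,
                                  searchAxial = tr$searchAxial,
                                  searchLateral = tr$searchLateral,
                                  filterAxial = tr$filterAxial,
                                  filterLateral = tr$filterLateral,
                                  gridDx = tr$gridDx, gridDy = tr$gridDy),
                     verbose = verbose))
  }
  dec <- stage("directional filtering", decomposeDirections(movie))
  det <- config@detection
  rmap <- .cropMap(accumulateReflected(dec), det$cropX, det$cropY)
  imap <- .cropMap(accumulateReflected(dec, "incident"), det$cropX,
                   det$cropY)
  finish <- function(rep, contour = NULL) {
    if (keepArtifacts)
      rep@artifacts <- list(roi = roi, movie = movie, reflected = rmap,
                            incident = imap, contour = contour)
    rep
  }
  if (max(rmap@values) < det$minReflectedFraction * max(imap@values))
    return(finish(.emptyReport(ph$shape, path)))
  edges <- detectEdges(rmap, method = det$thresholdMethod,
                       probs = det$thresholdQuantile,
                       borderPx = det$borderPx)
  contour <- tryCatch(
    extractContour(edges, minExtent = det$minExtent, provenance = path),
    uswiNoCrackError = function(e) NULL)
  if (ph$shape == "none") {
    rep <- .emptyReport(ph$shape, path)
    if (!is.null(contour)) rep@status <- "spurious detection"
    return(finish(rep, contour))
  }
  if (is.null(contour)) return(finish(.emptyReport(ph$shape, path)))
  truth <- groundTruthTable(crack, det$reportDepths)
  finish(measureContour(contour, truth, crack@depth, shape = ph$shape,
                        path = path), contour)
}
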