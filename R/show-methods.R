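#' @include pipeline.R
NULL

setMethod("show", "CrackSpec", function(object) {
  if (object@shape == "none") {
    cat("CrackSpec: homogeneous control (no crack)\n")
    return(invisible(NULL))
  }
  cat("CrackSpec:", object@shape, "crack\n")
  cat("  top edges x =", object@topLeftX, "to", object@topRightX, "cm\n")
  cat("  depth", object@depth, "cm, perpendicular thickness",
      signif(object@thickness * 10, 3), "mm\n")
  if (object@shape == "curved")
    cat("  arcs: radius", object@radius, "cm, centres x =",
        paste(object@centerX, collapse = ", "), "cm\n")
  else
    cat("  tilt", object@tilt, "degrees from vertical\n")
  invisible(NULL)
})

setMethod("show", "MaterialField", function(object) {
  cat("MaterialField:", length(object@x), "x", length(object@y),
      "cells at", object@resolution, "cm\n")
  cat("  shear modulus range:", signif(min(object@mu), 4), "-",
      signif(max(object@mu), 4), "Pa;", sum(object@mask), "crack cells\n")
  invisible(NULL)
})

setMethod("show", "WaveField", function(object) {
  d <- dim(object@u)
  cat("WaveField:", d[1], "x", d[2], "grid,", d[3], "frames (",
      signif(max(object@times) * 1e3, 4), "ms )\n")
  cat("  peak |u| =", signif(max(abs(object@u)) * 1e6, 4), "um\n")
  invisible(NULL)
})

setMethod("show", "RFStack", function(object) {
  d <- dim(object@frames)
  cat("RFStack:", d[1], "samples x", d[2], "beams x", d[3], "frames\n")
  cat("  axial pitch", signif(object@axialPitch * 1e6, 4),
      "um, beam pitch", signif(object@beamPitch * 1e6, 4), "um\n")
  invisible(NULL)
})

setMethod("show", "IQStack", function(object) {
  d <- dim(object@frames)
  cat("IQStack:", d[1], "samples x", d[2], "beams x", d[3],
      "frames (baseband, cutoff", object@cutoff / 1e6, "MHz)\n")
  invisible(NULL)
})

setMethod("show", "DisplacementMap", function(object) {
  d <- dim(object@u)
  cat("DisplacementMap:", d[1], "x", d[2], "estimation grid,", d[3],
      "frames\n")
  cat("  peak accumulated |u| =", signif(max(abs(object@u)) * 1e6, 4),
      "um; mean peak correlation", signif(mean(object@quality), 3), "\n")
  invisible(NULL)
})

setMethod("show", "ReflectedAmplitudeMap", function(object) {
  cat("ReflectedAmplitudeMap:", nrow(object@values), "x",
      ncol(object@values), "; max", signif(max(object@values) * 1e6, 4),
      "um (summed over frames)\n")
  invisible(NULL)
})

setMethod("show", "CrackContour", function(object) {
  cat("CrackContour (", object@provenance, " path): ",
      nrow(object@points), " points, depth extent ",
      signif(object@detectedDepth, 4), " cm\n", sep = "")
  invisible(NULL)
})

setMethod("show", "DetectionReport", function(object) {
  cat("DetectionReport:", object@shape, "crack,", object@path, "path -",
      object@status, "\n")
  if (object@status == "ok") {
    cat("  detected depth", signif(object@detectedDepth, 4), "cm / given",
        object@givenDepth, "cm (ratio",
        sprintf("%.1f%%", 100 * object@depthRatio), ")\n")
    if (is.finite(object@maxAbsError))
      cat("  max |relative error| of right-edge position:",
          sprintf("%.2f%%", object@maxAbsError), "\n")
    print(object@table, digits = 4)
  }
  invisible(NULL)
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:", object@phantom$shape, "crack, seed",
      object@seed, "\n")
  cat("  tracking grid", object@tracking$gridDx * 1e3, "mm, search",
      object@tracking$searchAxial * 1e3, "x",
      object@tracking$searchLateral * 1e3, "mm\n")
  invisible(NULL)
})
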