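# Shared, lazily built fixtures. The heavier objects (full-length wave
# simulations, end-to-end pipeline runs) are computed once per test session
# and reused across files.

.uswiCache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (is.null(.uswiCache[[key]])) .uswiCache[[key]] <- builder()
  .uswiCache[[key]]
}

# exported ROI wave movie for one phantom at the reference settings
cachedWave <- function(shape) {
  .cached(paste0("wave_", shape), function() {
    mf <- buildMaterialField(domainSpec(), crackSpec(shape))
    exportROI(simulateWaveField(mf))
  })
}

# end-to-end detection report (reduced tracking preset, seed 1)
cachedReport <- function(shape, path) {
  .cached(paste0("rep_", shape, "_", path), function() {
    cfg <- pipelineConfig(shape, preset = "reduced", seed = 1L)
    runFullDetection(cfg, path, keepArtifacts = TRUE)
  })
}

# one fully developed speckle frame (RF + baseband) on a mid-size lattice
cachedSpeckleFrame <- function() {
  .cached("speckle_frame", function() {
    spec <- psfSpec()
    geom <- imagingGeometry(spec, nAxial = 1200L, nBeams = 160L,
                            lateralExtent = 1.5625)
    psf <- makePSF(spec, geom$beamPitch)
    set <- seedScatterers(c(0, geom$lateralExtent, -0.05, 2.36),
                          seed = 42L, spec = spec)
    rf <- synthesizeFrame(set, psf, geom)
    list(rf = rf, iq = demodFrame(rf, spec), geom = geom, psf = psf,
         spec = spec, set = set)
  })
}

demodFrame <- function(rf, spec = psfSpec()) {
  stack <- new("RFStack", frames = array(rf, c(dim(rf), 1)), fs = spec@fs,
               f0 = spec@f0, soundSpeed = spec@soundSpeed,
               axialPitch = spec@soundSpeed / (2 * spec@fs),
               beamPitch = 2.5e-2 / 256, times = 0)
  demodulate(stack)@frames[, , 1]
}

rms <- function(a) sqrt(mean(a^2))
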