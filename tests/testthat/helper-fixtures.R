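# Shared fixtures, generated once per test run and cached in an
# environment so independent test files do not regenerate them.

.fixtures <- new.env(parent = emptyenv())

fixturePhantom <- function(class = "R-AAOCA", course = "interarterial",
                           seed = 42L, noise = 25) {
  key <- paste(class, course, seed, noise, sep = "|")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantom(
      phantomConfig(anomalyClass = class, course = course, seed = seed,
                    noiseSigmaHu = noise))
  .fixtures[[key]]
}

# left-ventricle mask (myocardium + cavity) of a label map
lvMask <- function(lm) {
  structureMask(lm, "lv_myocardium") | structureMask(lm, "lv_cavity")
}

# arc-length prefix of a polyline (mm)
proximalSegment <- function(cl, mm = 20) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  cl[arc <= mm, , drop = FALSE]
}

# a small trained-ish tiny network fixture on 16^3-ish inputs
fixtureTinyNet <- function() {
  if (is.null(.fixtures$tinynet)) {
    cfg <- networkConfig("tiny", inputDims = c(16L, 16L, 8L),
                         baseChannels = 4L, seReduction = 2L)
    .fixtures$tinynet <- buildNetwork(cfg, seed = 7L)
  }
  .fixtures$tinynet
}
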