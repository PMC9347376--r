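# Shared fixtures for the suite. Everything is generated in code; the only
# stored data are the small published-style assay tables under extdata.

extdataPath <- function(name) {
  system.file("extdata", name, package = "CapsidQuant", mustWork = TRUE)
}

vpRefRts <- function() {
  vp <- defaultVPTable()
  stats::setNames(vp$refRt, vp$name)
}

# variant response table in which VP4 is faintly visible (one tryptophan-
# equivalent); still satisfies trp(VP0) = trp(VP2) + trp(VP4)
vpTableVisibleVP4 <- function() {
  defaultVPTable(trp = c(VP0 = 11, VP1 = 9, VP2 = 10, VP3 = 8, VP4 = 1))
}

# a noiseless single-Gaussian trace for integration oracles
gaussianTrace <- function(A, mu, sigma, baseline = 0, rate = 600,
                          runTime = 11.5) {
  t <- seq(0, runTime, by = 1 / rate)
  Chromatogram(t, baseline + A * dnorm(t, mu, sigma))
}

# simulate one injection and measure its VP0/(VP2+VP4) area ratio
measureRatio <- function(emptyFraction, seed, refs = vpRefRts(),
                         conc = 3e12, noiseSd = 2e5, areaCV = 0.01) {
  sim <- simulateChromatogram(
    sampleSpec(conc, emptyFraction = emptyFraction),
    inst = instrumentSpec(noiseSd = noiseSd, areaCV = areaCV, seed = seed))
  pk <- assignPeaks(detectPeaks(sim$chromatogram), refs)$peaks
  areas <- stats::setNames(rep(0, length(refs)), names(refs))
  ok <- !is.na(pk$label)
  areas[pk$label[ok]] <- pk$area[ok]
  emptyFullRatio(areas)
}

# precision-study fixtures (published assay tables stored as CSV)
precisionAreas <- function() read.csv(extdataPath("cva21_precision_area.csv"))
precisionRts <- function() read.csv(extdataPath("cva21_precision_rt.csv"))
accuracyMixes <- function() read.csv(extdataPath("cva21_accuracy_mixes.csv"))
vpMasses <- function() read.csv(extdataPath("cva21_vp_masses.csv"))
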