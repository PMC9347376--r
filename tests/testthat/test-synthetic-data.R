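test_that("VP definition table satisfies the cleavage conservation laws", {
  vp <- defaultVPTable()
  m <- setNames(vp$calcMass, vp$name)
  # VP0 -> VP2 + VP4 loses one water, conserving residues
  expect_lt(abs(m[["VP0"]] - (m[["VP2"]] + m[["VP4"]] - 18.02)), 1)
  trp <- setNames(vp$trpCount, vp$name)
  expect_equal(trp[["VP0"]], trp[["VP2"]] + trp[["VP4"]])
  # a table violating tryptophan conservation is rejected
  expect_error(defaultVPTable(trp = c(VP0 = 5, VP1 = 9, VP2 = 10, VP3 = 8,
                                      VP4 = 0)),
               "trp")
})

test_that("capsid compositions have equal total response", {
  vp <- defaultVPTable()
  trp <- setNames(vp$trpCount, vp$name)
  cm <- capsidModel()
  expect_equal(sum(trp[cm$emptyComposition]), sum(trp[cm$fullComposition]))
})

test_that("zero-concentration sample gives a flat baseline and zero truth", {
  sim <- simulateChromatogram(sampleSpec(0, emptyFraction = 0))
  expect_true(all(sim$truth$area == 0))
  expect_true(all(chromSignal(sim$chromatogram) == 0))
})

test_that("ground-truth areas follow the occupancy model closed form", {
  sm <- sampleSpec(2e12, emptyFraction = 0.4, dilutionFactor = 2,
                   injectionVolume = 0.010)
  inst <- instrumentSpec()
  a <- groundTruthAreas(sm, inst = inst)
  injected <- 2e12 * 0.010 / 2
  vp <- defaultVPTable()
  trp <- setNames(vp$trpCount, vp$name)
  expect_equal(a[["VP0"]], injected * 60 * 0.4 * trp[["VP0"]] * 1e-6)
  expect_equal(a[["VP2"]], injected * 60 * 0.6 * trp[["VP2"]] * 1e-6)
  expect_equal(a[["VP1"]], injected * 60 * 1.0 * trp[["VP1"]] * 1e-6)
})

test_that("total ground-truth area is invariant to the empty fraction", {
  for (f in c(0, 0.1, 0.343, 0.5, 0.9, 1)) {
    a <- groundTruthAreas(sampleSpec(3.66e12, emptyFraction = f))
    a0 <- groundTruthAreas(sampleSpec(3.66e12, emptyFraction = 0))
    expect_equal(sum(a), sum(a0))
  }
})

test_that("ground-truth VP0/(VP2+VP4) ratio equals f/(1-f)", {
  for (f in c(0.05, 0.25, 0.343, 0.5, 0.75, 0.95)) {
    a <- groundTruthAreas(sampleSpec(1e12, emptyFraction = f))
    expect_equal(a[["VP0"]] / (a[["VP2"]] + a[["VP4"]]), f / (1 - f))
  }
})

test_that("simulated peaks land at the reference retention times", {
  sm <- sampleSpec(3.66e12, emptyFraction = 0.4)
  sim <- simulateChromatogram(sm, vps = vpTableVisibleVP4(),
                              inst = instrumentSpec(noiseSd = 1e5, seed = 3))
  pk <- detectPeaks(sim$chromatogram)
  expect_identical(nrow(pk), 5L)
  expect_true(all(abs(sort(pk$rt) - sort(sim$truth$refRt)) <= 1 / 600))
})

test_that("simulation is bit-reproducible from the seed", {
  inst <- instrumentSpec(noiseSd = 2e5, areaCV = 0.01, seed = 11)
  s1 <- simulateChromatogram(sampleSpec(1e12, 0.3), inst = inst)
  s2 <- simulateChromatogram(sampleSpec(1e12, 0.3), inst = inst)
  expect_identical(chromSignal(s1$chromatogram), chromSignal(s2$chromatogram))
  s3 <- simulateChromatogram(sampleSpec(1e12, 0.3),
                             inst = instrumentSpec(noiseSd = 2e5,
                                                   areaCV = 0.01, seed = 12))
  expect_false(identical(chromSignal(s1$chromatogram),
                         chromSignal(s3$chromatogram)))
})

test_that("overlapping reference retention times raise a warning", {
  vp <- defaultVPTable()
  vp$refRt[vp$name == "VP0"] <- vp$refRt[vp$name == "VP2"] + 0.01
  expect_warning(simulateChromatogram(sampleSpec(1e12, 0.3), vps = vp),
                 "closer than 3")
})

test_that("standard-series ground truth is exactly proportional to level", {
  levels <- c(2.78e9, 1e10, 5e10, 1.04e11)
  ser <- simulateStandardSeries(levels, inst = instrumentSpec(seed = 5))
  totals <- vapply(ser, function(s) sum(s$truth$area), numeric(1))
  expect_equal(totals / levels, rep(totals[1] / levels[1], length(levels)))
  # noiseless recovered slope equals responsePerTrp * copies * effective trp
  fit <- fitStandardCurve(levels, totals)
  vp <- defaultVPTable()
  trp <- setNames(vp$trpCount, vp$name)
  effTrp <- trp[["VP1"]] + trp[["VP2"]] + trp[["VP3"]] + trp[["VP4"]]
  expect_equal(curveSlope(fit), 1e-6 * 60 * effTrp, tolerance = 1e-12)
  expect_error(simulateStandardSeries(numeric(0)), "empty")
  expect_length(simulateStandardSeries(1e10), 1L)
})

test_that("ESI peaks appear at (M + z p)/z within the window only", {
  expect_identical(length(mz(simulateEsiSpectrum(numeric(0), 10:20))), 0L)
  sp <- simulateEsiSpectrum(29897, charges = 15, fwhm = 0.8)
  expected <- (29897 + 15 * 1.00728) / 15
  apex <- mz(sp)[which.max(intensity(sp))]
  expect_lt(abs(apex - expected), 0.1)
  expect_lt(abs(expected - 1994.14), 0.005)
  # charge whose m/z exceeds the window contributes nothing
  sp2 <- simulateEsiSpectrum(29897, charges = 5, window = c(400, 3000))
  expect_equal(max(intensity(sp2)), 0)
})

test_that("the m/z width-at-half-height parameter is honoured", {
  for (w in c(0.8, 1.0)) {
    sp <- simulateEsiSpectrum(15000, charges = 10, fwhm = w, step = 0.02)
    y <- intensity(sp)
    x <- mz(sp)
    half <- max(y) / 2
    above <- range(x[y > half])
    expect_equal(diff(above), w, tolerance = 0.05)
  }
})
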