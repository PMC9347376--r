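test_that("standard-curve fitting recovers an exact line", {
  sc <- fitStandardCurve(c(1, 2, 3), c(12, 14, 16))  # y = 2x + 10
  expect_equal(curveSlope(sc), 2)
  expect_equal(curveIntercept(sc), 10)
  expect_equal(curveR2(sc), 1)
  expect_equal(curveRange(sc), c(1, 3))
  expect_error(fitStandardCurve(c(1, 2), c(1, 2)), "3")
})

test_that("noiseless simulated series gives the closed-form slope and R2=1", {
  levels <- exp(seq(log(2.78e9), log(1.04e11), length.out = 6))
  ser <- simulateStandardSeries(levels, inst = instrumentSpec(seed = 2))
  totals <- vapply(ser, function(s) sum(s$truth$area), numeric(1))
  sc <- fitStandardCurve(levels, totals)
  expect_equal(curveR2(sc), 1, tolerance = 1e-12)
  trp <- setNames(defaultVPTable()$trpCount, defaultVPTable()$name)
  expect_equal(curveSlope(sc), 1e-6 * 60 * (trp[["VP1"]] + trp[["VP2"]] +
                                              trp[["VP3"]]),
               tolerance = 1e-9)
})

test_that("back-calculation inverts the curve and flags extrapolation", {
  sc <- new("StandardCurve", slope = 2, intercept = 10, r2 = 1,
            range = c(5, 100))
  expect_equal(as.numeric(capsidsPerInjection(sc, 30)), 10)
  expect_equal(as.numeric(capsidsPerInjection(sc, 10)), 0)
  low <- capsidsPerInjection(sc, 10 + 2 * 5 * 0.9)  # 10% below range min
  expect_true(attr(low, "extrapolated"))
  inr <- capsidsPerInjection(sc, 30)
  expect_false(attr(inr, "extrapolated"))
  expect_error(capsidsPerInjection(sc, 5), "negative")
})

test_that("concentration scales with volume and dilution as stated", {
  expect_equal(capsidConcentration(1e10, 0.01, 1), 1e12)
  expect_equal(capsidConcentration(0, 0.01, 5), 0)
  n <- 3.2e10
  base <- capsidConcentration(n, 0.01, 1)
  for (d in c(1.5, 3, 6, 15))
    expect_equal(capsidConcentration(n, 0.01, d), d * base)
  expect_error(capsidConcentration(1, 0), "positive")
})

test_that("empty/full ratio reproduces the precision-study values", {
  areas <- precisionAreas()
  inj1 <- setNames(as.numeric(areas[1, c("VP0", "VP2", "VP4")]),
                   c("VP0", "VP2", "VP4"))
  expect_equal(round(emptyFullRatio(inj1), 2), 0.53)
  avg <- colMeans(areas[areas$experiment == "Exp-1/Sys-1",
                        c("VP0", "VP2", "VP4")])
  expect_equal(round(emptyFullRatio(avg), 3), 0.523)
  # VP0 absent (purified full capsids) -> ratio 0
  expect_identical(emptyFullRatio(c(VP2 = 100, VP4 = 1)), 0)
  expect_error(emptyFullRatio(c(VP0 = 5, VP2 = 0, VP4 = 0)), "zero")
  # simplified form drops VP4
  expect_equal(emptyFullRatio(c(VP0 = 50, VP2 = 100), simplified = TRUE), 0.5)
})

test_that("empty fraction is the exact inverse of f -> f/(1-f)", {
  expect_identical(emptyFraction(0), 0)
  expect_equal(emptyFraction(1), 0.5)
  expect_equal(round(emptyFraction(0.522), 3), 0.343)
  for (f in seq(0.05, 0.95, by = 0.1))
    expect_equal(emptyFraction(f / (1 - f)), f)
})

test_that("ratio is monotone in the true empty fraction", {
  fs <- seq(0.05, 0.9, by = 0.05)
  ratios <- vapply(fs, function(f) {
    a <- groundTruthAreas(sampleSpec(1e12, emptyFraction = f))
    emptyFullRatio(a)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("dilutional linearity is perfect without noise, good with 1%", {
  trueConc <- 3.5e12
  d <- c(1, 1.5, 3, 6, 15)
  nTrue <- trueConc * 0.01 / d
  noiseless <- dilutionalLinearity(nTrue, d)
  expect_equal(noiseless$r2, 1)
  expect_equal(noiseless$concRsd, 0, tolerance = 1e-10)
  set.seed(17)
  noisy <- dilutionalLinearity(nTrue * (1 + rnorm(5, 0, 0.01)), d)
  expect_gt(noisy$r2, 0.999)
  expect_lt(noisy$concRsd, 5)
  expect_warning(dilutionalLinearity(c(nTrue, nTrue[1]), c(d, 1)),
                 "duplicate")
})

test_that("mixture theory conserves particles (brute-force bookkeeping)", {
  # identity: mixing a sample with itself changes nothing
  m <- theoreticalMixture(c(2e12, 2e12), c(0.3, 0.3), c(0.4, 0.6))
  expect_equal(m$conc, 2e12)
  expect_equal(m$emptyFraction, 0.3)
  # closed form 50:50
  m2 <- theoreticalMixture(c(1e12, 1e12), c(0, 0.5), c(0.5, 0.5))
  expect_equal(m2$conc, 1e12)
  expect_equal(m2$emptyFraction, 0.25)
  expect_equal(m2$efRatio, 1 / 3)
  # enumerate actual particles: 1 mL at 8/mL (2 empty) + 3 mL at 4/mL
  # (6 empty) -> 20 particles in 4 mL, 8 empty
  particles <- c(rep(TRUE, 2), rep(FALSE, 6), rep(TRUE, 6), rep(FALSE, 6))
  m3 <- theoreticalMixture(c(8, 4), c(2 / 8, 6 / 12), c(0.25, 0.75))
  expect_equal(m3$conc * 4, length(particles))
  expect_equal(m3$emptyFraction, mean(particles))
  expect_error(theoreticalMixture(c(0, 0), c(0, 0), c(0.5, 0.5)), "no capsids")
  expect_error(theoreticalMixture(1e12, 0.2, 0.8), "sum to 1")
})

test_that("accuracy percentages reproduce the spike-recovery table", {
  mixes <- accuracyMixes()
  expect_identical(accuracyPercent(mixes$measured_conc,
                                   mixes$theoretical_conc),
                   c(102, 105, 106, 105))
  expect_identical(accuracyPercent(mixes$measured_ratio,
                                   mixes$theoretical_ratio),
                   c(99, 90, 100, 98))
  expect_identical(accuracyPercent(7, 7), 100)
  expect_error(accuracyPercent(1, 0), "zero")
})

test_that("process flagging applies stage thresholds", {
  expect_identical(processFlag(0.25, threshold = 0.20), "flag")
  expect_identical(processFlag(0.035), "pass")            # intermediate 0.04
  expect_identical(processFlag(0.035, "drug_substance"), "flag")  # 0.01
  expect_identical(processFlag(0), "pass")
  expect_error(processFlag(0.1, threshold = -1), "positive")
})

test_that("end-to-end recovery of concentration and empty fraction", {
  # calibrate on a simulated standard series, then quantify unknown samples
  levels <- exp(seq(log(2.78e9), log(1.04e11), length.out = 6))
  ser <- simulateStandardSeries(levels,
                                inst = instrumentSpec(noiseSd = 2e5, seed = 8))
  refs <- vpRefRts()
  totals <- vapply(ser, function(s) {
    pk <- detectPeaks(s$chromatogram)
    sum(assignPeaks(pk, refs)$peaks$area)
  }, numeric(1))
  curve <- fitStandardCurve(levels, totals)

  for (case in list(c(3.66e12, 0.343), c(1.5e12, 0.05), c(2.5e12, 0.6))) {
    trueConc <- case[1]; trueF <- case[2]
    sim <- simulateChromatogram(sampleSpec(trueConc, emptyFraction = trueF),
                                inst = instrumentSpec(noiseSd = 2e5,
                                                      seed = 21))
    pk <- assignPeaks(detectPeaks(sim$chromatogram), refs)$peaks
    areas <- setNames(rep(0, 5), names(refs))
    ok <- !is.na(pk$label)
    areas[pk$label[ok]] <- pk$area[ok]
    q <- quantifyInjection(areas, curve)
    expect_lt(abs(capsidConc(q) / trueConc - 1), 0.05)
    expect_lt(abs(emptyFractionOf(q) - trueF), 0.02)
  }
})

test_that("small true ratio differences keep their ordering under noise", {
  # two process samples whose true empty/full ratios differ by 0.012
  fHigh <- emptyFraction(0.036)
  fLow <- emptyFraction(0.024)
  refs <- vpRefRts()
  ok <- 0L
  nRep <- 20L
  for (s in seq_len(nRep)) {
    rHigh <- measureRatio(fHigh, seed = 100 + s, refs = refs)
    rLow <- measureRatio(fLow, seed = 200 + s, refs = refs)
    ok <- ok + (rHigh > rLow)
  }
  expect_gte(ok / nRep, 0.95)
})
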