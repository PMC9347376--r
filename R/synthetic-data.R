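#' Default virion-protein definition table
#'
#' Reference properties of the five Coxsackievirus A21 capsid proteins:
#' average mass calculated from sequence, a tryptophan count used as the
#' fluorescence response proxy, a reference retention time on the two-stage
#' reverse-phase gradient (elution order VP4 < VP1 < VP2 < VP0 < VP3), and a
#' Gaussian peak width for simulation.
#'
#' The calculated masses are the published sequence-derived averages. The
#' tryptophan counts are synthetic fixtures (the VP sequences are not public):
#' they honour the two structural constraints the analysis rests on —
#' `trp(VP0) = trp(VP2) + trp(VP4)` because VP0 is cleaved into VP2 and VP4
#' without losing residues, and `trp(VP4) = 0` because VP4 carries no
#' tryptophan and is therefore essentially dark on the FLR channel.
#'
#' @param trp named numeric overriding the default tryptophan counts; must
#'   keep `trp["VP0"] == trp["VP2"] + trp["VP4"]`.
#' @return data.frame with columns `name`, `calcMass` (Da), `trpCount`,
#'   `refRt` (min), `peakSigma` (min), rows ordered by elution.
#' @examples
#' defaultVPTable()
#' @export
defaultVPTable <- function(trp = c(VP0 = 10, VP1 = 9, VP2 = 10, VP3 = 8,
                                   VP4 = 0)) {
  stopifnot(all(c("VP0", "VP1", "VP2", "VP3", "VP4") %in% names(trp)),
            all(trp >= 0))
  if (abs(trp[["VP0"]] - (trp[["VP2"]] + trp[["VP4"]])) > 1e-9)
    stop("tryptophan counts must satisfy trp(VP0) = trp(VP2) + trp(VP4)")
  vp <- data.frame(
    name      = c("VP4", "VP1", "VP2", "VP0", "VP3"),
    calcMass  = c(7304, 33231, 29897, 37183, 26546),
    refRt     = c(4.335, 5.669, 7.079, 7.527, 8.775),
    peakSigma = rep(0.02, 5),
    stringsAsFactors = FALSE
  )
  vp$trpCount <- as.numeric(trp[vp$name])
  # precursor cleavage conserves residues up to one water
  dm <- vp$calcMass[vp$name == "VP0"] -
    (vp$calcMass[vp$name == "VP2"] + vp$calcMass[vp$name == "VP4"] - 18.02)
  stopifnot(abs(dm) <= 1)
  vp[, c("name", "calcMass", "trpCount", "refRt", "peakSigma")]
}

#' Capsid stoichiometry model
#'
#' An empty procapsid carries 60 copies each of VP0, VP1 and VP3; a full
#' mature virion carries 60 copies each of VP1, VP2, VP3 and VP4 (VP0 is
#' cleaved into VP2 + VP4 on genome encapsidation). Because the cleavage
#' conserves residues, both compositions have the same total
#' tryptophan-equivalent response, which is what makes total peak area a
#' composition-independent measure of capsid count.
#'
#' @param copiesPerCapsid integer, copies of each listed VP per capsid.
#' @return list with `copiesPerCapsid`, `emptyComposition`, `fullComposition`.
#' @export
capsidModel <- function(copiesPerCapsid = 60L) {
  stopifnot(copiesPerCapsid >= 1)
  list(copiesPerCapsid = as.integer(copiesPerCapsid),
       emptyComposition = c("VP0", "VP1", "VP3"),
       fullComposition = c("VP1", "VP2", "VP3", "VP4"))
}

#' Sample specification for simulation
#'
#' @param capsidConc capsids/mL, >= 0.
#' @param emptyFraction fraction of capsids that are empty procapsids,
#'   between 0 and 1.
#' @param dilutionFactor dilution factor applied to the sample, at least 1.
#' @param injectionVolume mL (default 0.010 mL; configurable, not a fixed
#'   instrument constant).
#' @return list echoing the arguments.
#' @export
sampleSpec <- function(capsidConc, emptyFraction = 0, dilutionFactor = 1,
                       injectionVolume = 0.010) {
  stopifnot(capsidConc >= 0, emptyFraction >= 0, emptyFraction <= 1,
            dilutionFactor >= 1, injectionVolume > 0)
  list(capsidConc = capsidConc, emptyFraction = emptyFraction,
       dilutionFactor = dilutionFactor, injectionVolume = injectionVolume)
}

#' Instrument specification for simulation
#'
#' Defaults emulate a fluorescence detector sampled at 600 points/min over an
#' 11.5-min run. `responsePerTrp` converts (capsids x copies x tryptophans)
#' into integrated area units; `noiseSd` is additive white Gaussian noise on
#' the trace; `baselineDrift` adds a linear baseline; `areaCV` applies
#' multiplicative Gaussian noise to each peak amplitude (injection-to-
#' injection variability), with the pre-noise closed-form areas always
#' reported as ground truth.
#'
#' @param samplingRate points per minute.
#' @param runTime minutes.
#' @param noiseSd signal units.
#' @param baselineDrift signal units per minute.
#' @param responsePerTrp area units per capsid-copy-tryptophan equivalent.
#' @param areaCV relative SD of multiplicative per-peak amplitude noise.
#' @param seed integer or NULL; when set, simulation is bit-reproducible.
#' @return list echoing the arguments.
#' @export
instrumentSpec <- function(samplingRate = 600, runTime = 11.5, noiseSd = 0,
                           baselineDrift = 0, responsePerTrp = 1e-6,
                           areaCV = 0, seed = NULL) {
  stopifnot(samplingRate > 0, runTime > 0, noiseSd >= 0, areaCV >= 0,
            responsePerTrp > 0)
  list(samplingRate = samplingRate, runTime = runTime, noiseSd = noiseSd,
       baselineDrift = baselineDrift, responsePerTrp = responsePerTrp,
       areaCV = areaCV, seed = seed)
}

occupancy <- function(vpName, emptyFraction) {
  switch(vpName,
         VP0 = emptyFraction,
         VP2 = ,
         VP4 = 1 - emptyFraction,
         1)
}

#' Ground-truth per-VP areas for a simulated injection
#'
#' Closed form of the occupancy model: the area of VP `v` is
#' `injectedCapsids x copiesPerCapsid x occupancy(v) x trp(v) x
#' responsePerTrp`, where occupancy is `emptyFraction` for VP0,
#' `1 - emptyFraction` for VP2 and VP4, and 1 for VP1 and VP3, and
#' `injectedCapsids = capsidConc x injectionVolume / dilutionFactor`.
#'
#' @param sample a [sampleSpec()].
#' @param vps VP definition table, see [defaultVPTable()].
#' @param capsid a [capsidModel()].
#' @param inst an [instrumentSpec()].
#' @return named numeric of areas, one per VP.
#' @export
groundTruthAreas <- function(sample, vps = defaultVPTable(),
                             capsid = capsidModel(), inst = instrumentSpec()) {
  injected <- sample$capsidConc * sample$injectionVolume / sample$dilutionFactor
  occ <- vapply(vps$name, occupancy, numeric(1),
                emptyFraction = sample$emptyFraction)
  a <- injected * capsid$copiesPerCapsid * occ * vps$trpCount *
    inst$responsePerTrp
  names(a) <- vps$name
  a
}

#' Simulate a fluorescence chromatogram of a capsid sample
#'
#' The trace is `baselineDrift x t + noise + sum of Gaussian peaks`, one peak
#' per virion protein, with amplitudes fixed by the capsid occupancy model
#' (see [groundTruthAreas()]). A warning (not an error) is recorded when two
#' reference retention times sit closer than three peak widths.
#'
#' @inheritParams groundTruthAreas
#' @return list with `chromatogram` (a [Chromatogram-class]) and `truth`, a
#'   data.frame of per-VP reference rt, closed-form area, and realized area
#'   (after any multiplicative amplitude noise).
#' @examples
#' sim <- simulateChromatogram(sampleSpec(3.66e12, emptyFraction = 0.34),
#'                             inst = instrumentSpec(seed = 1))
#' sim$truth
#' @export
simulateChromatogram <- function(sample, vps = defaultVPTable(),
                                 capsid = capsidModel(),
                                 inst = instrumentSpec()) {
  stopifnot(all(vps$refRt > 0), all(vps$refRt < inst$runTime),
            all(vps$peakSigma > 0))
  if (!is.null(inst$seed)) set.seed(inst$seed)
  ord <- order(vps$refRt)
  gap <- diff(vps$refRt[ord])
  sig <- vps$peakSigma[ord]
  tooClose <- gap < 3 * pmax(sig[-length(sig)], sig[-1])
  if (any(tooClose))
    warning("reference retention times closer than 3 peak sigmas: ",
            paste(vps$name[ord][which(tooClose)], vps$name[ord][which(tooClose) + 1L],
                  sep = "/", collapse = ", "))

  areas <- groundTruthAreas(sample, vps, capsid, inst)
  realized <- areas
  if (inst$areaCV > 0)
    realized <- areas * (1 + stats::rnorm(length(areas), 0, inst$areaCV))

  t <- seq(0, inst$runTime, by = 1 / inst$samplingRate)
  y <- inst$baselineDrift * t
  for (i in seq_len(nrow(vps)))
    y <- y + realized[[i]] * stats::dnorm(t, vps$refRt[i], vps$peakSigma[i])
  if (inst$noiseSd > 0)
    y <- y + stats::rnorm(length(t), 0, inst$noiseSd)

  truth <- data.frame(name = vps$name, refRt = vps$refRt, area = unname(areas),
                      areaRealized = unname(realized),
                      stringsAsFactors = FALSE)
  list(chromatogram = Chromatogram(t, y, "FLR"), truth = truth)
}

#' Simulate a calibration standard series
#'
#' One seeded chromatogram per particle level, with per-VP ground-truth areas
#' exactly proportional to the level. In the noiseless case the slope of
#' total area vs particle level is exactly
#' `responsePerTrp x copiesPerCapsid x sum(trp)` (with the standard's own
#' empty fraction immaterial because tryptophan content is conserved by the
#' VP0 cleavage).
#'
#' @param levels numeric, capsid particles per injection, all > 0.
#' @param emptyFraction empty fraction of the standard material.
#' @inheritParams groundTruthAreas
#' @return list of simulation results as from [simulateChromatogram()], one
#'   per level; levels attached as attribute `"levels"`.
#' @export
simulateStandardSeries <- function(levels, vps = defaultVPTable(),
                                   capsid = capsidModel(),
                                   inst = instrumentSpec(),
                                   emptyFraction = 0) {
  if (length(levels) == 0L) stop("empty level list")
  stopifnot(all(levels > 0))
  if (!is.null(inst$seed)) set.seed(inst$seed)
  instNoSeed <- inst
  instNoSeed$seed <- NULL  # one RNG stream across the series
  out <- lapply(levels, function(lv) {
    # express the level directly as particles per injection
    sm <- sampleSpec(capsidConc = lv / 0.010, emptyFraction = emptyFraction,
                     dilutionFactor = 1, injectionVolume = 0.010)
    simulateChromatogram(sm, vps, capsid, instNoSeed)
  })
  attr(out, "levels") <- levels
  out
}

#' Simulate a multi-charge ESI spectrum of intact proteins
#'
#' For each neutral mass M and each charge z in `charges`, a Gaussian peak is
#' placed at `(M + z * 1.00728) / z`; peaks whose centre falls outside the
#' acquisition window are silently dropped. Charge-state intensities follow a
#' symmetric (Gaussian) envelope over the charge range. The m/z peak shape
#' uses a configurable width at half height (default 0.8, alternative 1.0).
#'
#' @param masses numeric, neutral average masses in Da (may be empty).
#' @param charges integer vector of charge states, e.g. `12:25`.
#' @param window length-2 acquisition window in m/z.
#' @param fwhm width at half height of each m/z peak.
#' @param step m/z sampling step of the profile.
#' @param intensities optional per-mass total intensities.
#' @param seed integer or NULL.
#' @return a [MassSpectrum-class].
#' @examples
#' sp <- simulateEsiSpectrum(29897, charges = 12:25)
#' @export
simulateEsiSpectrum <- function(masses, charges, window = c(400, 3000),
                                fwhm = 0.8, step = 0.1,
                                intensities = rep(1, length(masses)),
                                seed = NULL) {
  stopifnot(all(masses > 0) || length(masses) == 0L, length(charges) >= 1L,
            fwhm > 0, step > 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(masses) == 0L) return(MassSpectrum())
  grid <- seq(window[1], window[2], by = step)
  y <- numeric(length(grid))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  zmid <- mean(range(charges))
  zsd <- max(1, diff(range(charges)) / 4)
  for (i in seq_along(masses)) {
    for (z in charges) {
      centre <- (masses[i] + z * 1.00728) / z
      if (centre < window[1] || centre > window[2]) next
      amp <- intensities[i] * exp(-((z - zmid)^2) / (2 * zsd^2))
      y <- y + amp * exp(-((grid - centre)^2) / (2 * sigma^2))
    }
  }
  MassSpectrum(grid, y)
}
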