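#' Fit a linear standard curve of total VP area vs particle number
#'
#' Ordinary least squares with a free intercept (unweighted): the calibration
#' model under which capsid number is back-calculated as
#' `(total area - intercept) / slope`. The calibrated range is the span of
#' the fitted particle levels.
#'
#' @param particles numeric, capsid particles per injection (distinct, >= 3).
#' @param totalArea numeric, summed VP peak area per injection.
#' @return a [StandardCurve-class].
#' @examples
#' fitStandardCurve(c(1, 2, 3), c(12, 14, 16))  # y = 2x + 10
#' @export
fitStandardCurve <- function(particles, totalArea) {
  if (length(particles) < 3L) stop("need at least 3 calibration points")
  if (length(particles) != length(totalArea))
    stop("particles and totalArea must have equal length")
  if (length(unique(particles)) < 3L)
    stop("calibration points must have at least 3 distinct particle levels")
  fit <- stats::lm(totalArea ~ particles)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((totalArea - mean(totalArea))^2)
  r2 <- if (sst == 0 || sse == 0) 1 else 1 - sse / sst
  new("StandardCurve",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = min(max(r2, 0), 1),
      range = range(particles))
}

#' Back-calculate capsid number per injection from total VP area
#'
#' `(totalArea - intercept) / slope`. Values outside the calibrated range
#' are returned with attribute `extrapolated = TRUE`; a negative
#' back-calculated count is an error (the area is below the blank response).
#'
#' @param x a [StandardCurve-class].
#' @param totalArea summed VP peak area.
#' @return capsid particles per injection, with logical attribute
#'   `"extrapolated"`.
#' @rdname capsidsPerInjection
#' @export
setMethod("capsidsPerInjection", "StandardCurve", function(x, totalArea) {
  n <- (totalArea - x@intercept) / x@slope
  if (any(n < 0))
    stop("back-calculated capsid number is negative: total area ",
         format(totalArea[which(n < 0)[1]]), " lies below the curve ",
         "intercept ", format(x@intercept))
  extra <- n < x@range[1] | n > x@range[2]
  # a zero count (area exactly at the intercept, e.g. a blank) is reported
  # as such, not flagged
  extra[n == 0] <- FALSE
  attr(n, "extrapolated") <- extra
  n
})

#' Capsid concentration from particle count, volume and dilution
#'
#' `n / (injectionVolume / dilutionFactor)`: the count per injection scaled
#' to capsids per mL of the original (undiluted) sample.
#'
#' @param n capsid particles per injection.
#' @param injectionVolume mL, > 0.
#' @param dilutionFactor dilution factor applied to the sample, at least 1.
#' @return capsids/mL.
#' @examples
#' capsidConcentration(1e10, injectionVolume = 0.01)  # 1e12 capsids/mL
#' @export
capsidConcentration <- function(n, injectionVolume, dilutionFactor = 1) {
  if (any(injectionVolume <= 0)) stop("injection volume must be positive")
  if (any(dilutionFactor < 1)) stop("dilution factor must be >= 1")
  n / (injectionVolume / dilutionFactor)
}

#' Empty/full capsid ratio from per-VP peak areas
#'
#' The VP0/(VP2+VP4) FLR peak-area ratio: empty procapsids contribute all of
#' the VP0 area and none of VP2/VP4, full virions the reverse, and the VP0
#' cleavage conserves tryptophan content, so the area ratio tracks the molar
#' empty:full particle ratio without response correction. With
#' `simplified = TRUE` the VP0/VP2 form is used (VP4 carries no tryptophan
#' and contributes under 1% of the VP2 FLR area). A missing VP0 area is
#' treated as zero (purified full capsids); a missing or zero denominator is
#' an error. `responseFactors` allows a per-VP response correction; the
#' default is the identity.
#'
#' @param areas named numeric of per-VP areas (needs VP2, and VP4 unless
#'   simplified; VP0 optional).
#' @param simplified use VP0/VP2 instead of VP0/(VP2+VP4).
#' @param responseFactors named numeric multipliers applied to areas first.
#' @return the area ratio, >= 0.
#' @examples
#' emptyFullRatio(c(VP0 = 11698177, VP2 = 21890324, VP4 = 193564))
#' @export
emptyFullRatio <- function(areas, simplified = FALSE,
                           responseFactors = NULL) {
  if (!is.null(responseFactors)) {
    common <- intersect(names(areas), names(responseFactors))
    areas[common] <- areas[common] * responseFactors[common]
  }
  vp0 <- if ("VP0" %in% names(areas) && is.finite(areas[["VP0"]]))
    areas[["VP0"]] else 0
  if (!"VP2" %in% names(areas)) stop("VP2 area missing")
  den <- areas[["VP2"]]
  if (!simplified) {
    if (!"VP4" %in% names(areas)) stop("VP4 area missing (use simplified = TRUE)")
    den <- den + areas[["VP4"]]
  }
  if (!is.finite(den) || den <= 0)
    stop("no full-capsid signal: VP2", if (!simplified) "+VP4" else "",
         " area is zero")
  vp0 / den
}

#' Empty-capsid fraction from the empty/full ratio
#'
#' Model-based conversion `ratio / (1 + ratio)`, i.e. the area ratio is read
#' as the empty:full particle ratio. This is an interpretation layered on
#' the measured ratio, not itself a measured quantity.
#'
#' @param ratio empty/full area ratio, >= 0.
#' @return fraction in [0, 1).
#' @examples
#' emptyFraction(0.522)
#' @export
emptyFraction <- function(ratio) {
  stopifnot(all(ratio >= 0))
  ratio / (1 + ratio)
}

#' Quantify one injection from assigned per-VP areas
#'
#' Bundles the calibration back-calculation, the volume/dilution scaling and
#' the empty/full ratio into a [QuantResult-class].
#'
#' @param areas named numeric of per-VP peak areas.
#' @param curve a [StandardCurve-class].
#' @param injectionVolume mL.
#' @param dilutionFactor dilution factor applied to the sample, at least 1.
#' @return a [QuantResult-class].
#' @export
quantifyInjection <- function(areas, curve, injectionVolume = 0.010,
                              dilutionFactor = 1) {
  total <- sum(areas, na.rm = TRUE)
  n <- capsidsPerInjection(curve, total)
  conc <- capsidConcentration(as.numeric(n), injectionVolume, dilutionFactor)
  r <- emptyFullRatio(areas)
  rs <- emptyFullRatio(areas, simplified = TRUE)
  new("QuantResult",
      capsidsPerInjection = as.numeric(n), capsidConc = conc,
      efRatio = r, efRatioSimplified = rs,
      emptyFraction = emptyFraction(r), perVpAreas = areas,
      extrapolated = any(attr(n, "extrapolated")))
}

#' Dilutional linearity of a sample
#'
#' Regresses measured capsid number per injection against the corrected
#' injection volume (`injectionVolume / dilutionFactor`) across dilution
#' levels of one sample, and reports the %RSD of the back-calculated sample
#' concentration across levels. Both should be excellent when the assay
#' response is proportional to the amount on column.
#'
#' @param capsidsPerInj numeric, measured particles per injection per level.
#' @param dilutionFactors numeric, e.g. `c(1, 1.5, 3, 6, 15)`.
#' @param injectionVolume mL.
#' @return list with `r2` (of count vs corrected volume, through OLS with
#'   intercept), `concRsd` (%RSD of back-calculated concentration), and
#'   `conc` (per-level concentrations).
#' @export
dilutionalLinearity <- function(capsidsPerInj, dilutionFactors,
                                injectionVolume = 0.010) {
  if (length(capsidsPerInj) != length(dilutionFactors))
    stop("one measured count per dilution level required")
  if (length(unique(dilutionFactors)) < length(dilutionFactors)) {
    warning("duplicate dilution levels collapsed by averaging")
    agg <- tapply(capsidsPerInj, dilutionFactors, mean)
    dilutionFactors <- as.numeric(names(agg))
    capsidsPerInj <- as.numeric(agg)
  }
  if (length(dilutionFactors) < 3L) stop("need at least 3 dilution levels")
  v <- injectionVolume / dilutionFactors
  fit <- stats::lm(capsidsPerInj ~ v)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((capsidsPerInj - mean(capsidsPerInj))^2)
  conc <- capsidConcentration(capsidsPerInj, injectionVolume, dilutionFactors)
  list(r2 = if (sst == 0 || sse == 0) 1 else 1 - sse / sst,
       concRsd = rsd(conc), conc = conc)
}

#' Theoretical concentration and ratio of a volumetric mixture
#'
#' For components with concentrations `conc` (capsids/mL), empty fractions
#' `emptyFraction` and volume fractions `volumeFraction` (summing to 1):
#' total concentration is the volume-weighted mean of concentrations, while
#' the mixed empty fraction is weighted by capsid count
#' (`sum(v*C*f) / sum(v*C)`) — particle bookkeeping, not volume bookkeeping.
#' The corresponding empty/full ratio is `f / (1 - f)`.
#'
#' @param conc numeric, component concentrations, capsids/mL.
#' @param emptyFraction numeric between 0 and 1, per component.
#' @param volumeFraction numeric in (0, 1], summing to 1.
#' @return list with `conc`, `emptyFraction`, `efRatio`.
#' @examples
#' theoreticalMixture(c(1e12, 1e12), c(0, 0.5), c(0.5, 0.5))
#' @export
theoreticalMixture <- function(conc, emptyFraction, volumeFraction) {
  stopifnot(length(conc) == length(emptyFraction),
            length(conc) == length(volumeFraction),
            all(volumeFraction > 0), all(volumeFraction <= 1),
            all(emptyFraction >= 0), all(emptyFraction <= 1))
  if (abs(sum(volumeFraction) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  totalConc <- sum(volumeFraction * conc)
  if (totalConc <= 0) stop("mixture contains no capsids")
  f <- sum(volumeFraction * conc * emptyFraction) / totalConc
  list(conc = totalConc, emptyFraction = f, efRatio = f / (1 - f))
}

#' Accuracy as percent of theoretical
#'
#' `100 x measured / theoretical`, rounded to the nearest integer for
#' reporting (spike-recovery convention).
#'
#' @param measured,theoretical numeric; `theoretical` must be nonzero.
#' @param digits rounding for the report; `NULL` returns unrounded.
#' @return percent.
#' @examples
#' accuracyPercent(2.58e12, 2.52e12)  # 102
#' @export
accuracyPercent <- function(measured, theoretical, digits = 0) {
  if (any(theoretical == 0)) stop("theoretical value is zero")
  p <- 100 * measured / theoretical
  if (is.null(digits)) p else round(p, digits)
}

#' Flag a process sample by its simplified empty/full ratio
#'
#' Process monitoring uses the VP0/VP2 ratio against a stage-appropriate
#' threshold: purification intermediates are expected below ~0.04 after
#' process optimisation, final drug substance below ~0.01 (under 1% empty
#' particles).
#'
#' @param efRatioSimplified VP0/VP2 area ratio.
#' @param threshold positive flagging threshold (defaults: 0.04 for
#'   `stage = "intermediate"`, 0.01 for `stage = "drug_substance"`).
#' @param stage used only to pick the default threshold.
#' @return `"pass"` or `"flag"`.
#' @examples
#' processFlag(0.25, threshold = 0.20)  # "flag"
#' @export
processFlag <- function(efRatioSimplified,
                        stage = c("intermediate", "drug_substance"),
                        threshold = NULL) {
  stage <- match.arg(stage)
  if (is.null(threshold))
    threshold <- switch(stage, intermediate = 0.04, drug_substance = 0.01)
  if (threshold <= 0) stop("threshold must be positive")
  ifelse(efRatioSimplified > threshold, "flag", "pass")
}
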