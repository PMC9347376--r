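#' @import methods
NULL

#' Chromatogram: a sampled detector trace
#'
#' A single-channel detector signal sampled over time. Quantification in this
#' package is performed on the fluorescence (FLR) channel, which for virion
#' proteins is dominated by tryptophan emission; UV channels (A280, A220) are
#' carried as labels only.
#'
#' @slot time numeric, retention time in minutes, strictly increasing and
#'   near-uniformly spaced (max/min step ratio < 1.5).
#' @slot signal numeric, detector response, same length as `time`.
#' @slot channel character(1), one of `"FLR"`, `"A280"`, `"A220"`.
#'
#' @examples
#' ch <- Chromatogram(time = seq(0, 1, by = 0.01), signal = rep(0, 101))
#' ch
#' @export
setClass("Chromatogram",
  representation(time = "numeric", signal = "numeric", channel = "character"),
  prototype(channel = "FLR")
)

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@time) < 2L)
    msg <- c(msg, "chromatogram needs at least 2 points")
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have equal length")
  d <- diff(object@time)
  if (any(d <= 0))
    msg <- c(msg, "time must be strictly increasing")
  else if (length(d) && max(d) / min(d) >= 1.5)
    msg <- c(msg, "time spacing is too irregular (max/min step ratio >= 1.5)")
  if (length(object@channel) != 1L)
    msg <- c(msg, "channel must be a single label")
  if (length(msg)) msg else TRUE
})

#' @param time,signal,channel see slots.
#' @rdname Chromatogram-class
#' @export
Chromatogram <- function(time, signal, channel = "FLR") {
  new("Chromatogram", time = as.numeric(time), signal = as.numeric(signal),
      channel = channel)
}

#' MassSpectrum: an m/z vs intensity spectrum
#'
#' A profile-mode electrospray spectrum. The acquisition window used for
#' intact virion proteins is m/z 400-3,000, but the class places no window
#' restriction.
#'
#' @slot mz numeric, strictly increasing m/z values.
#' @slot intensity numeric, non-negative, same length as `mz`.
#'
#' @examples
#' MassSpectrum(mz = c(500, 501, 502), intensity = c(0, 10, 0))
#' @export
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric")
)

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param mz,intensity see slots.
#' @rdname MassSpectrum-class
#' @export
MassSpectrum <- function(mz = numeric(), intensity = numeric()) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' StandardCurve: linear calibration of total VP area vs particle number
#'
#' Ordinary least-squares fit (free intercept) of summed virion-protein peak
#' area against injected capsid particles, from a reference standard of known
#' capsid concentration. Capsid number in an unknown is back-calculated as
#' (total area - intercept) / slope.
#'
#' @slot slope numeric(1), area units per capsid per injection.
#' @slot intercept numeric(1), area units.
#' @slot r2 numeric(1), coefficient of determination between 0 and 1.
#' @slot range numeric(2), calibrated range in capsids per injection;
#'   back-calculations outside it are flagged as extrapolated.
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 range = "numeric")
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope <= 0)
    msg <- c(msg, "slope must be a single positive number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@r2) != 1L || object@r2 < 0 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(object@range) != 2L || object@range[1] > object@range[2])
    msg <- c(msg, "range must be an increasing length-2 vector")
  if (length(msg)) msg else TRUE
})

#' QuantResult: per-sample capsid quantification
#'
#' Holds the back-calculated capsid number per injection, the capsid
#' concentration after correcting for injection volume and dilution, the
#' empty/full area ratio VP0/(VP2+VP4) (and its simplified VP0/VP2 form), and
#' the model-based empty-capsid fraction ratio/(1+ratio).
#'
#' @slot capsidsPerInjection numeric(1).
#' @slot capsidConc numeric(1), capsids/mL.
#' @slot efRatio numeric(1), VP0/(VP2+VP4) peak-area ratio.
#' @slot efRatioSimplified numeric(1), VP0/VP2 peak-area ratio.
#' @slot emptyFraction numeric(1) between 0 and 1.
#' @slot perVpAreas named numeric, integrated FLR area per virion protein.
#' @slot extrapolated logical(1), TRUE when the total area fell outside the
#'   standard-curve range.
#' @export
setClass("QuantResult",
  representation(capsidsPerInjection = "numeric", capsidConc = "numeric",
                 efRatio = "numeric", efRatioSimplified = "numeric",
                 emptyFraction = "numeric", perVpAreas = "numeric",
                 extrapolated = "logical")
)

setValidity("QuantResult", function(object) {
  msg <- character()
  if (object@efRatio < 0) msg <- c(msg, "efRatio must be >= 0")
  if (object@emptyFraction < 0 || object@emptyFraction > 1)
    msg <- c(msg, "emptyFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MassAssignment: a deconvoluted mass matched to a protein plus adducts
#'
#' The result of matching an observed (zero-charge) mass against candidate
#' virion proteins decorated with adduct multisets (at most one myristoyl, at
#' most three sodium replacements by default). `matched` is FALSE when no
#' combination falls within tolerance; that is a value, not an error.
#'
#' @slot observed numeric(1), observed average mass in Da.
#' @slot species character(1), matched protein name ("" when unmatched).
#' @slot adducts named integer, adduct counts (e.g. c(Myr = 1, Na = 1)).
#' @slot residual numeric(1), observed - calculated - sum(adduct deltas), Da.
#' @slot matched logical(1).
#' @export
setClass("MassAssignment",
  representation(observed = "numeric", species = "character",
                 adducts = "integer", residual = "numeric",
                 matched = "logical")
)
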