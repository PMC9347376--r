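#' Accessors for CapsidQuant classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a CapsidQuant object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromTime", function(x) standardGeneric("chromTime"))
#' @rdname accessors
#' @export
setGeneric("chromSignal", function(x) standardGeneric("chromSignal"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setGeneric("curveR2", function(x) standardGeneric("curveR2"))
#' @rdname accessors
#' @export
setGeneric("curveRange", function(x) standardGeneric("curveRange"))
#' @rdname accessors
#' @export
setGeneric("capsidsPerInjection", function(x, ...) standardGeneric("capsidsPerInjection"))
#' @rdname accessors
#' @export
setGeneric("capsidConc", function(x) standardGeneric("capsidConc"))
#' @rdname accessors
#' @export
setGeneric("efRatio", function(x) standardGeneric("efRatio"))
#' @rdname accessors
#' @export
setGeneric("efRatioSimplified", function(x) standardGeneric("efRatioSimplified"))
#' @rdname accessors
#' @export
setGeneric("emptyFractionOf", function(x) standardGeneric("emptyFractionOf"))
#' @rdname accessors
#' @export
setGeneric("perVpAreas", function(x) standardGeneric("perVpAreas"))

setMethod("chromTime", "Chromatogram", function(x) x@time)
setMethod("chromSignal", "Chromatogram", function(x) x@signal)
setMethod("channel", "Chromatogram", function(x) x@channel)
setMethod("mz", "MassSpectrum", function(x) x@mz)
setMethod("intensity", "MassSpectrum", function(x) x@intensity)
setMethod("curveSlope", "StandardCurve", function(x) x@slope)
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)
setMethod("curveR2", "StandardCurve", function(x) x@r2)
setMethod("curveRange", "StandardCurve", function(x) x@range)
setMethod("capsidConc", "QuantResult", function(x) x@capsidConc)
setMethod("efRatio", "QuantResult", function(x) x@efRatio)
setMethod("efRatioSimplified", "QuantResult", function(x) x@efRatioSimplified)
setMethod("emptyFractionOf", "QuantResult", function(x) x@emptyFraction)
setMethod("perVpAreas", "QuantResult", function(x) x@perVpAreas)

setMethod("show", "Chromatogram", function(object) {
  t <- object@time
  cat(sprintf("Chromatogram [%s]: %d points, %.3f-%.3f min\n",
              object@channel, length(t), t[1], t[length(t)]))
})

setMethod("show", "MassSpectrum", function(object) {
  n <- length(object@mz)
  if (n == 0L) {
    cat("MassSpectrum: empty\n")
  } else {
    cat(sprintf("MassSpectrum: %d points, m/z %.2f-%.2f\n",
                n, object@mz[1], object@mz[n]))
  }
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: slope %.4g area/capsid, intercept %.4g, R^2 %.6f\n",
    object@slope, object@intercept, object@r2))
  cat(sprintf("  range: %.3g - %.3g capsids/injection\n",
              object@range[1], object@range[2]))
})

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult: %.4g capsids/injection, %.4g capsids/mL%s\n",
              object@capsidsPerInjection, object@capsidConc,
              if (object@extrapolated) " (extrapolated)" else ""))
  cat(sprintf("  empty/full ratio VP0/(VP2+VP4): %.4f  (VP0/VP2: %.4f)\n",
              object@efRatio, object@efRatioSimplified))
  cat(sprintf("  empty fraction (model-based): %.4f\n", object@emptyFraction))
})

setMethod("show", "MassAssignment", function(object) {
  if (!object@matched) {
    cat(sprintf("MassAssignment: %.2f Da -> no match\n", object@observed))
    return(invisible(NULL))
  }
  add <- object@adducts[object@adducts > 0L]
  lab <- object@species
  if (length(add))
    lab <- paste0(lab, "+", paste0(ifelse(add > 1L, add, ""), names(add),
                                   collapse = "+"))
  cat(sprintf("MassAssignment: %.2f Da -> %s (residual %+.2f Da)\n",
              object@observed, lab, object@residual))
})
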