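#' Robust noise estimate for a trace
#'
#' Median absolute deviation of the first differences, scaled to the SD of
#' white noise; insensitive to peaks and slow baseline drift.
#' @noRd
traceNoise <- function(signal) {
  stats::mad(diff(signal)) / sqrt(2)
}

#' Detect chromatographic peaks
#'
#' Local-maximum detection with a prominence filter relative to a robust
#' noise estimate of the trace. Peak bounds are placed at the flanking
#' signal minima: the return-to-baseline crossing (extended to cover the
#' peak tail) towards open baseline, or the inter-peak valley when a
#' neighbouring peak interrupts the descent. Apexes are refined by parabolic
#' interpolation over the three points around the discrete maximum; widths
#' are full width at half height above the drop-line baseline; areas come
#' from [integratePeak()].
#'
#' @param chrom a [Chromatogram-class].
#' @param minProminence minimum peak prominence as a multiple of the robust
#'   noise estimate (for a noiseless trace an absolute floor of 1e-9 times
#'   the signal range is used instead).
#' @param minFwhm minimum full width at half maximum, minutes; narrower
#'   features are treated as spikes and dropped.
#' @return data.frame with columns `rt`, `area`, `height`, `fwhm`, `start`,
#'   `end`, `label` (NA until assigned), sorted by `rt`.
#' @examples
#' sim <- simulateChromatogram(sampleSpec(3e12, 0.3),
#'                             inst = instrumentSpec(seed = 7))
#' detectPeaks(sim$chromatogram)
#' @export
detectPeaks <- function(chrom, minProminence = 10, minFwhm = 0.005) {
  stopifnot(is(chrom, "Chromatogram"))
  t <- chrom@time
  y <- chrom@signal
  n <- length(y)
  noise <- traceNoise(y)
  floorAbs <- 1e-9 * max(diff(range(y)), 1e-300)
  promThresh <- max(minProminence * noise, floorAbs)

  # interior local maxima, prefiltered by elevation above the trace minimum
  d <- diff(y)
  cand <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  cand <- cand[y[cand] - min(y) > promThresh]
  if (length(cand) == 0L) return(emptyPeakTable())

  prom <- vapply(cand, function(i) peakProminence(y, i), numeric(1))
  cand <- cand[prom >= promThresh]
  if (length(cand) == 0L) return(emptyPeakTable())

  peaks <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    si <- peakBound(y, i, lim = if (k > 1L) cand[k - 1L] else 1L,
                    atEdge = k == 1L, noise = noise)
    ei <- peakBound(y, i, lim = if (k < length(cand)) cand[k + 1L] else n,
                    atEdge = k == length(cand), noise = noise)
    if (ei - si < 2L) return(NULL)
    apex <- parabolicApex(t, y, i)
    yc <- y - lineBaseline(t, y, si, ei)
    hgt <- apex$height -
      (y[si] + (y[ei] - y[si]) * (apex$rt - t[si]) / (t[ei] - t[si]))
    fw <- halfHeightWidth(t, yc, i, si, ei)
    area <- integratePeak(chrom, c(t[si], t[ei]), baselineMode = "drop_line")
    c(rt = apex$rt, area = area, height = hgt, fwhm = fw,
      start = t[si], end = t[ei])
  })
  peaks <- peaks[!vapply(peaks, is.null, logical(1))]
  if (length(peaks) == 0L) return(emptyPeakTable())
  out <- as.data.frame(do.call(rbind, peaks))
  out$label <- NA_character_
  out <- out[is.finite(out$fwhm) & out$fwhm >= minFwhm, , drop = FALSE]
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyPeakTable <- function() {
  data.frame(rt = numeric(), area = numeric(), height = numeric(),
             fwhm = numeric(), start = numeric(), end = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

# topographic prominence: height above the higher of the two side minima,
# where each side runs to the nearest higher point (or the trace edge)
peakProminence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  hl <- which(y[seq_len(i - 1L)] > h)
  leftMin <- min(y[(if (length(hl)) max(hl) else 1L):i])
  hr <- which(y[(i + 1L):n] > h)
  rightMin <- min(y[i:(if (length(hr)) i + min(hr) else n)])
  h - max(leftMin, rightMin)
}

# boundary between apex i and lim (adjacent apex, or trace edge when
# atEdge): first return to within a noise floor of the segment minimum,
# pushed outward by 60% of the descent to cover the tail; if the signal
# never returns to baseline before the next apex, fall back to the valley
peakBound <- function(y, i, lim, atEdge, noise) {
  if (i == lim) return(i)
  step <- sign(lim - i)
  idx <- seq(i, lim, by = step)
  seg <- y[idx]
  mn <- min(seg)
  thr <- max(3 * noise, 1e-9 * (y[i] - mn))
  cross <- which(seg - mn <= thr)
  vi <- which.min(seg)
  if (length(cross) == 0L) return(idx[vi])
  ci <- cross[1L]
  bi <- min(ci + ceiling(0.6 * (ci - 1L)), if (atEdge) length(idx) else vi)
  idx[max(bi, ci)]
}

parabolicApex <- function(t, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(rt = t[i], height = y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(rt = t[i], height = y2))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  dt <- t[i + 1L] - t[i]
  list(rt = t[i] + delta * dt,
       height = y2 - 0.25 * (y1 - y3) * delta)
}

lineBaseline <- function(t, y, si, ei) {
  y[si] + (y[ei] - y[si]) * (t - t[si]) / (t[ei] - t[si])
}

halfHeightWidth <- function(t, ycorr, i, si, ei) {
  half <- ycorr[i] / 2
  li <- i
  while (li > si && ycorr[li] > half) li <- li - 1L
  ri <- i
  while (ri < ei && ycorr[ri] > half) ri <- ri + 1L
  if (ycorr[li] > half || ycorr[ri] > half) return(NA_real_)
  xl <- t[li] + (t[li + 1L] - t[li]) *
    (half - ycorr[li]) / (ycorr[li + 1L] - ycorr[li])
  xr <- t[ri - 1L] + (t[ri] - t[ri - 1L]) *
    (half - ycorr[ri - 1L]) / (ycorr[ri] - ycorr[ri - 1L])
  xr - xl
}

#' Integrate a peak over a retention-time window
#'
#' Trapezoidal integral of the baseline-subtracted signal. `drop_line`
#' subtracts the straight line joining the signal at the two window bounds
#' (each endpoint estimated as a 5-point median so single noise excursions
#' do not tilt the baseline); `valley_to_valley` first moves each bound to
#' the nearest local signal minimum before drawing the line. Negative
#' integrals (possible when the window is pure noise) are clipped to zero
#' with a warning.
#'
#' @param chrom a [Chromatogram-class].
#' @param bounds length-2 numeric, start/end in minutes, inside the trace.
#' @param baselineMode `"drop_line"` (default) or `"valley_to_valley"`.
#' @return area in detector units x minutes, >= 0.
#' @export
integratePeak <- function(chrom, bounds,
                          baselineMode = c("drop_line", "valley_to_valley")) {
  stopifnot(is(chrom, "Chromatogram"), length(bounds) == 2L)
  baselineMode <- match.arg(baselineMode)
  t <- chrom@time
  y <- chrom@signal
  if (bounds[1] >= bounds[2]) stop("empty integration window")
  if (bounds[1] < t[1] - 1e-9 || bounds[2] > t[length(t)] + 1e-9)
    stop("bounds outside trace span")
  si <- which.min(abs(t - bounds[1]))
  ei <- which.min(abs(t - bounds[2]))
  if (ei - si < 1L) stop("empty integration window")
  if (baselineMode == "valley_to_valley") {
    si <- localMinimumNear(y, si)
    ei <- localMinimumNear(y, ei)
    if (ei - si < 1L) stop("empty integration window")
  }
  ys <- medianAt(y, si)
  ye <- medianAt(y, ei)
  idx <- si:ei
  base <- ys + (ye - ys) * (t[idx] - t[si]) / (t[ei] - t[si])
  yc <- y[idx] - base
  a <- sum(diff(t[idx]) * (yc[-1] + yc[-length(yc)]) / 2)
  if (a < 0) {
    warning("negative integral clipped to zero")
    a <- 0
  }
  a
}

medianAt <- function(y, i, k = 2L) {
  stats::median(y[max(1L, i - k):min(length(y), i + k)])
}

localMinimumNear <- function(y, i, span = 20L) {
  lo <- max(1L, i - span)
  hi <- min(length(y), i + span)
  lo + which.min(y[lo:hi]) - 1L
}

#' Resolution between two chromatographic peaks
#'
#' Half-height formula `Rs = 1.18 (rt2 - rt1) / (fwhm1 + fwhm2)` (the
#' European Pharmacopoeia convention). The returned list includes a `pass`
#' flag against the usual regulatory acceptance threshold Rs > 2 for the
#' critical pair in method validation.
#'
#' @param p1,p2 single-row peak data.frames (or lists) with `rt` and `fwhm`;
#'   `p1` must elute first.
#' @param threshold acceptance threshold for the `pass` flag.
#' @return list with `pair` (labels if present), `rs`, and `pass`.
#' @examples
#' peakResolution(list(rt = 7.0, fwhm = 0.10), list(rt = 7.5, fwhm = 0.10))
#' @export
peakResolution <- function(p1, p2, threshold = 2) {
  rt1 <- p1$rt; rt2 <- p2$rt
  w1 <- p1$fwhm; w2 <- p2$fwhm
  if (rt1 > rt2) stop("p1 must elute before p2")
  if (w1 <= 0 || w2 <= 0) stop("zero or negative peak width")
  rs <- 1.18 * (rt2 - rt1) / (w1 + w2)
  lab <- c(if (!is.null(p1$label)) p1$label else NA_character_,
           if (!is.null(p2$label)) p2$label else NA_character_)
  list(pair = lab, rs = rs, pass = rs > threshold)
}

#' Assign detected peaks to virion proteins by retention time
#'
#' Each VP takes the nearest unassigned peak within `tol` minutes of its
#' reference retention time. When two VPs compete for one peak the conflict
#' is resolved by smaller |delta rt| first, then by larger peak area; the
#' collision is reported as a message. VPs with no peak within tolerance
#' are reported absent — the expected outcome for VP0 in purified full
#' capsids (and for VP4 on the FLR channel, where it is nearly dark).
#'
#' @param peaks data.frame as returned by [detectPeaks()].
#' @param refs named numeric of reference retention times, names are VP
#'   labels.
#' @param tol matching tolerance in minutes.
#' @return list with `peaks` (the input with `label` filled) and `absent`
#'   (character vector of unmatched VP names).
#' @export
assignPeaks <- function(peaks, refs, tol = 0.3) {
  if (length(refs) == 0L) stop("empty reference table")
  out <- peaks
  out$label <- rep(NA_character_, nrow(out))
  if (nrow(peaks) == 0L)
    return(list(peaks = out, absent = names(refs)))
  cand <- expand.grid(vp = seq_along(refs), pk = seq_len(nrow(peaks)))
  cand$drt <- abs(unname(refs)[cand$vp] - peaks$rt[cand$pk])
  cand <- cand[cand$drt <= tol, , drop = FALSE]
  cand <- cand[order(cand$drt, -peaks$area[cand$pk]), , drop = FALSE]
  usedVp <- logical(length(refs))
  usedPk <- logical(nrow(peaks))
  collided <- integer(0)
  for (r in seq_len(nrow(cand))) {
    v <- cand$vp[r]; p <- cand$pk[r]
    if (usedPk[p] && !usedVp[v]) collided <- c(collided, p)
    if (usedPk[p] || usedVp[v]) next
    usedVp[v] <- TRUE
    usedPk[p] <- TRUE
    out$label[p] <- names(refs)[v]
  }
  if (length(collided))
    message("peak collision(s) resolved by |delta rt| then area at rt ",
            paste(round(peaks$rt[unique(collided)], 3), collapse = ", "))
  list(peaks = out, absent = names(refs)[!usedVp])
}

#' Percent relative standard deviation
#'
#' `100 x sd / mean` with the n-1 (sample) standard deviation; the
#' convention used throughout assay-precision reporting.
#'
#' @param values numeric, length >= 2, nonzero mean.
#' @return percent RSD.
#' @examples
#' rsd(c(4.336, 4.334, 4.336, 4.374, 4.370, 4.375))
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  100 * stats::sd(values) / m
}
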