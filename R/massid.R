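# Average residue masses (Da) of the 20 standard amino acids and water;
# standard IUPAC average atomic weights.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153
PROTON_MASS <- 1.00728

#' Average mass of a protein sequence
#'
#' Sum of average residue masses plus one water. The empty sequence returns
#' the mass of water.
#'
#' @param sequence character(1), one-letter amino-acid codes.
#' @return average mass in Da.
#' @examples
#' averageMass("G")   # 75.07
#' averageMass("GG")  # 132.12
#' @export
averageMass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(WATER_MASS)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(AVERAGE_RESIDUE_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(AVERAGE_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Default adduct table for intact virion proteins
#'
#' Myristoylation (+210.36 Da average, the C14 N-terminal acyl chain found
#' on VP0 and VP4) and sodium adduction (+21.98 Da per H-to-Na replacement
#' on the neutral mass).
#'
#' @return data.frame with `name`, `delta` (Da), `maxCount`.
#' @export
defaultAdducts <- function() {
  data.frame(name = c("Myr", "Na"), delta = c(210.36, 21.98),
             maxCount = c(1L, 3L), stringsAsFactors = FALSE)
}

#' Default candidate protein table
#'
#' The five Coxsackievirus A21 virion proteins with sequence-calculated
#' average masses.
#'
#' @return data.frame with `name`, `mass` (Da).
#' @export
defaultCandidates <- function() {
  vp <- defaultVPTable()
  data.frame(name = vp$name, mass = vp$calcMass, stringsAsFactors = FALSE)
}

#' Charge-state deconvolution of an ESI spectrum
#'
#' A transparent charge-ladder scorer: each candidate neutral mass M on a
#' uniform grid is scored by summing the interpolated spectrum intensity at
#' its predicted m/z positions `(M + z * 1.00728) / z` over the charge
#' range, restricted to the observed m/z window. The raw sum is weighted by
#' the longest consecutive run of charge states carrying signal, as a
#' fraction of the in-window charge states considered: a genuine
#' multi-charge envelope is consecutive in z, whereas a harmonic artifact
#' at twice the true mass only matches through every other charge and is
#' suppressed. Components are extracted greedily: the best-scoring mass
#' (apex refined by parabolic interpolation) is accepted, its predicted
#' peaks are stripped from the working spectrum, and the grid is re-scored,
#' so sub-harmonic ghosts (half the true mass, which matches the same
#' peaks) cannot survive the extraction of their parent. Extraction stops
#' when the best remaining score falls below `threshold` times the first
#' one.
#'
#' @param spectrum a [MassSpectrum-class] (profile mode).
#' @param massRange length-2 numeric, candidate mass window in Da.
#' @param charges integer vector of charge states to sum over.
#' @param step mass grid step in Da.
#' @param threshold stop extracting when the best remaining score falls
#'   below this fraction of the first component's score.
#' @param minSupport minimum consecutive-run fraction of in-window charges.
#' @param maxComponents upper bound on extracted components.
#' @param stripWidth half-width (m/z) of the region removed around each
#'   predicted peak of an accepted component.
#' @return data.frame with `mass` and `score`, in extraction order
#'   (strongest first; 0 rows for an empty or featureless spectrum).
#' @examples
#' sp <- simulateEsiSpectrum(29897, charges = 12:25)
#' deconvoluteSpectrum(sp, c(25000, 35000), charges = 5:30)
#' @export
deconvoluteSpectrum <- function(spectrum, massRange, charges, step = 0.5,
                                threshold = 0.1, minSupport = 0.1,
                                maxComponents = 10L, stripWidth = 1.5) {
  stopifnot(is(spectrum, "MassSpectrum"), length(massRange) == 2L,
            length(charges) >= 1L)
  if (step <= 0) stop("mass grid step must be positive")
  mzv <- spectrum@mz
  iv <- spectrum@intensity
  empty <- data.frame(mass = numeric(), score = numeric())
  if (length(mzv) < 2L || max(iv) <= 0) return(empty)
  window <- range(mzv)
  grid <- seq(massRange[1], massRange[2], by = step)
  charges <- sort(charges)
  sigFloor <- 0.02 * max(iv)

  out <- empty
  firstScore <- NA_real_
  for (comp in seq_len(maxComponents)) {
    sc <- chargeLadderScore(grid, mzv, iv, charges, window, sigFloor,
                            minSupport)
    best <- which.max(sc)
    if (sc[best] <= 0) break
    if (is.na(firstScore)) firstScore <- sc[best]
    if (sc[best] < threshold * firstScore) break
    ap <- parabolicApex(grid, sc, best)
    out <- rbind(out, data.frame(mass = ap$rt, score = ap$height))
    # strip the accepted component's predicted peaks and re-score
    for (z in charges) {
      centre <- (ap$rt + z * PROTON_MASS) / z
      iv[mzv >= centre - stripWidth & mzv <= centre + stripWidth] <- 0
    }
    if (max(iv) <= sigFloor) break
  }
  out
}

# support-weighted charge-ladder score over a mass grid; one vectorised
# interpolation per charge
chargeLadderScore <- function(grid, mzv, iv, charges, window, sigFloor,
                              minSupport) {
  ng <- length(grid)
  raw <- numeric(ng)
  considered <- numeric(ng)
  run <- numeric(ng)
  maxRun <- numeric(ng)
  for (z in charges) {
    pred <- (grid + z * PROTON_MASS) / z
    inWin <- pred >= window[1] & pred <= window[2]
    val <- numeric(ng)
    if (any(inWin))
      val[inWin] <- stats::approx(mzv, iv, xout = pred[inWin], yleft = 0,
                                  yright = 0, ties = "ordered")$y
    raw <- raw + val
    considered <- considered + inWin
    hit <- val > sigFloor
    run <- ifelse(hit, run + 1, 0)
    maxRun <- pmax(maxRun, run)
  }
  support <- ifelse(considered > 0, maxRun / considered, 0)
  ifelse(support >= minSupport, raw * support, 0)
}

#' Assign an observed mass to a protein plus adducts
#'
#' Exhaustive search over every candidate protein and every adduct multiset
#' (by default up to one myristoyl and up to three sodiums). The assignment
#' minimising `(|residual|, total adduct count)` lexicographically wins; if
#' nothing falls within `tol` a no-match [MassAssignment-class] is returned
#' (a value, not an error).
#'
#' @param observed numeric(1), observed neutral average mass in Da.
#' @param candidates data.frame with `name`, `mass`; see
#'   [defaultCandidates()].
#' @param adducts data.frame with `name`, `delta`, `maxCount`; see
#'   [defaultAdducts()].
#' @param tol matching tolerance in Da.
#' @return a [MassAssignment-class].
#' @examples
#' assignMass(7516)   # VP4 + Myr
#' assignMass(37418)  # VP0 + Myr + Na
#' @export
assignMass <- function(observed, candidates = defaultCandidates(),
                       adducts = defaultAdducts(), tol = 5) {
  stopifnot(length(observed) == 1L, is.finite(observed))
  if (nrow(candidates) == 0L) stop("no candidate proteins")
  if (tol <= 0) stop("tolerance must be positive")
  counts <- do.call(expand.grid, lapply(adducts$maxCount, function(m) 0:m))
  names(counts) <- adducts$name
  shift <- as.matrix(counts) %*% adducts$delta
  best <- NULL
  for (ci in seq_len(nrow(candidates))) {
    res <- observed - candidates$mass[ci] - shift
    for (ai in seq_along(res)) {
      key <- c(abs(res[ai]), sum(counts[ai, ]))
      if (is.null(best) || key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2])) {
        best <- list(key = key, ci = ci, ai = ai, residual = res[ai])
      }
    }
  }
  if (abs(best$residual) > tol) {
    return(new("MassAssignment", observed = observed, species = "",
               adducts = stats::setNames(integer(nrow(adducts)), adducts$name),
               residual = NA_real_, matched = FALSE))
  }
  new("MassAssignment", observed = observed,
      species = candidates$name[best$ci],
      adducts = stats::setNames(as.integer(counts[best$ai, ]), adducts$name),
      residual = unname(best$residual), matched = TRUE)
}

#' Observed-minus-calculated mass table
#'
#' Pairs observed masses with candidate calculated masses by protein name
#' and reports the integer-rounded difference; missing pairs leave a gap
#' (NA).
#'
#' @param candidates data.frame with `name`, `mass`.
#' @param observations named numeric of observed masses.
#' @return data.frame with `name`, `calculated`, `observed`, `delta`.
#' @examples
#' massDeltaTable(observations = c(VP0 = 37418, VP1 = 33230, VP2 = 29922,
#'                                 VP3 = 26591, VP4 = 7516))
#' @export
massDeltaTable <- function(candidates = defaultCandidates(), observations) {
  obs <- observations[match(candidates$name, names(observations))]
  data.frame(name = candidates$name,
             calculated = candidates$mass,
             observed = unname(obs),
             delta = round(unname(obs) - candidates$mass),
             stringsAsFactors = FALSE)
}
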