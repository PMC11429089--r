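#' @include specs.R
NULL

# Run expr with a fixed, fully specified RNG state, restoring the caller's
# state afterwards. No global random state leaks out of the simulator.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("an explicit seed is required")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Gaussian-blurred indicator of a rotated square, evaluated analytically.
# Blurring the transmission map of a uniform-thickness insert is linear in
# its indicator, so the erf product below is the exact Gaussian-PSF blur.
.blurredSquareMask <- function(rowsMM, colsMM, square, sigma) {
  th <- square[["angleDeg"]] * pi / 180
  dr <- rowsMM - square[["rowCenter"]]
  dc <- colsMM - square[["colCenter"]]
  u <- outer(dr * cos(th), dc * sin(th), "+")
  v <- outer(-dr * sin(th), dc * cos(th), "+")
  h <- square[["side"]] / 2
  if (sigma > 0) {
    gu <- stats::pnorm((h - u) / sigma) + stats::pnorm((h + u) / sigma) - 1
    gv <- stats::pnorm((h - v) / sigma) + stats::pnorm((h + v) / sigma) - 1
  } else {
    gu <- (abs(u) <= h) * 1
    gv <- (abs(v) <= h) * 1
  }
  gu * gv
}

.muFor <- function(beam, material) {
  if (!material %in% names(beam@mu))
    stop(sprintf("no attenuation coefficient configured for material '%s'",
                 material))
  beam@mu[[material]]
}

# Transmission (Beer-Lambert) times heel field on a pixel-index subgrid.
# blur = TRUE applies the detector's Gaussian PSF to the insert edges.
.transmissionGrid <- function(phantom, beam, detector, rows, cols,
                              blur = TRUE) {
  validObject(phantom)
  p <- detector@pitch
  rowsMM <- (rows - 0.5) * p
  colsMM <- (cols - 0.5) * p
  sigma <- if (blur) detector@psfSigma else 0
  tpmma <- exp(-.muFor(beam, "PMMA") * phantom@pmmaThickness)
  tr <- matrix(tpmma, nrow = length(rows), ncol = length(cols))
  if (phantom@cuPresent) {
    f <- exp(-.muFor(beam, "Cu") * phantom@cuSquare[["thickness"]])
    tr <- tr * (1 + (f - 1) *
                  .blurredSquareMask(rowsMM, colsMM, phantom@cuSquare, sigma))
  }
  if (phantom@alPresent) {
    f <- exp(-.muFor(beam, "Al") * phantom@alSquare[["thickness"]])
    tr <- tr * (1 + (f - 1) *
                  .blurredSquareMask(rowsMM, colsMM, phantom@alSquare, sigma))
  }
  heel <- heelField(detector)[rows, cols, drop = FALSE]
  list(transmission = tr, heel = heel)
}

#' Expected (noise-free) detector signal of an acquisition
#'
#' Composes Beer-Lambert transmission through the PMMA slab and the
#' rotated insert squares, the multiplicative heel field, the detector
#' gain and the Gaussian presampling blur into the expected signal map
#'
#' `mean = dcOffset + gain * mAs * heel * blur(transmission)`.
#'
#' The blur is applied analytically to the insert edges (the transmission
#' of a uniform-thickness insert is linear in its indicator function), so
#' the map is deterministic and free of resampling artefacts; the realized
#' edge profile is an exact Gaussian error function of width `psfSigma`.
#'
#' @param phantom a [PhantomSpec-class].
#' @param beam a [BeamSpec-class].
#' @param detector a [DetectorSpec-class].
#' @param exposure an [ExposureSettings-class] (only `mas` is used here).
#' @return numeric matrix of expected counts (detector grid).
#' @examples
#' det <- defaultDetector()
#' m <- buildMeanSignalMap(iaeaPhantom(det), defaultBeam(), det,
#'                         ExposureSettings(28, 100, "manual"))
#' @export
buildMeanSignalMap <- function(phantom, beam, detector, exposure) {
  validObject(detector); validObject(beam); validObject(exposure)
  if (exposure@mas == 0)
    return(matrix(detector@dcOffset, detector@nrow, detector@ncol))
  g <- .transmissionGrid(phantom, beam, detector,
                         seq_len(detector@nrow), seq_len(detector@ncol),
                         blur = TRUE)
  detector@dcOffset +
    detector@gain * exposure@mas * g$heel * g$transmission
}

#' Simulate one noisy acquisition from an expected-signal map
#'
#' Adds quantum noise of variance `quantumGain * (mean - dcOffset)` plus
#' Gaussian electronic noise of SD `electronicSD`, rounds to integer
#' counts and clips to the 16-bit range. The same seed yields a
#' bit-identical image; the caller's RNG state is untouched.
#'
#' @param meanMap expected-signal matrix (pixelwise >= `dcOffset`).
#' @param detector a [DetectorSpec-class].
#' @param seed integer seed, recorded in the image metadata.
#' @param meta extra metadata merged into the image (e.g. `exposure`,
#'   `phantom`).
#' @return a [MammoImage-class].
#' @export
simulateAcquisition <- function(meanMap, detector, seed, meta = list()) {
  validObject(detector)
  if (any(meanMap < detector@dcOffset - 1e-9))
    stop("meanMap must be >= dcOffset pixelwise")
  v <- detector@quantumGain * (meanMap - detector@dcOffset) +
    detector@electronicSD^2
  px <- .withSeed(seed, {
    meanMap + stats::rnorm(length(meanMap)) * sqrt(v)
  })
  px <- round(pmin(pmax(px, 0), 65535))
  dim(px) <- dim(meanMap)
  MammoImage(px, pitch = detector@pitch, dcOffset = detector@dcOffset,
             meta = c(meta, list(seed = as.integer(seed))))
}

#' Emulate the automatic exposure control servo
#'
#' Returns the exposure the AEC would select for a phantom: kVp from a
#' compressed-thickness lookup, and the mAs that brings the mean expected
#' signal over the sensor footprint to `targetSignal` counts above the DC
#' offset, rounded to the mAs quantum of the console. The servo is
#' flat-field calibrated per position: the footprint signal is referenced
#' to the local heel level, so on a homogeneous slab all seven positions
#' select the same mAs and any mAs increase reflects attenuation by
#' radiopaque material over the sensor alone.
#'
#' @param phantom a [PhantomSpec-class].
#' @param beam a [BeamSpec-class].
#' @param detector a [DetectorSpec-class].
#' @param aecPosition sensor position 1-7.
#' @param targetSignal servo target in counts above the DC offset.
#' @param masQuantum mAs rounding step of the console.
#' @param masCap maximum deliverable mAs; an unreachable target stops with
#'   a saturation error.
#' @return an [ExposureSettings-class] (automatic mode).
#' @examples
#' det <- defaultDetector()
#' emulateAEC(iaeaPhantom(det), defaultBeam(), det, aecPosition = 4)
#' @export
emulateAEC <- function(phantom, beam, detector, aecPosition,
                       targetSignal = 460, masQuantum = 0.5, masCap = 500) {
  validObject(beam); validObject(detector)
  roi <- aecSensorROI(aecPosition, detector)
  rows <- seq.int(roi@row0 + 1L, roi@row0 + roi@height)
  cols <- seq.int(roi@col0 + 1L, roi@col0 + roi@width)
  if (max(rows) > detector@nrow || max(cols) > detector@ncol)
    stop("AEC sensor footprint falls outside the detector")
  g <- .transmissionGrid(phantom, beam, detector, rows, cols, blur = FALSE)
  # heel-referenced mean transmission over the footprint
  atten <- sum(g$heel * g$transmission) / sum(g$heel)
  masRaw <- targetSignal / (detector@gain * atten)
  mas <- round(masRaw / masQuantum) * masQuantum
  if (mas > masCap)
    stop(sprintf(paste0("AEC saturation: target %g counts needs %.1f mAs ",
                        "(cap %g) at position %d"),
                 targetSignal, masRaw, masCap, aecPosition))
  ExposureSettings(kvp = kvpForThickness(phantom@pmmaThickness), mas = mas,
                   mode = "automatic", aecPosition = aecPosition)
}

#' Simulate a flat-field acquisition of a uniform PMMA slab
#'
#' @param pmmaThickness slab thickness (mm); 40 mm is the AEC sensitivity
#'   test condition.
#' @param detector a [DetectorSpec-class].
#' @param beam a [BeamSpec-class].
#' @param exposure an [ExposureSettings-class]; if `NULL` the AEC selects
#'   it at `aecPosition`.
#' @param seed integer seed.
#' @param aecPosition sensor position used when `exposure` is `NULL`
#'   (default 2, the console default).
#' @return a [MammoImage-class].
#' @examples
#' ff <- generateFlatField(40, defaultDetector(), defaultBeam(), seed = 1)
#' @export
generateFlatField <- function(pmmaThickness = 40,
                              detector = defaultDetector(),
                              beam = defaultBeam(), exposure = NULL,
                              seed, aecPosition = 2) {
  phantom <- pmmaSlab(detector, pmmaThickness)
  if (is.null(exposure))
    exposure <- emulateAEC(phantom, beam, detector, aecPosition)
  m <- buildMeanSignalMap(phantom, beam, detector, exposure)
  simulateAcquisition(m, detector, seed,
                      meta = list(exposure = exposure, phantom = phantom))
}

#' Simulate a phantom acquisition end to end
#'
#' Convenience wrapper: AEC (automatic mode) or given manual settings,
#' expected-signal map, then one noise realization.
#'
#' @param phantom a [PhantomSpec-class].
#' @param detector a [DetectorSpec-class].
#' @param beam a [BeamSpec-class].
#' @param exposure an [ExposureSettings-class], or `NULL` to let the AEC
#'   choose at `aecPosition`.
#' @param seed integer seed.
#' @param aecPosition sensor position for `exposure = NULL`.
#' @return a [MammoImage-class].
#' @export
simulatePhantom <- function(phantom = iaeaPhantom(),
                            detector = defaultDetector(),
                            beam = defaultBeam(), exposure = NULL, seed,
                            aecPosition = 2) {
  if (is.null(exposure))
    exposure <- emulateAEC(phantom, beam, detector, aecPosition)
  m <- buildMeanSignalMap(phantom, beam, detector, exposure)
  simulateAcquisition(m, detector, seed,
                      meta = list(exposure = exposure, phantom = phantom))
}
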