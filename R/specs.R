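#' @include AllClasses.R
NULL

#' Construct an [ImageROI-class]
#'
#' @param row0,col0 0-based origin (row 0 = chest-wall edge).
#' @param height,width extent in pixels.
#' @param label optional label.
#' @return an [ImageROI-class].
#' @examples
#' imageROI(0, 0, 64, 64, label = "CW1")
#' @export
imageROI <- function(row0, col0, height, width, label = NA_character_) {
  new("ImageROI", row0 = as.integer(row0), col0 = as.integer(col0),
      height = as.integer(height), width = as.integer(width),
      label = as.character(label))
}

#' Construct a [MammoImage-class]
#'
#' @param pixels numeric matrix of counts.
#' @param pitch pixel pitch (mm).
#' @param dcOffset detector DC offset (counts).
#' @param meta metadata list (exposure, phantom, seed, ...).
#' @return a [MammoImage-class].
#' @export
MammoImage <- function(pixels, pitch, dcOffset = 50, meta = list()) {
  new("MammoImage", pixels = pixels, pitch = pitch, dcOffset = dcOffset,
      meta = meta)
}

#' Default detector models
#'
#' The full-size frame mirrors a 24 x 29 cm^2 amorphous-selenium panel at
#' 70 um pitch (3428 x 4142 px) with a DC offset of 50 counts. The default
#' `"test"` frame is a 512 x 640 px cut-down at the same pitch so the whole
#' analysis chain runs in seconds; ROI sizes elsewhere are held fixed in
#' pixels so statistics transfer between frame sizes. Gain and noise
#' defaults are calibrated so a flat field exposed to the AEC target signal
#' shows per-ROI SNR near 55 and corner-to-centre SNR deviations matching a
#' heel-effect pattern of a clinical unit (chest-wall corners a few percent
#' above centre, nipple corners 20-30 % below).
#'
#' @param frame `"test"` (512 x 640), `"full"` (3428 x 4142) or `"custom"`
#'   (give `nrow`/`ncol`).
#' @param nrow,ncol grid size for `frame = "custom"`.
#' @param heelAmplitude 0 disables the heel field, 1 (default) applies it
#'   fully.
#' @param electronicSD additive electronic noise SD in counts.
#' @param psfSigma Gaussian presampling blur sigma (mm).
#' @return a [DetectorSpec-class].
#' @examples
#' defaultDetector()
#' defaultDetector("custom", nrow = 1024, ncol = 1280)
#' @export
defaultDetector <- function(frame = c("test", "full", "custom"),
                            nrow = NULL, ncol = NULL,
                            heelAmplitude = 1, electronicSD = 3,
                            psfSigma = 0.035) {
  frame <- match.arg(frame)
  dims <- switch(frame,
    test   = c(512L, 640L),
    full   = c(3428L, 4142L),
    custom = c(as.integer(nrow), as.integer(ncol)))
  if (frame == "custom" && (is.null(nrow) || is.null(ncol)))
    stop("frame = 'custom' requires nrow and ncol")
  new("DetectorSpec", nrow = dims[1], ncol = dims[2], pitch = 0.07,
      dcOffset = 50, gain = 70, quantumGain = 0.17,
      electronicSD = electronicSD, psfSigma = psfSigma,
      heelAmplitude = heelAmplitude, heelCW = 1.113,
      heelNipple = 0.576, heelTilt = 0.06)
}

#' Default W/Rh beam model
#'
#' Monoenergetic-equivalent beam with effective attenuation coefficients
#' for PMMA, copper and aluminium. These are calibration constants, not
#' physical narrow-beam coefficients: they are chosen so the simulated AEC
#' servo reproduces the exposure inflation seen when the sensor sits under
#' the radiopaque square (roughly +80 % mAs) and so the Al-square contrast
#' lands near 0.13, typical of a thin Al insert at mammographic energies.
#'
#' @param kvp tube voltage; the effective coefficients are defined at the
#'   28 kVp operating point and held fixed across the narrow kVp range the
#'   AEC uses.
#' @return a [BeamSpec-class].
#' @export
defaultBeam <- function(kvp = 28) {
  new("BeamSpec", kvp = kvp, targetFilter = "W/Rh",
      mu = c(PMMA = 0.060, Cu = 0.598, Al = 0.68),
      tubeOutput = 0.0167, hvl = hvlForKvp(kvp), sourceToDetector = 700)
}

#' Half-value layer lookup (W/Rh)
#'
#' @param kvp tube voltage (kV).
#' @return HVL in mm Al.
#' @export
hvlForKvp <- function(kvp) {
  # linear ramp around the 28 kVp anchor of 0.53 mm Al
  0.53 + 0.015 * (kvp - 28)
}

#' kVp selected by the generator from compressed thickness
#'
#' Step lookup mimicking the clinical spread (28 kVp around 4-5 cm,
#' stepping up ~1-2 kVp per extra centimetre).
#'
#' @param thickness compressed thickness (mm).
#' @return kVp.
#' @export
kvpForThickness <- function(thickness) {
  breaks <- c(-Inf, 50, 60, 65, 70, Inf)
  kvps <- c(28, 29, 30, 32, 34)
  kvps[findInterval(thickness, breaks, left.open = TRUE)]
}

#' IAEA-style phantom scaled to a detector frame
#'
#' A PMMA slab covering the full detector, a thick copper square near the
#' chest-wall edge rotated by a few degrees (its sloping sides are the MTF
#' edges; it also stands in for a radiopaque implant under the first AEC
#' positions), and a thin aluminium square in the homogeneous half of the
#' field for contrast measurements. The insert layout is defined as
#' fractions of the frame so that scaled-down and full frames carry the
#' same relative geometry; in the default 512 x 640 test frame the copper
#' square is 160 px on a side centred 88 px from the chest wall and the
#' aluminium square 64 px in the homogeneous band, offset from the
#' centre-line so no AEC sensor footprint touches it.
#'
#' @param detector a [DetectorSpec-class] fixing the lateral size.
#' @param pmmaThickness PMMA thickness in mm (default 45).
#' @param cuAngle rotation of the Cu square in degrees (default 3).
#' @param withCu,withAl logical, include the inserts.
#' @return a [PhantomSpec-class].
#' @examples
#' iaeaPhantom(defaultDetector())
#' @export
iaeaPhantom <- function(detector = defaultDetector(), pmmaThickness = 45,
                        cuAngle = 3, withCu = TRUE, withAl = TRUE) {
  H <- detector@nrow * detector@pitch
  W <- detector@ncol * detector@pitch
  cu <- c(rowCenter = 0.172 * H, colCenter = 0.5 * W, side = 0.3125 * H,
          thickness = 1.0, angleDeg = cuAngle)
  al <- c(rowCenter = 0.52 * H, colCenter = 0.28 * W, side = 0.125 * H,
          thickness = 0.2, angleDeg = 0)
  new("PhantomSpec", pmmaThickness = pmmaThickness, lateralSize = c(H, W),
      cuSquare = cu, alSquare = al, cuPresent = withCu, alPresent = withAl)
}

#' Uniform PMMA slab (no inserts)
#'
#' @param detector a [DetectorSpec-class].
#' @param pmmaThickness slab thickness in mm (default 40, the flat-field
#'   thickness of the AEC sensitivity test).
#' @return a [PhantomSpec-class] with no inserts.
#' @export
pmmaSlab <- function(detector = defaultDetector(), pmmaThickness = 40) {
  iaeaPhantom(detector, pmmaThickness = pmmaThickness,
              withCu = FALSE, withAl = FALSE)
}

#' AEC sensor footprint for positions 1-7
#'
#' Seven rectangular footprints along the chest-wall-to-nipple axis on the
#' frame centre-line, position 1 closest to the chest wall. With the
#' default phantom, positions 1 and 2 lie fully under the copper square,
#' position 3 half under it, and positions 4-7 outside it.
#'
#' @param position integer 1-7.
#' @param detector a [DetectorSpec-class].
#' @return an [ImageROI-class].
#' @export
aecSensorROI <- function(position, detector = defaultDetector()) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > 7L)
    stop("aec position must be an integer in 1..7")
  nr <- detector@nrow; nc <- detector@ncol
  h <- max(2L, as.integer(round(0.078 * nr)))
  w <- max(2L, as.integer(round(0.0875 * nc)))
  centerRow <- (0.078 + 0.125 * (position - 1L)) * nr
  imageROI(round(centerRow - h / 2), round(nc / 2 - w / 2), h, w,
           label = sprintf("AEC%d", position))
}

#' Default NPWE eye filter
#'
#' Nominal display magnification 1.5, viewing distance 400 mm, band-pass
#' peak at 4 cycles/degree.
#'
#' @return an [EyeFilterSpec-class].
#' @export
defaultEyeFilter <- function() {
  new("EyeFilterSpec", viewingDistance = 400, magnification = 1.5,
      peakFrequency = 4, exponent = 1.3)
}

#' Construct an [ExposureSettings-class]
#'
#' @param kvp tube voltage.
#' @param mas current-time product.
#' @param mode "automatic" or "manual".
#' @param aecPosition sensor position 1-7 (automatic mode only).
#' @param masReductionLevel console mAs reduction level (manual mode).
#' @return an [ExposureSettings-class].
#' @export
ExposureSettings <- function(kvp, mas, mode = c("manual", "automatic"),
                             aecPosition = NA, masReductionLevel = 0) {
  mode <- match.arg(mode)
  new("ExposureSettings", kvp = kvp, mas = mas, mode = mode,
      aecPosition = as.integer(aecPosition),
      masReductionLevel = as.integer(masReductionLevel))
}

#' Heel-effect field of a detector
#'
#' Multiplicative non-uniformity in (0, 1]. Along the
#' chest-wall-to-nipple axis the log-profile is a three-plateau curve:
#' level `heelCW` on the chest-wall fifth of the frame, unit level in the
#' central band and `heelNipple` on the nipple fifth, joined by
#' smoothstep transitions over the row-fraction bands (0.16, 0.25) and
#' (0.64, 0.84). A small linear cross-tilt `1 + heelTilt*(cfrac - 1/2)`
#' splits the two corners of each side. The field is rescaled to maximum
#' 1 and blended with a flat field by `heelAmplitude`.
#'
#' @param detector a [DetectorSpec-class].
#' @param nrow,ncol grid size; defaults to the detector grid.
#' @return matrix of heel multipliers in (0, 1].
#' @export
heelField <- function(detector, nrow = detector@nrow, ncol = detector@ncol) {
  tilt <- detector@heelTilt; amp <- detector@heelAmplitude
  x <- (seq_len(nrow) - 0.5) / nrow
  s3 <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    3 * t^2 - 2 * t^3
  }
  lnProf <- log(detector@heelCW) * (1 - s3((x - 0.16) / 0.09)) +
    log(detector@heelNipple) * s3((x - 0.64) / 0.20)
  rowProf <- exp(lnProf)
  rowProf <- rowProf / max(rowProf)
  cfrac <- (seq_len(ncol) - 0.5) / ncol
  colProf <- 1 + tilt * (cfrac - 0.5)
  colProf <- colProf / max(colProf)
  h <- rowProf %o% colProf
  (1 - amp) + amp * h
}
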