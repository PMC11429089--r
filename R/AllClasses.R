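#' @import methods
NULL

#' Rectangular region of interest in pixel coordinates
#'
#' A 0-based, half-open rectangle: rows `row0 .. row0 + height - 1` and
#' columns `col0 .. col0 + width - 1` of an image matrix. Row 0 is the
#' chest-wall edge of the detector by convention.
#'
#' @slot row0,col0 integer, 0-based origin.
#' @slot height,width integer, extent in pixels (> 0).
#' @slot label character, optional label (e.g. "C", "CW1", "AL", "BG").
#' @export
setClass("ImageROI",
  representation(row0 = "integer", col0 = "integer",
                 height = "integer", width = "integer", label = "character"),
  prototype(label = NA_character_))

setValidity("ImageROI", function(object) {
  if (length(object@row0) != 1L || length(object@col0) != 1L ||
      length(object@height) != 1L || length(object@width) != 1L)
    return("row0, col0, height, width must be scalars")
  if (object@row0 < 0L || object@col0 < 0L) return("origin must be >= 0")
  if (object@height <= 0L || object@width <= 0L)
    return("height and width must be > 0")
  TRUE
})

#' Phantom geometry: PMMA slab with radiopaque inserts
#'
#' Describes a uniform PMMA attenuator carrying a thick copper square (the
#' implant stand-in, whose slanted sides supply the MTF edges) and a thin
#' aluminium square (the contrast insert for SDNR and the NPWE task
#' contrast). All lengths are in millimetres. Insert rectangles are given by
#' their centre (row, col, measured from the chest-wall edge), side length,
#' material thickness and in-plane rotation angle in degrees.
#'
#' @slot pmmaThickness numeric, PMMA thickness (mm).
#' @slot lateralSize numeric length 2, (height, width) of the slab (mm);
#'   height runs along the chest-wall-to-nipple axis.
#' @slot cuSquare,alSquare numeric length 5 or NULL-like empty: named
#'   `c(rowCenter, colCenter, side, thickness, angleDeg)`.
#' @slot cuPresent,alPresent logical flags.
#' @export
setClass("PhantomSpec",
  representation(pmmaThickness = "numeric", lateralSize = "numeric",
                 cuSquare = "numeric", alSquare = "numeric",
                 cuPresent = "logical", alPresent = "logical"))

.insertInside <- function(sq, lat) {
  # axis-aligned bounding half-extent of the rotated square
  th <- sq[["angleDeg"]] * pi / 180
  half <- sq[["side"]] / 2 * (abs(cos(th)) + abs(sin(th)))
  sq[["rowCenter"]] - half >= 0 && sq[["rowCenter"]] + half <= lat[1] &&
    sq[["colCenter"]] - half >= 0 && sq[["colCenter"]] + half <= lat[2]
}

setValidity("PhantomSpec", function(object) {
  if (object@pmmaThickness <= 0) return("pmmaThickness must be > 0")
  if (length(object@lateralSize) != 2 || any(object@lateralSize <= 0))
    return("lateralSize must be two positive lengths (mm)")
  for (nm in c("cuSquare", "alSquare")) {
    present <- if (nm == "cuSquare") object@cuPresent else object@alPresent
    if (!present) next
    sq <- slot(object, nm)
    need <- c("rowCenter", "colCenter", "side", "thickness", "angleDeg")
    if (!all(need %in% names(sq))) return(sprintf("%s needs fields %s", nm,
      paste(need, collapse = ", ")))
    if (sq[["side"]] <= 0 || sq[["thickness"]] <= 0)
      return(sprintf("%s side and thickness must be > 0", nm))
    if (!.insertInside(sq, object@lateralSize))
      return(sprintf("%s does not fit inside the lateral extent", nm))
  }
  if (object@cuPresent && object@alPresent) {
    # centre distance must exceed the sum of half-diagonals
    d <- sqrt((object@cuSquare[["rowCenter"]] - object@alSquare[["rowCenter"]])^2 +
              (object@cuSquare[["colCenter"]] - object@alSquare[["colCenter"]])^2)
    if (d < (object@cuSquare[["side"]] + object@alSquare[["side"]]) / 2 * sqrt(2))
      return("Cu and Al squares overlap")
  }
  TRUE
})

#' Detector model: geometry, gain, noise, blur and heel field
#'
#' An indirect description of an amorphous-selenium flat panel: pixel grid,
#' DC offset added to every pixel, linear gain (counts per mAs at unit
#' transmission), a Gaussian presampling point-spread function, a
#' quantum-noise gain (variance per offset-subtracted count) plus additive
#' electronic noise, and a smooth multiplicative heel-effect field along the
#' chest-wall-to-nipple axis.
#'
#' The heel field along the chest-wall-to-nipple axis is a three-plateau
#' profile (elevated chest-wall level `heelCW`, unit centre level, reduced
#' nipple level `heelNipple`) joined by smoothstep transitions, times a
#' small linear cross-tilt `1 + heelTilt*(cfrac - 1/2)`, rescaled so its
#' maximum is 1 and blended with a flat field by `heelAmplitude`. The
#' plateaus keep the field locally flat under the standard analysis ROIs
#' so ROI statistics reflect the heel level, not its gradient.
#'
#' @slot nrow,ncol integer pixel grid.
#' @slot pitch numeric, pixel pitch (mm).
#' @slot dcOffset numeric, DC offset (counts).
#' @slot gain numeric, counts per mAs at unit transmission.
#' @slot quantumGain numeric, noise variance per offset-subtracted count.
#' @slot electronicSD numeric, additive electronic noise SD (counts).
#' @slot psfSigma numeric, Gaussian presampling blur sigma (mm).
#' @slot heelAmplitude,heelCW,heelNipple,heelTilt numeric heel parameters.
#' @export
setClass("DetectorSpec",
  representation(nrow = "integer", ncol = "integer", pitch = "numeric",
                 dcOffset = "numeric", gain = "numeric",
                 quantumGain = "numeric", electronicSD = "numeric",
                 psfSigma = "numeric", heelAmplitude = "numeric",
                 heelCW = "numeric", heelNipple = "numeric",
                 heelTilt = "numeric"))

setValidity("DetectorSpec", function(object) {
  if (object@nrow <= 0L || object@ncol <= 0L) return("grid must be positive")
  if (object@pitch <= 0) return("pitch must be > 0")
  if (object@gain <= 0) return("gain must be > 0")
  if (object@dcOffset < 0) return("dcOffset must be >= 0")
  if (object@quantumGain < 0 || object@electronicSD < 0)
    return("noise parameters must be >= 0")
  if (object@psfSigma < 0) return("psfSigma must be >= 0")
  if (object@heelAmplitude < 0 || object@heelAmplitude > 1)
    return("heelAmplitude must be in [0, 1]")
  if (object@heelCW <= 0 || object@heelNipple <= 0)
    return("heel plateau levels must be > 0")
  TRUE
})

#' X-ray beam model: effective attenuation and output
#'
#' A monoenergetic-equivalent beam: per-material effective linear
#' attenuation coefficients (mm^-1), tube output (mGy per mAs at 1 m),
#' half-value layer (mm Al) and source-to-detector distance (mm).
#'
#' @slot kvp numeric, tube voltage (kV).
#' @slot targetFilter character, e.g. "W/Rh".
#' @slot mu named numeric, effective linear attenuation per material (mm^-1).
#' @slot tubeOutput numeric, air kerma per mAs at 1 m (mGy).
#' @slot hvl numeric, half-value layer (mm Al).
#' @slot sourceToDetector numeric (mm).
#' @export
setClass("BeamSpec",
  representation(kvp = "numeric", targetFilter = "character", mu = "numeric",
                 tubeOutput = "numeric", hvl = "numeric",
                 sourceToDetector = "numeric"))

setValidity("BeamSpec", function(object) {
  if (any(object@mu < 0)) return("attenuation coefficients must be >= 0")
  if (is.null(names(object@mu)) || any(!nzchar(names(object@mu))))
    return("mu must be a named vector (material -> mm^-1)")
  if (object@tubeOutput <= 0) return("tubeOutput must be > 0")
  if (object@hvl <= 0) return("hvl must be > 0")
  if (object@sourceToDetector <= 0) return("sourceToDetector must be > 0")
  TRUE
})

#' Exposure settings of one acquisition
#'
#' @slot kvp numeric (kV).
#' @slot mas numeric, tube current-time product (mAs).
#' @slot mode character, "automatic" or "manual".
#' @slot aecPosition integer 1-7 (automatic mode) or NA (manual).
#' @slot masReductionLevel integer >= 0, console mAs-reduction level
#'   applied to a manual exposure (0 = none).
#' @export
setClass("ExposureSettings",
  representation(kvp = "numeric", mas = "numeric", mode = "character",
                 aecPosition = "integer", masReductionLevel = "integer"),
  prototype(masReductionLevel = 0L, aecPosition = NA_integer_))

setValidity("ExposureSettings", function(object) {
  if (object@mas < 0) return("mas must be >= 0")
  if (!object@mode %in% c("automatic", "manual"))
    return("mode must be 'automatic' or 'manual'")
  if (object@mode == "automatic" &&
      (is.na(object@aecPosition) || object@aecPosition < 1L ||
       object@aecPosition > 7L))
    return("automatic mode requires aecPosition in 1..7")
  if (object@mode == "manual" && !is.na(object@aecPosition))
    return("manual mode must not carry an aecPosition")
  if (object@masReductionLevel < 0L) return("masReductionLevel must be >= 0")
  TRUE
})

#' Linear "for processing" mammography image
#'
#' Pixel counts plus the acquisition context every metric needs: pixel
#' pitch, detector DC offset, and a free-form metadata list (exposure
#' settings, phantom, seed, provenance).
#'
#' @slot pixels numeric matrix of counts (>= 0). Row 1 is the chest-wall
#'   edge.
#' @slot pitch numeric, pixel pitch (mm).
#' @slot dcOffset numeric (counts).
#' @slot meta list.
#' @export
setClass("MammoImage",
  representation(pixels = "matrix", pitch = "numeric", dcOffset = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("MammoImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (any(object@pixels < 0)) return("pixels must be >= 0")
  if (object@pitch <= 0) return("pitch must be > 0")
  if (object@dcOffset < 0) return("dcOffset must be >= 0")
  TRUE
})

#' Frequency-indexed curves: presampled MTF and normalized NPS
#'
#' `MTFCurve` holds a presampled modulation transfer function normalized to
#' 1 at zero frequency; small negative excursions from noise are tolerated.
#' `NPSCurve` holds a normalized noise power spectrum section (units mm^2)
#' along an axis or radially.
#'
#' @slot frequencies numeric, spatial frequencies (mm^-1), non-decreasing.
#' @slot values numeric, same length.
#' @name FrequencyCurves
#' @export
setClass("MTFCurve",
  representation(frequencies = "numeric", values = "numeric"))

setValidity("MTFCurve", function(object) {
  if (length(object@frequencies) != length(object@values))
    return("frequencies and values must have equal length")
  if (is.unsorted(object@frequencies)) return("frequencies must be sorted")
  if (abs(object@values[which.min(object@frequencies)] - 1) > 1e-6 &&
      min(object@frequencies) == 0)
    return("MTF must be 1 at zero frequency")
  if (any(object@values < -0.05 | object@values > 1.05))
    return("MTF values outside [-0.05, 1.05]")
  TRUE
})

#' @rdname FrequencyCurves
#' @slot axis character, one of "axial-u", "axial-v", "radial".
#' @export
setClass("NPSCurve",
  representation(frequencies = "numeric", values = "numeric",
                 axis = "character"))

setValidity("NPSCurve", function(object) {
  if (length(object@frequencies) != length(object@values))
    return("frequencies and values must have equal length")
  if (any(object@values < 0)) return("NPS values must be >= 0")
  if (!object@axis %in% c("axial-u", "axial-v", "radial"))
    return("axis must be axial-u, axial-v or radial")
  TRUE
})

#' Bundle of noise-power-spectrum estimates from one homogeneous region
#'
#' @slot axialU,axialV,radial [NPSCurve-class] sections of the 2D spectrum.
#' @slot spectrum2d numeric matrix, the fftshifted averaged 2D normalized
#'   NPS (mm^2), DC at the centre.
#' @slot frequencyStep numeric, bin width 1/(N*pitch) (mm^-1).
#' @slot largeAreaSignal numeric, offset-subtracted mean signal used for
#'   normalization (counts).
#' @slot pixelVariance numeric, mean detrended pixel variance over the
#'   analysis ROIs (counts^2), for Parseval checks.
#' @export
setClass("NPSEstimate",
  representation(axialU = "NPSCurve", axialV = "NPSCurve",
                 radial = "NPSCurve", spectrum2d = "matrix",
                 frequencyStep = "numeric", largeAreaSignal = "numeric",
                 pixelVariance = "numeric"))

#' Slanted-edge model fitted to an image band
#'
#' @slot orientation character, "vertical" (edge line nearly parallel to
#'   the column axis, scanned row-wise) or "horizontal".
#' @slot angleDeg numeric, edge angle from the axis in degrees; valid
#'   slanted-edge analysis needs 1-10 degrees.
#' @slot intercept numeric, subpixel intercept of the edge line in band
#'   coordinates (pixels, 0-based).
#' @slot slope numeric, pixels per pixel along the scan direction.
#' @slot band [ImageROI-class], the analysis band.
#' @slot edgeContrast numeric, signal step across the edge (counts).
#' @export
setClass("EdgeModel",
  representation(orientation = "character", angleDeg = "numeric",
                 intercept = "numeric", slope = "numeric",
                 band = "ImageROI", edgeContrast = "numeric"))

setValidity("EdgeModel", function(object) {
  if (!object@orientation %in% c("vertical", "horizontal"))
    return("orientation must be 'vertical' or 'horizontal'")
  a <- abs(object@angleDeg)
  if (a < 1 || a > 10)
    return("edge angle outside the 1-10 degree slanted-edge range")
  TRUE
})

#' Eye-filter (visual transfer function) specification for NPWE
#'
#' Band-pass contrast-sensitivity model `VTF(f) = f^1.3 * exp(-c*f^2)` in
#' angular frequency f (cycles/degree), normalized to peak 1, with `c`
#' fixed by the requested peak frequency. Image-plane frequencies are
#' converted via the display magnification and viewing distance.
#'
#' @slot viewingDistance numeric (mm).
#' @slot magnification numeric (display magnification, dimensionless).
#' @slot peakFrequency numeric (cycles/degree).
#' @slot exponent numeric, low-frequency power (default 1.3).
#' @export
setClass("EyeFilterSpec",
  representation(viewingDistance = "numeric", magnification = "numeric",
                 peakFrequency = "numeric", exponent = "numeric"))

setValidity("EyeFilterSpec", function(object) {
  if (object@viewingDistance <= 0) return("viewingDistance must be > 0")
  if (object@magnification <= 0) return("magnification must be > 0")
  if (object@peakFrequency <= 0) return("peakFrequency must be > 0")
  TRUE
})

#' Detection task: disc of given diameter and contrast
#'
#' @slot diameter numeric (mm).
#' @slot contrast numeric >= 0, relative signal contrast (measured on the
#'   Al square).
#' @export
setClass("TaskSpec", representation(diameter = "numeric", contrast = "numeric"))

setValidity("TaskSpec", function(object) {
  if (object@diameter <= 0) return("diameter must be > 0")
  if (object@contrast < 0) return("contrast must be >= 0")
  TRUE
})

#' NPWE detectability result
#'
#' @slot dprime numeric >= 0.
#' @slot numerator,denominator numeric, the two integrals of the NPWE ratio.
#' @slot frequencies numeric, integration grid (mm^-1).
#' @export
setClass("DPrimeResult",
  representation(dprime = "numeric", numerator = "numeric",
                 denominator = "numeric", frequencies = "numeric"))

#' Average glandular dose report (EUREF formalism)
#'
#' @slot incidentAirKerma numeric, K at the entrance surface (mGy).
#' @slot g,c,s numeric conversion factors.
#' @slot agd numeric, K * g * c * s (mGy).
#' @slot hvl numeric (mm Al).
#' @slot equivalentBreastThickness numeric (mm).
#' @export
setClass("DoseReport",
  representation(incidentAirKerma = "numeric", g = "numeric", c = "numeric",
                 s = "numeric", agd = "numeric", hvl = "numeric",
                 equivalentBreastThickness = "numeric"))

setValidity("DoseReport", function(object) {
  v <- c(object@incidentAirKerma, object@g, object@c, object@s, object@agd)
  if (any(v < 0)) return("dose quantities must be >= 0")
  if (abs(object@agd - object@incidentAirKerma * object@g * object@c *
          object@s) > 1e-9 * max(1, object@agd))
    return("agd must equal K * g * c * s")
  TRUE
})

#' Group-comparison report
#'
#' Per-group summaries (median/IQR, or mean +/- SD for groups of exactly
#' five), normality and variance screens, the Kruskal-Wallis omnibus test
#' and Bonferroni-corrected Dunn pairwise comparisons.
#'
#' @slot metric character, name of the compared metric.
#' @slot groupSummary data.frame with columns group, n, center, spread,
#'   summaryType ("median (IQR)" or "mean +/- SD"), q25, q75.
#' @slot shapiroP named numeric, Shapiro-Wilk p per group (NA if n < 3).
#' @slot leveneP numeric, Levene test p.
#' @slot kruskalH,kruskalP numeric, omnibus statistic and p.
#' @slot dunn data.frame with columns group1, group2, z, pRaw, pBonferroni,
#'   significant (at `alpha`).
#' @slot alpha numeric significance level.
#' @export
setClass("StatsReport",
  representation(metric = "character", groupSummary = "data.frame",
                 shapiroP = "numeric", leveneP = "numeric",
                 kruskalH = "numeric", kruskalP = "numeric",
                 dunn = "data.frame", alpha = "numeric"))
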