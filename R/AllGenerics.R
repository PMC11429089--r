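#' @include AllClasses.R
NULL

#' Accessors for mammoqc objects
#'
#' Small accessor generics so that downstream code never touches slots
#' directly: pixel data, pixel pitch, DC offset and metadata of a
#' [MammoImage-class]; frequency grid and values of [MTFCurve-class] /
#' [NPSCurve-class].
#'
#' @param object a mammoqc S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setMethod("pixelData", "MammoImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setMethod("pixelPitch", "MammoImage", function(object) object@pitch)

#' @rdname accessors
#' @export
setGeneric("dcOffset", function(object) standardGeneric("dcOffset"))
#' @rdname accessors
#' @export
setMethod("dcOffset", "MammoImage", function(object) object@dcOffset)
#' @rdname accessors
#' @export
setMethod("dcOffset", "DetectorSpec", function(object) object@dcOffset)

#' @rdname accessors
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))
#' @rdname accessors
#' @export
setMethod("imageMeta", "MammoImage", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setMethod("frequencies", "MTFCurve", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "NPSCurve", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "DPrimeResult", function(object) object@frequencies)

#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setMethod("curveValues", "MTFCurve", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("curveValues", "NPSCurve", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("dPrimeValue", function(object) standardGeneric("dPrimeValue"))
#' @rdname accessors
#' @export
setMethod("dPrimeValue", "DPrimeResult", function(object) object@dprime)

#' @rdname accessors
#' @export
setGeneric("agdValue", function(object) standardGeneric("agdValue"))
#' @rdname accessors
#' @export
setMethod("agdValue", "DoseReport", function(object) object@agd)

#' @describeIn accessors dimensions of the pixel matrix.
#' @export
setMethod("dim", "MammoImage", function(x) dim(x@pixels))

setMethod("show", "MammoImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MammoImage: %d x %d px, pitch %.3g mm, DC offset %g\n",
              d[1], d[2], object@pitch, object@dcOffset))
  m <- object@meta
  if (!is.null(m$exposure) && is(m$exposure, "ExposureSettings")) {
    e <- m$exposure
    cat(sprintf("  exposure: %s, %g kVp, %g mAs%s\n", e@mode, e@kvp, e@mas,
                if (!is.na(e@aecPosition))
                  sprintf(", AEC position %d", e@aecPosition) else ""))
  }
  if (!is.null(m$seed)) cat(sprintf("  seed: %s\n", format(m$seed)))
  invisible(NULL)
})

setMethod("show", "ImageROI", function(object) {
  cat(sprintf("ImageROI%s: rows [%d, %d), cols [%d, %d)\n",
              if (!is.na(object@label)) paste0(" '", object@label, "'") else "",
              object@row0, object@row0 + object@height,
              object@col0, object@col0 + object@width))
  invisible(NULL)
})

setMethod("show", "MTFCurve", function(object) {
  cat(sprintf("MTFCurve: %d frequencies in [0, %.3g] mm^-1\n",
              length(object@frequencies), max(object@frequencies)))
  invisible(NULL)
})

setMethod("show", "NPSCurve", function(object) {
  cat(sprintf("NPSCurve (%s): %d frequencies up to %.3g mm^-1\n",
              object@axis, length(object@frequencies),
              max(object@frequencies)))
  invisible(NULL)
})

setMethod("show", "NPSEstimate", function(object) {
  cat(sprintf(
    "NPSEstimate: %d x %d 2D spectrum, df = %.4g mm^-1, large-area signal %.4g\n",
    nrow(object@spectrum2d), ncol(object@spectrum2d), object@frequencyStep,
    object@largeAreaSignal))
  invisible(NULL)
})

setMethod("show", "DPrimeResult", function(object) {
  cat(sprintf("DPrimeResult: d' = %.4g\n", object@dprime))
  invisible(NULL)
})

setMethod("show", "DoseReport", function(object) {
  cat(sprintf(
    "DoseReport: AGD %.4g mGy (K %.4g mGy, g %.4g, c %.4g, s %.4g, HVL %.3g mm Al)\n",
    object@agd, object@incidentAirKerma, object@g, object@c, object@s,
    object@hvl))
  invisible(NULL)
})

setMethod("show", "StatsReport", function(object) {
  cat(sprintf("StatsReport for '%s' (%d groups)\n", object@metric,
              nrow(object@groupSummary)))
  print(object@groupSummary, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis H = %.4g, p = %.4g; Levene p = %.4g\n",
              object@kruskalH, object@kruskalP, object@leveneP))
  if (nrow(object@dunn)) {
    cat(sprintf("Dunn pairwise (Bonferroni, alpha = %g):\n", object@alpha))
    print(object@dunn, row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "ExposureSettings", function(object) {
  cat(sprintf("ExposureSettings: %s, %g kVp, %g mAs%s%s\n", object@mode,
              object@kvp, object@mas,
              if (!is.na(object@aecPosition))
                sprintf(", AEC position %d", object@aecPosition) else "",
              if (object@masReductionLevel > 0L)
                sprintf(", mAs reduction level %d", object@masReductionLevel)
              else ""))
  invisible(NULL)
})
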