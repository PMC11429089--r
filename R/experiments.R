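#' @include simulate.R metrics.R mtf.R nps.R npwe.R dose.R stats.R
NULL

#' Full image-quality analysis of one phantom acquisition
#'
#' Runs the whole metric chain on a single "for processing" image: SDNR
#' and contrast from the Al square, presampled MTF from the two Cu edges
#' averaged onto the radial-NNPS frequency grid, normalized NPS from the
#' homogeneous region, NPWE detectability for the 0.1 mm and 0.25 mm disc
#' tasks, and (when the image metadata carries its exposure) the average
#' glandular dose.
#'
#' @param image a [MammoImage-class].
#' @param phantom,detector the specs the image was acquired with (used for
#'   ROI placement); defaults match the image dimensions.
#' @param beam a [BeamSpec-class] (for the dose report).
#' @param eye an [EyeFilterSpec-class] or `NULL`.
#' @param taskDiameters disc diameters (mm) for the detectability tasks.
#' @return list with elements `sdnr`, `contrast`, `dprime` (named by
#'   diameter), `dose` ([DoseReport-class] or `NULL`), `mtf`, `nnps`,
#'   `exposure`.
#' @export
analyzeImage <- function(image, phantom = NULL, detector = NULL,
                         beam = defaultBeam(), eye = defaultEyeFilter(),
                         taskDiameters = c(0.1, 0.25)) {
  if (is.null(detector)) {
    d <- dim(image)
    detector <- defaultDetector("custom", nrow = d[1], ncol = d[2])
  }
  if (is.null(phantom)) {
    phantom <- imageMeta(image)$phantom
    if (is.null(phantom)) phantom <- iaeaPhantom(detector)
  }
  rois <- iaeaAnalysisROIs(phantom, detector)
  haveAl <- !is.null(rois$al)
  sdnrVal <- if (haveAl) sdnr(image, rois$al, rois$background) else NA_real_
  contrast <- if (haveAl)
    measureContrast(image, rois$al, rois$background) else NA_real_
  nps <- estimateNNPS(image, rois$npsRegion)
  mtf <- if (!is.null(rois$edgeH)) {
    edgeH <- estimateEdge(image, rois$edgeH, "horizontal")
    edgeV <- estimateEdge(image, rois$edgeV, "vertical")
    averageOrthogonal(presampledMTF(image, edgeH),
                      presampledMTF(image, edgeV),
                      frequencies(nps@radial))
  } else {
    # no Cu edges available (insert-free control): unit transfer
    new("MTFCurve", frequencies = frequencies(nps@radial),
        values = rep(1, length(frequencies(nps@radial))))
  }
  dp <- vapply(taskDiameters, function(dd) {
    if (!haveAl) return(NA_real_)
    dPrimeValue(dPrime(TaskSpec(dd, contrast), mtf, nps@radial, eye))
  }, numeric(1))
  names(dp) <- sprintf("d%.2f", taskDiameters)
  exposure <- imageMeta(image)$exposure
  dose <- if (!is.null(exposure)) acquisitionDose(phantom, beam, exposure)
    else NULL
  list(sdnr = sdnrVal, contrast = contrast, dprime = dp, dose = dose,
       mtf = mtf, nnps = nps, exposure = exposure)
}

.metricsRow <- function(res) {
  data.frame(kvp = if (!is.null(res$exposure)) res$exposure@kvp else NA,
             mas = if (!is.null(res$exposure)) res$exposure@mas else NA,
             sdnr = res$sdnr, contrast = res$contrast,
             dprime01 = unname(res$dprime[["d0.10"]]),
             dprime025 = unname(res$dprime[["d0.25"]]),
             agd = if (!is.null(res$dose)) agdValue(res$dose) else NA)
}

.experimentReports <- function(samples, groupCol, alpha) {
  metrics <- c("sdnr", "dprime01", "dprime025", "agd", "mas")
  reports <- lapply(metrics, function(m)
    compareGroups(samples[[m]], samples[[groupCol]], metric = m,
                  alpha = alpha))
  names(reports) <- metrics
  reports
}

#' AEC-position comparison study
#'
#' Simulates `replicates` acquisitions of the phantom at each AEC sensor
#' position, computes the full metric set per image, groups positions 1-3
#' (sensor under the Cu square) as "misused" and 4-7 as "reference", and
#' compares SDNR, detectability, AGD and mAs between the two groups with
#' Kruskal-Wallis plus Bonferroni-corrected Dunn tests.
#'
#' @param positions AEC positions to scan (default 1:7).
#' @param replicates acquisitions per position (default 10).
#' @param seedBase integer; the seed of each image is
#'   `seedBase + 1000 * position + replicate`.
#' @param detector,beam,phantom simulation specs.
#' @param alpha significance level.
#' @return list with `samples` (one row per image: position, group,
#'   replicate, seed, kvp, mas, sdnr, contrast, dprime01, dprime025,
#'   agd), `reports` (named [StatsReport-class] list) and `groupMedians`.
#' @export
runAECExperiment <- function(positions = 1:7, replicates = 10,
                             seedBase = 1000,
                             detector = defaultDetector(),
                             beam = defaultBeam(),
                             phantom = iaeaPhantom(detector),
                             alpha = 0.05) {
  unit <- buildMeanSignalMap(phantom, beam, detector,
                             ExposureSettings(28, 1, "manual")) -
    detector@dcOffset
  rows <- list()
  for (pos in positions) {
    exposure <- emulateAEC(phantom, beam, detector, pos)
    meanMap <- detector@dcOffset + exposure@mas * unit
    for (rep_ in seq_len(replicates)) {
      seed <- seedBase + 1000L * pos + rep_
      img <- simulateAcquisition(meanMap, detector, seed,
                                 meta = list(exposure = exposure,
                                             phantom = phantom))
      res <- analyzeImage(img, phantom, detector, beam)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(position = pos,
                   group = if (pos <= 3) "misused" else "reference",
                   replicate = rep_, seed = seed),
        .metricsRow(res))
    }
  }
  samples <- do.call(rbind, rows)
  reports <- .experimentReports(samples, "group", alpha)
  med <- stats::aggregate(
    samples[, c("sdnr", "dprime01", "dprime025", "agd", "mas")],
    by = list(group = samples$group), FUN = stats::median)
  list(samples = samples, reports = reports, groupMedians = med)
}

#' Manual-technique comparison study
#'
#' Compares three acquisition techniques of the phantom: the
#' manufacturer-recommended manual exposure (120 mAs for a 4-6 cm
#' breast), the console's first mAs-reduction level (a configurable
#' fractional cut, default 13 %), and the automatic reference exposure
#' with the AEC sensor outside the Cu square.
#'
#' @param replicates acquisitions per condition.
#' @param seedBase integer seed base.
#' @param recommendedMas manufacturer-recommended manual mAs.
#' @param reductionFraction fractional mAs cut of reduction level 1.
#' @param referencePosition AEC position of the reference arm (>= 4).
#' @param detector,beam,phantom simulation specs.
#' @param alpha significance level.
#' @return list as in [runAECExperiment()] with a `condition` grouping
#'   plus `percentChanges`, the median percent change of each metric for
#'   reduced vs recommended and reference vs reduced.
#' @export
runManualExperiment <- function(replicates = 10, seedBase = 2000,
                                recommendedMas = 120,
                                reductionFraction = 0.13,
                                referencePosition = 4,
                                detector = defaultDetector(),
                                beam = defaultBeam(),
                                phantom = iaeaPhantom(detector),
                                alpha = 0.05) {
  kvp <- kvpForThickness(phantom@pmmaThickness)
  conditions <- list(
    recommended = ExposureSettings(kvp, recommendedMas, "manual"),
    reduced = ExposureSettings(kvp, recommendedMas * (1 - reductionFraction),
                               "manual", masReductionLevel = 1),
    reference = emulateAEC(phantom, beam, detector, referencePosition))
  unit <- buildMeanSignalMap(phantom, beam, detector,
                             ExposureSettings(28, 1, "manual")) -
    detector@dcOffset
  rows <- list()
  for (cn in names(conditions)) {
    exposure <- conditions[[cn]]
    meanMap <- detector@dcOffset + exposure@mas * unit
    for (rep_ in seq_len(replicates)) {
      seed <- seedBase + 1000L * match(cn, names(conditions)) + rep_
      img <- simulateAcquisition(meanMap, detector, seed,
                                 meta = list(exposure = exposure,
                                             phantom = phantom))
      res <- analyzeImage(img, phantom, detector, beam)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(condition = cn, replicate = rep_, seed = seed),
        .metricsRow(res))
    }
  }
  samples <- do.call(rbind, rows)
  reports <- .experimentReports(samples, "condition", alpha)
  med <- stats::aggregate(
    samples[, c("sdnr", "dprime01", "dprime025", "agd", "mas")],
    by = list(condition = samples$condition), FUN = stats::median)
  pc <- function(a, b, metric)
    percentChange(med[med$condition == a, metric],
                  med[med$condition == b, metric])
  metrics <- c("sdnr", "dprime01", "dprime025", "agd")
  percentChanges <- data.frame(
    metric = metrics,
    reducedVsRecommended = vapply(metrics, function(m)
      pc("recommended", "reduced", m), numeric(1)),
    referenceVsReduced = vapply(metrics, function(m)
      pc("reduced", "reference", m), numeric(1)))
  list(samples = samples, reports = reports, groupMedians = med,
       percentChanges = percentChanges)
}
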