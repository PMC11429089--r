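#' @include metrics.R
NULL

#' Console-recorded acquisition data of the clinical implant case
#'
#' The printed acquisition parameters, breast-tissue SNR and displayed
#' AGD of a single clinical follow-up case with a silicone breast
#' implant: the left craniocaudal projection (Eklund maneuver possible;
#' manual recommended settings vs automatic reference settings) and the
#' left medio-lateral oblique projection (manual recommended settings vs
#' automatic misused settings with the AEC sensor partly over the
#' implant). These console values are inputs to the clinical-case
#' arithmetic, not quantities the package recomputes from pixels.
#'
#' @return data.frame with one row per projection/technique.
#' @export
clinicalCaseData <- function() {
  data.frame(
    projection = c("LCC", "LCC", "LMLO", "LMLO"),
    technique = c("recommended", "reference", "recommended", "misused"),
    mode = c("manual", "automatic", "manual", "automatic"),
    kvp = c(28, 29, 28, 32),
    mas = c(120, 108, 120, 159),
    breastThickness = c(46, 50, 51, 66),
    compressionForce = c(20.1, 63.6, 38.4, 54.7),
    anodeFilter = "W/Rh",
    snrBT = c(12.1, 4.6, 8.7, 17.2),
    snrBTsd = c(6.2, 1.7, 6.4, 10.2),
    agd = c(1.7, 1.4, 1.4, 2.5))
}

#' Clinical-case comparison arithmetic
#'
#' The headline comparisons between acquisition techniques of the
#' clinical case, computed from [clinicalCaseData()]: on the LCC
#' projection (reference vs recommended) the SNR fold-ratio and the AGD
#' percent change; on the LMLO projection (misused vs recommended) the
#' AGD and SNR percent changes. Values are returned unrounded with the
#' report-table rounding alongside (one decimal for fold ratios, integer
#' percent unless the source reports a decimal).
#'
#' @return data.frame with columns projection, comparison, quantity,
#'   value, printed.
#' @examples
#' clinicalCaseSummary()
#' @export
clinicalCaseSummary <- function() {
  d <- clinicalCaseData()
  g <- function(proj, tech, col) d[d$projection == proj &
                                     d$technique == tech, col]
  snrFold <- foldRatio(g("LCC", "recommended", "snrBT"),
                       g("LCC", "reference", "snrBT"))
  agdLCC <- percentChange(g("LCC", "recommended", "agd"),
                          g("LCC", "reference", "agd"))
  agdLMLO <- percentChange(g("LMLO", "recommended", "agd"),
                           g("LMLO", "misused", "agd"))
  snrLMLO <- percentChange(g("LMLO", "recommended", "snrBT"),
                           g("LMLO", "misused", "snrBT"))
  data.frame(
    projection = c("LCC", "LCC", "LMLO", "LMLO"),
    comparison = c("reference vs recommended", "reference vs recommended",
                   "misused vs recommended", "misused vs recommended"),
    quantity = c("SNR_BT fold ratio", "AGD percent change",
                 "AGD percent change", "SNR_BT percent change"),
    value = c(snrFold, agdLCC, agdLMLO, snrLMLO),
    printed = c(round(snrFold, 1), round(agdLCC), round(agdLMLO),
                round(snrLMLO, 1)))
}

#' All-position flat-field means of the AEC sensitivity test
#'
#' Mean acquisition parameters and per-ROI SNR over the seven AEC sensor
#' positions of the flat-field sensitivity test on a clinical unit
#' (five repeats per position): the printed all-position means that the
#' centre-to-corner uniformity arithmetic consumes.
#'
#' @return named numeric vector: kvp, mas, compressedThickness, agd,
#'   snrC, snrCW1, snrCW2, snrN1, snrN2.
#' @export
aecFlatFieldMeans <- function() {
  c(kvp = 28, mas = 94.1, compressedThickness = 42.1, agd = 1.3,
    snrC = 54.8, snrCW1 = 57.1, snrCW2 = 58.5, snrN1 = 39.3,
    snrN2 = 40.7)
}

#' Centre-to-corner SNR variation
#'
#' Percent change from the centre ROI SNR to each corner ROI SNR — the
#' uniformity signature of the heel effect (chest-wall corners a few
#' percent above centre, nipple corners 20-30 % below).
#'
#' @param snr named numeric with elements snrC, snrCW1, snrCW2, snrN1,
#'   snrN2 (default: the clinical flat-field means).
#' @return named numeric vector of percent changes (CW1, CW2, N1, N2).
#' @examples
#' centerToCornerVariation()
#' @export
centerToCornerVariation <- function(snr = aecFlatFieldMeans()) {
  corners <- c("CW1", "CW2", "N1", "N2")
  out <- vapply(corners, function(k)
    percentChange(snr[["snrC"]], snr[[paste0("snr", k)]]), numeric(1))
  names(out) <- corners
  out
}
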