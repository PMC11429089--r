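#' @include specs.R
NULL

.doseEnv <- new.env(parent = emptyenv())

#' Conversion-factor tables for the average glandular dose
#'
#' Reads (and caches) the packaged factor tables of the EUREF AGD
#' formalism: g (50 %-glandular standard breast), c (typical glandularity
#' of the 50-64 screening age group), s (target/filter), and the
#' PMMA-to-breast thickness equivalence. The tables ship as versioned CSV
#' assets under `inst/extdata` so their provenance and values are
#' inspectable data, not code.
#'
#' @return list with elements `g` (matrix thickness x HVL), `gThickness`,
#'   `gHvl`, `c`, `cThickness`, `cHvl`, `s` (named vector),
#'   `pmma` (data.frame pmma_mm, breast_mm).
#' @export
agdFactorTables <- function() {
  if (!is.null(.doseEnv$tables)) return(.doseEnv$tables)
  path <- function(f) system.file("extdata", f, package = "mammoqc",
                                  mustWork = TRUE)
  readGrid <- function(f) {
    d <- utils::read.csv(path(f), comment.char = "#",
                         check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    list(m = m, thickness = d[[1]], hvl = as.numeric(colnames(d)[-1]))
  }
  g <- readGrid("agd_g_factors.csv")
  cc <- readGrid("agd_c_factors.csv")
  s <- utils::read.csv(path("agd_s_factors.csv"), comment.char = "#")
  pm <- utils::read.csv(path("pmma_breast_equivalence.csv"),
                        comment.char = "#")
  .doseEnv$tables <- list(g = g$m, gThickness = g$thickness, gHvl = g$hvl,
                          c = cc$m, cThickness = cc$thickness,
                          cHvl = cc$hvl,
                          s = stats::setNames(s$s, s$target_filter),
                          pmma = pm)
  .doseEnv$tables
}

# bilinear interpolation on a (thickness, HVL) grid; no extrapolation
.bilinear <- function(m, tGrid, hGrid, t, h, what) {
  if (t < min(tGrid) || t > max(tGrid))
    stop(sprintf("%s: thickness %.1f mm outside table range [%g, %g]",
                 what, t, min(tGrid), max(tGrid)))
  if (h < min(hGrid) || h > max(hGrid))
    stop(sprintf("%s: HVL %.3f mm Al outside table range [%g, %g]",
                 what, h, min(hGrid), max(hGrid)))
  it <- findInterval(t, tGrid, all.inside = TRUE)
  ih <- findInterval(h, hGrid, all.inside = TRUE)
  ft <- (t - tGrid[it]) / (tGrid[it + 1] - tGrid[it])
  fh <- (h - hGrid[ih]) / (hGrid[ih + 1] - hGrid[ih])
  unname((1 - ft) * ((1 - fh) * m[it, ih] + fh * m[it, ih + 1]) +
           ft * ((1 - fh) * m[it + 1, ih] + fh * m[it + 1, ih + 1]))
}

#' Incident air kerma at the entrance surface
#'
#' Inverse-square scaling of the tube output: `K = output * mAs / d^2`
#' with `d` the source-to-surface distance in metres.
#'
#' @param beam a [BeamSpec-class] (uses `tubeOutput`, mGy/mAs at 1 m).
#' @param mas tube current-time product.
#' @param sourceToSurface distance source to entrance surface (mm).
#' @return incident air kerma (mGy).
#' @examples
#' incidentAirKerma(defaultBeam(), 100, 600)
#' @export
incidentAirKerma <- function(beam, mas, sourceToSurface) {
  if (sourceToSurface <= 0) stop("sourceToSurface must be > 0")
  if (mas < 0) stop("mas must be >= 0")
  beam@tubeOutput * mas / (sourceToSurface / 1000)^2
}

#' Average glandular dose (EUREF formalism)
#'
#' `AGD = K * g * c * s`, with g and c bilinearly interpolated in
#' (breast thickness, HVL) from the packaged tables and s looked up per
#' target/filter. No extrapolation outside the table ranges.
#'
#' @param K incident air kerma (mGy).
#' @param hvl half-value layer (mm Al).
#' @param breastThickness equivalent breast thickness (mm).
#' @param targetFilter e.g. "W/Rh".
#' @return a [DoseReport-class].
#' @examples
#' averageGlandularDose(4.1, 0.53, 53)
#' @export
averageGlandularDose <- function(K, hvl, breastThickness,
                                 targetFilter = "W/Rh") {
  if (K < 0) stop("incident air kerma must be >= 0")
  tb <- agdFactorTables()
  g <- .bilinear(tb$g, tb$gThickness, tb$gHvl, breastThickness, hvl,
                 "g-factor")
  c_ <- .bilinear(tb$c, tb$cThickness, tb$cHvl, breastThickness, hvl,
                  "c-factor")
  if (!targetFilter %in% names(tb$s))
    stop(sprintf("no s-factor for target/filter '%s'", targetFilter))
  s <- unname(tb$s[targetFilter])
  new("DoseReport", incidentAirKerma = K, g = g, c = c_, s = s,
      agd = K * g * c_ * s, hvl = hvl,
      equivalentBreastThickness = breastThickness)
}

#' Breast thickness equivalent in absorption to a PMMA slab
#'
#' Linear interpolation in the packaged equivalence table (valid 20-80 mm
#' PMMA; e.g. 45 mm PMMA corresponds to a 53 mm breast).
#'
#' @param tPmma PMMA thickness (mm).
#' @return equivalent breast thickness (mm).
#' @examples
#' pmmaToBreastEquivalent(45) # 53
#' @export
pmmaToBreastEquivalent <- function(tPmma) {
  tb <- agdFactorTables()$pmma
  if (tPmma < min(tb$pmma_mm) || tPmma > max(tb$pmma_mm))
    stop(sprintf("PMMA thickness %.1f mm outside table range [%g, %g]",
                 tPmma, min(tb$pmma_mm), max(tb$pmma_mm)))
  stats::approx(tb$pmma_mm, tb$breast_mm, tPmma)$y
}

#' Dose report of a simulated phantom acquisition
#'
#' Combines the beam output, delivered mAs, phantom thickness and the
#' EUREF factors: K at the phantom entrance (source-to-detector distance
#' minus slab thickness) and AGD for the PMMA-equivalent breast.
#'
#' @param phantom a [PhantomSpec-class].
#' @param beam a [BeamSpec-class].
#' @param exposure an [ExposureSettings-class].
#' @return a [DoseReport-class].
#' @export
acquisitionDose <- function(phantom, beam, exposure) {
  K <- incidentAirKerma(beam, exposure@mas,
                        beam@sourceToDetector - phantom@pmmaThickness)
  averageGlandularDose(K, beam@hvl,
                       pmmaToBreastEquivalent(phantom@pmmaThickness),
                       beam@targetFilter)
}
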