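#' @include specs.R
NULL

#' Extract the pixel block of an ROI
#'
#' @param image a [MammoImage-class] or numeric matrix.
#' @param roi an [ImageROI-class].
#' @return numeric matrix.
#' @export
cropPixels <- function(image, roi) {
  px <- if (is(image, "MammoImage")) pixelData(image) else image
  if (roi@row0 + roi@height > nrow(px) || roi@col0 + roi@width > ncol(px))
    stop("ROI does not fit inside the image")
  px[seq.int(roi@row0 + 1L, roi@row0 + roi@height),
     seq.int(roi@col0 + 1L, roi@col0 + roi@width), drop = FALSE]
}

#' First-order statistics of an ROI
#'
#' Mean, sample (n-1) standard deviation and pixel count.
#'
#' @inheritParams cropPixels
#' @return data.frame with columns label, mean, sd, n.
#' @export
roiStats <- function(image, roi) {
  v <- as.vector(cropPixels(image, roi))
  data.frame(label = roi@label, mean = mean(v), sd = stats::sd(v),
             n = length(v))
}

#' Signal-to-noise ratio of an ROI
#'
#' `(mean - dcOffset) / sd` over the ROI. Subtracting the DC offset makes
#' the SNR vanish at zero exposure, mirroring how the console statistics
#' account for the offset; set `subtractOffset = FALSE` for the raw-mean
#' convention.
#'
#' @inheritParams cropPixels
#' @param dcOffset offset in counts; defaults to the image's.
#' @param subtractOffset logical.
#' @return numeric scalar.
#' @examples
#' img <- MammoImage(matrix(150 + rnorm(1e4, sd = 10), 100), pitch = 0.07)
#' roiSNR(img, imageROI(0, 0, 100, 100))
#' @export
roiSNR <- function(image, roi, dcOffset = NULL, subtractOffset = TRUE) {
  if (is.null(dcOffset))
    dcOffset <- if (is(image, "MammoImage")) dcOffset(image) else
      stop("dcOffset required for plain matrices")
  s <- roiStats(image, roi)
  if (s$sd <= 0)
    stop("degenerate ROI: zero standard deviation, SNR undefined")
  ((s$mean - if (subtractOffset) dcOffset else 0)) / s$sd
}

#' Signal-difference-to-noise ratio between an insert and its background
#'
#' `(mean(background) - mean(insert)) / sd(background)`; the DC offset
#' cancels in the difference.
#'
#' @inheritParams cropPixels
#' @param roiInsert,roiBackground [ImageROI-class] on the Al square and the
#'   local background.
#' @return numeric scalar.
#' @export
sdnr <- function(image, roiInsert, roiBackground) {
  si <- roiStats(image, roiInsert)
  sb <- roiStats(image, roiBackground)
  if (sb$sd <= 0)
    stop("degenerate background ROI: zero standard deviation")
  (sb$mean - si$mean) / sb$sd
}

#' Relative signal contrast of the Al square
#'
#' `C = (mean(background) - mean(insert)) / (mean(background) - dcOffset)`,
#' the contrast that parameterizes the NPWE disc task.
#'
#' @inheritParams sdnr
#' @param dcOffset offset in counts; defaults to the image's.
#' @return numeric scalar in `[0, 1]` for an attenuating insert.
#' @export
measureContrast <- function(image, roiInsert, roiBackground,
                            dcOffset = NULL) {
  if (is.null(dcOffset))
    dcOffset <- if (is(image, "MammoImage")) dcOffset(image) else
      stop("dcOffset required for plain matrices")
  si <- roiStats(image, roiInsert)
  sb <- roiStats(image, roiBackground)
  if (sb$mean - dcOffset <= 0)
    stop("background at or below the DC offset: contrast undefined")
  (sb$mean - si$mean) / (sb$mean - dcOffset)
}

#' Coefficient of variation
#'
#' Sample standard deviation over mean.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return numeric scalar.
#' @examples
#' coefVar(c(1, 2, 3)) # 0.5
#' @export
coefVar <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: COV undefined")
  stats::sd(values) / m
}

#' Percent change and fold ratio
#'
#' `percentChange(old, new)` is `100 * (new - old) / old`;
#' `foldRatio(a, b)` is `a / b`. Rounding for report tables is left to the
#' caller.
#'
#' @param old,new,a,b numeric scalars; denominators must be non-zero.
#' @return numeric scalar.
#' @examples
#' percentChange(1.7, 1.4) # -17.6...
#' foldRatio(12.1, 4.6)    # 2.63...
#' @export
percentChange <- function(old, new) {
  if (old == 0) stop("zero baseline: percent change undefined")
  100 * (new - old) / old
}

#' @rdname percentChange
#' @export
foldRatio <- function(a, b) {
  if (b == 0) stop("zero denominator: fold ratio undefined")
  a / b
}

#' The five standard uniformity ROIs
#'
#' Centre (C) plus the four corners: CW1/CW2 on the chest-wall side and
#' N1/N2 on the nipple side, inset by a fixed margin. The ROI size defaults
#' to 256 px on frames of at least 1024 px in each dimension (the clinical
#' analysis size) and 64 px on the scaled-down test frames.
#'
#' @param dims integer length 2, image dimensions (rows, cols), or a
#'   [MammoImage-class].
#' @param roiSize side length in pixels; `NULL` picks 256 or 64 as above.
#' @param margin corner inset in pixels.
#' @return named list of five [ImageROI-class] (C, CW1, CW2, N1, N2).
#' @examples
#' standardROIs(c(512, 640))
#' @export
standardROIs <- function(dims, roiSize = NULL, margin = 16) {
  if (is(dims, "MammoImage")) dims <- dim(dims)
  nr <- dims[1]; nc <- dims[2]
  if (is.null(roiSize)) roiSize <- if (min(nr, nc) >= 1024) 256L else 64L
  roiSize <- as.integer(roiSize); margin <- as.integer(margin)
  if (nr < 3 * roiSize || nc < 3 * roiSize)
    stop(sprintf("image (%d x %d) too small for three %d px ROIs per axis",
                 nr, nc, roiSize))
  ctr <- function(n) as.integer(floor((n - roiSize) / 2))
  far <- function(n) as.integer(n - margin - roiSize)
  list(
    C   = imageROI(ctr(nr), ctr(nc), roiSize, roiSize, "C"),
    CW1 = imageROI(margin, margin, roiSize, roiSize, "CW1"),
    CW2 = imageROI(margin, far(nc), roiSize, roiSize, "CW2"),
    N1  = imageROI(far(nr), margin, roiSize, roiSize, "N1"),
    N2  = imageROI(far(nr), far(nc), roiSize, roiSize, "N2"))
}

#' Analysis ROIs of the phantom layout
#'
#' Derives, from the phantom geometry and detector frame, the pixel ROIs
#' the metric chain uses: the SDNR/contrast ROI inside the Al square, the
#' matched local-background ROI, the homogeneous NPS region, and the two
#' slanted-edge analysis bands straddling the lower (horizontal) and left
#' (vertical) sides of the Cu square. Band sizes are fixed in pixels so
#' scaled and full frames give comparable estimates.
#'
#' @param phantom a [PhantomSpec-class].
#' @param detector a [DetectorSpec-class].
#' @return named list of [ImageROI-class]: `al`, `background`,
#'   `npsRegion`, `edgeH`, `edgeV`.
#' @export
iaeaAnalysisROIs <- function(phantom = iaeaPhantom(),
                             detector = defaultDetector()) {
  p <- detector@pitch; nr <- detector@nrow; nc <- detector@ncol
  px <- function(mm) as.integer(round(mm / p))
  out <- list()
  if (phantom@alPresent) {
    al <- phantom@alSquare
    side <- px(al[["side"]])
    sz <- max(8L, as.integer(round(0.75 * side)))
    r0 <- px(al[["rowCenter"]]) - sz %/% 2L
    c0 <- px(al[["colCenter"]]) - sz %/% 2L
    out$al <- imageROI(r0, c0, sz, sz, "AL")
    # local background: same column band (same heel cross-tilt), directly
    # towards the chest wall, with a small guard gap from the Al edge
    bgRow <- px(al[["rowCenter"]]) - side %/% 2L - 8L - sz
    out$background <- imageROI(bgRow, c0, sz, sz, "BG")
  }
  regionSize <- if (min(nr, nc) >= 2048) 512L else 128L
  out$npsRegion <- imageROI(round(0.39 * nr), round(0.675 * nc),
                            regionSize, regionSize, "NPS")
  if (phantom@cuPresent) {
    cu <- phantom@cuSquare
    half <- px(cu[["side"]]) %/% 2L
    rc <- px(cu[["rowCenter"]]); cc <- px(cu[["colCenter"]])
    # horizontal edge: lower Cu side; band 80 px across x 112 px along
    out$edgeH <- imageROI(rc + half - 40L, cc - 56L, 80L, 112L, "EDGE_H")
    # vertical edge: left Cu side; band 96 px along x 80 px across
    out$edgeV <- imageROI(rc - 48L, cc - half - 40L, 96L, 80L, "EDGE_V")
  }
  out
}
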