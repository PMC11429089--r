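#' @include metrics.R
NULL

.fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(seq.int(n1 / 2 + 1, n1), seq_len(n1 / 2)),
    c(seq.int(n2 / 2 + 1, n2), seq_len(n2 / 2))]
}

#' Normalized noise power spectrum from a homogeneous region
#'
#' Tiles the homogeneous region with half-overlapping square ROIs (nine
#' for a region twice the ROI side), removes a fitted second-order 2D
#' polynomial trend from each ROI, averages the scaled periodograms
#' `pitch^2 / N^2 * |FFT|^2` over ROIs (and over images), and normalizes
#' by the squared offset-subtracted large-area signal to give the
#' normalized NPS in mm^2.
#'
#' Axial sections average the `axisBins` frequency rows on either side of
#' each axis; the radial section averages annuli of width one frequency
#' bin, excluding the bins within `axisBins` of either axis wherever the
#' annulus still has support (low-frequency annuli that would otherwise be
#' empty fall back to all off-DC bins).
#'
#' @param images a [MammoImage-class] or list of them (same settings).
#' @param region an [ImageROI-class], the homogeneous analysis region.
#' @param roiSize analysis ROI side in pixels; default half the region
#'   side (256 in a 512 region, 64 in a 128 region).
#' @param axisBins number of frequency bins flanking each axis used for
#'   the axial sections and excluded from the radial section.
#' @param dcOffset offset for the large-area signal; defaults to the
#'   images' DC offset.
#' @return an [NPSEstimate-class].
#' @export
estimateNNPS <- function(images, region, roiSize = NULL, axisBins = 7,
                         dcOffset = NULL) {
  if (is(images, "MammoImage")) images <- list(images)
  stopifnot(length(images) >= 1)
  pitch <- pixelPitch(images[[1]])
  if (is.null(dcOffset)) dcOffset <- dcOffset(images[[1]])
  if (is.null(roiSize)) roiSize <- as.integer(region@height %/% 2L)
  N <- as.integer(roiSize)
  stride <- N %/% 2L
  if (region@height < 2L * N || region@width < 2L * N)
    stop("region too small for nine half-overlapping ROIs")
  orig <- expand.grid(
    r = seq.int(0L, region@height - N, by = stride),
    c = seq.int(0L, region@width - N, by = stride))
  if (nrow(orig) < 9L)
    stop("fewer than nine half-overlapping ROIs available")
  # shared detrending design: second-order 2D polynomial
  xs <- (seq_len(N) - (N + 1) / 2) / (N / 2)
  X <- outer(xs, rep(1, N)); Y <- outer(rep(1, N), xs)
  design <- cbind(1, as.vector(X), as.vector(Y), as.vector(X)^2,
                  as.vector(X * Y), as.vector(Y)^2)
  qrD <- qr(design)
  acc <- matrix(0, N, N)
  nROI <- 0L
  sigSum <- 0
  varSum <- 0
  for (img in images) {
    px <- pixelData(img)
    if (region@row0 + region@height > nrow(px) ||
        region@col0 + region@width > ncol(px))
      stop("NPS region exceeds the image")
    reg <- cropPixels(img, region)
    sigSum <- sigSum + mean(reg)
    for (k in seq_len(nrow(orig))) {
      v <- reg[orig$r[k] + seq_len(N), orig$c[k] + seq_len(N)]
      res <- qr.resid(qrD, as.vector(v))
      dim(res) <- c(N, N)
      acc <- acc + (pitch^2 / (N * N)) * Mod(stats::fft(res))^2
      varSum <- varSum + sum(res^2) / (N * N)
      nROI <- nROI + 1L
    }
  }
  largeArea <- sigSum / length(images) - dcOffset
  if (largeArea <= 0)
    stop("large-area signal at or below the DC offset")
  nps2d <- .fftshift2(acc / nROI) / largeArea^2
  df <- 1 / (N * pitch)
  kIdx <- seq.int(-N / 2, N / 2 - 1)
  ku <- matrix(kIdx, N, N)         # frequency index along rows
  kv <- matrix(kIdx, N, N, byrow = TRUE)
  half <- seq.int(0L, N / 2 - 1L)
  axial <- function(kAlong, kAcross) {
    vapply(half, function(k) {
      sel <- abs(kAlong) == k & abs(kAcross) >= 1 & abs(kAcross) <= axisBins
      mean(nps2d[sel])
    }, numeric(1))
  }
  au <- axial(ku, kv)
  av <- axial(kv, ku)
  rbin <- round(sqrt(ku^2 + kv^2))
  offAxis <- abs(ku) > axisBins & abs(kv) > axisBins
  radial <- vapply(half, function(m) {
    sel <- rbin == m & offAxis
    if (!any(sel)) sel <- rbin == m & (ku != 0 | kv != 0)
    if (!any(sel)) sel <- rbin == m        # DC annulus only
    mean(nps2d[sel])
  }, numeric(1))
  freqs <- half * df
  new("NPSEstimate",
      axialU = new("NPSCurve", frequencies = freqs, values = au,
                   axis = "axial-u"),
      axialV = new("NPSCurve", frequencies = freqs, values = av,
                   axis = "axial-v"),
      radial = new("NPSCurve", frequencies = freqs, values = radial,
                   axis = "radial"),
      spectrum2d = nps2d, frequencyStep = df,
      largeAreaSignal = largeArea,
      pixelVariance = varSum / nROI)
}
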