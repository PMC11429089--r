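#' @include metrics.R
NULL

# Orient a band so the edge is "vertical": transition along columns,
# scanned row by row.
.orientBand <- function(image, band, orientation) {
  sub <- cropPixels(image, band)
  if (orientation == "horizontal") sub <- t(sub)
  sub
}

#' Fit a slanted-edge model inside an analysis band
#'
#' Locates, per scan line, the subpixel 50 %-threshold crossing of the
#' edge (linear interpolation around the maximum-gradient sample) and fits
#' a straight line through the crossings. The edge must be slanted between
#' 1 and 10 degrees from the axis and its step must exceed five times the
#' local noise SD.
#'
#' @param image a [MammoImage-class].
#' @param band an [ImageROI-class] straddling one edge of the Cu square
#'   (see [iaeaAnalysisROIs()]).
#' @param orientation `"vertical"` (edge nearly parallel to the column
#'   axis) or `"horizontal"`.
#' @return an [EdgeModel-class].
#' @export
estimateEdge <- function(image, band,
                         orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  sub <- .orientBand(image, band, orientation)
  H <- nrow(sub); W <- ncol(sub)
  q <- max(2L, W %/% 5L)
  lo <- rowMeans(sub[, seq_len(q), drop = FALSE])
  hi <- rowMeans(sub[, seq.int(W - q + 1L, W), drop = FALSE])
  noiseSD <- stats::sd(as.vector(
    sub[, seq_len(q), drop = FALSE] - lo))
  step <- mean(hi - lo)
  if (abs(step) <= 5 * max(noiseSD, .Machine$double.eps))
    stop("insufficient edge contrast in the analysis band (< 5 x noise SD)")
  crossings <- numeric(H)
  for (r in seq_len(H)) {
    p <- sub[r, ]
    # light 3-tap smoothing before locating the gradient peak
    ps <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    ps[c(1, W)] <- p[c(1, W)]
    thr <- (lo[r] + hi[r]) / 2
    j <- which.max(abs(diff(ps)))
    # refine: linear interpolation of the threshold crossing near j
    jj <- max(1L, j - 2L):min(W - 1L, j + 2L)
    cr <- NA_real_
    for (k in jj) {
      y0 <- p[k] - thr; y1 <- p[k + 1L] - thr
      if (is.finite(y0) && is.finite(y1) && y0 * y1 <= 0 && y0 != y1) {
        cr <- (k - 1) + y0 / (y0 - y1)  # 0-based subpixel column
        break
      }
    }
    crossings[r] <- if (is.na(cr)) (j - 0.5) else cr
  }
  if (mean(crossings) < 0.05 * W || mean(crossings) > 0.95 * W)
    stop("edge too close to the border of the analysis band")
  rows0 <- seq_len(H) - 1
  fit <- stats::lm.fit(cbind(1, rows0), crossings)
  slope <- fit$coefficients[2]
  angle <- atan(slope) * 180 / pi
  if (abs(angle) < 1 || abs(angle) > 10)
    stop(sprintf(
      "unsuitable edge: angle %.2f degrees outside the [1, 10] range",
      abs(angle)))
  new("EdgeModel", orientation = orientation, angleDeg = as.numeric(angle),
      intercept = as.numeric(fit$coefficients[1]),
      slope = as.numeric(slope), band = band,
      edgeContrast = abs(step))
}

#' Presampled MTF from a slanted edge
#'
#' Projects the band's pixels onto the edge normal, bins the edge-spread
#' function at `binFraction` of a pixel (default quarter-pixel), takes the
#' centred-difference line-spread function, applies a Hann window centred
#' on the LSF peak and returns the normalized DFT magnitude on the
#' supersampled frequency grid (zero-padded for fine frequency sampling).
#'
#' @param image a [MammoImage-class].
#' @param edge an [EdgeModel-class] from [estimateEdge()].
#' @param binFraction ESF bin width as a fraction of the pixel pitch.
#' @param maxFrequencyFactor keep frequencies up to this multiple of the
#'   detector Nyquist frequency.
#' @return an [MTFCurve-class]; value 1 at zero frequency.
#' @export
presampledMTF <- function(image, edge, binFraction = 0.25,
                          maxFrequencyFactor = 1.5) {
  sub <- .orientBand(image, edge@band, edge@orientation)
  pitch <- pixelPitch(image)
  H <- nrow(sub); W <- ncol(sub)
  rows0 <- seq_len(H) - 1; cols0 <- seq_len(W) - 1
  edgeCol <- edge@intercept + edge@slope * rows0
  dpx <- outer(-edgeCol, cols0, "+") * cos(atan(edge@slope))
  d <- as.vector(dpx) * pitch
  w <- binFraction * pitch
  bin <- floor((d - min(d)) / w)
  K <- max(bin) + 1L
  sums <- rowsum(as.vector(sub), bin)
  cnts <- rowsum(rep(1, length(bin)), bin)
  esf <- rep(NA_real_, K)
  esf[as.integer(rownames(sums)) + 1L] <- sums / cnts
  nEmpty <- sum(is.na(esf))
  if (nEmpty > 0.1 * K)
    stop("too many empty ESF bins; increase binFraction")
  if (nEmpty > 0)
    esf <- stats::approx(which(!is.na(esf)), esf[!is.na(esf)],
                         xout = seq_len(K), rule = 2)$y
  lsf <- c(0, (esf[-(1:2)] - esf[seq_len(K - 2L)]) / 2, 0)
  ipk <- which.max(abs(lsf))
  M <- min(ipk - 1L, K - ipk)
  win <- numeric(K)
  idx <- seq.int(ipk - M, ipk + M)
  win[idx] <- 0.5 * (1 + cos(pi * (idx - ipk) / M))
  lsfw <- lsf * win
  npad <- 2^ceiling(log2(max(4 * K, 1024)))
  F <- stats::fft(c(lsfw, numeric(npad - K)))
  mag <- Mod(F)
  if (mag[1] == 0) stop("degenerate LSF: zero integral")
  mtf <- mag / mag[1]
  freqs <- (seq_len(npad) - 1) / (npad * w)
  keep <- freqs <= maxFrequencyFactor / (2 * pitch)
  new("MTFCurve", frequencies = freqs[keep],
      values = pmin(mtf[keep], 1.05))
}

#' Average two orthogonal MTF curves onto a target frequency grid
#'
#' Each curve is linearly interpolated onto `targetFreqs`, then averaged
#' pointwise; the target grid is typically the radial-NNPS grid so that
#' the detectability integrals share one frequency axis.
#'
#' @param mtfH,mtfV [MTFCurve-class] from the horizontal and vertical
#'   edges.
#' @param targetFreqs numeric frequencies (mm^-1) covered by both curves.
#' @return an [MTFCurve-class] on `targetFreqs`.
#' @export
averageOrthogonal <- function(mtfH, mtfV, targetFreqs) {
  for (crv in list(mtfH, mtfV))
    if (max(targetFreqs) > max(frequencies(crv)) ||
        min(targetFreqs) < min(frequencies(crv)))
      stop("target frequencies outside the support of an MTF curve")
  vH <- stats::approx(frequencies(mtfH), curveValues(mtfH), targetFreqs)$y
  vV <- stats::approx(frequencies(mtfV), curveValues(mtfV), targetFreqs)$y
  new("MTFCurve", frequencies = targetFreqs, values = (vH + vV) / 2)
}
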