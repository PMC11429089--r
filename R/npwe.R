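#' @include specs.R
NULL

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Fourier transform of a uniform disc task
#'
#' `S(u) = R * J1(2 pi u R) / u` for `u > 0`, with the continuous limit
#' `S(0) = pi R^2`, where `R` is the disc radius and `J1` the Bessel
#' function of the first kind and order one. Units mm^2.
#'
#' @param diameter disc diameter (mm); the 0.1 and 0.25 mm tasks stand in
#'   for the smallest microcalcifications.
#' @param u spatial frequency (mm^-1), vectorized, `>= 0`.
#' @return numeric vector, same length as `u`.
#' @examples
#' discTaskFT(0.25, 0)            # pi * 0.125^2
#' @export
discTaskFT <- function(diameter, u) {
  stopifnot(diameter > 0, all(u >= 0))
  R <- diameter / 2
  out <- rep(pi * R^2, length(u))
  pos <- u > 0
  out[pos] <- R * besselJ(2 * pi * u[pos] * R, nu = 1) / u[pos]
  out
}

#' Visual transfer function (eye filter) at image-plane frequencies
#'
#' Converts image-plane frequency to angular frequency through the display
#' magnification and viewing distance, then evaluates the band-pass model
#' `VTF(f) = f^e * exp(-c f^2)` normalized to peak 1, with `c` set so the
#' peak sits at `peakFrequency` cycles/degree.
#'
#' @param u image-plane spatial frequency (mm^-1), vectorized.
#' @param spec an [EyeFilterSpec-class]; `NULL` returns 1 everywhere (the
#'   plain non-pre-whitening observer).
#' @return numeric vector in `[0, 1]`.
#' @export
eyeFilter <- function(u, spec = defaultEyeFilter()) {
  if (is.null(spec)) return(rep(1, length(u)))
  validObject(spec)
  # cycles/mm on the display -> cycles/degree at the eye
  f <- (u / spec@magnification) * spec@viewingDistance * pi / 180
  e <- spec@exponent
  cc <- e / (2 * spec@peakFrequency^2)
  peak <- spec@peakFrequency^e * exp(-e / 2)
  f^e * exp(-cc * f^2) / peak
}

#' Construct a [TaskSpec-class]
#'
#' @param diameter disc diameter (mm).
#' @param contrast relative signal contrast (from [measureContrast()]).
#' @export
TaskSpec <- function(diameter, contrast) {
  new("TaskSpec", diameter = diameter, contrast = contrast)
}

#' NPWE detectability index of a disc task
#'
#' The non-pre-whitening model observer with eye filter:
#'
#' `d'^2 = [2 pi C I1]^2 / [2 pi I2]`, with
#' `I1 = integral S^2(u) MTF^2(u) VTF^2(u) u du` and
#' `I2 = integral S^2(u) MTF^2(u) VTF^4(u) nNPS(u) u du`,
#'
#' integrated by the trapezoid rule over the shared frequency grid (the
#' NNPS grid, which for measured curves ends at the detector Nyquist
#' frequency). The closed white-noise form `d' = C sqrt(pi R^2 / N0)` (for
#' MTF = VTF = 1, flat NNPS `N0`, grid extended far beyond the task band)
#' anchors the implementation.
#'
#' @param task a [TaskSpec-class].
#' @param mtf an [MTFCurve-class] covering the NNPS grid.
#' @param nnps an [NPSCurve-class] (typically the radial section).
#' @param eye an [EyeFilterSpec-class], or `NULL` for no eye filter.
#' @return a [DPrimeResult-class].
#' @examples
#' u <- seq(0, 200, by = 0.02)
#' mtf1 <- new("MTFCurve", frequencies = u, values = rep(1, length(u)))
#' n0 <- new("NPSCurve", frequencies = u, values = rep(1e-5, length(u)),
#'           axis = "radial")
#' dPrime(TaskSpec(0.25, 0.1), mtf1, n0, eye = NULL)
#' @export
dPrime <- function(task, mtf, nnps, eye = defaultEyeFilter()) {
  validObject(task)
  u <- frequencies(nnps)
  if (max(u) > max(frequencies(mtf)) || min(u) < min(frequencies(mtf)))
    stop("MTF curve does not cover the NNPS frequency grid")
  m <- stats::approx(frequencies(mtf), curveValues(mtf), u)$y
  m <- pmin(pmax(m, 0), 1.05)
  vtf <- eyeFilter(u, eye)
  S2 <- discTaskFT(task@diameter, u)^2
  nv <- curveValues(nnps)
  I1 <- .trapz(u, S2 * m^2 * vtf^2 * u)
  I2 <- .trapz(u, S2 * m^2 * vtf^4 * nv * u)
  if (task@contrast == 0)
    return(new("DPrimeResult", dprime = 0, numerator = 0,
               denominator = 2 * pi * I2, frequencies = u))
  den <- 2 * pi * I2
  if (den <= 0)
    stop(paste("zero noise integral: d' diverges; use the analytic",
               "noise-free limit instead"))
  num <- (2 * pi * task@contrast * I1)^2
  new("DPrimeResult", dprime = sqrt(num / den), numerator = num,
      denominator = den, frequencies = u)
}
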