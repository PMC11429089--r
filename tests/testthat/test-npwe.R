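flatCurves <- function(umax = 250, du = 0.02, n0 = 2.68e-6) {
  u <- seq(0, umax, by = du)
  list(u = u,
       mtf = new("MTFCurve", frequencies = u, values = rep(1, length(u))),
       nps = new("NPSCurve", frequencies = u, values = rep(n0, length(u)),
                 axis = "radial"))
}

test_that("disc task transform: limit, first zero, raster-DFT oracle", {
  R <- 0.125
  expect_equal(discTaskFT(0.25, 0), pi * R^2)
  expect_equal(discTaskFT(0.25, 1e-12), pi * R^2, tolerance = 1e-6)
  # first zero at the first root of J1
  u0 <- 3.8317 / (2 * pi * R)
  eps <- 0.02
  expect_lt(discTaskFT(0.25, u0 - eps) * discTaskFT(0.25, u0 + eps), 0)
  # brute-force numeric FT of a rasterized disc (2 um grid)
  N <- 1024; px <- 0.002
  xs <- ((1:N) - (N + 1) / 2) * px
  d <- sqrt(outer(xs^2, xs^2, "+"))
  cover <- pmin(pmax(0.5 + (R - d) / px, 0), 1)
  F <- Mod(stats::fft(cover)) * px^2
  u <- (0:(N - 1)) / (N * px)
  k <- which(u <= 125)  # up to half the raster Nyquist
  expect_lt(max(abs(F[k, 1] - abs(discTaskFT(0.25, u[k])))),
            0.01 * pi * R^2)
})

test_that("eye filter is band-pass with the configured peak", {
  spec <- defaultEyeFilter()
  expect_equal(eyeFilter(0, spec), 0)
  expect_lt(eyeFilter(1000, spec), 1e-10)
  u <- seq(0.01, 5, by = 0.001)
  v <- eyeFilter(u, spec)
  expect_equal(max(v), 1, tolerance = 1e-6)
  # peak frequency in image-plane units: f_peak converted back
  uPeak <- u[which.max(v)]
  fPeak <- uPeak / spec@magnification * spec@viewingDistance * pi / 180
  expect_lt(abs(fPeak - spec@peakFrequency), 0.05)
  # NULL spec = plain NPW observer
  expect_equal(eyeFilter(c(0, 1, 5), NULL), c(1, 1, 1))
})

test_that("measured contrast matches the Beer-Lambert prediction", {
  img <- MammoImage(matrix(c(rep(250, 8), rep(150, 8)), 4, 4), 0.07,
                    dcOffset = 50)
  expect_equal(measureContrast(img, imageROI(0, 2, 4, 2),
                               imageROI(0, 0, 4, 2)), 0.5)
  expect_equal(measureContrast(img, imageROI(0, 0, 4, 2),
                               imageROI(0, 0, 4, 2)), 0)
  phImg <- refPhantomImage()
  rois <- iaeaAnalysisROIs(testPhantom(), testDetector())
  beam <- testBeam()
  predicted <- 1 - exp(-beam@mu[["Al"]] *
                         testPhantom()@alSquare[["thickness"]])
  expect_lt(abs(measureContrast(phImg, rois$al, rois$background) /
                  predicted - 1), 0.02)
})

test_that("d' reproduces the white-noise closed form within 1 %", {
  fc <- flatCurves()
  for (dd in c(0.1, 0.25)) {
    got <- dPrimeValue(dPrime(TaskSpec(dd, 0.127), fc$mtf, fc$nps,
                              eye = NULL))
    closed <- 0.127 * sqrt(pi * (dd / 2)^2 / 2.68e-6)
    expect_lt(abs(got / closed - 1), 0.01)
  }
})

test_that("d' is linear in contrast and zero for a null task", {
  fc <- flatCurves(umax = 20)
  expect_equal(dPrimeValue(dPrime(TaskSpec(0.25, 0), fc$mtf, fc$nps)), 0)
  d1 <- dPrimeValue(dPrime(TaskSpec(0.25, 0.1), fc$mtf, fc$nps))
  d3 <- dPrimeValue(dPrime(TaskSpec(0.25, 0.3), fc$mtf, fc$nps))
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("halving the NNPS scales d' by exactly sqrt(2)", {
  fc <- flatCurves(umax = 20)
  half <- new("NPSCurve", frequencies = fc$u,
              values = curveValues(fc$nps) / 2, axis = "radial")
  expect_equal(dPrimeValue(dPrime(TaskSpec(0.25, 0.1), fc$mtf, half)),
               sqrt(2) * dPrimeValue(dPrime(TaskSpec(0.25, 0.1), fc$mtf,
                                            fc$nps)),
               tolerance = 1e-12)
})

test_that("d' is monotone in MTF and NNPS and favours the larger disc", {
  u <- seq(0, 7.14, by = 0.02)
  mtfReal <- new("MTFCurve", frequencies = u,
                 values = exp(-2 * pi^2 * 0.05^2 * u^2))
  mtfBetter <- new("MTFCurve", frequencies = u,
                   values = exp(-2 * pi^2 * 0.03^2 * u^2))
  nps <- new("NPSCurve", frequencies = u,
             values = rep(2.7e-6, length(u)), axis = "radial")
  npsWorse <- new("NPSCurve", frequencies = u,
                  values = 1.5 * curveValues(nps), axis = "radial")
  base <- dPrimeValue(dPrime(TaskSpec(0.25, 0.127), mtfReal, nps))
  expect_gt(dPrimeValue(dPrime(TaskSpec(0.25, 0.127), mtfBetter, nps)),
            base)
  expect_lt(dPrimeValue(dPrime(TaskSpec(0.25, 0.127), mtfReal, npsWorse)),
            base)
  expect_gt(base, dPrimeValue(dPrime(TaskSpec(0.1, 0.127), mtfReal, nps)))
})

test_that("d' is stable under grid refinement", {
  u1 <- seq(0, 7.14, by = 0.05)
  u2 <- seq(0, 7.14, by = 0.025)
  mk <- function(u) list(
    mtf = new("MTFCurve", frequencies = u,
              values = exp(-2 * pi^2 * 0.05^2 * u^2)),
    nps = new("NPSCurve", frequencies = u,
              values = 2.7e-6 * (1 + 0.1 * u / 7), axis = "radial"))
  c1 <- mk(u1); c2 <- mk(u2)
  d1 <- dPrimeValue(dPrime(TaskSpec(0.25, 0.127), c1$mtf, c1$nps))
  d2 <- dPrimeValue(dPrime(TaskSpec(0.25, 0.127), c2$mtf, c2$nps))
  expect_lt(abs(d2 / d1 - 1), 0.005)
})

test_that("zero-noise d' is a degenerate error, not infinity", {
  u <- seq(0, 7, by = 0.1)
  mtf1 <- new("MTFCurve", frequencies = u, values = rep(1, length(u)))
  n0 <- new("NPSCurve", frequencies = u, values = rep(0, length(u)),
            axis = "radial")
  expect_error(dPrime(TaskSpec(0.25, 0.1), mtf1, n0), "zero noise")
})
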