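# synthetic band with a straight edge at a known angle (degrees), slight
# Gaussian blur (0.7 px, as a presampling PSF would leave), low/high
# levels and optional noise
syntheticEdge <- function(angleDeg = 3, H = 96, W = 80, lo = 100, hi = 300,
                          noiseSD = 0, edgeAt = W / 2, seed = 1) {
  set.seed(seed)
  slope <- tan(angleDeg * pi / 180)
  rows0 <- seq_len(H) - 1; cols0 <- seq_len(W) - 1
  d <- outer(-(edgeAt + slope * rows0), cols0, "+") * cos(atan(slope))
  px <- lo + (hi - lo) * pnorm(d / 0.7) +
    noiseSD * matrix(rnorm(H * W), H, W)
  MammoImage(pmax(px, 0), pitch = 0.07, dcOffset = 50)
}

test_that("edge angle is recovered within 0.1 degree", {
  img <- syntheticEdge(3, noiseSD = 5)
  e <- estimateEdge(img, imageROI(0, 0, 96, 80), "vertical")
  expect_lt(abs(abs(e@angleDeg) - 3), 0.1)
  img2 <- syntheticEdge(-6, noiseSD = 5)
  e2 <- estimateEdge(img2, imageROI(0, 0, 96, 80), "vertical")
  expect_lt(abs(abs(e2@angleDeg) - 6), 0.1)
})

test_that("axis-aligned, borderline and low-contrast edges are rejected", {
  expect_error(estimateEdge(syntheticEdge(0, noiseSD = 2),
                            imageROI(0, 0, 96, 80), "vertical"),
               "unsuitable edge")
  expect_error(estimateEdge(syntheticEdge(3, edgeAt = 77, noiseSD = 2),
                            imageROI(0, 0, 96, 80), "vertical"),
               "border|contrast")
  expect_error(estimateEdge(syntheticEdge(3, lo = 200, hi = 203,
                                          noiseSD = 5),
                            imageROI(0, 0, 96, 80), "vertical"),
               "contrast")
})

test_that("slanted-edge MTF recovers a known Gaussian blur", {
  img <- noiselessBlurImage()  # psfSigma = 0.1 mm, zero noise
  rois <- iaeaAnalysisROIs(iaeaPhantom(testDetector()), testDetector())
  nyq <- 1 / (2 * 0.07)
  for (o in c("horizontal", "vertical")) {
    band <- if (o == "horizontal") rois$edgeH else rois$edgeV
    e <- estimateEdge(img, band, o)
    m <- presampledMTF(img, e)
    expect_equal(curveValues(m)[1], 1)  # exact at u = 0
    sel <- frequencies(m) <= 0.8 * nyq
    truth <- exp(-2 * pi^2 * 0.1^2 * frequencies(m)[sel]^2)
    expect_lt(max(abs(curveValues(m)[sel] - truth)), 0.02)
  }
})

test_that("an unblurred edge stays above the pixel-aperture sinc envelope", {
  det <- testDetector(psfSigma = 0, electronicSD = 0)
  det@quantumGain <- 0
  img <- simulatePhantom(iaeaPhantom(det), det, testBeam(),
                         ExposureSettings(28, 120, "manual"), seed = 3)
  rois <- iaeaAnalysisROIs(iaeaPhantom(det), det)
  e <- estimateEdge(img, rois$edgeV, "vertical")
  m <- presampledMTF(img, e)
  nyq <- 1 / (2 * 0.07)
  sel <- frequencies(m) <= nyq & frequencies(m) > 0
  u <- frequencies(m)[sel]
  sincEnv <- abs(sin(pi * u * 0.07) / (pi * u * 0.07))
  expect_true(all(curveValues(m)[sel] >= sincEnv - 0.03))
})

test_that("MTF estimation is invariant to gain and offset changes", {
  img <- noiselessBlurImage()
  rois <- iaeaAnalysisROIs(iaeaPhantom(testDetector()), testDetector())
  e <- estimateEdge(img, rois$edgeV, "vertical")
  m1 <- presampledMTF(img, e)
  img2 <- MammoImage(3 * pixelData(img) + 200, pixelPitch(img),
                     dcOffset = dcOffset(img))
  e2 <- estimateEdge(img2, rois$edgeV, "vertical")
  m2 <- presampledMTF(img2, e2)
  expect_equal(curveValues(m1), curveValues(m2), tolerance = 1e-8)
})

test_that("orthogonal averaging interpolates and averages pointwise", {
  u <- seq(0, 7, by = 0.5)
  f <- new("MTFCurve", frequencies = u, values = exp(-0.1 * u^2) )
  g <- new("MTFCurve", frequencies = u, values = exp(-0.05 * u^2))
  tf <- seq(0, 6, by = 0.25)
  avg <- averageOrthogonal(f, g, tf)
  same <- averageOrthogonal(f, f, u)
  expect_equal(curveValues(same), curveValues(f))
  # exact at shared nodes
  node <- match(u[u <= 6], tf)
  expect_equal(curveValues(avg)[node],
               (curveValues(f)[u <= 6] + curveValues(g)[u <= 6]) / 2)
  expect_error(averageOrthogonal(f, g, seq(0, 10, 1)), "outside")
})

test_that("white-noise NNPS is flat at the closed-form level", {
  imgs <- whiteNoiseStack()
  np <- estimateNNPS(imgs, imageROI(0, 0, 128, 128))
  expected <- 20^2 * 0.07^2 / 950^2
  v <- curveValues(np@radial)
  # detrending eats the lowest annuli; assess the band above them
  expect_lt(abs(mean(v[-(1:2)]) / expected - 1), 0.05)
  expect_true(all(abs(v[-(1:2)] / expected - 1) < 0.15))
  # flatness: no trend with frequency
  fit <- lm(v[-(1:2)] ~ frequencies(np@radial)[-(1:2)])
  expect_lt(abs(coef(fit)[2]) * max(frequencies(np@radial)),
            0.05 * mean(v[-(1:2)]))
})

test_that("radial and axial NNPS of isotropic white noise agree", {
  imgs <- whiteNoiseStack(n = 20, seed = 6)
  np <- estimateNNPS(imgs, imageROI(0, 0, 128, 128))
  sel <- 4:28
  for (ax in list(np@axialU, np@axialV)) {
    rel <- curveValues(np@radial)[sel] / curveValues(ax)[sel] - 1
    expect_lt(max(abs(rel)), 0.10)
  }
})

test_that("NNPS of a constant image vanishes off DC", {
  img <- MammoImage(matrix(800, 128, 128), pitch = 0.07, dcOffset = 50)
  np <- estimateNNPS(img, imageROI(0, 0, 128, 128))
  expect_lt(max(curveValues(np@radial)[-1]), 1e-20)
})

test_that("the averaged periodogram satisfies Parseval's identity", {
  imgs <- whiteNoiseStack()
  np <- estimateNNPS(imgs, imageROI(0, 0, 128, 128))
  lhs <- sum(np@spectrum2d) * np@frequencyStep^2
  rhs <- np@pixelVariance / np@largeAreaSignal^2
  expect_lt(abs(lhs / rhs - 1), 0.02)
})

test_that("blur-correlated noise rolls off with frequency", {
  set.seed(8)
  imgs <- lapply(1:5, function(k) {
    w <- matrix(rnorm(140 * 140), 140, 140)
    sm <- stats::filter(w, rep(1 / 3, 3), circular = TRUE)
    sm <- t(stats::filter(t(sm), rep(1 / 3, 3), circular = TRUE))
    MammoImage(1000 + 20 * sm[7:134, 7:134], pitch = 0.07, dcOffset = 50)
  })
  np <- estimateNNPS(imgs, imageROI(0, 0, 128, 128))
  v <- curveValues(np@radial)
  expect_gt(mean(v[3:8]), 2 * mean(v[25:31]))
})

test_that("degenerate NNPS inputs are rejected", {
  img <- MammoImage(matrix(800, 64, 64), pitch = 0.07, dcOffset = 50)
  expect_error(estimateNNPS(img, imageROI(0, 0, 128, 128)), "exceeds")
  expect_error(estimateNNPS(img, imageROI(0, 0, 64, 64), roiSize = 48),
               "nine")
})
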