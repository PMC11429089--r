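test_that("zero exposure leaves only the DC offset", {
  det <- testDetector()
  m <- buildMeanSignalMap(testPhantom(), testBeam(), det,
                          ExposureSettings(28, 0, "manual"))
  expect_true(all(m == det@dcOffset))
})

test_that("mean signal follows Beer-Lambert by hand on a uniform slab", {
  det <- testDetector(heelAmplitude = 0)
  det@gain <- 10
  slab <- pmmaSlab(det, pmmaThickness = 45)  # mu * t = 0.06 * 45 = 2.7
  m <- buildMeanSignalMap(slab, testBeam(), det,
                          ExposureSettings(28, 100, "manual"))
  expect_equal(unique(as.vector(round(m, 9))),
               round(50 + 10 * 100 * exp(-2.7), 9))
  expect_equal(m[1, 1], 117.2064, tolerance = 1e-4)
})

test_that("attenuation orders the insert means: Cu < Al < background", {
  img <- refPhantomImage()
  rois <- iaeaAnalysisROIs(testPhantom(), testDetector())
  cuRoi <- imageROI(60, 290, 40, 40)  # well inside the Cu square
  cuMean <- mean(cropPixels(img, cuRoi))
  alMean <- mean(cropPixels(img, rois$al))
  bgMean <- mean(cropPixels(img, rois$background))
  expect_lt(cuMean, alMean)
  expect_lt(alMean, bgMean)
})

test_that("unknown material in the beam map is a configuration error", {
  det <- testDetector()
  beam <- testBeam()
  beam@mu <- c(PMMA = 0.06)  # no Cu entry
  expect_error(
    buildMeanSignalMap(testPhantom(), beam, det,
                       ExposureSettings(28, 100, "manual")),
    "material 'Cu'")
})

test_that("same seed gives a bit-identical image, and no RNG state leaks", {
  det <- testDetector()
  m <- buildMeanSignalMap(testPhantom(), testBeam(), det,
                          ExposureSettings(28, 100, "manual"))
  set.seed(123); before <- rnorm(3)
  set.seed(123)
  a <- simulateAcquisition(m, det, seed = 7)
  after <- rnorm(3)
  b <- simulateAcquisition(m, det, seed = 7)
  expect_identical(pixelData(a), pixelData(b))
  expect_identical(before, after)  # caller's RNG stream untouched
})

test_that("realized noise variance matches the configured model", {
  det <- testDetector()
  m <- matrix(500, 400, 256)  # uniform mean, 102400 px
  img <- simulateAcquisition(m, det, seed = 11)
  v <- var(as.vector(pixelData(img)))
  expected <- det@quantumGain * (500 - det@dcOffset) + det@electronicSD^2
  expect_lt(abs(v / (expected + 1 / 12) - 1), 0.05)  # 1/12: integer rounding
})

test_that("quadrupling mAs doubles ROI SNR in the quantum-limited regime", {
  det <- testDetector(electronicSD = 0, heelAmplitude = 0)
  slab <- pmmaSlab(det, 40)
  roi <- imageROI(200, 200, 64, 64)
  snr1 <- roiSNR(simulateAcquisition(
    buildMeanSignalMap(slab, testBeam(), det,
                       ExposureSettings(28, 25, "manual")),
    det, seed = 21), roi)
  snr4 <- roiSNR(simulateAcquisition(
    buildMeanSignalMap(slab, testBeam(), det,
                       ExposureSettings(28, 100, "manual")),
    det, seed = 22), roi)
  # SNR estimate SE over a 64x64 ROI is about SNR / sqrt(2 n)
  se <- 3 * snr4 / sqrt(2 * 64^2)
  expect_lt(abs(snr4 / snr1 - 2), 3 * se / snr1 + 0.02)
})

test_that("mean background signal is linear in mAs (heel off)", {
  det <- testDetector(heelAmplitude = 0)
  slab <- pmmaSlab(det, 40)
  mas <- c(20, 50, 200)
  lvl <- vapply(mas, function(x)
    mean(buildMeanSignalMap(slab, testBeam(), det,
                            ExposureSettings(28, x, "manual"))) -
      det@dcOffset, numeric(1))
  expect_lt(max(abs(lvl / mas / (lvl[1] / mas[1]) - 1)), 0.01)
})

test_that("AEC selects identical mAs at all positions on a uniform slab", {
  for (amp in c(0, 1)) {
    det <- testDetector(heelAmplitude = amp)
    slab <- pmmaSlab(det, 40)
    mas <- vapply(1:7, function(p)
      emulateAEC(slab, testBeam(), det, p)@mas, numeric(1))
    expect_length(unique(mas), 1)
  }
})

test_that("AEC compensates Cu coverage with the servo closed form", {
  det <- testDetector()
  ph <- testPhantom()
  beam <- testBeam()
  masUnder <- emulateAEC(ph, beam, det, 1)@mas    # footprint fully under Cu
  masOut <- emulateAEC(ph, beam, det, 5)@mas      # fully outside
  tCu <- exp(-beam@mu[["Cu"]] * ph@cuSquare[["thickness"]])
  expect_lt(abs(masUnder - masOut / tCu), 1.0)    # within quantization
  # monotone non-increasing mAs as coverage drops along positions 1..7
  mas <- vapply(1:7, function(p) emulateAEC(ph, beam, det, p)@mas,
                numeric(1))
  expect_true(all(diff(mas) <= 0.5 + 1e-9))
  expect_true(min(mas[1:3]) > max(mas[4:7]))
})

test_that("an unreachable servo target raises a saturation error", {
  det <- testDetector()
  expect_error(
    emulateAEC(testPhantom(), testBeam(), det, 1, targetSignal = 500,
               masCap = 50),
    "saturation")
})

test_that("flat field with heel off is uniform across the standard ROIs", {
  det <- testDetector(heelAmplitude = 0)
  ff <- generateFlatField(40, det, testBeam(), seed = 31)
  st <- do.call(rbind, lapply(standardROIs(ff), function(r)
    roiStats(ff, r)))
  se <- st$sd / sqrt(st$n)
  z <- abs(outer(st$mean, st$mean, "-")) /
    sqrt(outer(se^2, se^2, "+"))
  expect_lt(max(z[upper.tri(z)]), 2.58)  # pairwise z-test at alpha = 0.01
})

test_that("default heel field reproduces the corner SNR signature", {
  ff <- generateFlatField(40, testDetector(), testBeam(), seed = 1)
  snr <- vapply(standardROIs(ff), function(r) roiSNR(ff, r), numeric(1))
  rel <- 100 * (snr[-1] / snr[["C"]] - 1)
  expect_true(all(rel[c("CW1", "CW2")] > 0 & rel[c("CW1", "CW2")] < 15))
  expect_true(all(rel[c("N1", "N2")] > -32 & rel[c("N1", "N2")] < -18))
})

test_that("heel field stays in (0, 1] and amplitude 0 flattens it", {
  det <- testDetector()
  h <- heelField(det)
  expect_true(all(h > 0 & h <= 1))
  det0 <- testDetector(heelAmplitude = 0)
  expect_true(all(heelField(det0) == 1))
})

test_that("scaled and larger frames agree on fixed-pixel ROI statistics", {
  beam <- testBeam()
  det1 <- testDetector()
  det2 <- testDetector("custom", nrow = 1024, ncol = 1280)
  roiOf <- function(det) {
    # 64 px ROI at the frame centre (heel centre plateau in both frames)
    imageROI(det@nrow / 2 - 32, det@ncol / 2 - 32, 64, 64)
  }
  s1 <- roiStats(generateFlatField(40, det1, beam, seed = 51), roiOf(det1))
  s2 <- roiStats(generateFlatField(40, det2, beam, seed = 52), roiOf(det2))
  # same exposure, same heel level: means differ only by sampling error
  seDiff <- sqrt(s1$sd^2 / s1$n + s2$sd^2 / s2$n)
  expect_lt(abs(s1$mean - s2$mean), 4 * seDiff)
  expect_lt(abs(s1$sd / s2$sd - 1), 0.1)
})

test_that("negative mean-map values are rejected by the noise stage", {
  det <- testDetector()
  expect_error(simulateAcquisition(matrix(0, 4, 4), det, seed = 1),
               "dcOffset")
})
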