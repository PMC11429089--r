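# Shared fixtures, built once per test run and cached.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

testDetector <- function(...) defaultDetector(...)
testBeam <- function() defaultBeam()

testPhantom <- function() memo("phantom", iaeaPhantom(defaultDetector()))

# one default-condition phantom image at the reference AEC position
refPhantomImage <- function() memo("refimg", {
  simulatePhantom(testPhantom(), defaultDetector(), testBeam(),
                  seed = 42, aecPosition = 4)
})

# noiseless acquisition with a wide (0.1 mm) Gaussian PSF for MTF checks
noiselessBlurImage <- function() memo("blurimg", {
  det <- defaultDetector(psfSigma = 0.1, electronicSD = 0)
  det@quantumGain <- 0
  simulatePhantom(iaeaPhantom(det), det, testBeam(),
                  ExposureSettings(28, 120, "manual"), seed = 1)
})

# stack of pure white-Gaussian-noise frames for NNPS checks
whiteNoiseStack <- function(n = 10, mean = 1000, sd = 20, N = 128,
                            offset = 50, seed = 5) {
  memo(sprintf("wn_%d_%g_%g_%d", n, mean, sd, seed), {
    set.seed(seed)
    lapply(seq_len(n), function(k)
      MammoImage(matrix(mean + sd * rnorm(N * N), N, N), pitch = 0.07,
                 dcOffset = offset))
  })
}
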