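#' @include simulate.R
NULL

.exposureToList <- function(e) {
  if (is.null(e)) return(NULL)
  list(kvp = e@kvp, mas = e@mas, mode = e@mode,
       aecPosition = if (is.na(e@aecPosition)) NULL else e@aecPosition,
       masReductionLevel = e@masReductionLevel)
}

.exposureFromList <- function(l) {
  if (is.null(l)) return(NULL)
  ExposureSettings(kvp = l$kvp, mas = l$mas, mode = l$mode,
                   aecPosition = if (is.null(l$aecPosition)) NA
                     else l$aecPosition,
                   masReductionLevel = if (is.null(l$masReductionLevel)) 0
                     else l$masReductionLevel)
}

#' Write / read a linear image as 16-bit TIFF plus JSON sidecar
#'
#' The pixel counts are stored losslessly as 16-bit grayscale TIFF; the
#' acquisition context (pixel pitch, DC offset, exposure settings, seed)
#' goes into a JSON sidecar next to the image (`<path>.json`). Reading
#' requires the sidecar: the pixel pitch is never guessed.
#'
#' @param image a [MammoImage-class] with integer counts in
#'   `[0, 65535]`.
#' @param path output TIFF path.
#' @return `writeMammoImage`: the path, invisibly. `readMammoImage`: a
#'   [MammoImage-class] identical to the one written.
#' @export
writeMammoImage <- function(image, path) {
  px <- pixelData(image)
  if (any(px != round(px)) || max(px) > 65535)
    stop("pixels must be integer counts in [0, 65535] for 16-bit TIFF")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- imageMeta(image)
  side <- list(pitch = pixelPitch(image), dcOffset = dcOffset(image),
               exposure = .exposureToList(meta$exposure),
               seed = meta$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeMammoImage
#' @export
readMammoImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such image: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar %s: pixel pitch is never guessed",
                 sidecar))
  px <- tryCatch(tiff::readTIFF(path, as.is = FALSE),
                 error = function(e)
                   stop(sprintf("cannot parse TIFF %s: %s", path,
                                conditionMessage(e))))
  if (length(dim(px)) != 2)
    stop("expected single-channel grayscale TIFF")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$pitch)) stop("sidecar lacks the pixel pitch")
  meta <- list(exposure = .exposureFromList(side$exposure),
               seed = side$seed)
  MammoImage(round(px * 65535), pitch = side$pitch,
             dcOffset = side$dcOffset,
             meta = meta[!vapply(meta, is.null, logical(1))])
}

#' Generate the deterministic fixture corpus
#'
#' Writes the small image corpus the test suite and worked examples use:
#' five flat-field repeats, one phantom acquisition per AEC position,
#' manual recommended and reduced exposures, a noiseless edge image and a
#' three-frame white-noise stack — each as 16-bit TIFF with a JSON
#' sidecar, plus a manifest with MD5 hashes. The same seed reproduces the
#' corpus byte for byte.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer base seed.
#' @param detector a [DetectorSpec-class].
#' @param beam a [BeamSpec-class].
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
generateFixtures <- function(outDir, seed = 1,
                             detector = defaultDetector(),
                             beam = defaultBeam()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  phantom <- iaeaPhantom(detector)
  files <- character()
  put <- function(img, name) {
    p <- file.path(outDir, name)
    writeMammoImage(img, p)
    files <<- c(files, p, paste0(p, ".json"))
  }
  for (k in 1:5)
    put(generateFlatField(40, detector, beam, seed = seed + k),
        sprintf("flatfield_rep%d.tif", k))
  for (pos in 1:7)
    put(simulatePhantom(phantom, detector, beam, seed = seed + 100 + pos,
                        aecPosition = pos),
        sprintf("phantom_aec%d.tif", pos))
  kvp <- kvpForThickness(phantom@pmmaThickness)
  put(simulatePhantom(phantom, detector, beam,
                      ExposureSettings(kvp, 120, "manual"),
                      seed = seed + 200),
      "phantom_manual120.tif")
  put(simulatePhantom(phantom, detector, beam,
                      ExposureSettings(kvp, 120 * 0.87, "manual",
                                       masReductionLevel = 1),
                      seed = seed + 201),
      "phantom_manual_reduced.tif")
  detNoiseless <- detector
  detNoiseless@quantumGain <- 0; detNoiseless@electronicSD <- 0
  put(simulatePhantom(phantom, detNoiseless, beam,
                      ExposureSettings(kvp, 120, "manual"),
                      seed = seed + 300),
      "phantom_noiseless_edge.tif")
  for (k in 1:3) {
    px <- .withSeed(seed + 400 + k, {
      matrix(round(pmax(0, 500 + 10 * stats::rnorm(64 * 64))), 64, 64)
    })
    put(MammoImage(px, pitch = detector@pitch, dcOffset = 0,
                   meta = list(seed = seed + 400 + k)),
        sprintf("whitenoise_rep%d.tif", k))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a simulation/experiment run configuration from YAML
#'
#' Assembles detector, beam, phantom and exposure objects from a YAML
#' file with optional `detector`, `beam`, `phantom`, `exposure` and
#' `experiment` blocks; unknown fields are rejected so configs stay
#' honest. Fields not given fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with elements `detector`, `beam`, `phantom`, `exposure`
#'   (may be `NULL`), `experiment` (list).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("detector", "beam", "phantom", "exposure", "experiment")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("unknown config blocks: %s", paste(extra, collapse = ", ")))
  pick <- function(block, allowed) {
    b <- cfg[[block]]
    if (is.null(b)) return(list())
    bad <- setdiff(names(b), allowed)
    if (length(bad))
      stop(sprintf("unknown fields in '%s': %s", block,
                   paste(bad, collapse = ", ")))
    b
  }
  db <- pick("detector", c("frame", "nrow", "ncol", "heelAmplitude",
                           "electronicSD", "psfSigma"))
  detector <- do.call(defaultDetector, db)
  bb <- pick("beam", c("kvp"))
  beam <- do.call(defaultBeam, bb)
  pb <- pick("phantom", c("pmmaThickness", "cuAngle", "withCu", "withAl"))
  phantom <- do.call(iaeaPhantom, c(list(detector = detector), pb))
  eb <- pick("exposure", c("kvp", "mas", "mode", "aecPosition",
                           "masReductionLevel"))
  exposure <- if (length(eb)) do.call(ExposureSettings, eb) else NULL
  list(detector = detector, beam = beam, phantom = phantom,
       exposure = exposure, experiment = pick("experiment",
         c("positions", "replicates", "seedBase", "recommendedMas",
           "reductionFraction", "referencePosition", "alpha")))
}
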