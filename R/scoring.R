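#' Well image container
#'
#' An 8-bit grayscale photograph of one culture well, together with the
#' geometry of the well disc used for cropping. Pixel values are stored as a
#' numeric matrix on the 0-255 scale.
#'
#' @param pixels numeric matrix of grey levels in \[0, 255\].
#' @param center well-disc center `c(row, col)` in pixels; defaults to the
#'   raster center.
#' @param radius well-disc radius in pixels; defaults to 70% of half the
#'   shorter raster side.
#' @return an object of class `well_image`.
#' @export
well_image <- function(pixels, center = NULL, radius = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  center <- center %||% ((dim(pixels) + 1) / 2)
  radius <- radius %||% floor(min(dim(pixels)) / 2 * 0.7)
  if (center[1] - radius < 1 || center[1] + radius > nrow(pixels) ||
      center[2] - radius < 1 || center[2] + radius > ncol(pixels)) {
    stop_rpe("well disc (center %.1f,%.1f radius %.1f) exceeds the %dx%d raster",
             center[1], center[2], radius, nrow(pixels), ncol(pixels))
  }
  structure(list(pixels = pixels, center = center, radius = radius),
            class = "well_image")
}

#' Pigmentation scoring configuration
#'
#' Constants of the pigmented-area pipeline. The pipeline steps (Gaussian
#' blur, background subtraction, constant-threshold binarization, well-disc
#' crop) are fixed; the constants are calibrated on the synthetic well
#' generator and fully exposed here. Background estimation is a grayscale
#' morphological closing with a disc structuring element (a rolling-ball-style
#' estimate of the illumination field over the dark pigment blobs); its
#' radius must exceed the largest distance from any disc pixel to background
#' so the illumination is recovered everywhere.
#'
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param background_radius structuring-element radius in pixels for the
#'   closing-based background estimate.
#' @param threshold 8-bit intensity constant applied to the
#'   background-minus-image difference; pixels deeper than this count as
#'   pigmented.
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(blur_sigma = 2.0, background_radius = 64,
                           threshold = 40) {
  stopifnot(blur_sigma > 0, threshold > 0, threshold < 255,
            background_radius >= 1)
  structure(list(blur_sigma = blur_sigma,
                 background_radius = background_radius,
                 threshold = threshold),
            class = "scoring_config")
}

disc_mask <- function(dims, center, radius) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cl <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (r - center[1])^2 + (cl - center[2])^2 <= radius^2
}

#' Pigmented-area score of a well image
#'
#' Pipeline, in order: Gaussian blur; background estimation by grayscale
#' closing (dilation then erosion with a disc structuring element) and
#' subtraction, which removes smooth illumination gradients and constant
#' offsets; binarization of the background-minus-image difference at a
#' constant threshold (pigment is darker than background); crop to the well
#' disc; score = pigment-positive pixels inside the disc / disc pixels.
#'
#' @param img a [well_image()].
#' @param cfg a [scoring_config()].
#' @return pigmentation score in \[0, 1\].
#' @examples
#' sw <- synthesize_well_image(0.3, seed = 1)
#' score_image(sw$image)
#' @export
score_image <- function(img, cfg = scoring_config()) {
  stopifnot(inherits(img, "well_image"), inherits(cfg, "scoring_config"))
  px <- img$pixels
  blurred <- as.matrix(EBImage::gblur(px, sigma = cfg$blur_sigma))

  side <- 2L * as.integer(cfg$background_radius) + 1L
  max_side <- min(dim(px)) - (1 - min(dim(px)) %% 2)  # largest odd <= min dim
  if (side > max_side) side <- max_side
  brush <- EBImage::makeBrush(side, shape = "disc")
  # EBImage grayscale morphology saturates outside [0,1]; work on that scale
  closed <- EBImage::erode(EBImage::dilate(blurred / 255, brush), brush)
  background <- as.matrix(closed) * 255

  pigment <- (background - blurred) > cfg$threshold
  disc <- disc_mask(dim(px), img$center, img$radius)
  sum(pigment & disc) / sum(disc)
}

#' Synthesize a well image with known pigmented fraction
#'
#' Renders a well disc carrying dark pigmented blobs that cover exactly the
#' requested fraction of the disc (by constructive pixel counting), on a
#' bright background with a smooth linear illumination gradient and seeded
#' Gaussian pixel noise. Blobs are grown around random seed points by ranking
#' disc pixels on their (jittered, weighted) distance to the nearest seed and
#' taking the first `round(fraction * disc pixels)` — so for a fixed seed the
#' truth masks of increasing fractions are nested. The exact truth mask is
#' returned alongside the image.
#'
#' @param fraction target pigmented fraction of the well disc, in \[0, 1\].
#' @param seed integer seed.
#' @param size raster side length in pixels (square image).
#' @param radius well-disc radius in pixels.
#' @param n_blobs number of blob seed points.
#' @param background mean background grey level.
#' @param depth grey-level depth of pigment below background; the default
#'   scoring threshold (40) sits at half this depth, so the blur-smeared
#'   blob boundary is recovered without bias.
#' @param gradient amplitude of the linear illumination gradient (grey levels).
#' @param noise_sd standard deviation of the pixel noise (grey levels).
#' @return list with `image` (a [well_image()]) and `truth_mask` (logical
#'   matrix, `TRUE` = pigmented).
#' @export
synthesize_well_image <- function(fraction, seed = 1L, size = 160L,
                                  radius = 56, n_blobs = 6L,
                                  background = 170, depth = 80,
                                  gradient = 15, noise_sd = 4) {
  stopifnot(fraction >= 0, fraction <= 1)
  size <- as.integer(size)
  center <- c((size + 1) / 2, (size + 1) / 2)
  disc <- disc_mask(c(size, size), center, radius)
  n_disc <- sum(disc)
  target <- round(fraction * n_disc)

  withr::with_seed(seed, {
    rr <- matrix(seq_len(size), size, size)
    cc <- matrix(seq_len(size), size, size, byrow = TRUE)

    truth <- matrix(FALSE, size, size)
    if (target > 0) {
      theta <- runif(n_blobs, 0, 2 * pi)
      rad <- radius * sqrt(runif(n_blobs, 0.05, 0.85))
      sr <- center[1] + rad * cos(theta)
      sc <- center[2] + rad * sin(theta)
      wt <- runif(n_blobs, 0.6, 1.6)
      prio <- matrix(Inf, size, size)
      for (b in seq_len(n_blobs)) {
        d <- sqrt((rr - sr[b])^2 + (cc - sc[b])^2) * wt[b]
        prio <- pmin(prio, d)
      }
      prio <- prio + matrix(runif(size * size, 0, 0.01), size, size)
      prio[!disc] <- Inf
      cut <- sort(prio[disc], partial = target)[target]
      truth <- prio <= cut
      # exact count: resolve any ties at the cut (jitter makes them unlikely)
      excess <- sum(truth) - target
      if (excess > 0) {
        at_cut <- which(truth & abs(prio - cut) < 1e-12)
        truth[at_cut[seq_len(excess)]] <- FALSE
      }
    }

    dir <- runif(1, 0, 2 * pi)
    illum <- background + gradient *
      (cos(dir) * (rr / size - 0.5) + sin(dir) * (cc / size - 0.5)) * 2
    px <- illum - depth * truth +
      matrix(rnorm(size * size, 0, noise_sd), size, size)
    px <- pmin(pmax(px, 0), 255)
  })

  list(image = well_image(px, center = center, radius = radius),
       truth_mask = truth)
}

#' Score a plate-layout list of well images
#'
#' Applies [score_image()] to each well of a round. `images` is a list in
#' slot order matching `plate`/`well`; a `NULL` element (a missing or
#' deficient well) yields an `NA` score with a warning, mirroring a round in
#' which one condition could not be validated.
#'
#' @param images list of [well_image()] objects (or `NULL` for missing).
#' @param cfg a [scoring_config()].
#' @param plate,well slot indices; default the 8 x 6 plate-major layout.
#' @return data frame with columns `plate`, `well`, `score`.
#' @export
score_plate <- function(images, cfg = scoring_config(),
                        plate = rep(1:8, each = 6), well = rep(1:6, times = 8)) {
  n <- length(images)
  plate <- rep_len(plate, n)
  well <- rep_len(well, n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(images[[i]])) {
      warn_rpe("missing image for plate %d well %d; score left empty",
               plate[i], well[i])
    } else {
      score[i] <- score_image(images[[i]], cfg)
    }
  }
  data.frame(plate = plate, well = well, score = score)
}

#' Read / write well images (PNG, TIFF)
#'
#' RGB inputs are converted to grayscale with Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); intensities are rescaled to 0-255.
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @param center,radius optional well-disc geometry (see [well_image()]).
#' @return `read_well_image()`: a [well_image()].
#' @export
read_well_image <- function(path, center = NULL, radius = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_rpe("unsupported image format: .%s", ext))
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , 1]
  }
  well_image(arr * 255, center = center, radius = radius)
}

#' @param img a [well_image()] to write (PNG only).
#' @rdname read_well_image
#' @return `write_well_image()`: invisibly `path`.
#' @export
write_well_image <- function(img, path) {
  stopifnot(inherits(img, "well_image"))
  png::writePNG(pmin(pmax(img$pixels / 255, 0), 1), path)
  invisible(path)
}

#' Score a directory of well images
#'
#' Scores every PNG/TIFF in `dir` whose filename contains a
#' `<plate>-<well>` or `<plate>_<well>` pair (e.g. `well_2-3.png`), and
#' writes a `plate, well, score` CSV.
#'
#' @param dir directory of images.
#' @param out optional CSV output path.
#' @param cfg a [scoring_config()].
#' @param center,radius optional disc geometry forwarded to
#'   [read_well_image()].
#' @return the score data frame, invisibly if `out` is given.
#' @export
score_image_dir <- function(dir, out = NULL, cfg = scoring_config(),
                            center = NULL, radius = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop_rpe("no PNG/TIFF images found in %s", dir)
  m <- regmatches(basename(files),
                  regexpr("([0-9]+)[-_]([0-9]+)", basename(files)))
  if (any(lengths(m) == 0)) {
    stop_rpe("cannot parse <plate>-<well> from: %s",
             basename(files)[which(lengths(m) == 0)[1]])
  }
  pw <- do.call(rbind, strsplit(unlist(m), "[-_]"))
  imgs <- lapply(files, read_well_image, center = center, radius = radius)
  res <- score_plate(imgs, cfg, plate = as.integer(pw[, 1]),
                     well = as.integer(pw[, 2]))
  if (!is.null(out)) {
    write.csv(res, out, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(res))
  }
  res
}
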