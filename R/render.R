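# Dark-field-like rendering of centerline series into uint16 image stacks.

#' Render a centerline series into a synthetic dark-field image stack
#'
#' Each frame is drawn as a bright ridge along the centerline (uniform linear
#' intensity density), convolved with a Gaussian point-spread function, on a
#' uniform background. Counts are Poisson shot noise on (background + ridge)
#' plus Gaussian read noise, quantized to uint16. The canvas is sized to
#' contain the flagellum in every frame with a margin.
#'
#' The signal-to-noise ratio is defined as the mid-ridge peak intensity over
#' the background noise standard deviation `sqrt(background + read_noise^2)`.
#'
#' @param series a `centerline_series` (um coordinates, head at origin).
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian PSF standard deviation in um.
#' @param snr peak-signal-to-noise ratio; sets the ridge peak intensity.
#' @param background mean background level in counts.
#' @param read_noise Gaussian read-noise standard deviation in counts.
#' @param noise one of `"poisson-gaussian"` (default) or `"none"`.
#' @param margin_px margin around the flagellum's bounding box, in pixels.
#' @param dim optional `c(nrow, ncol)` canvas size; with `origin`, overrides
#'   the automatic bounding box. A flagellum leaving this canvas is an error.
#' @param origin optional um coordinates `c(x, y)` of the center of pixel
#'   (row 1, col 1).
#' @param seed optional integer seed for the noise realization.
#' @return a `synthetic_scene`: list with `images` (list of integer matrices,
#'   rows = y), `pixel_size`, `psf_sigma`, `origin`, `fps`, `ground_truth`
#'   (the input series), `label` (NULL unless set by the population sampler).
#' @export
render_frames <- function(series, pixel_size = 0.33, psf_sigma = 0.6,
                          snr = 10, background = 100, read_noise = 3,
                          noise = c("poisson-gaussian", "none"),
                          margin_px = 8, dim = NULL, origin = NULL,
                          seed = NULL) {
  stopifnot(inherits(series, "centerline_series"))
  noise <- match.arg(noise)
  if (pixel_size <= 0) stop_flagkin("pixel_size must be > 0",
                                    "flagkin_invalid_parameter")
  if (psf_sigma < 0) stop_flagkin("psf_sigma must be >= 0",
                                  "flagkin_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  pad <- margin_px * pixel_size + 3.5 * psf_sigma
  if (is.null(dim)) {
    x0 <- min(series$x) - pad; x1 <- max(series$x) + pad
    y0 <- min(series$y) - pad; y1 <- max(series$y) + pad
    nc <- ceiling((x1 - x0) / pixel_size) + 1L
    nr <- ceiling((y1 - y0) / pixel_size) + 1L
    origin <- c(x0, y0)
  } else {
    if (is.null(origin)) origin <- c(0, 0)
    nr <- dim[1]; nc <- dim[2]
  }
  sigma_px <- psf_sigma / pixel_size
  noise_sd <- sqrt(background + read_noise^2)
  ridge_peak <- snr * noise_sd
  # linear density (counts per pixel of ridge length) giving that blurred peak
  dens <- if (sigma_px > 0) ridge_peak * sqrt(2 * pi) * sigma_px else ridge_peak
  step <- 0.4 * pixel_size   # sub-pixel splat spacing along the curve (um)
  n_t <- nrow(series$x)
  s_dense <- seq(0, max(series$s), by = step)
  images <- vector("list", n_t)
  for (f in seq_len(n_t)) {
    xs <- approx(series$s, series$x[f, ], xout = s_dense)$y
    ys <- approx(series$s, series$y[f, ], xout = s_dense)$y
    cc <- round((xs - origin[1]) / pixel_size) + 1
    rr <- round((ys - origin[2]) / pixel_size) + 1
    if (any(cc < 1 | cc > nc | rr < 1 | rr > nr))
      stop_flagkin(sprintf("flagellum exceeds canvas in frame %d", f),
                   "flagkin_geometry_error")
    idx <- rr + (cc - 1) * nr
    img <- matrix(tabulate(idx, nbins = nr * nc) * (dens * step / pixel_size),
                  nr, nc)
    if (sigma_px > 0) img <- blur_gaussian(img, sigma_px)
    img <- img + background
    if (noise == "poisson-gaussian") {
      img <- rpois(length(img), lambda = img) +
        rnorm(length(img), sd = read_noise)
      img <- matrix(img, nr, nc)
    }
    img <- round(pmin(pmax(img, 0), 65535))
    storage.mode(img) <- "integer"
    images[[f]] <- img
  }
  structure(list(images = images, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background = background,
                 read_noise = read_noise, snr = snr, origin = origin,
                 fps = series$fps, ground_truth = series, label = NULL),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Synthetic scene: %d frames of %d x %d px (%.2f um/px), psf %.2f um\n",
              length(x$images), d[1], d[2], x$pixel_size, x$psf_sigma))
  cat(sprintf("  background %g, read noise %g, peak SNR %g\n",
              x$background, x$read_noise, x$snr))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Write a synthetic scene as a multi-page TIFF
#'
#' @param scene a `synthetic_scene`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  pages <- lapply(scene$images, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a list of integer matrices
#'
#' @param path TIFF file path.
#' @return list of integer matrices (counts, uint16 scale).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) {
    m <- round(m * 65535)
    storage.mode(m) <- "integer"
    m
  })
}
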