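# Centerline tracing: segmentation, skeletonization, ordering, spline
# smoothing and arc-length resampling of image stacks.

#' Tracing configuration
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold in counts (for `"fixed"`).
#' @param min_object_px connected components smaller than this are removed
#'   before the single-flagellum check.
#' @param head_anchor um coordinates of the tethered head (point 0 of every
#'   traced frame is the skeleton endpoint nearest this anchor).
#' @param head_mask_radius um radius of a disk around `head_anchor` excluded
#'   from the skeleton (use when a bright head blob is present; synthetic
#'   scenes render no head, so the default is 0).
#' @param max_offpath_frac maximum tolerated fraction of skeleton pixels not
#'   on the head-to-tip path (staircase corners and short side twigs are
#'   bypassed harmlessly; a larger fraction indicates a self-crossing or
#'   looped flagellum and the frame is a trace error).
#' @param head_snap_dist maximum distance (um) allowed between the head
#'   anchor and the nearest skeleton endpoint; frames violating it (e.g. a
#'   self-touching flagellum whose skeleton loops away from the head) are
#'   trace errors.
#' @param spline_df_per_um degrees of freedom of the smoothing spline per um
#'   of traced length (controls spatial smoothing of the pixel chain).
#' @param resample_ds arc-length spacing of the traced series in um.
#' @param max_length analysis length cap in um (<= 120).
#' @param min_frame_fraction a recording is rejected when fewer than this
#'   fraction of frames trace successfully.
#' @return an object of class `trace_config`.
#' @export
trace_config <- function(threshold_method = c("otsu", "fixed"),
                         fixed_threshold = NULL, min_object_px = 40,
                         head_anchor = c(0, 0), head_mask_radius = 0,
                         max_offpath_frac = 0.35, head_snap_dist = 6.3,
                         spline_df_per_um = 0.25,
                         resample_ds = 1, max_length = 100,
                         min_frame_fraction = 0.8) {
  threshold_method <- match.arg(threshold_method)
  if (resample_ds <= 0)
    stop_flagkin("resample_ds must be > 0", "flagkin_invalid_parameter")
  if (max_length > 120)
    stop_flagkin("max_length must be <= 120 um", "flagkin_invalid_parameter")
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop_flagkin("fixed_threshold required for threshold_method = 'fixed'",
                 "flagkin_invalid_parameter")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_object_px = min_object_px, head_anchor = head_anchor,
                 head_mask_radius = head_mask_radius,
                 max_offpath_frac = max_offpath_frac,
                 head_snap_dist = head_snap_dist,
                 spline_df_per_um = spline_df_per_um,
                 resample_ds = resample_ds, max_length = max_length,
                 min_frame_fraction = min_frame_fraction),
            class = "trace_config")
}

#' Segment one frame into a single-flagellum binary mask
#'
#' Thresholds the frame (Otsu or fixed), removes connected components smaller
#' than `config$min_object_px`, and requires exactly one surviving component.
#'
#' @param image integer or numeric matrix (counts).
#' @param config a [trace_config()].
#' @return logical matrix mask.
#' @export
segment_frame <- function(image, config = trace_config()) {
  if (length(dim(image)) != 2L)
    stop_flagkin("segment_frame expects a 2-D grayscale image",
                 "flagkin_invalid_parameter")
  thr <- if (config$threshold_method == "otsu") otsu_threshold(image)
         else config$fixed_threshold
  mask <- image > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$min_object_px)
  if (length(keep) == 0L)
    stop_flagkin("segmentation error: 0 components survive size filtering",
                 "flagkin_segmentation_error")
  if (length(keep) > 1L)
    stop_flagkin(sprintf("segmentation error: %d components survive size filtering",
                         length(keep)),
                 "flagkin_segmentation_error")
  matrix(lab == keep, nrow(image), ncol(image))
}

# Otsu's between-class-variance threshold on an integer count histogram.
otsu_threshold <- function(image) {
  v <- as.integer(round(image))
  lo <- min(v)
  h <- as.numeric(tabulate(v - lo + 1L))
  lev <- as.numeric(seq_along(h) - 1L)
  n <- sum(h)
  w1 <- cumsum(h)
  mu1 <- cumsum(h * lev)
  mu_tot <- mu1[length(mu1)]
  w2 <- n - w1
  between <- (mu_tot * w1 - mu1 * n)^2 / (w1 * w2 * n^2)
  between[w1 == 0 | w2 == 0] <- 0
  lev[which.max(between)] + lo
}

#' Extract an ordered centerline from a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), identifies the skeleton
#' endpoint nearest the head anchor as point 0, orders the pixels along the
#' shortest head-to-farthest-pixel graph path (which bypasses short side
#' branches), fits smoothing splines x(u), y(u) against cumulative chord
#' length, and resamples the smoothed curve at uniform arc length up to
#' `max_length`. Frames whose skeleton mass lies substantially off that path
#' (self-crossing or looped shapes) are trace errors to be dropped upstream.
#'
#' @param mask logical matrix from [segment_frame()].
#' @param config a [trace_config()].
#' @param pixel_size um per pixel.
#' @param origin um coordinates of the center of pixel (row 1, col 1).
#' @return matrix with columns `x`, `y` (um); attribute `"arc_length"` gives
#'   the traced (possibly capped) length.
#' @export
extract_centerline <- function(mask, config = trace_config(),
                               pixel_size = 0.33, origin = c(0, 0)) {
  skel <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (config$head_mask_radius > 0) {
    rr <- (row(skel) - 1) * pixel_size + origin[2]
    cc <- (col(skel) - 1) * pixel_size + origin[1]
    skel[(cc - config$head_anchor[1])^2 + (rr - config$head_anchor[2])^2 <
           config$head_mask_radius^2] <- 0L
  }
  skel <- thin_mask(skel)
  nb <- neighbour_counts(skel)
  ends <- which(skel == 1L & nb == 1L, arr.ind = TRUE)
  if (nrow(ends) < 1L)
    stop_flagkin("trace error: skeleton has no endpoints (closed loop)",
                 "flagkin_trace_error")
  ex <- origin[1] + (ends[, 2] - 1) * pixel_size
  ey <- origin[2] + (ends[, 1] - 1) * pixel_size
  d2 <- (ex - config$head_anchor[1])^2 + (ey - config$head_anchor[2])^2
  if (min(d2) > config$head_snap_dist^2)
    stop_flagkin(sprintf(
      "trace error: nearest skeleton endpoint is %.1f um from the head anchor",
      sqrt(min(d2))), "flagkin_trace_error")
  head_end <- ends[which.min(d2), ]
  path <- skeleton_path(skel, head_end[1], head_end[2])
  if (nrow(path) < 5L)
    stop_flagkin("trace error: skeleton path too short", "flagkin_trace_error")
  off <- 1 - nrow(path) / sum(skel)
  if (off > config$max_offpath_frac)
    stop_flagkin(sprintf(
      "trace error: %.0f%% of skeleton off the main path (self-crossing or looped flagellum)",
      100 * off), "flagkin_trace_error")
  px <- origin[1] + (path[, 2] - 1) * pixel_size
  py <- origin[2] + (path[, 1] - 1) * pixel_size
  u <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  df <- max(6, min(config$spline_df_per_um * max(u), length(u) - 2))
  fx <- smooth.spline(u, px, df = df)
  fy <- smooth.spline(u, py, df = df)
  u_dense <- seq(0, max(u), by = 0.2)
  xd <- predict(fx, u_dense)$y
  yd <- predict(fy, u_dense)$y
  # re-anchor arc length at the known tether point: the skeleton endpoint
  # erodes ~1 um into the blurred ridge cap, which would shift every arc
  # station outward; cut at the curve point nearest the anchor and prepend
  # the anchor itself so s = 0 is the head-flagellum junction
  near <- which(u_dense <= 4)
  i0 <- near[which.min((xd[near] - config$head_anchor[1])^2 +
                         (yd[near] - config$head_anchor[2])^2)]
  xd <- xd[i0:length(xd)]; yd <- yd[i0:length(yd)]
  d0 <- sqrt((xd[1] - config$head_anchor[1])^2 +
               (yd[1] - config$head_anchor[2])^2)
  if (d0 > 1e-6) {
    xd <- c(config$head_anchor[1], xd)
    yd <- c(config$head_anchor[2], yd)
  }
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- min(max(arc), config$max_length)
  s_out <- seq(0, L, by = config$resample_ds)
  out <- cbind(x = approx(arc, xd, xout = s_out)$y,
               y = approx(arc, yd, xout = s_out)$y)
  attr(out, "arc_length") <- max(arc)
  attr(out, "s") <- s_out
  out
}

#' Trace every frame of an image stack
#'
#' Runs [segment_frame()] and [extract_centerline()] on each frame. Frames
#' that fail are dropped, logged, and filled by linear interpolation between
#' the nearest successfully traced frames so the time grid stays uniform. The
#' recording is rejected when fewer than `min_frame_fraction` of frames trace.
#' All frames are cut to the common traced length before resampling so the
#' point grid is identical across frames.
#'
#' @param scene a `synthetic_scene`, or a list of image matrices (in which
#'   case `pixel_size`, `origin` and `fps` must be given).
#' @param config a [trace_config()].
#' @param pixel_size,origin,fps scene geometry when `scene` is a plain list.
#' @return a `centerline_series` with a `qc` field listing failed frames.
#' @export
trace_stack <- function(scene, config = trace_config(), pixel_size = NULL,
                        origin = NULL, fps = NULL) {
  if (inherits(scene, "synthetic_scene")) {
    images <- scene$images
    pixel_size <- scene$pixel_size
    origin <- scene$origin
    fps <- scene$fps
  } else {
    images <- scene
    if (is.null(pixel_size) || is.null(origin) || is.null(fps))
      stop_flagkin("pixel_size, origin and fps are required for plain stacks",
                   "flagkin_invalid_parameter")
  }
  n_t <- length(images)
  traces <- vector("list", n_t)
  failed <- integer(0)
  for (f in seq_len(n_t)) {
    traces[[f]] <- tryCatch({
      mask <- segment_frame(images[[f]], config)
      extract_centerline(mask, config, pixel_size, origin)
    }, flagkin_error = function(e) {
      failed <<- c(failed, f)
      NULL
    })
  }
  ok <- setdiff(seq_len(n_t), failed)
  # drop frames whose traced length is an outlier (self-touching shapes trace
  # short along a looped skeleton)
  if (length(ok) > 2) {
    lens <- vapply(traces[ok], function(tr) max(attr(tr, "s")), 0)
    short <- ok[lens < 0.85 * stats::median(lens)]
    failed <- sort(c(failed, short))
    ok <- setdiff(ok, short)
  }
  if (length(ok) < config$min_frame_fraction * n_t)
    stop_flagkin(sprintf(
      "recording rejected: only %d/%d frames traced successfully",
      length(ok), n_t), "flagkin_trace_error")
  L_common <- min(vapply(traces[ok], function(tr) max(attr(tr, "s")), 0))
  s_out <- seq(0, L_common, by = config$resample_ds)
  x <- matrix(NA_real_, n_t, length(s_out))
  y <- matrix(NA_real_, n_t, length(s_out))
  for (f in ok) {
    s_f <- attr(traces[[f]], "s")
    x[f, ] <- approx(s_f, traces[[f]][, "x"], xout = s_out)$y
    y[f, ] <- approx(s_f, traces[[f]][, "y"], xout = s_out)$y
  }
  for (f in failed) {
    lo <- max(ok[ok < f], -Inf)
    hi <- min(ok[ok > f], Inf)
    if (is.infinite(lo)) { x[f, ] <- x[hi, ]; y[f, ] <- y[hi, ] }
    else if (is.infinite(hi)) { x[f, ] <- x[lo, ]; y[f, ] <- y[lo, ] }
    else {
      w <- (f - lo) / (hi - lo)
      x[f, ] <- (1 - w) * x[lo, ] + w * x[hi, ]
      y[f, ] <- (1 - w) * y[lo, ] + w * y[hi, ]
    }
  }
  new_centerline_series(x, y, s = s_out, ds = config$resample_ds, fps = fps,
                        total_length = L_common,
                        qc = list(frames_total = n_t, frames_ok = length(ok),
                                  failed_frames = failed))
}

#' Build the tangent-angle waveform from a centerline series
#'
#' psi(s, t) is the angle of the local tangent (central differences of the
#' coordinates; one-sided at the ends), unwrapped along arc length within each
#' frame and kept continuous in time at the head.
#'
#' @param series a `centerline_series` on a common grid.
#' @return a `waveform`: list with `psi` (frames x points, radians), `s`,
#'   `ds`, `dt`, and the originating `series`.
#' @export
to_waveform <- function(series) {
  stopifnot(inherits(series, "centerline_series"))
  x <- series$x; y <- series$y
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_flagkin("grid error: non-finite coordinates in centerline series",
                 "flagkin_grid_error")
  n_s <- ncol(x)
  if (n_s < 3L)
    stop_flagkin("grid error: need at least 3 points per frame",
                 "flagkin_grid_error")
  ip <- c(2:n_s, n_s); im <- c(1, 1:(n_s - 1))
  dx <- x[, ip, drop = FALSE] - x[, im, drop = FALSE]
  dy <- y[, ip, drop = FALSE] - y[, im, drop = FALSE]
  psi <- atan2(dy, dx)
  psi <- t(apply(psi, 1, unwrap))
  # temporal continuity of the head angle (avoid 2*pi jumps between frames)
  base <- psi[, 1]
  shift <- 2 * pi * round((base - unwrap(base)) / (2 * pi))
  psi <- psi - shift
  structure(list(psi = psi, s = series$s, ds = series$ds,
                 dt = 1 / series$fps, n_s = n_s, n_t = nrow(psi),
                 series = series),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Tangent-angle waveform: %d frames x %d stations (ds = %g um, dt = %g s)\n",
              x$n_t, x$n_s, x$ds, x$dt))
  cat(sprintf("  psi range [%.2f, %.2f] rad\n", min(x$psi), max(x$psi)))
  invisible(x)
}

#' Write a centerline series to CSV (frame, index, x_um, y_um)
#' @param series a `centerline_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(series, path) {
  n_t <- nrow(series$x); n_s <- ncol(series$x)
  df <- data.frame(frame = rep(seq_len(n_t), each = n_s),
                   index = rep(seq_len(n_s) - 1L, n_t),
                   x_um = as.vector(t(series$x)),
                   y_um = as.vector(t(series$y)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline series from CSV written by [write_centerline_csv()]
#' @param path CSV path.
#' @param ds arc-length spacing in um of the stored series.
#' @param fps frame rate of the stored series.
#' @return a `centerline_series`.
#' @export
read_centerline_csv <- function(path, ds, fps) {
  df <- read.csv(path)
  n_t <- length(unique(df$frame))
  n_s <- nrow(df) / n_t
  x <- matrix(df$x_um, n_t, n_s, byrow = TRUE)
  y <- matrix(df$y_um, n_t, n_s, byrow = TRUE)
  new_centerline_series(x, y, s = seq(0, by = ds, length.out = n_s), ds = ds,
                        fps = fps, total_length = ds * (n_s - 1))
}
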