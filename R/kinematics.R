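# Kinematics: curvature kymographs, beat frequency from curvature turning
# points, per-section amplitudes at the anatomical set points, and the
# four-category midpiece flexibility classification.

#' Anatomical section boundaries of the mouse sperm tail
#'
#' Set points: head 6.3 um, midpiece 22.4 um, principal piece 80 um, giving
#' cumulative edges head [0, 6.3), midpiece [6.3, 28.7), principal
#' [28.7, 108.7) um of arc length from the head.
#'
#' @param head_len,mid_len,principal_len section lengths in um.
#' @return object of class `section_boundaries` with the cumulative `edges`.
#' @export
section_boundaries <- function(head_len = 6.3, mid_len = 22.4,
                               principal_len = 80) {
  edges <- cumsum(c(0, head_len, mid_len, principal_len))
  if (any(diff(edges) <= 0))
    stop_flagkin("section lengths must be positive", "flagkin_invalid_parameter")
  structure(list(head_len = head_len, mid_len = mid_len,
                 principal_len = principal_len, edges = edges),
            class = "section_boundaries")
}

#' Curvature kymograph kappa(s, t) = d psi / d s
#'
#' Central differences along arc length (one-sided at the ends), with optional
#' Gaussian smoothing along s. Positive curvature denotes a bend toward the
#' side of the head hook.
#'
#' @param w a `waveform`.
#' @param sigma_s optional Gaussian smoothing sigma along s, in um (0 = none).
#' @return a `curvature_kymograph`: list with `kappa` (frames x stations,
#'   1/um), `s`, `ds`, `dt`.
#' @export
curvature_kymograph <- function(w, sigma_s = 0) {
  stopifnot(inherits(w, "waveform"))
  n_s <- w$n_s
  if (n_s < 3L)
    stop_flagkin("grid too small: need at least 3 arc-length stations",
                 "flagkin_grid_error")
  psi <- w$psi
  kappa <- psi
  kappa[, 2:(n_s - 1)] <- (psi[, 3:n_s] - psi[, 1:(n_s - 2)]) / (2 * w$ds)
  kappa[, 1] <- (psi[, 2] - psi[, 1]) / w$ds
  kappa[, n_s] <- (psi[, n_s] - psi[, n_s - 1]) / w$ds
  if (sigma_s > 0) {
    # smooth each frame along s with a 1-D Gaussian kernel (replicate ends)
    sig_px <- sigma_s / w$ds
    rad <- ceiling(3.5 * sig_px)
    k <- exp(-0.5 * ((-rad):rad)^2 / sig_px^2); k <- k / sum(k)
    kappa <- t(apply(kappa, 1, function(r) {
      rp <- c(rep(r[1], rad), r, rep(r[length(r)], rad))
      as.numeric(stats::filter(rp, k, sides = 2))[(rad + 1):(rad + length(r))]
    }))
  }
  structure(list(kappa = kappa, s = w$s, ds = w$ds, dt = w$dt),
            class = "curvature_kymograph")
}

#' @export
print.curvature_kymograph <- function(x, ...) {
  cat(sprintf("Curvature kymograph: %d frames x %d stations, |kappa| max %.3f 1/um\n",
              nrow(x$kappa), ncol(x$kappa), max(abs(x$kappa))))
  invisible(x)
}

#' Plot a curvature kymograph (diverging red/blue, bend direction)
#' @param x a `curvature_kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.curvature_kymograph <- function(x, ...) {
  tt <- (seq_len(nrow(x$kappa)) - 1) * x$dt
  pal <- colorRampPalette(c("blue", "white", "red"))(64)
  lim <- max(abs(x$kappa))
  image(tt, x$s, x$kappa, zlim = c(-lim, lim), col = pal,
        xlab = "T (s)", ylab = "s (um)", ...)
  invisible(x)
}

# significant alternating extrema of a 1-D series via persistence pruning:
# drop adjacent extremum pairs closer in value than `prominence`.
turning_points <- function(v, prominence) {
  d <- diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  chg <- which(diff(s[nz]) != 0)      # strict max/min alternation
  idx <- nz[chg] + 1L
  if (length(idx) == 0L) return(integer(0))
  repeat {
    if (length(idx) < 2L) break
    gaps <- abs(diff(v[idx]))
    j <- which.min(gaps)
    if (gaps[j] >= prominence) break
    idx <- idx[-c(j, j + 1L)]         # adjacent pair has opposite types, so
  }                                   # alternation is preserved
  idx
}

#' Beat frequency from curvature turning points
#'
#' At stations 50% and 75% of the traced length, detects significant turning
#' points (alternating local extrema) of the temporally smoothed curvature
#' series and estimates the per-station frequency as
#' (number of turning points - 1) / (2 * time between first and last turning
#' point); the result is the mean over the two stations.
#'
#' @param k a `curvature_kymograph`.
#' @param stations fractions of the traced length at which to read kappa(t).
#' @param prominence_frac turning points closer in value than this fraction of
#'   the station's kappa(t) range are pruned.
#' @param smooth_window Savitzky-Golay window (frames) applied to kappa(t);
#'   the default NULL spans about 1/12 s (at least 5 frames) -- long relative
#'   to frame noise, short relative to a beat period of a few Hz.
#' @return beat frequency in Hz.
#' @export
beat_frequency <- function(k, stations = c(0.5, 0.75), prominence_frac = 0.1,
                           smooth_window = NULL) {
  stopifnot(inherits(k, "curvature_kymograph"))
  if (is.null(smooth_window)) {
    smooth_window <- max(5, round(1 / (12 * k$dt)))
    if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  }
  L <- max(k$s)
  freqs <- vapply(stations, function(frac) {
    j <- which.min(abs(k$s - frac * L))
    v <- sg_smooth(k$kappa[, j], smooth_window)
    rng <- diff(range(v))
    if (rng <= 1e-9 * max(abs(v), 1e-300))
      stop_flagkin(sprintf(
        "insufficient cycles: curvature is constant at station s = %.1f um",
        k$s[j]), "flagkin_insufficient_cycles")
    tp <- turning_points(v, prominence = prominence_frac * rng)
    if (length(tp) < 3L)
      stop_flagkin(sprintf(
        "insufficient cycles: %d turning points at station s = %.1f um",
        length(tp), k$s[j]), "flagkin_insufficient_cycles")
    span <- (tp[length(tp)] - tp[1]) * k$dt
    (length(tp) - 1) / (2 * span)
  }, 0)
  mean(freqs)
}

#' Per-section amplitudes of a centerline series
#'
#' The cell axis is the time-averaged tangent direction over the head-adjacent
#' 6.3 um. For every arc-length station the transverse excursion of that
#' material point across frames is measured perpendicular to the axis (after
#' Savitzky-Golay smoothing in time); its amplitude is the full peak-to-peak
#' excursion. The reported section amplitude is the amplitude at the section's
#' distal set point: head 6.3 um, midpiece 28.7 um, principal piece
#' min(108.7, L) um.
#'
#' @param series a `centerline_series` covering at least one full beat period.
#' @param b a [section_boundaries()].
#' @param smooth_window Savitzky-Golay window (frames) for the transverse
#'   trajectories; set 0 to disable.
#' @return named numeric vector `c(head, mid, principal)` in um, with the
#'   per-station amplitude profile in attribute `"profile"`.
#' @export
section_amplitude <- function(series, b = section_boundaries(),
                              smooth_window = 5) {
  stopifnot(inherits(series, "centerline_series"))
  s <- series$s
  L <- max(s)
  if (b$edges[2] > L)
    stop_flagkin("section out of range: traced length shorter than the head section",
                 "flagkin_section_error")
  head_idx <- which(s <= b$edges[2])
  if (length(head_idx) < 2L) head_idx <- 1:2
  dx <- series$x[, head_idx[-1], drop = FALSE] -
    series$x[, head_idx[-length(head_idx)], drop = FALSE]
  dy <- series$y[, head_idx[-1], drop = FALSE] -
    series$y[, head_idx[-length(head_idx)], drop = FALSE]
  axis_vec <- c(mean(dx), mean(dy))
  axis_vec <- axis_vec / sqrt(sum(axis_vec^2))
  normal <- c(-axis_vec[2], axis_vec[1])
  q <- series$x * normal[1] + series$y * normal[2]   # frames x stations
  if (smooth_window >= 3 && nrow(q) >= smooth_window)
    q <- apply(q, 2, sg_smooth, window = smooth_window)
  prof <- apply(q, 2, function(col) diff(range(col)))
  amp_at <- function(s0) {
    if (s0 > L + 1e-9)
      stop_flagkin(sprintf("section out of range: set point %.1f um beyond traced length %.1f um",
                           s0, L), "flagkin_section_error")
    approx(s, prof, xout = min(s0, L))$y
  }
  out <- c(head = amp_at(b$edges[2]), mid = amp_at(b$edges[3]),
           principal = amp_at(min(b$edges[4], L)))
  attr(out, "profile") <- prof
  attr(out, "axis") <- axis_vec
  out
}

#' Classify midpiece flexibility from midpiece amplitude
#'
#' Contiguous half-open bins over midpiece amplitude (um): [0, 6) highly
#' stiff, [6, 16) moderately stiff, [16, 27) relatively flexible, [27, Inf)
#' highly flexible. The printed category ranges (0.6-6, 6-15, 16-27, 27-39)
#' leave small gaps, treated here as rounding of a contiguous scale.
#'
#' @param amplitude_mid midpiece amplitude(s) in um (vectorized).
#' @return factor with levels `highly_flexible`, `relatively_flexible`,
#'   `moderately_stiff`, `highly_stiff`.
#' @export
classify_flexibility <- function(amplitude_mid) {
  if (any(!is.finite(amplitude_mid)) || any(amplitude_mid < 0))
    stop_flagkin("invalid amplitude: must be finite and >= 0",
                 "flagkin_invalid_amplitude")
  cut(amplitude_mid, breaks = c(-Inf, 6, 16, 27, Inf), right = FALSE,
      labels = c("highly_stiff", "moderately_stiff", "relatively_flexible",
                 "highly_flexible")) |>
    factor(levels = c("highly_flexible", "relatively_flexible",
                      "moderately_stiff", "highly_stiff"))
}

#' Kinematic summary of one recording
#'
#' Combines beat frequency, section amplitudes and the flexibility class.
#' A frequency failure (e.g. a static cell) is recorded as `NA` with the
#' error message kept in `qc`.
#'
#' @param series a `centerline_series`.
#' @param b a [section_boundaries()].
#' @param ... passed to [beat_frequency()].
#' @return object of class `kinematic_summary`.
#' @export
kinematic_summary <- function(series, b = section_boundaries(), ...) {
  w <- to_waveform(series)
  k <- curvature_kymograph(w)
  freq <- tryCatch(beat_frequency(k, ...), flagkin_error = function(e) {
    structure(NA_real_, msg = conditionMessage(e))
  })
  amps <- section_amplitude(series, b)
  cls <- classify_flexibility(amps[["mid"]])
  structure(list(beat_frequency = as.numeric(freq),
                 amplitude_head = amps[["head"]],
                 amplitude_mid = amps[["mid"]],
                 amplitude_principal = amps[["principal"]],
                 flexibility_class = cls,
                 frames_used = nrow(series$x),
                 qc = attr(freq, "msg")),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat("Kinematic summary\n")
  cat(sprintf("  beat frequency: %s Hz\n",
              ifelse(is.na(x$beat_frequency), "NA",
                     sprintf("%.2f", x$beat_frequency))))
  cat(sprintf("  amplitude (um): head %.2f, midpiece %.2f, principal %.2f\n",
              x$amplitude_head, x$amplitude_mid, x$amplitude_principal))
  cat(sprintf("  flexibility class: %s (%d frames)\n",
              as.character(x$flexibility_class), x$frames_used))
  if (!is.null(x$qc)) cat("  QC:", x$qc, "\n")
  invisible(x)
}
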