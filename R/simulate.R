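# Synthetic beat generator: tangent-angle traveling waves integrated to
# head-tethered planar centerlines.

#' Beat parameters for the synthetic flagellar wave generator
#'
#' The generator produces a tangent-angle traveling wave
#' \deqn{\psi(s, t) = A(s) \sin(2\pi (f t - s/\lambda) + \phi_0)}
#' which is integrated along arc length to planar centerline coordinates with
#' the head clamped at the origin (tethered-head assay). Built-in envelopes
#' ramp from A(0) = 0, i.e. the tether clamps head orientation as well as
#' position, so the prescribed wave exchanges no power across the anchor and
#' the motor energy ledger closes. Defaults emulate the recording conditions of high-speed dark-field
#' imaging of head-tethered mouse sperm: total length 110 um, beat frequencies
#' of a few Hz, 250 frames/s, 1000 frames (4 s).
#'
#' @param total_length flagellum length in um (> 0).
#' @param beat_frequency beat frequency f in Hz (> 0).
#' @param wavelength bend wavelength lambda in um (> 0).
#' @param envelope_kind one of `"flexible"`, `"stiff-midpiece"`, `"custom"`.
#'   `"flexible"` has substantial proximal (midpiece) amplitude;
#'   `"stiff-midpiece"` suppresses the tangent-angle amplitude proximal to the
#'   midpiece--principal-piece junction (28.7 um), emulating a rigid midpiece.
#' @param envelope_scale peak tangent-angle amplitude in radians applied to the
#'   unit envelope shape.
#' @param amplitude_envelope for `envelope_kind = "custom"`: a function of arc
#'   length (um) returning the tangent-angle amplitude A(s) in radians
#'   (must be >= 0 everywhere).
#' @param phase0 initial phase phi_0 in radians.
#' @param duration record duration in s; `duration * fps` must cover at least
#'   two full beat cycles.
#' @param fps frame rate in frames/s (> 0).
#' @param seed optional integer seed (the pure wave is deterministic; the seed
#'   is carried along for downstream stochastic stages).
#' @return an object of class `beat_params`.
#' @export
beat_params <- function(total_length = 110, beat_frequency = 5, wavelength = 110,
                        envelope_kind = c("flexible", "stiff-midpiece", "custom"),
                        envelope_scale = 0.9, amplitude_envelope = NULL,
                        phase0 = 0, duration = 4, fps = 250, seed = NULL) {
  envelope_kind <- match.arg(envelope_kind)
  if (!is.numeric(total_length) || total_length <= 0)
    stop_flagkin("total_length must be > 0", "flagkin_invalid_parameter")
  if (!is.numeric(fps) || fps <= 0)
    stop_flagkin("fps must be > 0", "flagkin_invalid_parameter")
  if (!is.numeric(beat_frequency) || beat_frequency < 0)
    stop_flagkin("beat_frequency must be >= 0", "flagkin_invalid_parameter")
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop_flagkin("wavelength must be > 0", "flagkin_invalid_parameter")
  if (beat_frequency > 0 && duration * beat_frequency < 2 - 1e-9)
    stop_flagkin("duration must cover at least 2 full beat cycles",
                 "flagkin_invalid_parameter")
  if (envelope_kind == "custom") {
    if (!is.function(amplitude_envelope))
      stop_flagkin("custom envelope_kind requires an amplitude_envelope function",
                   "flagkin_invalid_parameter")
    env <- amplitude_envelope
  } else {
    env <- envelope_shape(envelope_kind, envelope_scale)
  }
  test_s <- seq(0, total_length, length.out = 101)
  if (any(env(test_s) < 0))
    stop_flagkin("amplitude_envelope must be >= 0 everywhere",
                 "flagkin_invalid_parameter")
  structure(list(total_length = total_length, beat_frequency = beat_frequency,
                 wavelength = wavelength, envelope_kind = envelope_kind,
                 envelope_scale = envelope_scale, amplitude_envelope = env,
                 phase0 = phase0, duration = duration, fps = fps, seed = seed),
            class = "beat_params")
}

#' @export
print.beat_params <- function(x, ...) {
  cat("Flagellar beat parameters\n")
  cat(sprintf("  length %.1f um, f = %.2f Hz, wavelength %.1f um\n",
              x$total_length, x$beat_frequency, x$wavelength))
  cat(sprintf("  envelope '%s' (scale %.3f rad), %d frames at %g fps\n",
              x$envelope_kind, x$envelope_scale,
              round(x$duration * x$fps), x$fps))
  invisible(x)
}

# Unit envelope shapes. All ramp from A(0) = 0 (the tether clamps head
# orientation as well as position, so no power crosses the anchor) and taper
# distally to keep extreme beats from self-crossing in projection. The
# "stiff-midpiece" family keeps a small proximal floor so midpiece amplitude
# scales continuously to zero.
envelope_shape <- function(kind, scale) {
  ss <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  if (kind == "flexible") {
    function(s) scale * ss(s / 14) * (1 - 0.45 * ss((s - 70) / 35))
  } else {
    # suppressed proximal to the midpiece-principal junction at 28.7 um
    function(s) scale * ss(s / 14) *
      (0.17 + 0.83 * ss((s - 28.7) / 35 + 0.08)) *
      (1 - 0.35 * ss((s - 70) / 35))
  }
}

#' Simulate a head-tethered flagellar beat
#'
#' Integrates the tangent-angle field of a [beat_params()] wave to planar
#' centerline coordinates on a uniform arc-length grid, with the head anchored
#' at the origin in every frame. Integration uses a fine internal grid
#' (midpoint rule) so that arc length is conserved to well below 0.1%.
#'
#' @param params a [beat_params()] object.
#' @param ds arc-length spacing of the returned series in um.
#' @param ds_fine internal integration step in um.
#' @return a `centerline_series`: list with `x`, `y` (frames x points matrices,
#'   um), `s` (arc-length grid), `ds`, `fps`, `total_length`.
#' @export
simulate_beat <- function(params, ds = 1, ds_fine = 0.25) {
  stopifnot(inherits(params, "beat_params"))
  L <- params$total_length
  n_t <- max(1L, as.integer(round(params$duration * params$fps)))
  tt <- (seq_len(n_t) - 1) / params$fps
  # midpoint arc stations of fine segments
  n_fine <- ceiling(L / ds_fine)
  h <- L / n_fine
  s_mid <- (seq_len(n_fine) - 0.5) * h
  A <- params$amplitude_envelope(s_mid)
  # psi on (time x fine segments)
  phase <- outer(2 * pi * params$beat_frequency * tt,
                 2 * pi * s_mid / params$wavelength, `-`) + params$phase0
  psi <- sweep(sin(phase), 2, A, `*`)
  dx <- cos(psi) * h
  dy <- sin(psi) * h
  xf <- cbind(0, t(apply(dx, 1, cumsum)))
  yf <- cbind(0, t(apply(dy, 1, cumsum)))
  s_fine <- c(0, seq_len(n_fine) * h)
  s_out <- seq(0, L, by = ds)
  if (abs(s_out[length(s_out)] - L) > 1e-9) s_out <- c(s_out, L)
  x <- t(apply(xf, 1, function(r) approx(s_fine, r, xout = s_out)$y))
  y <- t(apply(yf, 1, function(r) approx(s_fine, r, xout = s_out)$y))
  new_centerline_series(x, y, s = s_out, ds = ds, fps = params$fps,
                        total_length = L)
}

new_centerline_series <- function(x, y, s, ds, fps, total_length,
                                  qc = NULL) {
  structure(list(x = x, y = y, s = s, ds = ds, fps = fps,
                 total_length = total_length, qc = qc),
            class = "centerline_series")
}

#' @export
print.centerline_series <- function(x, ...) {
  cat(sprintf("Centerline series: %d frames x %d points, ds = %g um, fps = %g\n",
              nrow(x$x), ncol(x$x), x$ds, x$fps))
  cat(sprintf("  arc length %.2f um, head anchored at origin\n",
              max(x$s)))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d/%d frames traced\n", x$qc$frames_ok, x$qc$frames_total))
  invisible(x)
}

#' Per-frame polyline arc lengths of a centerline series
#' @param series a `centerline_series`.
#' @return numeric vector, one arc length (um) per frame.
#' @export
arc_lengths <- function(series) {
  dx <- series$x[, -1, drop = FALSE] - series$x[, -ncol(series$x), drop = FALSE]
  dy <- series$y[, -1, drop = FALSE] - series$y[, -ncol(series$y), drop = FALSE]
  rowSums(sqrt(dx^2 + dy^2))
}

#' @export
plot.centerline_series <- function(x, frames = NULL, ...) {
  if (is.null(frames))
    frames <- unique(round(seq(1, nrow(x$x), length.out = min(20, nrow(x$x)))))
  cols <- colorRampPalette(c("blue", "red"))(length(frames))
  plot(NA, xlim = range(x$x[frames, ]), ylim = range(x$y[frames, ]),
       xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  for (i in seq_along(frames))
    lines(x$x[frames[i], ], x$y[frames[i], ], col = cols[i])
  invisible(x)
}
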