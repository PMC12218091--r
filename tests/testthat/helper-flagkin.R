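# Shared fixture builders (all fixtures are generated in code).

# straight static rod along +x of given length, n_frames identical frames
make_static_rod <- function(length_um = 100, ds = 1, n_frames = 5, fps = 250) {
  s <- seq(0, length_um, by = ds)
  x <- matrix(rep(s, each = n_frames), nrow = n_frames)
  y <- matrix(0, n_frames, length(s))
  flagkin:::new_centerline_series(x, y, s = s, ds = ds, fps = fps,
                                  total_length = length_um)
}

# rigid transverse oscillation y(s,t) = Y sin(2 pi f t) of a straight rod
make_transverse_oscillator <- function(Y = 10, f = 5, length_um = 100, ds = 1,
                                       fps = 250, duration = 4) {
  s <- seq(0, length_um, by = ds)
  tt <- (seq_len(round(duration * fps)) - 1) / fps
  x <- matrix(rep(s, each = length(tt)), nrow = length(tt))
  y <- matrix(Y * sin(2 * pi * f * tt), nrow = length(tt), ncol = length(s))
  flagkin:::new_centerline_series(x, y, s = s, ds = ds, fps = fps,
                                  total_length = length_um)
}

# circular arc of radius R (um), static, as a centerline series
make_arc_series <- function(R = 20, length_um = 60, ds = 1, n_frames = 3,
                            fps = 250) {
  s <- seq(0, length_um, by = ds)
  x <- R * sin(s / R)
  y <- R * (1 - cos(s / R))
  xm <- matrix(rep(x, each = n_frames), nrow = n_frames)
  ym <- matrix(rep(y, each = n_frames), nrow = n_frames)
  flagkin:::new_centerline_series(xm, ym, s = s, ds = ds, fps = fps,
                                  total_length = length_um)
}

# a short default beat for round-trip tests (2 cycles at 12 frames/cycle)
make_quick_beat <- function(envelope_scale = 0.9, f = 5,
                            kind = "flexible", phase0 = 0.7) {
  beat_params(beat_frequency = f, envelope_kind = kind,
              envelope_scale = envelope_scale, phase0 = phase0,
              duration = 2 / f, fps = 12 * f)
}

expect_flagkin_error <- function(expr, class) {
  expect_error(expr, class = class)
}
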