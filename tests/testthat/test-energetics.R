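# Energetics: RFT fields, dissipations, active-moment recovery, motor powers,
# cycle averaging and the energy-balance contract.

test_that("static filaments produce no forces and no dissipation", {
  rod <- make_static_rod(100, n_frames = 5)
  m <- material_params()
  fl <- rft_velocity_and_force(rod, m)
  expect_equal(max(abs(fl$vt)), 0)
  expect_equal(max(abs(fl$fx)), 0)
  expect_equal(max(hydrodynamic_dissipation(fl, m)$total), 0)
  expect_equal(max(internal_dissipation(to_waveform(rod), m)), 0)
  ma <- recover_active_moment(rod, m = m)
  expect_equal(max(abs(ma)), 0)
})

test_that("axial translation gives a purely tangential drag force", {
  U <- 50e-6                                 # 50 um/s along +x
  s <- seq(0, 100, by = 1)
  tt <- (0:9) / 250
  x <- outer(U * 1e6 * tt, rep(1, length(s))) + matrix(rep(s, each = 10), 10)
  y <- matrix(0, 10, length(s))
  ser <- flagkin:::new_centerline_series(x, y, s, 1, 250, 100)
  m <- material_params()
  fl <- rft_velocity_and_force(ser, m)
  interior <- 2:9
  expect_equal(fl$vt[interior, ], matrix(U, 8, length(s)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(max(abs(fl$vn[interior, ])), 0)
  expect_equal(fl$fx[interior, ], matrix(-m$xi_t * U, 8, length(s)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("transverse oscillation force matches the analytic time series", {
  Y <- 10; f <- 5
  ser <- make_transverse_oscillator(Y = Y, f = f, duration = 1, fps = 250)
  m <- material_params()
  fl <- rft_velocity_and_force(ser, m)
  tt <- (seq_len(nrow(ser$x)) - 1) / 250
  analytic <- -m$xi_n * (Y * 1e-6) * 2 * pi * f * cos(2 * pi * f * tt)
  interior <- 2:(length(tt) - 1)
  expect_equal(fl$fy[interior, 50], analytic[interior],
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("hydrodynamic dissipation matches the rigid-oscillation closed form", {
  Y <- 10; f <- 5; L <- 100
  ser <- make_transverse_oscillator(Y = Y, f = f, length_um = L,
                                    duration = 4, fps = 250)
  m <- material_params()                     # xi_n = 1.4e-3 N s/m^2
  Dh <- hydrodynamic_dissipation(rft_velocity_and_force(ser, m), m)
  closed <- m$xi_n * (L * 1e-6) * (Y * 1e-6 * 2 * pi * f)^2 / 2 * 1e15
  expect_equal(cycle_average(Dh$total, f, 1 / 250), closed, tolerance = 0.02)
})

test_that("hydrodynamic dissipation matches a dense-quadrature oracle", {
  p <- make_quick_beat(envelope_scale = 0.4)
  ser <- simulate_beat(p, ds = 1)
  m <- material_params()
  fl <- rft_velocity_and_force(ser, m)
  Dh <- hydrodynamic_dissipation(fl, m)$total
  # oracle: independent trapezoid quadrature of the same integrand
  oracle <- vapply(seq_len(nrow(ser$x)), function(f_) {
    dens <- m$xi_t * fl$vt[f_, ]^2 + m$xi_n * fl$vn[f_, ]^2
    h <- 1e-6
    sum((dens[-1] + dens[-length(dens)]) / 2 * h)
  }, 0)
  expect_equal(Dh, oracle, tolerance = 0.01)
})

test_that("regional hydrodynamic splits sum to the total", {
  p <- make_quick_beat(envelope_scale = 0.9)
  ser <- simulate_beat(p)
  m <- material_params()
  Dh <- hydrodynamic_dissipation(rft_velocity_and_force(ser, m), m,
                                 section_boundaries())
  total_from_parts <- Dh$head + Dh$mid + Dh$principal
  expect_equal(total_from_parts, Dh$total, tolerance = 1e-10)
  expect_true(all(Dh$mid >= 0 & Dh$principal >= 0))
})

test_that("internal dissipation matches its closed form and is linear in eta", {
  # kappa(s, t) = K sin(omega t), uniform in s
  K <- 0.02 * 1e6; f <- 5; L <- 100e-6
  s <- seq(0, 100, by = 1)
  tt <- (0:999) / 250
  psi <- outer(K * 1e-6 * sin(2 * pi * f * tt), s)   # psi = kappa * s
  w <- structure(list(psi = psi, s = s, ds = 1, dt = 1 / 250,
                      n_s = length(s), n_t = length(tt)), class = "waveform")
  m <- material_params()
  Di <- internal_dissipation(w, m)
  closed <- m$eta_i * L * (K * 2 * pi * f)^2 / 2 * 1e15
  expect_equal(cycle_average(Di, f, 1 / 250), closed, tolerance = 0.01)
  m2 <- material_params(eta_i = 2 * m$eta_i)
  expect_equal(internal_dissipation(w, m2), 2 * Di, tolerance = 1e-12)
})

test_that("a static bent filament carries a purely elastic active moment", {
  arc <- make_arc_series(R = 20, length_um = 60, n_frames = 5)
  m <- material_params()
  ma <- recover_active_moment(arc, m = m)
  K <- 1 / (20e-6)
  interior_s <- 3:(ncol(ma) - 2)
  expect_equal(ma[2, interior_s], rep(-m$EI * K, length(interior_s)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("the internal moment of a point force is piecewise linear", {
  rod <- make_static_rod(100, n_frames = 3)
  m <- material_params()
  fl <- rft_velocity_and_force(rod, m)
  j0 <- 61                                   # point force at s0 = 60 um
  F0 <- 2e-12                                # N (as density spike F0/ds)
  fl$fy[, j0] <- F0 / 1e-6
  ma <- recover_active_moment(rod, m = m, fields = fl)
  M <- attr(ma, "M")
  # brute-force moment oracle with the same trapezoid rule
  s_m <- rod$s * 1e-6
  h <- 1e-6
  wts <- rep(h, length(s_m)); wts[c(1, length(s_m))] <- h / 2
  oracle <- vapply(seq_along(s_m), function(i) {
    distal <- seq(i, length(s_m))
    wd <- wts; wd[i] <- h / 2
    -sum((s_m[distal] - s_m[i]) * fl$fy[2, distal] * wd[distal])
  }, 0)
  expect_equal(M[2, ], oracle, tolerance = 0.01, ignore_attr = TRUE)
  # piecewise linear: slope constant below s0, zero above
  below <- 5:(j0 - 5)
  slopes <- diff(M[2, below])
  expect_lt(diff(range(slopes)) / abs(mean(slopes)), 1e-6)
  expect_equal(max(abs(M[2, (j0 + 1):ncol(M)])), 0, tolerance = 1e-25)
})

test_that("motor powers split the signed power density exactly", {
  rod <- make_static_rod(100, n_frames = 5)
  w <- to_waveform(rod)
  mp <- motor_powers(matrix(1e-18, 5, ncol(rod$x)), w)
  expect_equal(max(mp$P_in), 0)              # frozen shape: no sliding
  expect_equal(max(mp$D_m), 0)
  p <- make_quick_beat(envelope_scale = 0.7)
  ser <- simulate_beat(p)
  w2 <- to_waveform(ser)
  m <- material_params()
  ma <- recover_active_moment(ser, w2, m)
  mp2 <- motor_powers(ma, w2)
  expect_true(all(mp2$P_in >= 0) && all(mp2$D_m >= 0))
  # constructed all-positive density: D_m = 0 and P_in integrates the density
  psidot <- flagkin:::time_deriv(w2$psi, w2$dt)
  n_s <- w2$n_s
  sl <- psidot
  sl[, 2:(n_s - 1)] <- (psidot[, 3:n_s] - psidot[, 1:(n_s - 2)]) / (2 * w2$ds)
  sl[, 1] <- (psidot[, 2] - psidot[, 1]) / w2$ds
  sl[, n_s] <- (psidot[, n_s] - psidot[, n_s - 1]) / w2$ds
  ma_pos <- sign(sl) * 1e-18
  mp3 <- motor_powers(ma_pos, w2)
  expect_equal(max(mp3$D_m), 0)
  dens <- abs(sl / 1e-6) * 1e-18
  h <- w2$ds * 1e-6
  oracle <- h * (rowSums(dens) - 0.5 * (dens[, 1] + dens[, n_s]))
  expect_equal(mp3$P_in, oracle, tolerance = 1e-10)
  expect_flagkin_error(motor_powers(ma[, 1:10], w2), "flagkin_grid_error")
})

test_that("cycle averages use integer periods and convert to fW", {
  expect_equal(cycle_average(rep(5e-13, 1000), f = 5, dt = 1 / 250), 500)
  tt <- (0:999) / 250
  zero_mean <- sin(2 * pi * 5 * tt)   # 1 W amplitude = 1e15 fW scale
  expect_lt(abs(cycle_average(zero_mean, 5, 1 / 250)), 1e-12 * 1e15)
  # 4.7-period record: integer-period mean beats the full-record mean
  f <- 4.7 / (940 / 250)                     # 4.7 periods in 940 frames
  x <- 1 + sin(2 * pi * f * (0:939) / 250)
  int_mean <- cycle_average(x, f, 1 / 250) / 1e15
  expect_equal(int_mean, 1, tolerance = 0.005)
  expect_gt(abs(mean(x) - 1), 0.01)
  expect_flagkin_error(cycle_average(x[1:30], f, 1 / 250),
                       "flagkin_insufficient_record")
})

test_that("the cycle-averaged motor ledger balances within 5%", {
  for (kind in c("flexible", "stiff-midpiece")) for (sc in c(0.5, 1.2)) {
    p <- beat_params(envelope_kind = kind, envelope_scale = sc,
                     beat_frequency = 5, duration = 2, fps = 250)
    pr <- energetics_profile(simulate_beat(p), f = 5)
    expect_lt(energy_balance_residual(pr), 0.05)
    expect_true(all(pr$averages >= 0))
  }
})

test_that("hydrodynamic dissipation scales quadratically in rate and size", {
  base <- make_transverse_oscillator(Y = 5, f = 4, duration = 1, fps = 250)
  dbl_Y <- make_transverse_oscillator(Y = 10, f = 4, duration = 1, fps = 250)
  dbl_f <- make_transverse_oscillator(Y = 5, f = 8, duration = 1, fps = 250)
  m <- material_params()
  d <- function(ser, f) cycle_average(
    hydrodynamic_dissipation(rft_velocity_and_force(ser, m), m)$total,
    f, 1 / 250)
  expect_equal(d(dbl_Y, 4) / d(base, 4), 4, tolerance = 0.01)
  expect_equal(d(dbl_f, 8) / d(base, 4), 4, tolerance = 0.02)
})

test_that("a vigorous wildtype-like beat lands at hundreds of fW motor input", {
  p <- beat_params(envelope_scale = 1.2, beat_frequency = 7,
                   duration = 2, fps = 250)
  pr <- energetics_profile(simulate_beat(p), f = 7)
  expect_gte(pr$averages[["P_in"]], 100)
  expect_lte(pr$averages[["P_in"]], 1000)
})

test_that("material parameters are validated", {
  expect_flagkin_error(material_params(EI = 0), "flagkin_invalid_parameter")
  expect_flagkin_error(material_params(xi_n = 1e-4),
                       "flagkin_invalid_parameter")
})
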