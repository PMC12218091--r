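# Energetics: resistive-force-theory hydrodynamics, Euler-Bernoulli
# elasticity, internal (inter-cross-section) friction, and recovery of the
# active (dynein) moment by quasi-static force balance. All computations are
# in SI units internally; cycle averages are reported in fW.

UM <- 1e-6  # um -> m

#' Material and drag parameters of the flagellum
#'
#' Literature-scale defaults; the power definitions fix the functional forms
#' while these coefficients set the absolute scale, so reported fW values are
#' parameter-dependent and comparisons across conditions are what carry
#' meaning.
#'
#' @param EI bending stiffness, N m^2.
#' @param eta_i internal friction coefficient, N m^2 s.
#' @param xi_t tangential drag per unit length, N s / m^2.
#' @param xi_n normal drag per unit length, N s / m^2 (>= xi_t).
#' @param a effective interfilament spacing, m.
#' @return object of class `material_params`.
#' @export
material_params <- function(EI = 2e-21, eta_i = 1e-22, xi_t = 0.7e-3,
                            xi_n = 2 * xi_t, a = 1.85e-7) {
  vals <- c(EI = EI, eta_i = eta_i, xi_t = xi_t, xi_n = xi_n, a = a)
  if (any(vals <= 0))
    stop_flagkin("all material parameters must be strictly positive",
                 "flagkin_invalid_parameter")
  if (xi_n < xi_t)
    stop_flagkin("xi_n must be >= xi_t", "flagkin_invalid_parameter")
  structure(as.list(vals), class = "material_params")
}

# central time differences (one-sided at the ends) of a frames x stations
# matrix; dt in s
time_deriv <- function(m, dt) {
  n_t <- nrow(m)
  if (n_t < 3L)
    stop_flagkin("need at least 3 frames for time derivatives",
                 "flagkin_grid_error")
  d <- m
  d[2:(n_t - 1), ] <- (m[3:n_t, ] - m[1:(n_t - 2), ]) / (2 * dt)
  d[1, ] <- (m[2, ] - m[1, ]) / dt
  d[n_t, ] <- (m[n_t, ] - m[n_t - 1, ]) / dt
  d
}

# unit tangents per frame/station by central differences in s
tangents_of <- function(series) {
  x <- series$x; y <- series$y
  n_s <- ncol(x)
  ip <- c(2:n_s, n_s); im <- c(1, 1:(n_s - 1))
  tx <- x[, ip] - x[, im]; ty <- y[, ip] - y[, im]
  nrm <- sqrt(tx^2 + ty^2)
  list(tx = tx / nrm, ty = ty / nrm)
}

#' Resistive-force-theory velocity and force-density fields
#'
#' Material-point velocities by central time differences, decomposed onto the
#' local tangent/normal; hydrodynamic force density
#' f_h = -(xi_t v_t t + xi_n v_n n) per unit length.
#'
#' @param series a `centerline_series` with at least 3 frames and uniform dt.
#' @param m a [material_params()].
#' @return an `rft_fields` list: `vt`, `vn` (m/s), `fx`, `fy` (N/m), unit
#'   tangents `tx`, `ty`, plus grid metadata.
#' @export
rft_velocity_and_force <- function(series, m = material_params()) {
  stopifnot(inherits(series, "centerline_series"))
  dt <- 1 / series$fps
  vx <- time_deriv(series$x * UM, dt)
  vy <- time_deriv(series$y * UM, dt)
  tg <- tangents_of(series)
  vt <- vx * tg$tx + vy * tg$ty
  vn <- -vx * tg$ty + vy * tg$tx
  ft <- -m$xi_t * vt
  fn <- -m$xi_n * vn
  fx <- ft * tg$tx - fn * tg$ty
  fy <- ft * tg$ty + fn * tg$tx
  structure(list(vt = vt, vn = vn, fx = fx, fy = fy,
                 tx = tg$tx, ty = tg$ty, s = series$s, ds = series$ds,
                 dt = dt), class = "rft_fields")
}

# row-wise trapezoid integral over stations, optionally restricted to a
# station mask (uniform spacing h in m)
row_trapz <- function(m, h, cols = NULL) {
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  h * (rowSums(m) - 0.5 * (m[, 1] + m[, n]))
}

#' Hydrodynamic dissipation with midpiece/principal split
#'
#' D_h(t) = integral of (xi_t v_t^2 + xi_n v_n^2) ds over the flagellum;
#' regional integrals over the head, midpiece and principal-piece windows.
#'
#' @param fields an `rft_fields` from [rft_velocity_and_force()].
#' @param m a [material_params()].
#' @param b a [section_boundaries()].
#' @return list with time series (W): `total`, `head`, `mid`, `principal`.
#' @export
hydrodynamic_dissipation <- function(fields, m = material_params(),
                                     b = section_boundaries()) {
  dens <- m$xi_t * fields$vt^2 + m$xi_n * fields$vn^2   # W/m
  h <- fields$ds * UM
  s <- fields$s
  region <- function(lo, hi) {
    cols <- which(s >= lo & s <= hi)
    if (length(cols) < 2) return(rep(0, nrow(dens)))
    row_trapz(dens, h, cols)
  }
  list(total = row_trapz(dens, h),
       head = region(0, b$edges[2]),
       mid = region(b$edges[2], b$edges[3]),
       principal = region(b$edges[3], b$edges[4]))
}

#' Internal dissipation D_i(t) = integral of eta_i kappadot^2 ds
#'
#' Friction between flagellar cross-sectional planes, modelled as viscous
#' resistance to the curvature rate.
#'
#' @param w a `waveform`.
#' @param m a [material_params()].
#' @param smooth_window Savitzky-Golay window (frames) for the curvature rate
#'   (0 disables smoothing).
#' @return numeric vector D_i(t) in W.
#' @export
internal_dissipation <- function(w, m = material_params(), smooth_window = 0) {
  kap <- curvature_kymograph(w)$kappa / UM       # 1/m
  kdot <- time_deriv(kap, w$dt)
  if (smooth_window >= 3 && nrow(kdot) >= smooth_window)
    kdot <- apply(kdot, 2, sg_smooth, window = smooth_window)
  row_trapz(m$eta_i * kdot^2, w$ds * UM)
}

#' Recover the active (dynein) moment by quasi-static force balance
#'
#' With inertia neglected and a free distal end, the internal contact force is
#' F(s,t) = -int_s^L f_h ds' and the internal moment (planar z-component) is
#' M(s,t) = -int_s^L (r(s') - r(s)) x f_h ds'. The active (motor) moment is
#' what remains after removing the elastic response, plus the interfilament
#' friction the motors must overcome at the sliding interface (friction acts
#' in series with the motors, so its sign is positive here):
#' m_a = M - EI kappa + eta_i kappadot. M(L) = F(L) = 0 hold by construction,
#' and this decomposition closes the motor energy ledger:
#' cycle-averaged P_in - D_m equals D_i + D_h.
#'
#' @param series a `centerline_series`.
#' @param w the matching `waveform` (same grid); built from `series` if NULL.
#' @param m a [material_params()].
#' @param fields optional precomputed [rft_velocity_and_force()] output.
#' @return matrix m_a (frames x stations, N m), with the internal moment in
#'   attribute `"M"`.
#' @export
recover_active_moment <- function(series, w = NULL, m = material_params(),
                                  fields = NULL) {
  if (is.null(w)) w <- to_waveform(series)
  if (is.null(fields)) fields <- rft_velocity_and_force(series, m)
  h <- series$ds * UM
  x <- series$x * UM; y <- series$y * UM
  fx <- fields$fx; fy <- fields$fy
  if (any(!is.finite(fx)) || any(!is.finite(fy)))
    stop_flagkin("numeric error: non-finite force density (tracing artifact)",
                 "flagkin_numeric_error")
  # reverse cumulative trapezoid along stations for each frame
  revcum <- function(mat) {
    n <- ncol(mat)
    inc <- 0.5 * h * (mat[, -1, drop = FALSE] + mat[, -n, drop = FALSE])
    cbind(t(apply(inc, 1, function(r) rev(cumsum(rev(r))))), 0)
  }
  Ix  <- revcum(fx)        # int_s^L fx ds'
  Iy  <- revcum(fy)
  Ixf <- revcum(x * fy - y * fx)   # int_s^L (x' fy' - y' fx') ds'
  M <- -(Ixf - x * Iy + y * Ix)
  kap <- curvature_kymograph(w)$kappa / UM
  kdot <- time_deriv(kap, w$dt)
  m_a <- M - m$EI * kap + m$eta_i * kdot
  if (any(!is.finite(m_a)))
    stop_flagkin("numeric error: non-finite active moment",
                 "flagkin_numeric_error")
  attr(m_a, "M") <- M
  m_a
}

#' Motor input and motor dissipation from the active moment
#'
#' The local motor power density is pi(s,t) = m_a * d(dpsi/dt)/ds. Motor
#' input P_in(t) integrates its positive part (power delivered by the dynein
#' motors to the flagellum); motor dissipation D_m(t) integrates the negative
#' part (power absorbed by the motors from other flagellar structures).
#'
#' @param m_a active-moment matrix from [recover_active_moment()].
#' @param w the matching `waveform`.
#' @return list with `P_in` and `D_m` time series in W.
#' @export
motor_powers <- function(m_a, w) {
  stopifnot(inherits(w, "waveform"))
  if (!all(dim(m_a) == dim(w$psi)))
    stop_flagkin("grid error: active moment and waveform grids differ",
                 "flagkin_grid_error")
  psidot <- time_deriv(w$psi, w$dt)
  n_s <- w$n_s
  h_um <- w$ds
  sl <- psidot
  sl[, 2:(n_s - 1)] <- (psidot[, 3:n_s] - psidot[, 1:(n_s - 2)]) / (2 * h_um)
  sl[, 1] <- (psidot[, 2] - psidot[, 1]) / h_um
  sl[, n_s] <- (psidot[, n_s] - psidot[, n_s - 1]) / h_um
  sl <- sl / UM                      # d(psidot)/ds in 1/(m s)
  dens <- m_a * sl                   # W/m
  h <- w$ds * UM
  list(P_in = row_trapz(pmax(dens, 0), h),
       D_m = row_trapz(pmax(-dens, 0), h))
}

#' Average power time series over an integer number of beat cycles
#'
#' Means are taken over the integer number of periods of `f` nearest the
#' record length (at least one), and converted from W to fW.
#'
#' @param x numeric power time series in W.
#' @param f beat frequency in Hz.
#' @param dt frame interval in s.
#' @return cycle-averaged power in fW.
#' @export
cycle_average <- function(x, f, dt) {
  T_rec <- length(x) * dt
  if (T_rec * f < 1)
    stop_flagkin("insufficient record: shorter than one beat period",
                 "flagkin_insufficient_record")
  samples_per <- 1 / (f * dt)
  n_per <- round(T_rec * f)
  if (round(n_per * samples_per) > length(x)) n_per <- n_per - 1L
  n_use <- max(1L, round(n_per * samples_per))
  mean(x[seq_len(n_use)]) * 1e15
}

#' Full energetics profile of a recording
#'
#' Chains [rft_velocity_and_force()], [hydrodynamic_dissipation()],
#' [internal_dissipation()], [recover_active_moment()] and [motor_powers()],
#' and reports cycle averages (fW) when a beat frequency is supplied.
#'
#' @param series a `centerline_series`.
#' @param w matching `waveform` (built from `series` if NULL).
#' @param m a [material_params()].
#' @param b a [section_boundaries()].
#' @param f beat frequency in Hz for cycle averaging (NA skips averages).
#' @param smooth_window Savitzky-Golay window (frames) applied to the
#'   coordinate time series before any derivative is taken; controls noise
#'   amplification in curvature and sliding rates on traced recordings
#'   (0 disables; identities between the power terms are unaffected because
#'   the smoothing is applied to the input series once).
#' @return object of class `energetics_profile` with time series (W) and
#'   `averages` (fW).
#' @export
energetics_profile <- function(series, w = NULL, m = material_params(),
                               b = section_boundaries(), f = NA,
                               smooth_window = 5) {
  if (smooth_window >= 3 && nrow(series$x) >= smooth_window) {
    series$x <- apply(series$x, 2, sg_smooth, window = smooth_window)
    series$y <- apply(series$y, 2, sg_smooth, window = smooth_window)
    w <- NULL
  }
  if (is.null(w)) w <- to_waveform(series)
  fields <- rft_velocity_and_force(series, m)
  Dh <- hydrodynamic_dissipation(fields, m, b)
  Di <- internal_dissipation(w, m)
  m_a <- recover_active_moment(series, w, m, fields)
  mp <- motor_powers(m_a, w)
  averages <- NULL
  if (is.finite(f)) {
    dt <- 1 / series$fps
    averages <- c(P_in = cycle_average(mp$P_in, f, dt),
                  D_m = cycle_average(mp$D_m, f, dt),
                  D_i = cycle_average(Di, f, dt),
                  D_h = cycle_average(Dh$total, f, dt),
                  D_h_mid = cycle_average(Dh$mid, f, dt),
                  D_h_principal = cycle_average(Dh$principal, f, dt))
  }
  structure(list(P_in = mp$P_in, D_m = mp$D_m, D_i = Di,
                 D_h = Dh$total, D_h_head = Dh$head, D_h_mid = Dh$mid,
                 D_h_principal = Dh$principal,
                 dt = 1 / series$fps, f = f, averages = averages),
            class = "energetics_profile")
}

#' @export
print.energetics_profile <- function(x, ...) {
  cat(sprintf("Energetics profile: %d frames (dt = %g s)\n",
              length(x$P_in), x$dt))
  if (!is.null(x$averages)) {
    cat("  cycle averages (fW):\n")
    for (nm in names(x$averages))
      cat(sprintf("    %-14s %.3g\n", nm, x$averages[[nm]]))
  }
  invisible(x)
}

#' Cycle-averaged energy-balance residual
#'
#' On an integer number of beat cycles elastic storage averages to zero, so
#' <P_in> - <D_m> should equal <D_i> + <D_h>. Returns the relative residual
#' |(<P_in> - <D_m>) - (<D_i> + <D_h>)| / (<D_i> + <D_h>).
#'
#' @param profile an `energetics_profile` with cycle averages.
#' @return relative residual (dimensionless).
#' @export
energy_balance_residual <- function(profile) {
  a <- profile$averages
  if (is.null(a))
    stop_flagkin("profile has no cycle averages (f was NA)",
                 "flagkin_invalid_parameter")
  lhs <- a[["P_in"]] - a[["D_m"]]
  rhs <- a[["D_i"]] + a[["D_h"]]
  abs(lhs - rhs) / rhs
}
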