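# Shape-mode decomposition of the tangent-angle waveform and the B1-B2
# shape-cycle circularity score.

#' Fit dominant shape modes of a waveform
#'
#' Subtracts the time-mean tangent-angle profile and takes the singular value
#' decomposition of the centered (time x arclength) matrix. Modes are the
#' right singular vectors, orthonormal under the ds-weighted inner product;
#' coefficients B_k(t) are the projections of each frame onto the modes;
#' variance explained comes from the squared singular values.
#'
#' @param w a `waveform`.
#' @param K number of modes to retain (default 2: the B1-B2 shape cycle).
#' @return a `shape_cycle`: list with `basis` (stations x K), `coefficients`
#'   (frames x K), `variance_explained`, `s`, `ds`, `dt`.
#' @export
fit_shape_modes <- function(w, K = 2) {
  stopifnot(inherits(w, "waveform"))
  if (w$n_t <= K)
    stop_flagkin("need more frames than modes", "flagkin_invalid_parameter")
  M <- sweep(w$psi, 2, colMeans(w$psi))
  sv <- svd(M)
  tot <- sum(sv$d^2)
  if (tot < 1e-20)
    stop_flagkin("rank error: waveform is constant in time",
                 "flagkin_rank_error")
  basis <- sv$v[, seq_len(K), drop = FALSE] / sqrt(w$ds)
  coeff <- M %*% basis * w$ds        # = U D sqrt(ds)
  ve <- sv$d^2 / tot
  structure(list(basis = basis, coefficients = coeff,
                 variance_explained = ve[seq_len(K)],
                 singular_values = sv$d, s = w$s, ds = w$ds, dt = w$dt),
            class = "shape_cycle")
}

#' @export
print.shape_cycle <- function(x, ...) {
  cat(sprintf("Shape cycle: %d modes over %d frames\n",
              ncol(x$basis), nrow(x$coefficients)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot the B1-B2 shape cycle
#' @param x a `shape_cycle`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_cycle <- function(x, ...) {
  B <- x$coefficients
  plot(B[, 1], B[, 2], type = "l", xlab = expression(B[1]),
       ylab = expression(B[2]), asp = 1, ...)
  invisible(x)
}

#' Shape-cycle circularity score
#'
#' Whitens (B1, B2) to unit covariance and scores the cycle as
#' `1 - sd(radius)/mean(radius)`, clipped to [0, 1]. A perfect circle scores
#' 1; irregular, beat-to-beat-variable cycles score lower. Collinear or
#' zero-variance coefficients are degenerate (no cycle area).
#'
#' @param B1,B2 coefficient time series of the two dominant modes, or a
#'   `shape_cycle` as `B1` with `B2` missing.
#' @return circularity score in [0, 1].
#' @export
shape_cycle_circularity <- function(B1, B2 = NULL) {
  if (inherits(B1, "shape_cycle")) {
    B2 <- B1$coefficients[, 2]
    B1 <- B1$coefficients[, 1]
  }
  stopifnot(length(B1) == length(B2), length(B1) >= 8)
  B <- cbind(B1 - mean(B1), B2 - mean(B2))
  C <- crossprod(B) / (nrow(B) - 1)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * ev$values[1] || ev$values[1] <= 0)
    stop_flagkin("degenerate cycle: coefficients are collinear or constant",
                 "flagkin_degenerate_cycle")
  Wh <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Z <- B %*% Wh
  r <- sqrt(rowSums(Z^2))
  max(0, min(1, 1 - sd(r) / mean(r)))
}
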